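Package: genecensus
Title: Assembly-Free Gene-Centric Census of Metagenomes with Profile HMMs
    and Phylogenetic Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the per-genome abundance of a gene family in
    unassembled shotgun metagenome reads without assembly. Reference gene
    families are curated (fragment removal, greedy redundancy clustering,
    conserved-motif checks), nucleotide profile hidden Markov models are
    built from reference alignments and used to search reads through a
    staged MSV/Viterbi/Forward filter cascade with empirically calibrated
    E-values, candidate reads are confirmed by six-frame translation
    against the protein-level family model, confirmed reads are placed on
    a reference phylogeny by maximum-likelihood edge attachment, and
    abundance is reported as percent genome equivalents using
    size-normalized counts of the universal single-copy genes recA, atpD,
    gyrB and rpoB. A synthetic-data generator with known ground truth
    makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
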