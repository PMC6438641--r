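---
title: "Methods: an assembly-free, gene-centric metagenome census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an assembly-free, gene-centric metagenome census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Shotgun metagenomes sample DNA fragments from whole communities. For a
gene family of interest — here motivated by the bacterial non-specific
acid phosphatases (NSAP classes A, B and C), enzymes that release
phosphate from diverse organic phosphoesters — two questions recur: *how
abundant is the family per genome*, and *which phylogenetic variants
("ecotypes") carry it*? Assembling short reads first discards rare
variants and biases abundance, so this package takes the assembly-free,
gene-centric route: every unassembled read is interrogated directly
against a reference model of the family, confirmed at the protein level,
placed on a reference phylogeny, and counted relative to universal
single-copy genes.

The pipeline is: **curate** a reference set → **build** nucleotide
profile HMMs → **calibrate** their null score distributions → **trim**
reads → **search** them through a staged filter cascade → **confirm** by
six-frame translation against the protein-level model → **place**
confirmed reads on the reference tree → report **abundance** as percent
genome equivalents (%GE).

## Reference-set curation

Curation starts from a user-supplied FASTA of family members with a
designated archetype (harvesting homologs from live databases is out of
scope). Three steps:

* **Fragment removal.** A record shorter than 70% of the archetype
  length is a fragment; the inequality is strict, so a record at exactly
  70% is retained.
* **Motif verification.** The NSAP classes carry conserved motifs
  (class A `K-X6-RP …​ PSGH …​ SR-X5-H-X2-D`; class B
  `P-X4-FDIDDT-X-VLFSSP-X-F` and `YGD(S/A)DXD-X3-A`; class C `DXDET` and
  `GD-X3-DF`). `scan_motif()` matches ordered literal/wildcard elements
  with bounded spacers, leftmost-first with minimal spacers. Because the
  motifs are descriptive rather than diagnostic, records that fail are
  *flagged* by default, not dropped (`motif_policy = "drop"` reverses
  this).
* **Redundancy removal.** Greedy clustering in decreasing length order
  (ties by id): a sequence joins the first representative it matches at
  ≥ 95% identity, else founds a cluster. Identity is identical aligned
  residues over the shorter sequence length under global alignment — the
  convention of the usual greedy clustering tools. The literature source
  for this workflow names no threshold; 0.95 is this package's default
  and is configurable.

## The profile HMM and its scoring model

`build_phmm()` turns a reference alignment into a profile HMM over
match/insert/delete states. Columns with ≥ 50% residues become match
states (configurable). Emissions receive additive pseudocounts (+1 for
DNA, +0.1 for protein); transitions receive a light +0.05 — a heavy
transition pseudocount on a 10-row ungapped alignment would put >10% of
per-node probability on indels and silently tax every match step by
~0.35 bits, crippling 150-step read alignments. Sequence weighting is
uniform.

The search architecture is **uni-hit local**: entry from begin into any
match state with probability 1/L, exit from match state *k* with
probability `eps_k = 1/(L−k+1)` (so the model always terminates and exit
at node L is certain), core transitions scaled by `1−eps_k`, and deletes
allowed to run through to node L. This makes the model a *proper
generative process* — every score the package reports can be checked
against exhaustive path enumeration, and `sample_from_hmm()` can draw
positive-control reads from it. Scores are log2-odds against an i.i.d.
background over subpaths that emit at least one match residue; the empty
sequence scores 0 and an impossible sequence −∞. One consequence of the
position-dependent exit is that scores are not exactly invariant under
jointly reverse-complementing model and read; strand symmetry of
*detection* is instead guaranteed by searching both strands explicitly.

Three scorers share this model:

* **MSV** — the match-only multi-segment filter: no inserts/deletes,
  segments chained through cost-free re-entry. On a model whose indel
  probabilities are zero it coincides with Viterbi.
* **Viterbi** — best single local alignment path, log space.
* **Forward** — total path probability, computed in scaled linear space
  (per-row rescaling; no per-cell log-sum-exp).

### Calibration and E-values

`calibrate()` scores `n_shuffles` (default 200) i.i.d. background
sequences of a representative length (150 nt for DNA — a typical short
read — and 50 residues for protein models, a translated read frame) and
fits a Gumbel law per stage. The fitting method is stage-specific by
design: the MSV and Viterbi stages use maximum likelihood, which tracks
the distribution body best — and their P-value thresholds (0.02, 0.001)
lie inside the observable range of a 200-draw sample. The Forward
stage's E-value cutoff extrapolates to P ≈ 1e-9; the Forward null is
right-skewed relative to a Gumbel, so a body-optimal fit underestimates
that far tail (in testing, it admitted bursts of false positives from
single high-scoring background loci). The moment estimator's
skew-inflated scale is the conservative extrapolation and is used for
Forward. P-values are upper tails of the fitted law;
`E = P_forward × db_size` with `db_size` = the number of reads searched
(each read record counted once; paired mates are not tracked). The
cascade thresholds are the standard staged-filter settings: P ≤ 0.02
(MSV), ≤ 0.001 (Viterbi), ≤ 1e-5 (Forward), and a final full-length
E < 1e-5.

### Numerical engineering

The exact kernels are double precision and are what `phmm_viterbi()`,
`phmm_forward()`, `phmm_msv()` and calibration use. Inside
`search_reads()` the per-read work is dominated by reads that are
nowhere near any threshold, so the cascade first consults quantized
mirrors — an int16 saturating-arithmetic MSV (1/256-bit units) and
float Viterbi/Forward — and falls back to the double kernel whenever a
score lands within 1 bit (MSV screen) or 0.5 bits (float mirrors) of the
stage threshold. Quantization error is bounded well below these margins,
so the survivor set is identical to the all-double computation (verified
directly in the tests).

## Read preparation and confirmation

`trim_reads()` scans 5'→3' with a 4-base window; at the first window
whose mean Phred quality falls below 25 the read is cut at the window
start and then extended through immediately following bases that
individually pass the threshold — the common convention of 5'-scan
trimmers, whose dialect the source methods do not specify. Reads shorter
than 70 nt after cutting are dropped.

`confirm_hits()` translates each cascade survivor in all six frames
(standard code; stops retained as `*`, N-containing codons as `X`) and
requires at least one frame to reach E < 1e-5 against the family's
*protein* model. Stops and `X` score as background emissions — never a
match bonus. Translations are not split at stop codons before scoring
(the original workflow's behavior is unstated; splitting is not
implemented as the unsplit forward score already treats stop-crossing
frames fairly). Confirmation is against the curated family model only;
the original confirmation searched a comprehensive protein database, but
its accept condition — "a hit of the appropriate family" — is the same.

## Phylogenetic placement

The reference tree is canonically rooted on the pendant edge of the
alphabetically first leaf and edges are numbered in preorder, so edge
numbering is reproducible across runs and serializations. A read is
projected onto the model's match columns through its Viterbi path
(insert residues dropped, unvisited columns gapped), which puts reads
and reference alignment in one coordinate system.

`edge_likelihood()` attaches the query at the *midpoint* of an edge by a
pendant branch and computes the likelihood by the pruning recursion
under JC69 (K80 with fixed kappa optional); query gap columns are
missing data and contribute factor 1. `place_read()` scans every edge,
optimizing only the pendant length (bounded golden-section search on
[1e-6, 5], tolerance 1e-4, with the default pendant 0.1 also evaluated
as a safeguard); attachment position along the edge is fixed at the
midpoint — full two-dimensional optimization buys little at read length
and is a non-goal. Likelihood-weight ratios are the softmax of per-edge
optimized log-likelihoods over the full edge set; ties break toward the
lowest edge id; edges within 3 log units of the best are reported,
capped at 7, in jplace (version 3) format.

Ecotypes — accumulations of placed reads on one edge — are counted per
(sample, edge) from each read's best edge by default;
`count_mode = "spread_lwr"` instead spreads each read across its
reported edges by likelihood weight (how the original figures resolved
multi-edge placements is unstated, so both modes are exposed).
Normalization to the maximum cell is available to mirror the common
presentation.

## Abundance as percent genome equivalents

The number of genomes sampled by a read set is estimated from four
universal single-copy genes (*recA*, *atpD*, *gyrB*, *rpoB*). Longer
genes catch proportionally more reads, so counts are size-normalized to
the shortest gene: each count is multiplied by
`modal_length(recA) / modal_length(gene)`, with reference modal lengths
1044, 1422, 2415 and 4029 nt. Genome equivalents (GE) are the arithmetic
mean of the four normalized counts; all four genes are required by
default (a missing gene is a hard error, since GE is defined on the full
panel).

The published %GE formula ("target gene count · read length / mean
normalized single-copy counts") is dimensionally ambiguous, so three
documented interpretations are implemented and the mode is recorded in
every report:

* `length_ratio` (default): `100 · count · (L_recA / L_target) / GE` —
  the target count is size-normalized exactly like the single-copy
  counts. Under this mode a gene carried by p% of genomes is estimated
  as p %GE, which is the spike-in recovery property the tests verify.
* `ratio`: `100 · count / GE`.
* `literal`: `100 · count · mean_read_length / GE`, the formula read at
  face value.

The mean read length is the arithmetic mean of trimmed read lengths.

## The synthetic-data generator

Real soil and marine metagenomes run to tens of millions of reads and
cannot ship with a package, so every stage is exercised on synthetic
communities with known ground truth:

* **Taxon tree**: pure-birth topology; branch lengths
  `0.03 + Exp(mean 0.05)` substitutions/site. The floor prevents
  effectively-zero edges that would make sister taxa unresolvable by any
  method; the resulting leaf-to-leaf divergences (roughly 0.1–0.5)
  represent a moderately diverged gene family.
* **Gene families**: each family evolves independently on the shared
  taxon tree by site-independent JC69 from a random root — vertical
  descent, no indels, so the true alignment is the ungapped stack of
  leaf sequences. Default lengths are mini-gene stand-ins: 450, 540,
  630, 720 nt for the four single-copy normalizers and 600 nt for the
  target. The ordering mirrors the real genes (recA shortest, rpoB
  longest); the target length sits near the harmonic mean of the
  single-copy lengths so that read-end effects cancel from the %GE
  ratio. The target root is built stop-free in frame +1 so the protein
  confirmation model is meaningful.
* **Community**: every genome carries one copy of each single-copy
  gene; the target family is carried by designated taxa whose summed
  relative abundance is the spike-in fraction (default one carrier at
  2%).
* **Reads**: single-end 150 nt (the pipeline treats paired mates
  independently, so single-end simulation loses nothing), drawn from
  gene loci embedded in 150 nt random flanks with probability
  proportional to abundance × copy number × available start positions;
  50% reverse-complemented; i.i.d. substitution errors at 0.005 per
  base (a conservative short-read error rate); constant Q35 qualities by
  default, with a degrading-tail profile available to exercise trimming.
  60% of reads come from background filler sequence, so most reads are
  non-target.

What the generator does *not* emulate: indel sequencing errors, quality-
dependent error profiles, GC and coverage bias, horizontal transfer
(gene trees equal the taxon tree), genome-scale context, and real
inter-family homology. Passing tests therefore demonstrate correctness
of the machinery and calibration of the statistics under the model's
assumptions — not performance on real soil metagenomes, where divergence
from references, composition bias and contamination add error the
synthetic benchmark cannot see.

## Problem sizes used by the test suite

The spike-in benchmark runs 10 taxa × 100,000 reads across 10 seeds and
recovers 2.0 %GE within three simulation standard errors; placement
recovery uses a 16-leaf tree and 100 error-free reads at 0.04
divergence; calibration checks use 200 null draws and 4,000 background
reads; determinism is checked byte-for-byte on a 15,000-read community.
DP and likelihood oracles run on instances small enough to enumerate
exhaustively (models of ≤ 5 states against reads of ≤ 8 nt; trees of
≤ 5 leaves), where enumeration is exact and fast.

## Known limitations

* JC69/K80 only; no gamma rate heterogeneity or richer nucleotide
  models for placement.
* Uni-hit local alignment; glocal and multi-hit core modes (beyond the
  MSV filter) are not implemented.
* Empirical Gumbel calibration extrapolates into the far tail when
  E-value cutoffs demand P ≈ 1e-10; this is adequate for filtering
  (true hits sit orders of magnitude above threshold) but reported
  far-tail P-values are extrapolations, not measurements.
* Scores are not exactly strand-reversal invariant (see above);
  detection is, because both strands are searched.
* The ecotype tables are exported for downstream community statistics;
  ordination and multiple-comparison procedures are deliberately left
  to dedicated statistics software.
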