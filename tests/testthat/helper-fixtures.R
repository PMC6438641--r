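# Shared fixtures, built once per test run (everything is generated in
# code; nothing is read from disk).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small synthetic metagenome shared by readprep/pipeline tests
fix_sim_small <- function() {
  fixture("sim_small", simulate_metagenome(
    n_taxa = 6,
    gene_lengths = c(target = 300L, recA = 240L, atpD = 270L,
                     gyrB = 330L, rpoB = 360L),
    config = sim_config(n_reads = 4000), seed = 11))
}

# calibrated nucleotide model of the small target family
fix_hmm_small <- function() {
  fixture("hmm_small", {
    sim <- fix_sim_small()
    calibrate(build_phmm(sim$families$target$msa), 200, seed = 21)
  })
}

# protein alignment of a DNA family (frame +1 translation of every leaf)
translate_leaves <- function(leaf_seqs) {
  as_msa(vapply(leaf_seqs, function(s) {
    six_frame_translate(s)$peptide[1]
  }, ""), alphabet = "protein")
}

random_dna <- function(len, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""))
}

random_reads_df <- function(n, len, seed) {
  with_seed(seed, {
    data.frame(id = sprintf("bg%05d", seq_len(n)),
               seq = vapply(seq_len(n), function(i) {
                 paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
               }, ""),
               stringsAsFactors = FALSE)
  })
}
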