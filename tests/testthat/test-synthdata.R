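# Synthetic trees, sequence evolution, communities and read sets with
# ground truth.

test_that("simulated trees have the expected shape and are seed-reproducible", {
  t2 <- simulate_tree(2, seed = 5)
  expect_identical(length(t2$tip.label), 2L)

  t16 <- simulate_tree(16, seed = 5)
  expect_identical(length(t16$tip.label), 16L)
  expect_identical(nrow(t16$edge), 30L)  # 2n - 2 edges, rooted binary
  expect_true(all(t16$edge.length >= 0.03))

  again <- simulate_tree(16, seed = 5)
  expect_identical(ape::write.tree(t16), ape::write.tree(again))
  other <- simulate_tree(16, seed = 6)
  expect_false(ape::write.tree(t16) == ape::write.tree(other))
})

test_that("JC69 evolution matches its closed-form divergence", {
  # zero-length branches copy sequences unchanged
  tr0 <- simulate_tree(4, seed = 7)
  tr0$edge.length[] <- 0
  fam0 <- evolve_sequences(tr0, 200, seed = 8)
  expect_identical(length(unique(fam0$leaf_seqs)), 1L)

  # saturating branches approach 0.75 observed divergence
  trL <- simulate_tree(2, seed = 9)
  trL$edge.length[] <- 25
  famL <- evolve_sequences(trL, 3000, seed = 10)
  dL <- 1 - hamming_identity(famL$leaf_seqs[[1]], famL$leaf_seqs[[2]])
  expect_lt(abs(dL - 0.75), 3 * sqrt(0.75 * 0.25 / 3000))

  # intermediate distance: observed divergence within 3 SE of the JC69
  # expectation p = 3/4 (1 - exp(-4d/3)) for the leaf-to-leaf path length
  trM <- simulate_tree(2, seed = 11)
  trM$edge.length <- c(0.07, 0.13)
  famM <- evolve_sequences(trM, 1000, seed = 12)
  d <- sum(trM$edge.length)
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  p_obs <- 1 - hamming_identity(famM$leaf_seqs[[1]], famM$leaf_seqs[[2]])
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1000))

  # seeded reproducibility
  expect_identical(evolve_sequences(trM, 100, seed = 13)$leaf_seqs,
                   evolve_sequences(trM, 100, seed = 13)$leaf_seqs)

  # stop-free roots translate without stops in frame +1
  tr <- simulate_tree(3, seed = 14)
  fam <- evolve_sequences(tr, 300, seed = 15, stop_free_root = TRUE)
  root_pep <- six_frame_translate(substr(fam$leaf_seqs[[1]], 1, 300))
  expect_lt(lengths(regmatches(root_pep$peptide[1],
                               gregexpr("\\*", root_pep$peptide[1]))), 12)
})

test_that("community specs put the target in the stated fraction of genomes", {
  taxa <- sprintf("taxon%02d", 1:10)
  cm <- community_spec(taxa, target_fraction = 0.02)
  expect_equal(sum(cm$abundance), 1)
  expect_equal(sum(cm$abundance[cm$target_copy == 1L]), 0.02)
  expect_identical(sum(cm$target_copy), 1L)

  cm2 <- community_spec(taxa, target_fraction = 0.3, carriers = c(2, 5))
  expect_equal(sum(cm2$abundance[cm2$target_copy == 1L]), 0.3)
  expect_error(community_spec(taxa, target_fraction = 0))
})

test_that("fragmented reads are exact locus substrings when error-free", {
  sim <- simulate_metagenome(
    n_taxa = 4,
    gene_lengths = c(target = 210L, recA = 180L, atpD = 240L,
                     gyrB = 270L, rpoB = 300L),
    config = sim_config(n_reads = 600, error_rate = 0,
                        background_fraction = 0.3),
    seed = 31)
  expect_identical(nrow(sim$reads), 600L)
  expect_identical(nrow(sim$truth), 600L)
  expect_identical(sim$reads$id, sim$truth$read_id)

  # every gene-origin read is a substring of its source gene locus
  # (up to strand); spot-check reads fully inside the gene
  inside <- which(sim$truth$gene != "background" &
                    sim$truth$gene_overlap == 150L)
  expect_gt(length(inside), 10)
  for (i in head(inside, 20)) {
    g <- sim$truth$gene[i]
    tx <- sim$truth$taxon[i]
    src <- sim$families[[g]]$leaf_seqs[[tx]]
    rd <- sim$reads$seq[i]
    if (sim$truth$strand[i] == "-") rd <- revcomp(rd)
    expect_true(grepl(rd, src, fixed = TRUE))
  }

  # strand assignment is a fair coin
  minus <- mean(sim$truth$strand == "-")
  expect_lt(abs(minus - 0.5), 3 * sqrt(0.25 / 600))

  # background fraction honored within binomial error
  bgf <- mean(sim$truth$gene == "background")
  expect_lt(abs(bgf - 0.3), 3 * sqrt(0.3 * 0.7 / 600))

  # same seed, same reads
  sim2 <- simulate_metagenome(
    n_taxa = 4,
    gene_lengths = c(target = 210L, recA = 180L, atpD = 240L,
                     gyrB = 270L, rpoB = 300L),
    config = sim_config(n_reads = 600, error_rate = 0,
                        background_fraction = 0.3),
    seed = 31)
  expect_identical(sim$reads, sim2$reads)
})

test_that("sequencing errors hit at the configured rate", {
  sim <- fix_sim_small()
  inside <- which(sim$truth$gene == "target" & sim$truth$gene_overlap == 150L)
  mm <- vapply(head(inside, 50), function(i) {
    src <- sim$families$target$leaf_seqs[[sim$truth$taxon[i]]]
    rd <- sim$reads$seq[i]
    if (sim$truth$strand[i] == "-") rd <- revcomp(rd)
    st <- sim$truth$start[i] - sim$config$flank
    1 - hamming_identity(rd, substr(src, st, st + 149))
  }, 0)
  rate <- mean(mm)
  # errors substitute to one of the three other bases, so every error is
  # observable; allow 3 SE on the mean mismatch rate
  expect_lt(abs(rate - sim$config$error_rate),
            3 * sqrt(sim$config$error_rate / (50 * 150)) + 1e-3)

  # degrading quality profile produces falling tail qualities
  cfgd <- sim_config(n_reads = 10, quality = "degrading")
  q <- genecensus:::qual_string(cfgd)
  qv <- utf8ToInt(q) - 33L
  expect_identical(qv[1], 38L)
  expect_lt(qv[150], 25L)
})

test_that("simulation files round-trip through standard formats", {
  sim <- simulate_metagenome(
    n_taxa = 3,
    gene_lengths = c(target = 150L, recA = 120L, atpD = 150L,
                     gyrB = 180L, rpoB = 210L),
    config = sim_config(n_reads = 50), seed = 91)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  reads <- read_reads(file.path(dir, "reads.fastq"))
  expect_identical(reads$seq, sim$reads$seq)
  expect_identical(reads$qual, sim$reads$qual)
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, sim$tree$tip.label)
  aln <- read_msa(file.path(dir, "target_aln.fasta"))
  expect_identical(length(aln$seqs), 3L)
  cm <- yaml::read_yaml(file.path(dir, "community.yaml"))
  expect_equal(sum(unlist(cm$abundance)), 1)
  truth <- read.table(file.path(dir, "truth.tsv"), sep = "\t", header = TRUE)
  expect_identical(nrow(truth), 50L)
})
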