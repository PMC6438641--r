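# Phylogenetic placement: pruning likelihoods vs ancestral-state
# enumeration, read projection, ML edge attachment, ecotype aggregation,
# jplace output.

# tiny reference: tree + ungapped alignment evolved on it
make_ref <- function(n_leaves, ncol, seed, bl_mean = 0.15, bl_min = 0.02) {
  tree <- simulate_tree(n_leaves, bl_mean = bl_mean, bl_min = bl_min,
                        seed = seed)
  fam <- evolve_sequences(tree, ncol, seed = seed + 1)
  list(tree = tree, aln = fam$msa, seqs = fam$leaf_seqs)
}

test_that("edge likelihoods equal brute-force ancestral-state enumeration", {
  for (rep in 1:6) {
    ref <- make_ref(sample(3:5, 1), 12, seed = 900 + rep)
    eng <- placement_engine(ref$tree, setNames(ref$seqs, names(ref$seqs)))
    qsrc <- ref$seqs[[sample(length(ref$seqs), 1)]]
    q <- strsplit(qsrc, "")[[1]]
    gap_at <- sample(nchar(qsrc), 4)
    q[gap_at] <- "-"
    edge_id <- sample(nrow(eng$edge), 1)
    pend <- runif(1, 0.01, 0.6)
    expect_equal(edge_likelihood(eng, q, edge_id, pend),
                 brute_edge_loglik(eng, q, edge_id, pend),
                 tolerance = 1e-8)
  }
  set.seed(NULL)
})

test_that("leaf missing data is handled as a uniform partial likelihood", {
  ref <- make_ref(4, 10, seed = 950)
  seqs <- ref$seqs
  sub <- strsplit(seqs[[2]], "")[[1]]
  sub[3:5] <- "N"
  seqs[[2]] <- paste(sub, collapse = "")
  eng <- placement_engine(ref$tree, seqs)
  q <- strsplit(ref$seqs[[1]], "")[[1]]
  expect_equal(edge_likelihood(eng, q, 2, 0.05),
               brute_edge_loglik(eng, q, 2, 0.05), tolerance = 1e-8)
})

test_that("an infinite pendant branch detaches the query (JC69 stationary limit)", {
  ref <- make_ref(4, 20, seed = 911)
  eng <- placement_engine(ref$tree, ref$seqs)
  q <- strsplit(ref$seqs[[1]], "")[[1]]
  ll_inf <- edge_likelihood(eng, q, 3, 60)
  # per non-gap column the query factor tends to 1/4 times the
  # reference-tree column likelihood
  ref_cols <- sum(log(colSums(eng$amat[[3]])))
  expect_equal(ll_inf, ref_cols + 20 * log(0.25), tolerance = 1e-6)
  expect_error(edge_likelihood(eng, q, 3, -0.1), "pendant")
  expect_error(edge_likelihood(eng, rep("-", 20), 3, 0.1), "non-gap")
})

test_that("a query identical to a leaf prefers that leaf's pendant edge", {
  ref <- make_ref(4, 400, seed = 921)
  eng <- placement_engine(ref$tree, ref$seqs)
  leaf <- ref$tree$tip.label[2]
  q <- strsplit(ref$seqs[[leaf]], "")[[1]]
  leaf_node <- match(leaf, eng$tree$tip.label)
  leaf_edge <- eng$edge$edge_id[eng$edge$child == leaf_node]
  ll_leaf <- edge_likelihood(eng, q, leaf_edge, 1e-6)
  for (e in setdiff(eng$edge$edge_id, leaf_edge)) {
    expect_gte(ll_leaf, edge_likelihood(eng, q, e, 1e-6))
  }
  pl <- place_read(eng, q)
  expect_identical(pl$edge_id[1], leaf_edge)
  # lwr sums to 1 over the full edge set; reported runner-ups capped
  expect_lte(nrow(pl), 7L)
  expect_lte(sum(pl$like_weight_ratio), 1 + 1e-9)
  expect_true(all(diff(pl$log_likelihood) <= 0))
  expect_true(all(pl$log_likelihood >= pl$log_likelihood[1] - 3))
})

test_that("the pendant optimizer never loses to the default pendant 0.1", {
  ref <- make_ref(5, 60, seed = 931)
  eng <- placement_engine(ref$tree, ref$seqs)
  q <- strsplit(ref$seqs[[3]], "")[[1]]
  pl <- place_read(eng, q)
  for (i in seq_len(nrow(pl))) {
    expect_gte(pl$log_likelihood[i] + 1e-9,
               edge_likelihood(eng, q, pl$edge_id[i], 0.1))
  }
})

test_that("two identical sister leaves split the placement weight evenly", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.3,(C:0.2,D:0.2):0.3);")
  seqA <- random_dna(300, seed = 77)
  seqs <- c(A = seqA, B = seqA,
            C = paste(rev(strsplit(seqA, "")[[1]]), collapse = ""),
            D = random_dna(300, seed = 78))
  eng <- placement_engine(tr, seqs)
  q <- strsplit(seqA, "")[[1]]
  pl <- place_read(eng, q)
  ntip <- length(eng$tree$tip.label)
  eA <- eng$edge$edge_id[eng$edge$child == match("A", eng$tree$tip.label)]
  eB <- eng$edge$edge_id[eng$edge$child == match("B", eng$tree$tip.label)]
  lwrA <- pl$like_weight_ratio[pl$edge_id == eA]
  lwrB <- pl$like_weight_ratio[pl$edge_id == eB]
  expect_gt(length(lwrA), 0)
  expect_gt(length(lwrB), 0)
  expect_true(lwrA > 0.2 && lwrA < 0.7)
  expect_equal(lwrA, lwrB, tolerance = 0.05)
})

test_that("two-leaf trees place trivially with all weight on the two half-edges", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.3);")
  seqs <- c(A = random_dna(120, seed = 81), B = random_dna(120, seed = 82))
  eng <- placement_engine(tr, seqs)
  expect_identical(nrow(eng$edge), 2L)
  pl <- place_read(eng, strsplit(seqs[["A"]], "")[[1]])
  expect_equal(sum(pl$like_weight_ratio), 1, tolerance = 1e-9)
  expect_identical(pl$rank[1], 1L)
})

test_that("reads project onto match columns through their Viterbi path", {
  sim <- fix_sim_small()
  hmm <- fix_hmm_small()
  leaf <- sim$families$target$leaf_seqs[[1]]
  frag <- substr(leaf, 41, 160)
  proj <- map_read_to_columns(frag, hmm)
  expect_length(proj, hmm$L)
  expect_identical(paste(proj[41:160], collapse = ""), frag)
  expect_true(all(proj[c(1:40, 161:hmm$L)] == "-"))

  # an inserted base is dropped by the projection
  ins <- paste0(substr(frag, 1, 60), "A", substr(frag, 61, 120))
  proj2 <- map_read_to_columns(ins, hmm)
  expect_identical(proj2[41:160], proj[41:160])

  # minus-strand reads are reverse-complemented before alignment
  proj3 <- map_read_to_columns(revcomp(frag), hmm, strand = "-")
  expect_identical(proj3, proj)

  expect_error(map_read_to_columns(strrep("N", 100), hmm), "null Viterbi|informative")
})

test_that("reads simulated from a leaf place onto that leaf's pendant edge", {
  ref <- make_ref(8, 500, seed = 941)
  aln <- ref$aln
  hmm <- build_phmm(aln)
  eng <- placement_engine(ref$tree, genecensus:::project_msa_to_match(aln, hmm))
  donor <- ref$tree$tip.label[4]
  reads <- simulate_leaf_reads(ref$seqs[[donor]], 12, divergence = 0.01,
                               seed = 951)
  donor_edge <- eng$edge$edge_id[eng$edge$child == match(donor, eng$tree$tip.label)]
  best <- vapply(reads, function(r) {
    place_read(eng, map_read_to_columns(r, hmm))$edge_id[1]
  }, 0L)
  expect_gte(sum(best == donor_edge), 10)
})

test_that("ecotype aggregation counts reads per edge with optional normalization", {
  pl <- data.frame(read_id = rep(sprintf("r%02d", 1:10), each = 1),
                   edge_id = 7L, log_likelihood = -10, pendant_length = 0.1,
                   like_weight_ratio = 1, rank = 1L)
  ref <- make_ref(5, 30, seed = 961)
  eng <- placement_engine(ref$tree, ref$seqs)
  tab <- aggregate_ecotypes(pl, eng)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$count, 10)
  expect_identical(tab$edge_id, 7L)
  expect_true(nzchar(tab$annotation))

  tabn <- aggregate_ecotypes(pl, eng, normalize = "max")
  expect_equal(max(tabn$abundance), 1)

  # two samples on disjoint edges: per-sample sums equal reads placed
  pl2 <- rbind(transform(pl, sample = "s1"),
               transform(pl, sample = "s2", edge_id = 3L,
                         read_id = sprintf("q%02d", 1:10)))
  tab2 <- aggregate_ecotypes(pl2, eng)
  sums <- tapply(tab2$count, tab2$sample, sum)
  expect_equal(as.numeric(sums), c(10, 10))
  expect_setequal(tab2$edge_id, c(3L, 7L))

  # spreading by likelihood weight conserves total mass
  pl3 <- rbind(pl, transform(pl, edge_id = 2L, rank = 2L,
                             like_weight_ratio = 0.4))
  pl3$like_weight_ratio[pl3$rank == 1L] <- 0.6
  tab3 <- aggregate_ecotypes(pl3, eng, count_mode = "spread_lwr")
  expect_equal(sum(tab3$count), 10)
})

test_that("jplace output is valid versioned JSON with numbered edges", {
  ref <- make_ref(4, 40, seed = 971)
  eng <- placement_engine(ref$tree, ref$seqs)
  q <- strsplit(ref$seqs[[1]], "")[[1]]
  pl <- place_read(eng, q, read_id = "readA")
  path <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(pl, eng, path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(js$version, 3L)
  expect_identical(unlist(js$fields),
                   c("edge_num", "likelihood", "like_weight_ratio",
                     "pendant_length"))
  expect_match(js$tree, "\\{1\\}")
  expect_identical(js$placements[[1]]$n[[1]], "readA")
  expect_identical(js$placements[[1]]$p[[1]][[1]], pl$edge_id[1])
})
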