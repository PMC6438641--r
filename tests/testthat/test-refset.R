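# Reference-set curation: fragment filtering, greedy redundancy
# clustering, conserved-motif scanning.

aa <- function(n, seed) random_protein(n, seed)

test_that("fragment filter applies a strict less-than rule at the length boundary", {
  arch <- data.frame(id = "arch", seq = aa(100, 1))
  recs <- data.frame(id = c("a69", "a70", "a100"),
                     seq = c(aa(69, 2), aa(70, 3), aa(100, 4)))
  kept <- filter_fragments(recs, arch, fraction = 0.70)
  expect_identical(kept$id, c("a70", "a100"))

  # identity case: nothing shorter than the threshold
  all_long <- data.frame(id = c("x", "y"), seq = c(aa(80, 5), aa(95, 6)))
  expect_identical(filter_fragments(all_long, arch), all_long)

  # idempotence and output-subset-of-input
  again <- filter_fragments(kept, arch)
  expect_identical(again, kept)
  expect_true(all(kept$id %in% recs$id))
})

test_that("fragment filter rejects empty archetypes and mixed alphabets", {
  recs <- data.frame(id = "a", seq = aa(50, 7))
  expect_error(filter_fragments(recs, ""), "empty")
  dna_recs <- data.frame(id = "d", seq = random_dna(60, 8))
  expect_error(filter_fragments(dna_recs, data.frame(id = "p", seq = "MKLVWPQR")),
               "alphabet")
})

test_that("identical and unrelated sequences cluster as expected", {
  s <- aa(60, 10)
  recs <- data.frame(id = c("s1", "s2"), seq = c(s, s))
  cl <- cluster_redundant(recs, threshold = 0.95)
  expect_identical(attr(cl, "n_clusters"), 1L)
  expect_setequal(cl$member, c("s1", "s2"))
  expect_identical(unique(cl$representative), "s1")

  # two dissimilar random sequences: singletons
  recs2 <- data.frame(id = c("u", "v"), seq = c(aa(60, 11), aa(60, 12)))
  cl2 <- cluster_redundant(recs2, threshold = 0.9)
  expect_identical(attr(cl2, "n_clusters"), 2L)

  expect_error(cluster_redundant(recs, threshold = 1.5), "threshold")
})

test_that("greedy clustering matches an independent oracle on substitution-only variants", {
  # equal-length sequences differing only by substitutions, so identity is
  # exactly the Hamming fraction whatever the aligner does
  base <- aa(50, 20)
  mut <- function(s, k, seed) {
    with_seed(seed, {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), k)
      for (p in pos) ch[p] <- sample(setdiff(genecensus:::AA_LETTERS, ch[p]), 1)
      paste(ch, collapse = "")
    })
  }
  seqs <- c(A = base, B = mut(base, 1, 21), C = mut(base, 2, 22),
            D = mut(base, 20, 23), E = mut(base, 21, 24))
  recs <- data.frame(id = names(seqs), seq = unname(seqs))
  idm <- outer(seq_along(seqs), seq_along(seqs), Vectorize(function(i, j) {
    hamming_identity(seqs[[i]], seqs[[j]])
  }))
  dimnames(idm) <- list(names(seqs), names(seqs))
  thr <- 0.95
  want <- greedy_cluster_oracle(names(seqs), nchar(seqs), idm, thr)
  got <- cluster_redundant(recs, threshold = thr)
  got_map <- setNames(got$representative, got$member)
  expect_mapequal(as.list(got_map), as.list(want))

  # partition invariants: every record exactly once, members meet threshold
  expect_setequal(got$member, names(seqs))
  expect_false(anyDuplicated(got$member) > 0)
  expect_true(all(got$identity >= thr))
})

test_that("motif scanning honors element order and spacer bounds", {
  X <- function(n) strrep("A", n)
  classA <- paste0("K", X(6), "RP", X(20), "PSGH", X(40), "SR", X(5), "H",
                   X(2), "D")
  hitA <- scan_motif(classA, nsap_motif("classA"))
  expect_true(hitA$match)
  expect_identical(hitA$start, 1L)
  expect_identical(hitA$end, nchar(classA))

  # spacer of 60 between RP and PSGH exceeds the 54 bound
  tooFar <- paste0("K", X(6), "RP", X(60), "PSGH", X(40), "SR", X(5), "H",
                   X(2), "D")
  expect_false(scan_motif(tooFar, nsap_motif("classA"))$match)

  expect_false(scan_motif("", nsap_motif("classA"))$match)
  expect_error(scan_motif("ACGTACGT", nsap_motif("classA")), "protein")

  # X in the sequence matches any literal; (S/A) alternatives both match
  expect_true(scan_motif(paste0("YGDSDXD", X(3), "A"),
                         nsap_motif("classB_C"))$match)
  expect_true(scan_motif(paste0("YGDADCD", X(3), "A"),
                         nsap_motif("classB_C"))$match)
  expect_true(scan_motif("XXXXXXXXXXXX", nsap_motif("classC_N"))$match)
})

test_that("motif scanner agrees with a regex-expansion oracle on random strings", {
  pats <- lapply(c("classA", "classB_N", "classB_C", "classC_N", "classC_C"),
                 nsap_motif)
  for (i in 1:40) {
    s <- random_protein(sample(20:300, 1), seed = 400 + i)
    for (p in pats) {
      got <- scan_motif(s, p)
      m <- regexpr(motif_regex(p), s, perl = TRUE)
      expect_identical(got$match, m[1] != -1L,
                       info = sprintf("pattern %s on string %d", p$family, i))
      if (got$match) {
        expect_identical(got$start, as.integer(m[1]))
        expect_identical(got$end, as.integer(m[1] + attr(m, "match.length") - 1L))
      }
    }
  }
})

test_that("validate_family composes the curation steps and reports counts", {
  X <- function(n) strrep("L", n)
  motif_ok <- paste0("K", X(6), "RP", X(20), "PSGH", X(40), "SR", X(5), "H",
                     X(2), "D")  # length 84
  arch <- data.frame(id = "arch", seq = motif_ok)
  pad <- function(s, seed) paste0(s, aa(10, seed))
  full1 <- pad(motif_ok, 31)
  recs <- data.frame(
    id = c("m1", "m1dup", "m2", "frag1", "frag2", "frag3", "nomotif"),
    seq = c(full1, full1, pad(motif_ok, 32), aa(20, 33), aa(30, 34),
            aa(10, 35), aa(94, 36)))
  out <- suppressWarnings(
    validate_family(recs, arch, patterns = nsap_motif("classA"),
                    fraction = 0.70, threshold = 0.95))
  rep <- setNames(out$report$count, out$report$step)
  expect_identical(rep[["input"]], 7L)
  expect_identical(rep[["fragments_removed"]], 3L)
  expect_identical(rep[["clusters"]], 3L)  # m1 (+dup), m2, nomotif
  expect_identical(out$motif_flagged, "nomotif")
  expect_true(all(out$records$id %in% recs$id))

  # warn-only policy retains flagged records; drop removes them
  expect_true("nomotif" %in% out$records$id)
  out2 <- validate_family(recs, arch, patterns = nsap_motif("classA"),
                          motif_policy = "drop")
  expect_false("nomotif" %in% out2$records$id)

  # all-pass input survives untouched
  clean <- data.frame(id = c("a", "b"), seq = c(pad(motif_ok, 41), full1))
  out3 <- validate_family(clean, arch, patterns = nsap_motif("classA"))
  expect_setequal(out3$records$id, clean$id)

  expect_error(validate_family(data.frame(id = "f", seq = aa(10, 42)), arch),
               "survive")
})
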