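# Profile-HMM construction, DP scoring against enumeration oracles,
# calibration, and the staged filter cascade.

test_that("build_phmm estimates Laplace emissions and applies the match-column rule", {
  aln <- as_msa(c(a = "ACGTAC", b = "ACGTAC"))
  hmm <- build_phmm(aln)
  expect_identical(hmm$L, 6L)
  # two identical DNA rows, +1 pseudocount: observed residue (2+1)/(2+4)
  expect_equal(hmm$mat_e[1, 1], 3 / 6)
  expect_equal(hmm$mat_e[2, 2], 3 / 6)
  expect_true(all(abs(rowSums(hmm$mat_e) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm$ins_e) - 1) < 1e-9))

  # a column gapped in 3 of 4 rows becomes an insert column
  aln2 <- as_msa(c(a = "AC-GT", b = "AC-GT", c = "AC-GT", d = "ACAGT"))
  hmm2 <- build_phmm(aln2, match_rule = 0.5)
  expect_identical(hmm2$L, 4L)
  expect_identical(hmm2$match_columns, c(1L, 2L, 4L, 5L))

  expect_error(build_phmm(as_msa(c(a = "---", b = "---"))), "match columns")
  expect_error(build_phmm(as_msa(c(a = "ACGT"))), "2 alignment rows")
  validate_phmm(hmm2)
})

test_that("Viterbi and Forward match exhaustive path enumeration", {
  set.seed(71)
  for (rep in 1:12) {
    L <- sample(1:4, 1)
    n <- sample(0:6, 1)
    hmm <- random_phmm(L, seed = 500 + rep)
    codes <- if (n) sample(1:4, n, replace = TRUE) else integer(0)
    seq <- paste(c("A", "C", "G", "T")[codes], collapse = "")
    expect_equal(phmm_viterbi(hmm, seq)$bits, oracle_viterbi_bits(hmm, codes),
                 tolerance = 1e-11)
    expect_equal(phmm_forward(hmm, seq), oracle_forward_bits(hmm, codes),
                 tolerance = 1e-11)
  }
})

test_that("degenerate models give closed-form scores", {
  # (near-)deterministic emissions: the consensus path carries ~all mass,
  # so viterbi == forward == sum of entry/exit/emission log-odds
  L <- 4
  hmm <- random_phmm(L, seed = 601)
  hmm$mat_e <- matrix(1e-12, L, 4)
  hmm$mat_e[cbind(1:4, c(1, 3, 2, 4))] <- 1 - 3e-12
  hmm$trans[, "MI"] <- 0
  hmm$trans[, "MD"] <- 0
  hmm$trans[, "MM"] <- ifelse(seq_len(L) < L, 1, 0)
  hmm$prof <- genecensus:::scoring_profile(hmm)
  seq <- "AGCT"  # the deterministic consensus
  path_bits <- log2(1 / L) +                       # entry
    4 * log2((1 - 3e-12) / 0.25) +                 # emissions
    sum(log2((1 - hmm$exit[1:3]) * 1)) +           # MM transitions
    log2(hmm$exit[4])                              # exit at node L
  expect_equal(phmm_viterbi(hmm, seq)$bits, path_bits, tolerance = 1e-6)
  expect_gte(phmm_forward(hmm, seq), phmm_viterbi(hmm, seq)$bits)

  # an L=1 model admits exactly one path for a length-1 sequence, so
  # forward and viterbi coincide
  hmm1 <- random_phmm(1, seed = 602)
  expect_equal(phmm_forward(hmm1, "G"), phmm_viterbi(hmm1, "G")$bits,
               tolerance = 1e-12)

  # impossible residue with zero emission everywhere: -Inf, no overflow
  hmm0 <- hmm
  hmm0$mat_e[, 2] <- 0       # C impossible at every node
  hmm0$ins_e[, 2] <- 0
  hmm0$prof <- genecensus:::scoring_profile(hmm0)
  expect_identical(phmm_viterbi(hmm0, "CCCC")$bits, -Inf)
  expect_identical(phmm_forward(hmm0, "CCCC"), -Inf)

  # empty sequence: defined null score
  expect_identical(phmm_viterbi(hmm, "")$bits, 0)
  expect_identical(phmm_forward(hmm, ""), 0)
  expect_identical(phmm_msv(hmm, ""), 0)
})

test_that("forward dominates viterbi and MSV equals viterbi without indels", {
  for (rep in 1:100) {
    hmm <- random_phmm(sample(2:5, 1), seed = 700 + rep)
    seq <- random_dna(sample(1:30, 1), seed = 800 + rep)
    v <- phmm_viterbi(hmm, seq)$bits
    f <- phmm_forward(hmm, seq)
    expect_gte(f + 1e-9, v)
  }

  # zero indel probability: the match-only MSV model coincides with the
  # full model; score the consensus (single-segment optimum)
  hmm <- random_phmm(5, seed = 901)
  hmm$trans[, "MI"] <- 0
  hmm$trans[, "MD"] <- 0
  hmm$trans[1:4, "MM"] <- 1
  hmm$trans[5, "MM"] <- 0
  hmm$prof <- genecensus:::scoring_profile(hmm)
  cons <- paste(c("A", "C", "G", "T")[apply(hmm$mat_e, 1, which.max)],
                collapse = "")
  expect_equal(phmm_msv(hmm, cons), phmm_viterbi(hmm, cons)$bits,
               tolerance = 1e-9)

  # MSV tracks forward: positive rank correlation on model draws
  hmm2 <- fix_hmm_small()
  reads <- sample_from_hmm(hmm2, 200, seed = 77)
  reads <- reads[nchar(reads) >= 20]
  sc <- score_reads(data.frame(id = seq_along(reads), seq = reads), hmm2,
                    both_strands = FALSE)
  expect_gt(cor(sc$msv_bits, sc$fwd_bits, method = "spearman"), 0)
})

test_that("calibration fits a usable null law", {
  hmm <- fix_hmm_small()
  st <- hmm$calibration$stages
  expect_identical(st$stage, c("msv", "viterbi", "forward"))
  expect_true(all(is.finite(st$loc)), all(st$scale > 0))

  # P-value of the median null score is ~0.5
  nulls <- random_reads_df(201, 150, seed = 31)
  sc <- score_reads(nulls, hmm, both_strands = FALSE)
  med <- median(sc$fwd_bits)
  p_med <- genecensus:::stage_pvalue(hmm, "forward", med)
  expect_lt(abs(p_med - 0.5), 0.1)

  # more shuffles shrink the location standard error (consistency);
  # 16x the sample size should give ~4x smaller spread
  locs_small <- vapply(1:12, function(i) {
    calibrate(hmm, 50, seed = 100 + i)$calibration$stages$loc[3]
  }, 0)
  locs_big <- vapply(1:12, function(i) {
    calibrate(hmm, 800, seed = 200 + i)$calibration$stages$loc[3]
  }, 0)
  expect_lt(sd(locs_big), sd(locs_small))

  # degenerate scores refuse to calibrate
  aln <- as_msa(c(a = "ACGT", b = "ACGT"))
  tiny <- build_phmm(aln)
  expect_error(calibrate(tiny, 50, seed = 1, length = 0), "degenerate")
  expect_error(calibrate(tiny, 10), "n_shuffles")
})

test_that("the cascade filters, reports attrition, and honors E-values", {
  hmm <- fix_hmm_small()
  sim <- fix_sim_small()
  reads <- sim$reads[1:1500, ]
  hits <- search_reads(reads, hmm, db_size = nrow(reads))
  att <- attr(hits, "attrition")
  expect_identical(att$stage, c("input", "msv", "viterbi", "forward"))
  expect_true(all(diff(att$reads) <= 0))  # monotone attrition
  truth <- sim$truth[match(reads$id, sim$truth$read_id), ]
  expect_true(all(truth$gene[match(hits$read_id, reads$id)] == "target"))

  # survivors' reported P-values respect the thresholds
  cc <- cascade_config()
  expect_true(all(hits$p_msv <= cc$p_msv))
  expect_true(all(hits$p_vit <= cc$p_vit))
  expect_true(all(hits$evalue <= cc$evalue_max))

  # lowering any threshold never enlarges the survivor set
  tight <- search_reads(reads, hmm,
                        cascade_config(p_msv = 0.005, p_vit = 1e-4,
                                       p_fwd = 1e-6),
                        db_size = nrow(reads))
  expect_true(all(tight$read_id %in% hits$read_id))

  # an enormous db_size pushes E above the cutoff: everything rejected
  none <- search_reads(reads, hmm, db_size = 1e300)
  expect_identical(nrow(none), 0L)

  # reverse-complemented true positives come back on the minus strand
  plus_hits <- hits[hits$strand == "+", ]
  rc <- data.frame(id = plus_hits$read_id, seq = revcomp(
    reads$seq[match(plus_hits$read_id, reads$id)]))
  rc_hits <- search_reads(rc, hmm, db_size = nrow(reads))
  expect_setequal(rc_hits$read_id, plus_hits$read_id)
  expect_true(all(rc_hits$strand == "-"))

  uncal <- build_phmm(sim$families$target$msa)
  expect_error(search_reads(reads, uncal), "calibrated")
  expect_error(cascade_config(p_msv = 1e-4, p_vit = 0.01), "p_fwd")
})

test_that("model text serialization round-trips scores and calibration", {
  hmm <- fix_hmm_small()
  path <- withr::local_tempfile(fileext = ".phmm")
  write_phmm(hmm, path)
  back <- read_phmm(path)
  expect_identical(back$L, hmm$L)
  expect_equal(back$mat_e, hmm$mat_e, tolerance = 1e-12)
  expect_equal(back$calibration$stages$loc, hmm$calibration$stages$loc,
               tolerance = 1e-12)
  seq <- random_dna(120, seed = 9)
  expect_equal(phmm_forward(back, seq), phmm_forward(hmm, seq),
               tolerance = 1e-12)
  expect_equal(phmm_viterbi(back, seq)$bits, phmm_viterbi(hmm, seq)$bits,
               tolerance = 1e-12)
})

test_that("sampled model reads score far above background", {
  hmm <- fix_hmm_small()
  reads <- sample_from_hmm(hmm, 50, seed = 55)
  reads <- reads[nchar(reads) >= 50]
  sc <- score_reads(data.frame(id = seq_along(reads), seq = reads), hmm,
                    both_strands = FALSE)
  bg <- score_reads(random_reads_df(50, 100, seed = 56), hmm,
                    both_strands = FALSE)
  # the bulk of model draws outscore every background read (a few samples
  # are dominated by insert states and score low; that tail is expected)
  expect_gt(unname(quantile(sc$fwd_bits, 0.2)), max(bg$fwd_bits))
})
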