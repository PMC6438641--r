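# Profile hidden Markov models over DNA or protein alphabets: construction
# from a reference alignment, MSV/Viterbi/Forward scoring (C++ kernels),
# empirical Gumbel calibration, and the staged filter cascade used to
# search unassembled reads.
#
# Model architecture (uni-hit local alignment):
#   * entry from begin into any match state M_k with probability 1/L;
#   * exit from M_k to end with probability eps_k = 1/(L - k + 1), so the
#     model always terminates and eps_L = 1; core transitions out of M_k
#     are scaled by (1 - eps_k);
#   * deletes may run through to node L, which exits with probability 1;
#   * insert states exist between consecutive match states (no flanking
#     inserts in local mode).
# Scores are log2-odds of the summed (Forward) or best (Viterbi) local
# subpath against an i.i.d. background; the empty subpath (odds 1) is part
# of the path set, so scores are >= 0 and defined for empty sequences.
# The MSV filter is the same model restricted to match states, with
# cost-free multi-segment re-entry.

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns with at least `match_rule` non-gap fraction become match states;
#' other columns are treated as inserts. Emissions and transitions are
#' maximum a-posteriori estimates with additive pseudocounts (Laplace +1
#' for DNA, +0.1 for protein by default; a light +0.05 for transitions,
#' so that a mostly ungapped alignment yields a model that stays on the
#' match path). Sequence weighting is uniform.
#'
#' @param aln an [as_msa()] alignment (or anything coercible to one) with
#'   at least two rows.
#' @param match_rule minimum non-gap fraction for a column to become a
#'   match state (default 0.5).
#' @param pseudocount additive emission pseudocount; default 1 for DNA and
#'   0.1 for protein.
#' @param trans_pseudocount additive transition pseudocount (default
#'   0.05).
#' @param background background residue frequencies (default uniform).
#' @return an object of class `profile_hmm` with elements `L`, `alphabet`,
#'   `mat_e` (L x K match emissions), `ins_e`, `trans` (L x 7 core
#'   transition probabilities MM MI MD IM II DM DD), `entry`, `exit`,
#'   `background`, `match_columns`, `consensus`, and a pre-computed
#'   scoring profile for the C++ kernels.
#' @export
build_phmm <- function(aln, match_rule = 0.5, pseudocount = NULL,
                       trans_pseudocount = 0.05, background = NULL) {
  aln <- as_msa(aln)
  if (length(aln$seqs) < 2L) stopf("need at least 2 alignment rows")
  alphabet <- aln$alphabet
  K <- alphabet_size(alphabet)
  letters <- if (alphabet == "dna") DNA_LETTERS else AA_LETTERS
  pc <- pseudocount %||% (if (alphabet == "dna") 1 else 0.1)
  if (is.null(background)) background <- rep(1 / K, K)
  if (abs(sum(background) - 1) > 1e-9) stopf("background must sum to 1")

  mat <- msa_matrix(aln)
  nongap <- mat != "-"
  frac <- colMeans(nongap)
  match_cols <- which(frac >= match_rule)
  L <- length(match_cols)
  if (L < 1L) stopf("alignment has no match columns (all-gap?)")
  is_match <- seq_len(ncol(mat)) %in% match_cols
  # node index for each column: match columns get their own node; insert
  # columns belong to the node of the last match column before them
  node_of <- cumsum(is_match)

  code <- function(ch) match(ch, letters)  # NA for gap/ambiguous

  mat_counts <- matrix(0, L, K)
  ins_counts <- matrix(0, L, K)
  # transition counts
  tm <- matrix(0, L, 3, dimnames = list(NULL, c("MM", "MI", "MD")))
  ti <- matrix(0, L, 2, dimnames = list(NULL, c("IM", "II")))
  td <- matrix(0, L, 2, dimnames = list(NULL, c("DM", "DD")))

  for (r in seq_len(nrow(mat))) {
    prev_state <- NULL  # c(type, node); type 1=M, 2=I, 3=D
    for (j in seq_len(ncol(mat))) {
      res <- mat[r, j]
      k <- node_of[j]
      if (is_match[j]) {
        if (res == "-") {
          state <- c(3L, k)
        } else {
          state <- c(1L, k)
          cd <- code(res)
          if (!is.na(cd)) mat_counts[k, cd] <- mat_counts[k, cd] + 1
        }
      } else {
        if (res == "-") next
        if (k < 1L || k >= L) next  # no flanking insert states in local mode
        state <- c(2L, k)
        cd <- code(res)
        if (!is.na(cd)) ins_counts[k, cd] <- ins_counts[k, cd] + 1
      }
      if (!is.null(prev_state)) {
        pt <- prev_state[1]; pk <- prev_state[2]
        if (pt == 1L) {
          if (state[1] == 1L && state[2] == pk + 1L) tm[pk, 1] <- tm[pk, 1] + 1
          if (state[1] == 2L && state[2] == pk) tm[pk, 2] <- tm[pk, 2] + 1
          if (state[1] == 3L && state[2] == pk + 1L) tm[pk, 3] <- tm[pk, 3] + 1
        } else if (pt == 2L) {
          if (state[1] == 1L && state[2] == pk + 1L) ti[pk, 1] <- ti[pk, 1] + 1
          if (state[1] == 2L && state[2] == pk) ti[pk, 2] <- ti[pk, 2] + 1
        } else {
          if (state[1] == 1L && state[2] == pk + 1L) td[pk, 1] <- td[pk, 1] + 1
          if (state[1] == 3L && state[2] == pk + 1L) td[pk, 2] <- td[pk, 2] + 1
        }
      }
      prev_state <- state
    }
  }

  mat_e <- sweep(mat_counts + pc, 1, rowSums(mat_counts + pc), "/")
  ins_e <- sweep(ins_counts + pc, 1, rowSums(ins_counts + pc), "/")

  trans <- matrix(0, L, 7,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  if (L > 1L) {
    tpc <- trans_pseudocount
    core <- tm[-L, , drop = FALSE] + tpc
    trans[-L, 1:3] <- core / rowSums(core)
    ci <- ti[-L, , drop = FALSE] + tpc
    trans[-L, 4:5] <- ci / rowSums(ci)
    cd2 <- td[-L, , drop = FALSE] + tpc
    trans[-L, 6:7] <- cd2 / rowSums(cd2)
  }
  # node L: exit probability 1, no outgoing core transitions

  hmm <- structure(list(
    L = L,
    alphabet = alphabet,
    K = K,
    mat_e = mat_e,
    ins_e = ins_e,
    trans = trans,
    entry = rep(1 / L, L),
    exit = 1 / (L - seq_len(L) + 1),
    background = background,
    match_columns = match_cols,
    consensus = paste(letters[apply(mat_e, 1, which.max)], collapse = ""),
    nseq = length(aln$seqs),
    calibration = NULL
  ), class = "profile_hmm")
  validate_phmm(hmm)
  hmm$prof <- scoring_profile(hmm)
  hmm
}

#' Validate profile HMM invariants
#'
#' Checks that every emission row and every per-node outgoing transition
#' distribution (including local exit) sums to 1 within 1e-9.
#'
#' @param hmm a `profile_hmm`.
#' @return `hmm`, invisibly; errors if an invariant is violated.
#' @export
validate_phmm <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"), hmm$L >= 1)
  chk <- function(x, what) {
    if (any(abs(x - 1) > 1e-9)) stopf("%s rows do not sum to 1", what)
  }
  chk(rowSums(hmm$mat_e), "match emission")
  chk(rowSums(hmm$ins_e), "insert emission")
  L <- hmm$L
  m_out <- hmm$exit + (1 - hmm$exit) * rowSums(hmm$trans[, 1:3, drop = FALSE])
  chk(m_out, "match transition")
  if (L > 1L) {
    chk(rowSums(hmm$trans[-L, 4:5, drop = FALSE]), "insert transition")
    chk(rowSums(hmm$trans[-L, 6:7, drop = FALSE]), "delete transition")
  }
  if (any(hmm$background <= 0)) stopf("background must be positive")
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s, L = %d match states, built from %d sequences%s\n",
              x$alphabet, x$L, x$nseq %||% NA_integer_,
              if (is.null(x$calibration)) " (uncalibrated)" else " (calibrated)"))
  invisible(x)
}

# flat numeric view consumed by the C++ kernels
scoring_profile <- function(hmm) {
  L <- hmm$L; K <- hmm$K
  bg <- hmm$background
  modds <- hmm$mat_e / matrix(bg, L, K, byrow = TRUE)
  iodds <- hmm$ins_e / matrix(bg, L, K, byrow = TRUE)
  mpr <- cbind(modds, 1)  # unknown residue: background emission, odds 1
  ipr <- cbind(iodds, 1)
  scale <- 1 - hmm$exit
  tpr <- hmm$trans
  tpr[, 1:3] <- tpr[, 1:3] * scale
  list(L = L, K = K,
       mlo = log2(mpr), ilo = log2(ipr), tlo = log2(tpr),
       entry_lo = log2(hmm$entry), exit_lo = log2(hmm$exit),
       mpr = mpr, ipr = ipr, tpr = tpr,
       entry_pr = hmm$entry, exit_pr = hmm$exit)
}

check_seq_alphabet <- function(hmm, seq) {
  if (hmm$alphabet == "dna" && !all(is_dna_seq(seq))) {
    stopf("sequence alphabet does not match the DNA model")
  }
}

#' Viterbi score (and alignment path) of a sequence against a profile HMM
#'
#' @param hmm a `profile_hmm`.
#' @param seq a single residue string.
#' @return list with `bits` (log2-odds of the best local path; 0 for the
#'   empty path) and `path`, a data.frame mapping emitting sequence
#'   positions (`pos`) to match nodes (`node`).
#' @export
phmm_viterbi <- function(hmm, seq) {
  check_seq_alphabet(hmm, seq)
  r <- cpp_viterbi_path(seq, hmm$prof, alphabet_code(hmm$alphabet))
  list(bits = r$bits, path = data.frame(pos = r$pos, node = r$node))
}

#' Forward score of a sequence against a profile HMM
#'
#' @inheritParams phmm_viterbi
#' @return log2-odds of the total local-path probability vs background.
#' @export
phmm_forward <- function(hmm, seq) {
  check_seq_alphabet(hmm, seq)
  cpp_score_seq(seq, hmm$prof, alphabet_code(hmm$alphabet), "forward")
}

#' MSV (multi-segment, match-only) filter score
#'
#' @inheritParams phmm_viterbi
#' @return log2-odds MSV score.
#' @export
phmm_msv <- function(hmm, seq) {
  check_seq_alphabet(hmm, seq)
  cpp_score_seq(seq, hmm$prof, alphabet_code(hmm$alphabet), "msv")
}

# Gumbel null law ---------------------------------------------------------

# Gumbel fit by maximum likelihood (moment-initialized) or by the
# method of moments.  ML tracks the distribution body best and is used
# for the MSV and Viterbi stages, whose P-value thresholds (0.02, 0.001)
# sit inside the observable range.  The Forward E-value cutoff
# extrapolates to P ~ 1e-9; the Forward null is right-skewed relative to
# a Gumbel, so a body-optimal fit underestimates that far tail, and the
# moment estimator's inflated scale is the tail-safe choice there.
fit_gumbel <- function(scores, method = c("ml", "moments")) {
  method <- match.arg(method)
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-12) {
    stopf("degenerate null score distribution (zero variance); cannot calibrate")
  }
  scale0 <- s * sqrt(6) / pi
  loc0 <- mean(scores) - 0.5772156649015329 * scale0
  if (method == "moments") return(c(loc = loc0, scale = scale0))
  nll <- function(p) {
    z <- (scores - p[1]) / exp(p[2])
    sum(z + exp(-z)) + length(scores) * p[2]
  }
  opt <- tryCatch(stats::optim(c(loc0, log(scale0)), nll),
                  error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) {
    return(c(loc = loc0, scale = scale0))
  }
  c(loc = opt$par[1], scale = exp(opt$par[2]))
}

#' Upper-tail P-value under a fitted Gumbel null
#'
#' @param score numeric score(s).
#' @param loc,scale Gumbel location and scale.
#' @return `P(S >= score)` under the null.
#' @export
gumbel_pvalue <- function(score, loc, scale) {
  z <- (score - loc) / scale
  -expm1(-exp(-z))
}

gumbel_score_at <- function(p, loc, scale) {
  loc - scale * log(-log1p(-p))
}

#' Calibrate the null score distributions of a profile HMM
#'
#' Scores `n_shuffles` i.i.d. background sequences of a representative
#' length with each cascade stage and fits a Gumbel law per stage
#' (maximum likelihood for MSV/Viterbi, method of moments for Forward,
#' whose E-value cutoff extrapolates far into the tail; see
#' `fit_gumbel`). Deterministic given `seed`.
#'
#' @param hmm a `profile_hmm`.
#' @param n_shuffles number of null sequences (>= 50; default 200).
#' @param seed integer seed.
#' @param length length of the null sequences; defaults to 150 (a typical
#'   short read) for DNA models and 50 (a translated read frame) for
#'   protein models.
#' @return the HMM with a `calibration` element (per-stage Gumbel
#'   location/scale, the null length and `n_shuffles`).
#' @export
calibrate <- function(hmm, n_shuffles = 200, seed = 1, length = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (n_shuffles < 50) stopf("n_shuffles must be >= 50")
  length <- length %||% (if (hmm$alphabet == "dna") 150L else 50L)
  letters <- if (hmm$alphabet == "dna") DNA_LETTERS else AA_LETTERS
  nulls <- with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) random_residues(length, letters, hmm$background),
           "")
  })
  sc <- cpp_cascade_search(nulls, hmm$prof, alphabet_code(hmm$alphabet),
                           -Inf, -Inf, -Inf, FALSE)
  stages <- data.frame(stage = c("msv", "viterbi", "forward"),
                       loc = NA_real_, scale = NA_real_)
  fit_method <- c("ml", "ml", "moments")  # see fit_gumbel()
  for (i in 1:3) {
    g <- fit_gumbel(sc[, i + 1L], method = fit_method[i])
    stages$loc[i] <- g[["loc"]]
    stages$scale[i] <- g[["scale"]]
  }
  hmm$calibration <- list(n_shuffles = n_shuffles, length = length,
                          seed = seed, stages = stages)
  hmm
}

#' Stage thresholds for the read-search filter cascade
#'
#' The defaults are the standard staged-filter settings: MSV P <= 0.02,
#' Viterbi P <= 0.001, Forward P <= 1e-5, and a final full-length E-value
#' cutoff of 1e-5.
#'
#' @param p_msv,p_vit,p_fwd per-stage P-value thresholds
#'   (0 < p_fwd <= p_vit <= p_msv <= 1).
#' @param evalue_max maximum E-value (`P_fwd * db_size`).
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(p_msv = 0.02, p_vit = 0.001, p_fwd = 1e-5,
                           evalue_max = 1e-5) {
  if (!(p_fwd > 0 && p_fwd <= p_vit && p_vit <= p_msv && p_msv <= 1)) {
    stopf("need 0 < p_fwd <= p_vit <= p_msv <= 1")
  }
  if (evalue_max <= 0) stopf("evalue_max must be positive")
  structure(list(p_msv = p_msv, p_vit = p_vit, p_fwd = p_fwd,
                 evalue_max = evalue_max), class = "cascade_config")
}

stage_threshold <- function(hmm, stage, p) {
  st <- hmm$calibration$stages
  i <- match(stage, st$stage)
  gumbel_score_at(p, st$loc[i], st$scale[i])
}

stage_pvalue <- function(hmm, stage, score) {
  st <- hmm$calibration$stages
  i <- match(stage, st$stage)
  gumbel_pvalue(score, st$loc[i], st$scale[i])
}

#' Search reads with a calibrated profile HMM through the filter cascade
#'
#' Each read is scored on both strands (DNA models). A strand survives if
#' its MSV, Viterbi and Forward P-values pass the cascade thresholds and
#' its E-value (`P_fwd * db_size`) passes `evalue_max`; the better strand
#' is reported once per read. Per-stage attrition counts are attached as
#' the `"attrition"` attribute.
#'
#' @param reads data.frame with `id` and `seq` columns, or a character
#'   vector of sequences (optionally named).
#' @param hmm a calibrated `profile_hmm`.
#' @param cascade a [cascade_config()].
#' @param db_size effective database size for E-values (number of reads
#'   searched; defaults to `nrow(reads)`).
#' @return data.frame of surviving reads: `read_id`, `strand`, `msv_bits`,
#'   `vit_bits`, `fwd_bits`, `p_msv`, `p_vit`, `p_fwd`, `evalue`.
#' @export
search_reads <- function(reads, hmm, cascade = cascade_config(),
                         db_size = NULL) {
  if (is.character(reads)) {
    reads <- data.frame(id = names(reads) %||% paste0("read", seq_along(reads)),
                        seq = unname(reads))
  }
  if (is.null(hmm$calibration)) stopf("HMM must be calibrated before searching")
  db_size <- db_size %||% nrow(reads)
  p_fwd_eff <- min(cascade$p_fwd, cascade$evalue_max / db_size)
  thr <- c(stage_threshold(hmm, "msv", cascade$p_msv),
           stage_threshold(hmm, "viterbi", cascade$p_vit),
           stage_threshold(hmm, "forward", p_fwd_eff))
  both <- hmm$alphabet == "dna"
  sc <- cpp_cascade_search(reads$seq, hmm$prof, alphabet_code(hmm$alphabet),
                           thr[1], thr[2], thr[3], both)
  stage <- sc[, "stage"]
  attrition <- data.frame(
    stage = c("input", "msv", "viterbi", "forward"),
    reads = c(nrow(reads), sum(stage >= 1), sum(stage >= 2), sum(stage >= 3)))
  keep <- which(stage >= 3)
  res <- data.frame(
    read_id = reads$id[keep],
    strand = ifelse(sc[keep, "strand"] > 0, "+", "-"),
    msv_bits = sc[keep, "msv"],
    vit_bits = sc[keep, "vit"],
    fwd_bits = sc[keep, "fwd"],
    stringsAsFactors = FALSE)
  res$p_msv <- stage_pvalue(hmm, "msv", res$msv_bits)
  res$p_vit <- stage_pvalue(hmm, "viterbi", res$vit_bits)
  res$p_fwd <- stage_pvalue(hmm, "forward", res$fwd_bits)
  res$evalue <- res$p_fwd * db_size
  attr(res, "attrition") <- attrition
  attr(res, "db_size") <- db_size
  res
}

#' Score reads with every cascade stage (no filtering)
#'
#' Convenience for calibration diagnostics and tests: returns MSV, Viterbi
#' and Forward scores for each read (best strand for DNA models).
#'
#' @inheritParams search_reads
#' @param both_strands score the reverse complement too and keep the
#'   better strand (DNA only).
#' @return data.frame with `read_id`, `strand`, `msv_bits`, `vit_bits`,
#'   `fwd_bits`.
#' @export
score_reads <- function(reads, hmm, both_strands = hmm$alphabet == "dna") {
  if (is.character(reads)) {
    reads <- data.frame(id = names(reads) %||% paste0("read", seq_along(reads)),
                        seq = unname(reads))
  }
  sc <- cpp_cascade_search(reads$seq, hmm$prof, alphabet_code(hmm$alphabet),
                           -Inf, -Inf, -Inf, both_strands)
  data.frame(read_id = reads$id,
             strand = ifelse(sc[, "strand"] > 0, "+", "-"),
             msv_bits = sc[, "msv"], vit_bits = sc[, "vit"],
             fwd_bits = sc[, "fwd"], stringsAsFactors = FALSE)
}

#' Sample sequences from a profile HMM
#'
#' Draws state paths from the generative model (local entry/exit) and
#' emits residues, e.g. to create positive-control reads.
#'
#' @param hmm a `profile_hmm`.
#' @param n number of sequences.
#' @param seed integer seed.
#' @param full_length if `TRUE`, force entry at node 1 and suppress early
#'   exit so the sampled sequence traverses the whole model.
#' @return character vector of sampled sequences.
#' @export
sample_from_hmm <- function(hmm, n = 1, seed = 1, full_length = FALSE) {
  letters <- if (hmm$alphabet == "dna") DNA_LETTERS else AA_LETTERS
  L <- hmm$L
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      k <- if (full_length) 1L else sample.int(L, 1)
      out <- character(0)
      state <- "M"
      repeat {
        if (state == "M") {
          out <- c(out, sample(letters, 1, prob = hmm$mat_e[k, ]))
          if (k == L) break
          if (!full_length && runif(1) < hmm$exit[k]) break
          nxt <- sample(c("M", "I", "D"), 1, prob = hmm$trans[k, 1:3])
          if (nxt == "M") k <- k + 1L
          else if (nxt == "D") { state <- "D"; k <- k + 1L }
          else state <- "I"
        } else if (state == "I") {
          out <- c(out, sample(letters, 1, prob = hmm$ins_e[k, ]))
          if (sample(c("M", "I"), 1, prob = hmm$trans[k, 4:5]) == "M") {
            state <- "M"; k <- k + 1L
          }
        } else {  # D
          if (k == L) break
          if (sample(c("M", "D"), 1, prob = hmm$trans[k, 6:7]) == "M") state <- "M"
          k <- k + 1L
        }
      }
      paste(out, collapse = "")
    }, "")
  })
}

# plain-text model serialization ------------------------------------------

#' Write a profile HMM to a plain-text file
#'
#' One header block (`L`, alphabet, background, match-column map, optional
#' calibration) followed by one `node` block per match state with match
#' emissions, insert emissions and core transitions.
#'
#' @param hmm a `profile_hmm`.
#' @param path output path.
#' @export
write_phmm <- function(hmm, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  num <- function(x) paste(formatC(x, digits = 17, format = "g"), collapse = " ")
  writeLines(c("# genecensus profile HMM v1",
               paste("L", hmm$L),
               paste("alphabet", hmm$alphabet),
               paste("nseq", hmm$nseq %||% NA),
               paste("background", num(hmm$background)),
               paste("match_columns", paste(hmm$match_columns, collapse = " "))),
             con)
  if (!is.null(hmm$calibration)) {
    st <- hmm$calibration$stages
    for (i in seq_len(nrow(st))) {
      writeLines(paste("calibration", st$stage[i], num(st$loc[i]),
                       num(st$scale[i]), hmm$calibration$length,
                       hmm$calibration$n_shuffles), con)
    }
  }
  for (k in seq_len(hmm$L)) {
    writeLines(c(paste("node", k),
                 paste("me", num(hmm$mat_e[k, ])),
                 paste("ie", num(hmm$ins_e[k, ])),
                 paste("tr", num(hmm$trans[k, ]))), con)
  }
  invisible(path)
}

#' Read a profile HMM written by [write_phmm()]
#'
#' @param path file path.
#' @return a `profile_hmm`.
#' @export
read_phmm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\\s+")
  key <- vapply(fields, `[[`, "", 1L)
  val <- function(k) fields[[match(k, key)]][-1L]
  L <- as.integer(val("L"))
  alphabet <- val("alphabet")
  K <- alphabet_size(alphabet)
  hmm <- list(L = L, alphabet = alphabet, K = K,
              mat_e = matrix(0, L, K), ins_e = matrix(0, L, K),
              trans = matrix(0, L, 7, dimnames = list(NULL,
                c("MM", "MI", "MD", "IM", "II", "DM", "DD"))),
              entry = rep(1 / L, L), exit = 1 / (L - seq_len(L) + 1),
              background = as.numeric(val("background")),
              match_columns = as.integer(val("match_columns")),
              nseq = suppressWarnings(as.integer(val("nseq"))),
              calibration = NULL)
  cal <- which(key == "calibration")
  if (length(cal)) {
    st <- do.call(rbind, lapply(fields[cal], function(f) {
      data.frame(stage = f[2], loc = as.numeric(f[3]), scale = as.numeric(f[4]))
    }))
    hmm$calibration <- list(stages = st,
                            length = as.integer(fields[[cal[1]]][5]),
                            n_shuffles = as.integer(fields[[cal[1]]][6]))
  }
  nodes <- which(key == "node")
  for (i in nodes) {
    k <- as.integer(fields[[i]][2])
    hmm$mat_e[k, ] <- as.numeric(fields[[i + 1L]][-1L])
    hmm$ins_e[k, ] <- as.numeric(fields[[i + 2L]][-1L])
    hmm$trans[k, ] <- as.numeric(fields[[i + 3L]][-1L])
  }
  hmm$consensus <- paste((if (alphabet == "dna") DNA_LETTERS else AA_LETTERS)[
    apply(hmm$mat_e, 1, which.max)], collapse = "")
  hmm <- structure(hmm, class = "profile_hmm")
  validate_phmm(hmm)
  hmm$prof <- scoring_profile(hmm)
  hmm
}
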