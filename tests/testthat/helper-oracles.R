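# Independent reference implementations used as oracles: exhaustive
# path enumeration for profile-HMM scores, exhaustive ancestral-state
# enumeration for attachment likelihoods, Hamming identities plus an
# independent greedy clustering, and regex expansion for motif scans.

# a random valid profile HMM built directly from random distributions
# (bypasses build_phmm so scoring is tested against arbitrary models)
random_phmm <- function(L, alphabet = "dna", seed = 1) {
  K <- if (alphabet == "dna") 4L else 20L
  with_seed(seed, {
    rdir <- function(n) {
      x <- runif(n) + 0.05
      x / sum(x)
    }
    mat_e <- t(vapply(seq_len(L), function(k) rdir(K), numeric(K)))
    ins_e <- t(vapply(seq_len(L), function(k) rdir(K), numeric(K)))
    trans <- matrix(0, L, 7, dimnames = list(NULL,
      c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
    if (L > 1) {
      for (k in seq_len(L - 1)) {
        trans[k, 1:3] <- rdir(3)
        trans[k, 4:5] <- rdir(2)
        trans[k, 6:7] <- rdir(2)
      }
    }
    hmm <- structure(list(L = L, alphabet = alphabet, K = K,
      mat_e = mat_e, ins_e = ins_e, trans = trans,
      entry = rep(1 / L, L), exit = 1 / (L - seq_len(L) + 1),
      background = rep(1 / K, K), match_columns = seq_len(L),
      consensus = "", nseq = 0L, calibration = NULL),
      class = "profile_hmm")
    validate_phmm(hmm)
    hmm$prof <- genecensus:::scoring_profile(hmm)
    hmm
  })
}

# enumerate the odds (likelihood ratio vs background) of every local
# subpath that emits at least one match residue
enum_path_odds <- function(hmm, codes) {
  L <- hmm$L
  K <- hmm$K
  m_od <- cbind(hmm$mat_e / matrix(hmm$background, L, K, byrow = TRUE), 1)
  i_od <- cbind(hmm$ins_e / matrix(hmm$background, L, K, byrow = TRUE), 1)
  tr <- hmm$trans
  eps <- hmm$exit
  n <- length(codes)
  out <- c()
  recM <- function(k, i, acc) {
    out <<- c(out, acc * eps[k])
    if (k < L) {
      cont <- acc * (1 - eps[k])
      if (i < n) recM(k + 1, i + 1, cont * tr[k, "MM"] * m_od[k + 1, codes[i + 1]])
      if (i < n) recI(k, i + 1, cont * tr[k, "MI"] * i_od[k, codes[i + 1]])
      recD(k + 1, i, cont * tr[k, "MD"])
    }
  }
  recI <- function(k, i, acc) {
    if (i < n) recM(k + 1, i + 1, acc * tr[k, "IM"] * m_od[k + 1, codes[i + 1]])
    if (i < n) recI(k, i + 1, acc * tr[k, "II"] * i_od[k, codes[i + 1]])
  }
  recD <- function(k, i, acc) {
    if (k == L) {
      out <<- c(out, acc)   # deletes ran to node L, which exits w.p. 1
      return(invisible(NULL))
    }
    if (i < n) recM(k + 1, i + 1, acc * tr[k, "DM"] * m_od[k + 1, codes[i + 1]])
    recD(k + 1, i, acc * tr[k, "DD"])
  }
  for (i0 in seq_len(n)) {
    for (k0 in seq_len(L)) {
      recM(k0, i0, (1 / L) * m_od[k0, codes[i0]])
    }
  }
  out
}

oracle_viterbi_bits <- function(hmm, codes) {
  if (length(codes) == 0) return(0)
  log2(max(enum_path_odds(hmm, codes)))
}

oracle_forward_bits <- function(hmm, codes) {
  if (length(codes) == 0) return(0)
  log2(sum(enum_path_odds(hmm, codes)))
}

dna_to_codes <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  m[is.na(m)] <- 5L   # unknown -> odds-1 column
  m
}

# brute-force attachment likelihood: enumerate states of every free node
# (internal nodes, the attachment point, missing-data leaves) and sum the
# products of JC69 transition probabilities, column by column
brute_edge_loglik <- function(engine, query, edge_id, pendant) {
  stopifnot(engine$model == "JC69")
  phy <- engine$tree
  edge <- engine$edge
  ntip <- length(phy$tip.label)
  root <- edge$parent[1]
  nnode <- ntip + phy$Nnode
  leafcodes <- lapply(phy$tip.label, function(tp) {
    genecensus:::nuc_code4(strsplit(toupper(
      engine$.leaf_seqs[[tp]]), "")[[1]])
  })
  qc <- genecensus:::nuc_code4(toupper(query))
  cols <- which(qc > 0L)
  pm <- function(t) genecensus:::pmat_jc69(t)
  total <- 0
  for (j in cols) {
    obs <- vapply(seq_len(ntip), function(i) leafcodes[[i]][j], 0L)
    states <- lapply(seq_len(nnode + 1L), function(nd) {
      if (nd <= ntip && obs[nd] > 0L) obs[nd] else 1:4
    })  # node nnode+1 = attachment point x
    grid <- expand.grid(states)
    colsum <- 0
    for (r in seq_len(nrow(grid))) {
      st <- as.integer(grid[r, ])
      pr <- 0.25   # stationary prior at the root
      ok <- TRUE
      for (ei in seq_len(nrow(edge))) {
        a <- st[edge$parent[ei]]
        b <- st[edge$child[ei]]
        if (ei == edge_id) {
          x <- st[nnode + 1L]
          pr <- pr * pm(edge$length[ei] / 2)[a, x] *
            pm(edge$length[ei] / 2)[x, b]
        } else {
          pr <- pr * pm(edge$length[ei])[a, b]
        }
        if (pr == 0) { ok <- FALSE; break }
      }
      if (ok) {
        pr <- pr * pm(pendant)[st[nnode + 1L], qc[j]]
        colsum <- colsum + pr
      }
    }
    total <- total + log(colsum)
  }
  total
}

# independent greedy clustering on a precomputed identity matrix
greedy_cluster_oracle <- function(ids, lens, identity, threshold) {
  ord <- order(-lens, ids)
  reps <- character(0)
  assign <- setNames(character(length(ids)), ids)
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (identity[ids[i], r] >= threshold) {
        assign[ids[i]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      assign[ids[i]] <- ids[i]
    }
  }
  assign
}

hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca == cb) / length(ca)
}

# regex expansion of a motif pattern (lazy quantifiers = leftmost-minimal)
motif_regex <- function(pattern) {
  parts <- vapply(pattern$elements, function(e) {
    if (e$type == "literal") {
      paste(vapply(e$sets, function(s) paste0("[", s, "X]"), ""),
            collapse = "")
    } else if (e$min == e$max) {
      sprintf(".{%d}", e$min)
    } else {
      sprintf(".{%d,%d}?", e$min, e$max)
    }
  }, "")
  paste(parts, collapse = "")
}

random_protein <- function(n, seed) {
  with_seed(seed, paste(sample(genecensus:::AA_LETTERS, n, replace = TRUE),
                        collapse = ""))
}
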