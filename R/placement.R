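# Maximum-likelihood placement of confirmed reads on a reference
# phylogeny: reads are projected onto the model's match columns via their
# Viterbi path, then attached to the midpoint of each tree edge by a
# pendant branch whose length is optimized; the best edge wins and
# likelihood-weight ratios are reported over all edges.
#
# Substitution models: JC69 (default) or K80 with fixed kappa; gaps and N
# in the query are missing data. The Felsenstein pruning recursion runs
# once over the reference tree; per-edge "upper" and "lower" conditional
# likelihood vectors are cached so each pendant evaluation is O(columns).

nuc_code4 <- function(chars) {
  m <- match(chars, DNA_LETTERS)
  m[is.na(m)] <- 0L  # gap / N / anything else = missing data
  m
}

pmat_jc69 <- function(t) {
  e <- exp(-4 * t / 3)
  p <- matrix(0.25 * (1 - e), 4, 4)
  diag(p) <- 0.25 + 0.75 * e
  p
}

# K80 with unit expected substitution rate: beta = 1/(kappa + 2)
pmat_k80 <- function(t, kappa = 2) {
  b <- 1 / (kappa + 2)
  a <- kappa * b
  e1 <- exp(-4 * b * t)
  e2 <- exp(-2 * (a + b) * t)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  tsn <- 0.25 + 0.25 * e1 - 0.5 * e2   # transition (A<->G, C<->T)
  tsv <- 0.25 - 0.25 * e1              # transversion
  p <- matrix(tsv, 4, 4)
  p[1, 3] <- p[3, 1] <- p[2, 4] <- p[4, 2] <- tsn
  diag(p) <- same
  p
}

#' Canonicalize a reference tree
#'
#' Roots the tree on the pendant edge of the alphabetically first leaf
#' and numbers edges deterministically in preorder (cladewise order).
#'
#' @param tree an `ape::phylo` object or path to a newick file. Branch
#'   lengths are required.
#' @return a `phylo` tree in cladewise order; edge i of `tree$edge` has
#'   `edge_id = i`.
#' @export
canonical_tree <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.null(tree$edge.length)) stopf("reference tree needs branch lengths")
  out_leaf <- sort(tree$tip.label)[1]
  if (length(tree$tip.label) > 2L) {
    tree <- ape::unroot(tree)
    tree <- ape::root(tree, outgroup = out_leaf, resolve.root = TRUE)
  }
  ape::reorder.phylo(tree, "cladewise")
}

#' Build a placement engine for a reference tree and alignment
#'
#' Precomputes per-edge conditional likelihood vectors by the pruning
#' algorithm so that any number of reads can be placed cheaply.
#'
#' @param tree reference phylogeny (`phylo` or newick path); leaves must
#'   match alignment rows.
#' @param ref_aln reference alignment restricted to the model's match
#'   columns: an `msa`, named character vector, or character matrix
#'   (rows = leaves).
#' @param model `"JC69"` (default) or `"K80"`.
#' @param kappa transition/transversion rate ratio for K80.
#' @return a `placement_engine` object.
#' @export
placement_engine <- function(tree, ref_aln, model = c("JC69", "K80"),
                             kappa = 2) {
  model <- match.arg(model)
  phy <- canonical_tree(tree)
  if (is.matrix(ref_aln)) {
    seqs <- apply(ref_aln, 1, paste, collapse = "")
  } else if (inherits(ref_aln, "msa")) {
    seqs <- setNames(ref_aln$seqs, ref_aln$ids)
  } else {
    seqs <- ref_aln
  }
  miss <- setdiff(phy$tip.label, names(seqs))
  if (length(miss)) stopf("alignment rows missing for leaves: %s",
                          paste(head(miss), collapse = ", "))
  ncols <- unique(nchar(seqs))
  if (length(ncols) != 1L) stopf("reference rows differ in length")
  pm <- function(t) if (model == "JC69") pmat_jc69(t) else pmat_k80(t, kappa)

  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  edge <- phy$edge
  elen <- phy$edge.length
  # lower conditional likelihoods, postorder
  lower <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    codes <- nuc_code4(strsplit(toupper(seqs[[phy$tip.label[i]]]), "")[[1]])
    m <- matrix(0, 4, ncols)
    obs <- codes > 0L
    m[cbind(codes[obs], which(obs))] <- 1
    m[, !obs] <- 1
    lower[[i]] <- m
  }
  post <- rev(seq_len(nrow(edge)))  # cladewise reversed = valid postorder
  child_contrib <- vector("list", nrow(edge))
  for (ei in post) {
    ch <- edge[ei, 2]
    child_contrib[[ei]] <- pm(elen[ei]) %*% lower[[ch]]
    pa <- edge[ei, 1]
    lower[[pa]] <- if (is.null(lower[[pa]])) child_contrib[[ei]] else
      lower[[pa]] * child_contrib[[ei]]
  }
  root <- edge[1, 1]
  # upper conditional likelihoods per edge (state at the parent end)
  upper <- vector("list", nrow(edge))
  for (ei in seq_len(nrow(edge))) {  # cladewise = parents before children
    pa <- edge[ei, 1]
    sibs <- which(edge[, 1] == pa & seq_len(nrow(edge)) != ei)
    u <- matrix(1, 4, ncols)
    for (si in sibs) u <- u * child_contrib[[si]]
    if (pa != root) {
      pe <- which(edge[, 2] == pa)
      u <- u * (pm(elen[pe]) %*% upper[[pe]])
    }
    upper[[ei]] <- u
  }
  # per-edge attachment factor at the edge midpoint (prior 1/4 folded in)
  amat <- vector("list", nrow(edge))
  for (ei in seq_len(nrow(edge))) {
    half <- pm(elen[ei] / 2)
    amat[[ei]] <- 0.25 * (half %*% lower[[edge[ei, 2]]]) * (half %*% upper[[ei]])
  }
  structure(list(tree = phy, model = model, kappa = kappa, ncol = ncols,
                 edge = data.frame(edge_id = seq_len(nrow(edge)),
                                   parent = edge[, 1], child = edge[, 2],
                                   length = elen),
                 amat = amat, lower = lower, upper = upper, pm = pm,
                 .leaf_seqs = as.list(seqs)),
            class = "placement_engine")
}

#' @export
print.placement_engine <- function(x, ...) {
  cat(sprintf("<placement_engine> %d leaves, %d edges, %d columns, %s\n",
              length(x$tree$tip.label), nrow(x$edge), x$ncol, x$model))
  invisible(x)
}

#' Project a read onto reference match columns via its Viterbi path
#'
#' Runs the read (on its given strand) through the nucleotide model's
#' Viterbi path; residues emitted by match states land in the
#' corresponding columns, insert-state residues are dropped, unvisited
#' columns are gapped.
#'
#' @param read_seq the read sequence (as sequenced).
#' @param hmm the nucleotide family `profile_hmm`.
#' @param strand `"+"` or `"-"` (the strand on which the read passed the
#'   cascade; `"-"` reverse-complements before alignment).
#' @return character vector of length `hmm$L` with residues or `"-"`.
#' @export
map_read_to_columns <- function(read_seq, hmm, strand = "+") {
  s <- if (identical(strand, "-")) revcomp(read_seq) else read_seq
  v <- phmm_viterbi(hmm, s)
  if (nrow(v$path) == 0L) stopf("read has a null Viterbi path; cannot project")
  out <- rep("-", hmm$L)
  res <- substring(s, v$path$pos, v$path$pos)
  out[v$path$node] <- res
  if (!any(out %in% DNA_LETTERS)) {
    stopf("projection contains no informative residue (all gap/N)")
  }
  out
}

query_codes <- function(engine, query) {
  if (length(query) == 1L && nchar(query[1]) == engine$ncol) {
    query <- strsplit(toupper(query), "")[[1]]
  }
  if (length(query) != engine$ncol) {
    stopf("query has %d columns; engine expects %d", length(query), engine$ncol)
  }
  nuc_code4(toupper(query))
}

#' Log-likelihood of attaching a query at one edge
#'
#' The query is attached by a pendant branch of length `pendant` at the
#' midpoint of edge `edge_id`; the likelihood is computed by the pruning
#' recursion over the columns where the query is non-gap (gap columns
#' contribute factor 1).
#'
#' @param engine a [placement_engine()].
#' @param query column-aligned query (character vector of length
#'   `engine$ncol`, or a string); `-` and `N` are missing.
#' @param edge_id edge number (see `engine$edge`).
#' @param pendant pendant branch length (substitutions/site, >= 0).
#' @return log-likelihood (natural log).
#' @export
edge_likelihood <- function(engine, query, edge_id, pendant) {
  if (pendant < 0) stopf("pendant length must be >= 0")
  qc <- query_codes(engine, query)
  cols <- which(qc > 0L)
  if (!length(cols)) stopf("query has no non-gap columns")
  a <- engine$amat[[edge_id]][, cols, drop = FALSE]
  p <- engine$pm(pendant)
  vals <- colSums(a * p[, qc[cols], drop = FALSE])
  sum(log(vals))
}

#' Place one read on the reference tree
#'
#' Scans every edge, optimizing the pendant branch length by bounded 1-D
#' search on `[1e-6, 5]` (tolerance 1e-4; the default pendant 0.1 is also
#' evaluated as a safeguard). Likelihood-weight ratios are the softmax of
#' per-edge optimized log-likelihoods over the full edge set. Ties break
#' toward the lowest edge id. Edges within 3 log units of the best are
#' reported, capped at 7.
#'
#' @param engine a [placement_engine()].
#' @param query column-aligned query (see [edge_likelihood()]).
#' @param read_id identifier stored in the result.
#' @return data.frame of reported placements (best first): `read_id`,
#'   `edge_id`, `log_likelihood`, `pendant_length`, `like_weight_ratio`,
#'   `rank`.
#' @export
place_read <- function(engine, query, read_id = "read") {
  qc <- query_codes(engine, query)
  cols <- which(qc > 0L)
  if (!length(cols)) stopf("query has no non-gap columns")
  qsel <- qc[cols]
  ne <- nrow(engine$edge)
  ll <- numeric(ne)
  pend <- numeric(ne)
  for (ei in seq_len(ne)) {
    a <- engine$amat[[ei]][, cols, drop = FALSE]
    f <- function(t) {
      p <- engine$pm(t)
      sum(log(colSums(a * p[, qsel, drop = FALSE])))
    }
    opt <- optimize(f, interval = c(1e-6, 5), maximum = TRUE, tol = 1e-4)
    f01 <- f(0.1)
    if (f01 > opt$objective) {
      ll[ei] <- f01; pend[ei] <- 0.1
    } else {
      ll[ei] <- opt$objective; pend[ei] <- opt$maximum
    }
  }
  lwr <- exp(ll - max(ll))
  lwr <- lwr / sum(lwr)
  best <- which.max(ll)  # which.max takes the first (lowest edge id) on ties
  keep <- which(ll >= ll[best] - 3)
  keep <- keep[order(-ll[keep], keep)]
  keep <- head(keep, 7L)
  data.frame(read_id = read_id, edge_id = engine$edge$edge_id[keep],
             log_likelihood = ll[keep], pendant_length = pend[keep],
             like_weight_ratio = lwr[keep], rank = seq_along(keep),
             stringsAsFactors = FALSE)
}

#' Place many reads
#'
#' @param engine a [placement_engine()].
#' @param queries named list (or data.frame with `read_id`, `query`) of
#'   column-aligned queries.
#' @return row-bound [place_read()] results.
#' @export
place_reads <- function(engine, queries) {
  if (is.data.frame(queries)) {
    queries <- setNames(as.list(queries$query), queries$read_id)
  }
  res <- lapply(seq_along(queries), function(i) {
    place_read(engine, queries[[i]],
               read_id = names(queries)[i] %||% paste0("read", i))
  })
  do.call(rbind, res)
}

# nearest labeled taxon below the child end of each edge (annotation)
edge_annotation <- function(engine) {
  phy <- engine$tree
  ntip <- length(phy$tip.label)
  ann <- character(nrow(engine$edge))
  dist_to_leaf <- rep(Inf, ntip + phy$Nnode)
  near_leaf <- character(ntip + phy$Nnode)
  dist_to_leaf[seq_len(ntip)] <- 0
  near_leaf[seq_len(ntip)] <- phy$tip.label
  for (ei in rev(seq_len(nrow(engine$edge)))) {  # postorder
    pa <- engine$edge$parent[ei]; ch <- engine$edge$child[ei]
    cand <- dist_to_leaf[ch] + engine$edge$length[ei]
    if (cand < dist_to_leaf[pa]) {
      dist_to_leaf[pa] <- cand
      near_leaf[pa] <- near_leaf[ch]
    }
  }
  for (ei in seq_len(nrow(engine$edge))) ann[ei] <- near_leaf[engine$edge$child[ei]]
  ann
}

#' Aggregate placements into per-edge ecotype counts
#'
#' An "ecotype" is the accumulation of placed reads at one edge of the
#' reference tree. Counts are per (sample, edge); abundance is optionally
#' normalized to the maximum cell.
#'
#' @param placements [place_reads()] output with an added `sample` column
#'   (a single implicit sample is assumed if absent).
#' @param engine the [placement_engine()] used.
#' @param count_mode `"best_edge"` counts each read once at its best
#'   edge; `"spread_lwr"` spreads each read over its reported edges by
#'   likelihood-weight ratio.
#' @param normalize `"none"` or `"max"` (normalize to the maximum cell).
#' @return data.frame: `sample`, `edge_id`, `annotation`, `count`,
#'   `abundance`.
#' @export
aggregate_ecotypes <- function(placements, engine,
                               count_mode = c("best_edge", "spread_lwr"),
                               normalize = c("none", "max")) {
  count_mode <- match.arg(count_mode)
  normalize <- match.arg(normalize)
  if (is.null(placements$sample)) placements$sample <- "sample1"
  use <- if (count_mode == "best_edge") {
    df <- placements[placements$rank == 1L, , drop = FALSE]
    df$w <- 1
    df
  } else {
    df <- placements
    df$w <- df$like_weight_ratio
    df
  }
  agg <- stats::aggregate(w ~ sample + edge_id, data = use, FUN = sum)
  names(agg)[names(agg) == "w"] <- "count"
  ann <- edge_annotation(engine)
  agg$annotation <- ann[agg$edge_id]
  agg$abundance <- if (normalize == "max" && nrow(agg) > 0L) {
    agg$count / max(agg$count)
  } else {
    agg$count
  }
  agg <- agg[order(agg$sample, agg$edge_id), c("sample", "edge_id",
                                               "annotation", "count",
                                               "abundance")]
  rownames(agg) <- NULL
  agg
}

# newick string with {edge_id} tags (jplace convention)
jplace_tree_string <- function(engine) {
  phy <- engine$tree
  edge <- engine$tree$edge
  ntip <- length(phy$tip.label)
  root <- edge[1, 1]
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  rec <- function(node) {
    eis <- kids[[as.character(node)]]
    inner <- vapply(eis, function(ei) {
      ch <- edge[ei, 2]
      lab <- if (ch <= ntip) phy$tip.label[ch] else rec(ch)
      sprintf("%s:%s{%d}", lab, formatC(phy$edge.length[ei], format = "g"), ei)
    }, "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Write placements as a jplace (version 3) file
#'
#' @param placements [place_reads()] output.
#' @param engine the [placement_engine()] used.
#' @param path output path.
#' @export
write_jplace <- function(placements, engine, path) {
  by_read <- split(placements, placements$read_id)
  pl <- lapply(names(by_read), function(id) {
    df <- by_read[[id]]
    list(p = lapply(seq_len(nrow(df)), function(i) {
      list(df$edge_id[i], df$log_likelihood[i], df$like_weight_ratio[i],
           df$pendant_length[i])
    }), n = list(id))
  })
  obj <- list(version = 3,
              tree = jplace_tree_string(engine),
              placements = pl,
              fields = list("edge_num", "likelihood", "like_weight_ratio",
                            "pendant_length"),
              metadata = list(invocation = "genecensus"))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
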