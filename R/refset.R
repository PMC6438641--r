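# Curation of non-redundant, full-length reference sets for a gene
# family: fragment removal relative to an archetype, greedy
# identity-based redundancy clustering, and conserved-motif checks.

seq_of <- function(x) {
  if (is.data.frame(x)) x$seq else if (is.list(x)) x$seq else as.character(x)
}

#' Remove fragment sequences relative to an archetype
#'
#' A record is a fragment if its length is strictly less than `fraction`
#' times the archetype length (a record at exactly the threshold is
#' retained). Input order is preserved.
#'
#' @param records data.frame with `id` and `seq`.
#' @param archetype the archetype record (data.frame row, list with
#'   `seq`, or a bare sequence string).
#' @param fraction minimum length fraction (default 0.70).
#' @return the non-fragment subset of `records`.
#' @export
filter_fragments <- function(records, archetype, fraction = 0.70) {
  aseq <- seq_of(archetype)
  if (length(aseq) != 1L || !nzchar(aseq)) stopf("archetype sequence is empty")
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  arch_a <- guess_alphabet(aseq)
  per <- vapply(records$seq, guess_alphabet, "")
  if (any(per != arch_a)) {
    stopf("mixed alphabets: records do not match the archetype")
  }
  keep <- nchar(records$seq) >= fraction * nchar(aseq)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pairwise identity: identical aligned residues / length of the shorter
# sequence, global (Needleman-Wunsch) alignment -- the convention of the
# usual greedy clustering tools
pairwise_identity <- function(a, b, alphabet = NULL) {
  alphabet <- alphabet %||% guess_alphabet(c(a, b))
  if (alphabet == "protein") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5)
  }
  Biostrings::pid(aln, type = "PID3") / 100
}

#' Greedy redundancy clustering of a reference set
#'
#' Sequences are sorted by length (descending, ties by id) and assigned
#' greedily: each sequence joins the first existing cluster whose
#' representative it matches at `threshold` identity or better, otherwise
#' it founds a new cluster. Identity is identical aligned residues over
#' the shorter sequence length (global alignment).
#'
#' @param records data.frame with `id` and `seq` (ids unique).
#' @param threshold identity threshold in (0, 1] (default 0.95).
#' @return data.frame with one row per input record: `representative`,
#'   `member`, `identity` (1 for representatives themselves), ordered by
#'   cluster foundation then membership; the number of clusters is
#'   attached as attribute `"n_clusters"`.
#' @export
cluster_redundant <- function(records, threshold = 0.95) {
  if (nrow(records) < 1L) stopf("need at least one record")
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  if (anyDuplicated(records$id)) stopf("record ids must be unique")
  alphabet <- guess_alphabet(records$seq)
  ord <- order(-nchar(records$seq), records$id)
  recs <- records[ord, , drop = FALSE]
  reps <- integer(0)  # indices into recs
  assign_rep <- integer(nrow(recs))
  ident <- numeric(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    placed <- FALSE
    for (r in reps) {
      pid <- pairwise_identity(recs$seq[i], recs$seq[r], alphabet)
      if (pid >= threshold) {
        assign_rep[i] <- r
        ident[i] <- pid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign_rep[i] <- i
      ident[i] <- 1
    }
  }
  # order: clusters by foundation order, representative first
  key <- match(assign_rep, reps)
  ord2 <- order(key, assign_rep != seq_len(nrow(recs)), recs$id)
  out <- data.frame(representative = recs$id[assign_rep][ord2],
                    member = recs$id[ord2],
                    identity = ident[ord2],
                    stringsAsFactors = FALSE)
  attr(out, "n_clusters") <- length(reps)
  attr(out, "threshold") <- threshold
  out
}

#' Curate a reference set (fragments, motifs, redundancy)
#'
#' Applies [filter_fragments()], then [scan_motif()] against the supplied
#' conserved-motif patterns (warn-and-flag by default; the motifs are
#' descriptive, not a hard filter), then [cluster_redundant()], keeping
#' cluster representatives.
#'
#' @param records data.frame with `id` and `seq`.
#' @param archetype archetype record (see [filter_fragments()]).
#' @param patterns a single motif pattern or list of patterns; a record
#'   is flagged if it matches none of them. `NULL` skips the motif step.
#' @param fraction fragment length fraction (default 0.70).
#' @param threshold clustering identity threshold (default 0.95).
#' @param motif_policy `"warn"` (flag, keep) or `"drop"`.
#' @return list with `records` (curated representatives), `clusters`,
#'   `report` (per-step removed/retained counts) and `motif_flagged`
#'   (ids).
#' @export
validate_family <- function(records, archetype, patterns = NULL,
                            fraction = 0.70, threshold = 0.95,
                            motif_policy = c("warn", "drop")) {
  motif_policy <- match.arg(motif_policy)
  n0 <- nrow(records)
  full <- filter_fragments(records, archetype, fraction)
  n_frag <- n0 - nrow(full)
  flagged <- character(0)
  n_motif_removed <- 0L
  if (!is.null(patterns) && nrow(full) > 0L) {
    if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
    ok <- vapply(full$seq, function(s) {
      any(vapply(patterns, function(p) scan_motif(s, p)$match, NA))
    }, NA)
    flagged <- full$id[!ok]
    if (motif_policy == "drop") {
      full <- full[ok, , drop = FALSE]
      n_motif_removed <- length(flagged)
    } else if (length(flagged)) {
      warning(sprintf("%d record(s) lack the family motif(s): %s",
                      length(flagged), paste(head(flagged), collapse = ", ")))
    }
  }
  if (nrow(full) == 0L) stopf("no records survive curation")
  cl <- cluster_redundant(full, threshold)
  rep_ids <- unique(cl$representative)
  curated <- full[match(rep_ids, full$id), , drop = FALSE]
  rownames(curated) <- NULL
  report <- data.frame(
    step = c("input", "fragments_removed", "motif_flagged", "motif_removed",
             "redundant_removed", "clusters"),
    count = c(n0, n_frag, length(flagged), n_motif_removed,
              nrow(full) - nrow(curated), nrow(curated)))
  list(records = curated, clusters = cl, report = report,
       motif_flagged = flagged)
}
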