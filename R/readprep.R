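# Read quality control and translated confirmation of candidate hits.

#' Sliding-window quality trimming
#'
#' Scans each read 5' to 3' with a window of `window` bases; at the first
#' window whose mean Phred quality drops below `min_mean_q` the read is
#' cut at the window start, then extended through any immediately
#' following bases that individually meet `min_mean_q` (the common
#' 5'-scan trimmer convention). Reads shorter than `min_len` after
#' cutting are dropped. Reads without qualities pass through the length
#' filter only.
#'
#' @param reads data.frame with `id`, `seq` and `qual` (Phred+33 strings;
#'   may be `NA`).
#' @param window window width in bases (default 4).
#' @param min_mean_q minimum mean window quality (default 25).
#' @param min_len minimum retained read length (default 70).
#' @return the trimmed reads (same columns); the number of reads dropped
#'   is attached as attribute `"dropped"`.
#' @export
trim_reads <- function(reads, window = 4, min_mean_q = 25, min_len = 70) {
  if (window < 1) stopf("window must be >= 1")
  n <- nrow(reads)
  keep_len <- nchar(reads$seq)
  has_q <- !is.na(reads$qual)
  # fast path: reads whose minimum base quality is already >= threshold
  # cannot contain a failing window
  needs_scan <- which(has_q &
    vapply(reads$qual, function(q) any(utf8ToInt(q) - 33L < min_mean_q), NA))
  for (i in needs_scan) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    len <- length(q)
    if (len < window) next
    cs <- cumsum(c(0L, q))
    wmean <- (cs[(window + 1L):(len + 1L)] - cs[1:(len - window + 1L)]) / window
    bad <- which(wmean < min_mean_q)
    if (length(bad)) {
      s <- bad[1L]  # window start (1-based); cut here...
      e <- s - 1L
      while (e + 1L <= len && q[e + 1L] >= min_mean_q) e <- e + 1L
      keep_len[i] <- e
    }
  }
  trimmed <- keep_len < nchar(reads$seq)
  reads$seq[trimmed] <- substr(reads$seq[trimmed], 1L, keep_len[trimmed])
  reads$qual[trimmed & has_q] <-
    substr(reads$qual[trimmed & has_q], 1L, keep_len[trimmed & has_q])
  drop <- keep_len < min_len
  out <- reads[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(drop)
  out
}

#' Six-frame translation of a DNA read
#'
#' Standard genetic code; stop codons are rendered `*` and retained;
#' codons containing `N` translate to `X`. Reverse frames translate the
#' reverse complement.
#'
#' @param seq a single DNA string (N allowed).
#' @return data.frame with `frame` (one of +1,+2,+3,-1,-2,-3) and
#'   `peptide`.
#' @export
six_frame_translate <- function(seq) {
  if (!is_dna_seq(seq)) stopf("six_frame_translate expects a DNA sequence")
  code <- Biostrings::GENETIC_CODE
  fr_pep <- function(s, off) {
    len <- 3L * ((nchar(s) - off) %/% 3L)
    if (len < 3L) return("")
    starts <- seq.int(off + 1L, off + len, by = 3L)
    codons <- substring(toupper(s), starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
    paste(aa, collapse = "")
  }
  rc <- revcomp(seq)
  data.frame(
    frame = c("+1", "+2", "+3", "-1", "-2", "-3"),
    peptide = c(fr_pep(seq, 0L), fr_pep(seq, 1L), fr_pep(seq, 2L),
                fr_pep(rc, 0L), fr_pep(rc, 1L), fr_pep(rc, 2L)),
    stringsAsFactors = FALSE)
}

#' Translate an ungapped nucleotide reference set in frame +1
#'
#' Convenience for building the protein-level family model from coding
#' reference sequences: every sequence is translated in frame +1 (stops
#' retained as `*`, fuzzy codons as `X`) and returned as a protein
#' alignment (the input must be ungapped and equal-length).
#'
#' @param seqs named character vector of coding DNA sequences.
#' @return a protein [as_msa()] alignment.
#' @export
translate_refs <- function(seqs) {
  peps <- vapply(seqs, function(s) six_frame_translate(s)$peptide[1], "")
  as_msa(peps, alphabet = "protein")
}

#' Confirm cascade candidates by six-frame translation
#'
#' A candidate read is confirmed if at least one of its six translation
#' frames scores an E-value below `evalue_max` against the family's
#' protein model (Forward stage). `*` and `X` residues score as
#' background (never a match bonus).
#'
#' @param candidates data.frame from [search_reads()] (needs `read_id`).
#' @param reads data.frame with `id` and `seq` for every candidate.
#' @param protein_hmm calibrated protein `profile_hmm` of the family.
#' @param evalue_max confirmation E-value threshold (default 1e-5).
#' @param db_size effective database size (default: number of
#'   candidates).
#' @return the confirmed subset of `candidates` with extra columns
#'   `frame`, `prot_bits`, `prot_evalue`.
#' @export
confirm_hits <- function(candidates, reads, protein_hmm, evalue_max = 1e-5,
                         db_size = NULL) {
  if (protein_hmm$alphabet != "protein") stopf("protein model required")
  if (is.null(protein_hmm$calibration)) stopf("protein HMM must be calibrated")
  if (nrow(candidates) == 0L) {
    out <- cbind(candidates,
                 data.frame(frame = character(0), prot_bits = numeric(0),
                            prot_evalue = numeric(0)))
    return(out)
  }
  idx <- match(candidates$read_id, reads$id)
  if (anyNA(idx)) {
    stopf("candidate read(s) missing from the read set: %s",
          paste(head(candidates$read_id[is.na(idx)]), collapse = ", "))
  }
  db_size <- db_size %||% nrow(candidates)
  frame <- character(nrow(candidates))
  bits <- numeric(nrow(candidates))
  ev <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    tr <- six_frame_translate(reads$seq[idx[i]])
    sc <- vapply(tr$peptide, function(p) {
      if (!nzchar(p)) return(0)
      phmm_forward(protein_hmm, p)
    }, 0)
    best <- which.max(sc)
    frame[i] <- tr$frame[best]
    bits[i] <- sc[best]
    ev[i] <- stage_pvalue(protein_hmm, "forward", sc[best]) * db_size
  }
  out <- candidates
  out$frame <- frame
  out$prot_bits <- bits
  out$prot_evalue <- ev
  out <- out[out$prot_evalue < evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}
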