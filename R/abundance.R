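# Percent genome equivalents: single-copy-gene normalization of
# per-family read counts.
#
# Genome equivalents (GE) estimate the number of genomes sampled in a
# read set as the mean of the size-normalized counts of four universal
# single-copy genes (recA, atpD, gyrB, rpoB). Counts are size-normalized
# to the shortest gene, recA, by multiplying each count by
# modal_length(recA) / modal_length(gene); a target family's abundance is
# then expressed as a percentage of GE.

#' Modal (most frequent) ungapped sequence length of a reference set
#'
#' Ties are broken toward the smallest length.
#'
#' @param x data.frame with a `seq` column, a character vector of
#'   sequences, or an integer vector of lengths.
#' @return integer modal length.
#' @export
modal_length <- function(x) {
  if (is.data.frame(x)) x <- x$seq
  lens <- if (is.numeric(x)) as.integer(x) else nchar(gsub("-", "", x, fixed = TRUE))
  if (length(lens) == 0L) stopf("empty reference set")
  tab <- table(lens)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

#' Default single-copy gene modal lengths (nt)
#'
#' The modal reference lengths of the four normalizer genes: recA 1044,
#' atpD 1422, gyrB 2415, rpoB 4029.
#'
#' @return named integer vector.
#' @export
default_modal_lengths <- function() {
  c(recA = 1044L, atpD = 1422L, gyrB = 2415L, rpoB = 4029L)
}

#' Size-normalize a single-copy gene count
#'
#' Multiplies `count` by `ref_modal_len / gene_modal_len`, correcting for
#' the length-proportional sampling of longer genes.
#'
#' @param count raw homologue count (>= 0).
#' @param gene_modal_len modal length (nt) of the counted gene.
#' @param ref_modal_len modal length of the reference (shortest) gene,
#'   default recA's 1044 nt.
#' @return normalized count.
#' @export
size_normalize <- function(count, gene_modal_len, ref_modal_len = 1044) {
  if (any(count < 0)) stopf("count must be >= 0")
  if (any(gene_modal_len <= 0) || any(ref_modal_len <= 0)) {
    stopf("modal lengths must be positive")
  }
  count * ref_modal_len / gene_modal_len
}

#' Assemble a single-copy gene panel
#'
#' @param counts named numeric vector of raw per-sample counts for the
#'   four single-copy genes.
#' @param modal_lengths named integer vector of modal lengths; defaults
#'   to [default_modal_lengths()].
#' @param ref_gene the size-normalization reference gene (default
#'   `"recA"`).
#' @return a `single_copy_panel` object.
#' @export
single_copy_panel <- function(counts,
                              modal_lengths = default_modal_lengths(),
                              ref_gene = "recA") {
  if (!ref_gene %in% names(modal_lengths)) {
    stopf("reference gene '%s' missing from modal lengths", ref_gene)
  }
  if (any(modal_lengths <= 0)) stopf("modal lengths must be positive")
  structure(list(counts = counts, modal_lengths = modal_lengths,
                 ref_gene = ref_gene),
            class = "single_copy_panel")
}

#' Genome equivalents from a single-copy gene panel
#'
#' Arithmetic mean of the four size-normalized single-copy gene counts.
#' By default all panel genes must be counted; set
#' `allow_missing = TRUE` to average over the available genes with a
#' warning.
#'
#' @param panel a [single_copy_panel()].
#' @param allow_missing tolerate missing genes (warn, average the rest).
#' @return genome-equivalent estimate (numeric).
#' @export
genome_equivalents <- function(panel, allow_missing = FALSE) {
  stopifnot(inherits(panel, "single_copy_panel"))
  genes <- names(panel$modal_lengths)
  have <- genes %in% names(panel$counts) & !is.na(panel$counts[genes])
  if (!all(have)) {
    if (!allow_missing) {
      stopf("missing single-copy gene count(s): %s",
            paste(genes[!have], collapse = ", "))
    }
    warning("averaging genome equivalents over available genes only: ",
            paste(genes[have], collapse = ", "))
    genes <- genes[have]
  }
  ref_len <- panel$modal_lengths[[panel$ref_gene]]
  norm <- size_normalize(panel$counts[genes], panel$modal_lengths[genes],
                         ref_len)
  mean(norm)
}

#' Percent genome equivalents of a target gene family
#'
#' Expresses a target family's confirmed-read count as a percentage of
#' the genome equivalents in the read set. Three documented
#' interpretations of the size factor are available:
#' \describe{
#'   \item{`length_ratio` (default)}{`100 * count * (ref_modal_len /
#'     target_modal_len) / GE` - the target count is size-normalized
#'     exactly like the single-copy counts, so a gene carried by p% of
#'     genomes is reported as p %GE.}
#'   \item{`ratio`}{`100 * count / GE` (no size factor).}
#'   \item{`literal`}{`100 * count * mean_read_length / GE`.}
#' }
#'
#' @param target_count confirmed-read count for the family (>= 0).
#' @param GE genome equivalents (> 0), from [genome_equivalents()].
#' @param mode size-factor interpretation (see above).
#' @param target_modal_len modal length of the target gene (nt; required
#'   for `length_ratio`).
#' @param ref_modal_len modal length of the normalization reference gene
#'   (default 1044 nt, recA).
#' @param mean_read_length mean trimmed read length (nt; required for
#'   `literal`).
#' @return list with `percent_GE`, `raw_ratio` (`count / GE`) and the
#'   `mode` used.
#' @export
percent_GE <- function(target_count, GE,
                       mode = c("length_ratio", "ratio", "literal"),
                       target_modal_len = NULL, ref_modal_len = 1044,
                       mean_read_length = NULL) {
  mode <- match.arg(mode)
  if (GE <= 0) stopf("GE must be positive")
  if (target_count < 0) stopf("target_count must be >= 0")
  factor <- switch(mode,
    length_ratio = {
      if (is.null(target_modal_len)) {
        stopf("target_modal_len required for length_ratio mode")
      }
      ref_modal_len / target_modal_len
    },
    ratio = 1,
    literal = {
      if (is.null(mean_read_length)) {
        stopf("mean_read_length required for literal mode")
      }
      mean_read_length
    })
  list(percent_GE = 100 * target_count * factor / GE,
       raw_ratio = target_count / GE,
       mode = mode)
}

#' Build an abundance report row
#'
#' @param sample sample label.
#' @param family target family label.
#' @param target_count confirmed-read count.
#' @param panel [single_copy_panel()] for the sample.
#' @param mode `percent_GE` mode.
#' @param target_modal_len,mean_read_length see [percent_GE()].
#' @return one-row data.frame: sample, family, raw_count, GE, percent_GE,
#'   mode, mean_read_length.
#' @export
abundance_report <- function(sample, family, target_count, panel,
                             mode = "length_ratio",
                             target_modal_len = NULL,
                             mean_read_length = NA_real_) {
  GE <- genome_equivalents(panel)
  pg <- percent_GE(target_count, GE, mode,
                   target_modal_len = target_modal_len,
                   ref_modal_len = panel$modal_lengths[[panel$ref_gene]],
                   mean_read_length = mean_read_length)
  data.frame(sample = sample, family = family, raw_count = target_count,
             GE = GE, percent_GE = pg$percent_GE, mode = pg$mode,
             mean_read_length = mean_read_length,
             stringsAsFactors = FALSE)
}
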