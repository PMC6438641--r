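# FASTA/FASTQ/alignment readers and writers (Biostrings-backed, gzip
# transparent) plus small sequence utilities shared across modules.

split_header <- function(x) {
  id <- sub("\\s.*$", "", x)
  desc <- ifelse(grepl("\\s", x), sub("^\\S+\\s+", "", x), "")
  list(id = id, desc = desc)
}

#' Read sequences from a FASTA file
#'
#' @param path file path (plain or gzip).
#' @return data.frame with columns `id`, `seq`, `desc`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  h <- split_header(names(x))
  data.frame(id = h$id, seq = as.character(x), desc = h$desc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x data.frame with `id` and `seq` (optionally `desc`), or a named
#'   character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- data.frame(id = names(x), seq = unname(x))
  hdr <- if (!is.null(x$desc) && any(nzchar(x$desc))) {
    trimws(paste(x$id, x$desc))
  } else {
    x$id
  }
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read reads from a FASTQ (or FASTA) file
#'
#' @param path file path; format is taken from the extension (`.fastq`,
#'   `.fq` possibly gzipped mean FASTQ).
#' @return data.frame with columns `id`, `seq` and `qual` (Phred+33 string,
#'   `NA` for FASTA input).
#' @export
read_reads <- function(path) {
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  if (fastq) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    qual <- rep(NA_character_, length(x))
  }
  h <- split_header(names(x))
  data.frame(id = h$id, seq = as.character(x), qual = qual,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33 strings).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$id
  q <- Biostrings::PhredQuality(reads$qual)
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param seqs character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Phred+33 quality string -> integer scores
#' @param qual character vector of quality strings.
#' @return list of integer vectors.
#' @export
decode_qual <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) integer(0) else utf8ToInt(q) - 33L
  })
}

random_residues <- function(n, letters, prob = NULL) {
  paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
}

# multiple sequence alignment container ----------------------------------

#' Construct a multiple sequence alignment object
#'
#' @param seqs named character vector (or data.frame with `id`, `seq`) of
#'   equal-length gapped sequences; `-` and `.` are gap symbols.
#' @param alphabet `"dna"`, `"protein"`, or `NULL` to guess.
#' @return an object of class `msa`: list with `ids`, `seqs`, `ncol`,
#'   `alphabet`.
#' @export
as_msa <- function(seqs, alphabet = NULL) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  if (inherits(seqs, "msa")) return(seqs)
  widths <- nchar(seqs)
  if (length(seqs) < 1L) stopf("alignment needs at least one row")
  if (length(unique(widths)) != 1L) stopf("alignment rows differ in length")
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  alphabet <- alphabet %||% guess_alphabet(seqs)
  structure(list(ids = names(seqs) %||% paste0("row", seq_along(seqs)),
                 seqs = unname(seqs), ncol = widths[[1]],
                 alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns (%s)\n",
              length(x$seqs), x$ncol, x$alphabet))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm format (detected from the first
#' non-blank line).
#'
#' @param path file path.
#' @param alphabet `"dna"`, `"protein"`, or `NULL` to guess.
#' @return an `msa` object.
#' @export
read_msa <- function(path, alphabet = NULL) {
  con <- file(path, "rt")
  on.exit(close(con))
  first <- ""
  while (!nzchar(trimws(first))) first <- readLines(con, 1L)
  close(con)
  on.exit()
  if (startsWith(first, "# STOCKHOLM")) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines)) & !grepl("^//", lines)]
    parts <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(parts, `[[`, "", 1L)
    segs <- vapply(parts, `[[`, "", 2L)
    seqs <- vapply(split(segs, factor(ids, levels = unique(ids))),
                   paste, "", collapse = "")
    as_msa(seqs, alphabet)
  } else {
    df <- read_fasta(path)
    as_msa(setNames(df$seq, df$id), alphabet)
  }
}

# character matrix view of an alignment (rows x columns)
msa_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}
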