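# Conserved amino-acid motifs of the non-specific acid phosphatase
# (NSAP) classes, and a spacer-aware motif scanner.
#
# Class A enzymes share K-X6-RP ... PSGH ... SR-X5-H-X2-D (phosphatase
# signature also found in lipid phosphatases and glucose-6-phosphatases);
# class B has an N-terminal P-X4-FDIDDT-X-VLFSSP-X-F and a C-terminal
# YGD(S/A)DXD-X3-A; class C carries four conserved aspartates across
# DXDET (N-terminal) and GD-X3-DF (C-terminal).

el_lit <- function(...) {
  sets <- as.character(unlist(list(...)))
  list(type = "literal", sets = sets)
}

el_x <- function(min, max = min) {
  stopifnot(min <= max, min >= 0)
  list(type = "gap", min = as.integer(min), max = as.integer(max))
}

#' Construct a motif pattern
#'
#' A pattern is an ordered list of elements: literal positions (each a
#' string of allowed residues, e.g. `"SA"` for S-or-A) and wildcard runs
#' with length bounds.
#'
#' @param elements list of elements built with the internal `el_lit()` /
#'   `el_x()` helpers; see [nsap_motif()] for the built-in patterns.
#' @param family optional family label.
#' @return a `motif_pattern` object.
#' @export
motif_pattern <- function(elements, family = NA_character_) {
  lits <- vapply(elements, function(e) e$type == "literal", NA)
  if (!any(lits)) stopf("pattern needs at least one literal element")
  for (e in elements) {
    if (e$type == "gap" && e$min > e$max) stopf("wildcard run has min > max")
  }
  structure(list(family = family, elements = elements),
            class = "motif_pattern")
}

#' Built-in NSAP class motif patterns
#'
#' @param family one of `"classA"`, `"classB_N"`, `"classB_C"`,
#'   `"classC_N"`, `"classC_C"`.
#' @return a `motif_pattern`.
#' @export
nsap_motif <- function(family = c("classA", "classB_N", "classB_C",
                                  "classC_N", "classC_C")) {
  family <- match.arg(family)
  els <- switch(family,
    # K X6 RP (X12-54) PSGH (X31-54) SR X5 H X2 D
    classA = list(el_lit("K"), el_x(6), el_lit("R", "P"), el_x(12, 54),
                  el_lit("P", "S", "G", "H"), el_x(31, 54),
                  el_lit("S", "R"), el_x(5), el_lit("H"), el_x(2),
                  el_lit("D")),
    # P X4 FDIDDT X VLFSSP X F
    classB_N = list(el_lit("P"), el_x(4),
                    el_lit("F", "D", "I", "D", "D", "T"), el_x(1),
                    el_lit("V", "L", "F", "S", "S", "P"), el_x(1),
                    el_lit("F")),
    # YGD(S/A)DXD X3 A
    classB_C = list(el_lit("Y", "G", "D", "SA", "D"), el_x(1), el_lit("D"),
                    el_x(3), el_lit("A")),
    # DXDET
    classC_N = list(el_lit("D"), el_x(1), el_lit("D", "E", "T")),
    # GD X3 DF
    classC_C = list(el_lit("G", "D"), el_x(3), el_lit("D", "F")))
  motif_pattern(els, family)
}

#' Scan a protein sequence for a motif
#'
#' Elements must occur in order with spacer lengths inside their bounds.
#' An `X` in the sequence matches any literal position. The leftmost
#' match is reported, with minimal (lazy) spacer lengths.
#'
#' @param record a protein sequence string (or data.frame row / list with
#'   `seq`).
#' @param pattern a [motif_pattern()].
#' @return list with `match` (logical), `start`, `end` (NA if no match).
#' @export
scan_motif <- function(record, pattern) {
  seq <- seq_of(record)
  stopifnot(inherits(pattern, "motif_pattern"))
  if (is_dna_seq(seq) && nzchar(seq)) {
    stopf("scan_motif expects a protein sequence")
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  els <- pattern$elements
  match_from <- function(pos, ei) {
    if (ei > length(els)) return(pos - 1L)  # end position of the match
    e <- els[[ei]]
    if (e$type == "literal") {
      m <- length(e$sets)
      if (pos + m - 1L > n) return(NA_integer_)
      for (j in seq_len(m)) {
        ch <- chars[pos + j - 1L]
        if (ch != "X" && !grepl(ch, e$sets[j], fixed = TRUE)) {
          return(NA_integer_)
        }
      }
      match_from(pos + m, ei + 1L)
    } else {
      for (w in e$min:e$max) {  # minimal spacer first (lazy)
        if (pos + w > n + 1L) return(NA_integer_)
        r <- match_from(pos + w, ei + 1L)
        if (!is.na(r)) return(r)
      }
      NA_integer_
    }
  }
  for (start in seq_len(max(n, 0L))) {
    r <- match_from(start, 1L)
    if (!is.na(r)) {
      return(list(match = TRUE, start = start, end = r))
    }
  }
  list(match = FALSE, start = NA_integer_, end = NA_integer_)
}
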