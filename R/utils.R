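#' @keywords internal
"_PACKAGE"

#' @useDynLib genecensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize optim rbinom rexp runif sd setNames rmultinom median
#' @importFrom utils head write.table read.table
NULL

DNA_LETTERS <- c("A", "C", "G", "T")
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

# 0 = dna, 1 = protein (codes shared with the C++ kernels)
alphabet_code <- function(alphabet) {
  switch(match.arg(alphabet, c("dna", "protein")), dna = 0L, protein = 1L)
}

alphabet_size <- function(alphabet) if (alphabet == "dna") 4L else 20L

#' Guess the alphabet of a set of sequences
#'
#' @param seqs character vector of residue strings.
#' @return `"dna"` or `"protein"`.
#' @export
guess_alphabet <- function(seqs) {
  chars <- unique(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]])
  chars <- setdiff(chars, c("-", ".", "N", "U"))
  if (all(chars %in% DNA_LETTERS)) "dna" else "protein"
}

is_dna_seq <- function(seqs) {
  !grepl("[^ACGTUNacgtun]", seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic numeric formatting for byte-stable TSV output
format_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_tsv_stable <- function(df, path, digits = 6) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
      df2[[j]] <- format_num(df2[[j]], digits)
    }
  }
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
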