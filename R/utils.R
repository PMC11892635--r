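#' @importFrom methods is
#' @importFrom stats median quantile rnorm rlnorm runif setNames complete.cases
#' @importFrom utils combn head tail
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over character strings (DNA alphabet,
#' `N` allowed).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length, each string reverse
#'   complemented.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# substring that returns "" (not NA) for empty intervals
substr_safe <- function(s, start, end) {
  if (end < start) return("")
  substr(s, start, end)
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# normalize a nucleotide string: uppercase, U -> T
normalize_nt <- function(s) {
  chartr("uU", "tT", toupper(s))
}

# check alphabet; returns offset of first bad char or 0L
first_bad_base <- function(s, allowed = c(BASES, "N")) {
  cc <- chars(s)
  bad <- which(!cc %in% allowed)
  if (length(bad)) bad[1] else 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
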