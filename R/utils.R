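#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(as.character(x), revcomp_cpp, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' Uniform i.i.d. draw over A/C/G/T, using the current RNG state.
#'
#' @param n sequence length in bp.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "anchorasm_error")))
}
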