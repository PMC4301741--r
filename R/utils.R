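#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom methods as
NULL

BASES <- c("A", "C", "G", "T")

#' Random DNA sequence with a target GC content
#'
#' @param n Length in bp.
#' @param gc Target GC fraction.
#' @return A character scalar over {A,C,G,T}.
#' @keywords internal
random_dna <- function(n, gc = 0.44) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#' @param s Character scalar.
#' @return Character scalar.
#' @keywords internal
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' All k-mers of a string (vectorized)
#' @param s Character scalar.
#' @param k Word size.
#' @return Character vector of length nchar(s) - k + 1 (empty if shorter).
#' @keywords internal
kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

#' Split a string into single characters
#' @keywords internal
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Overwrite a substring in place
#' @keywords internal
str_assign <- function(s, at, replacement) {
  len <- nchar(replacement)
  paste0(substr(s, 1, at - 1), replacement, substr(s, at + len, nchar(s)))
}
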