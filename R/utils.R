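#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats runif quantile setNames rmultinom
#' @importFrom utils head tail write.table
NULL

# Round half away from zero, the convention used by the summary tables.
# base::round() rounds half to even, which disagrees with printed tables
# (e.g. 1.2225 must report as 1.223 at 3 decimals).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequence
#'
#' Uniform i.i.d. nucleotides; used for synthetic genome backgrounds.
#'
#' @param n Length in bp.
#' @param alphabet Characters to draw from.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Reverse complement for plain character vectors.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Partition `total` bp of background into `k` non-negative gap lengths.
random_composition <- function(total, k) {
  if (k == 1) return(total)
  if (total == 0) return(rep(0L, k))
  as.integer(rmultinom(1, total, rep(1 / k, k)))
}
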