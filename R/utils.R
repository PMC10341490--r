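# Shared small helpers.

#' Round half away from zero
#'
#' Commercial rounding as used for the percentage columns of the library
#' summary report (R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Amplicon primer set
#'
#' The common forward primer and the two hinge-specific reverse primers of
#' the VHH sequencing amplicon. The reverse primers distinguish the short
#' (IgG2-derived) from the long (IgG3-derived) hinge isotype.
#'
#' @return named list with `fwd`, `rev_short_IgG2`, `rev_long_IgG3`
#'   (IUPAC nucleotide strings, written 5'->3' on their own strand).
#' @export
defaultPrimers <- function() {
  list(fwd = "GGTGCAGCTCGTGGAGTCTGGGGG",
       rev_short_IgG2 = "GGGGTCTTCGCTGTGGTGCGC",
       rev_long_IgG3 = "GTGGTTTTGGTGTCTTGGGTTC")
}

# reverse complement of a character vector of DNA strings
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse each string (for reversing quality strings alongside revComp)
revString <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# derive a stream-specific 32-bit seed from a master seed
deriveSeed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}

# IUPAC-aware mismatch count of a primer against fixed positions of sequences
iupacMismatches <- function(seqs, primer, starts) {
  .iupacMatchCountCpp(seqs, primer, as.integer(starts))
}

phredToChar <- function(q) {
  intToUtf8(pmin(q, 60L) + 33L, multiple = FALSE)
}
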