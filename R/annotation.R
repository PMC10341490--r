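#' Locate CDR3 within a VHH amino-acid sequence
#'
#' Uses an IMGT-like anchor convention: the conserved FR3 cysteine is the
#' C of the last `[YFW][YFAVLI]C` motif whose C falls within the first
#' 110 residues (fallback: the last C before position 110), and the
#' conserved FR4 tryptophan is the W of the first `WG.G` motif at or
#' after four residues past the cysteine (fallback: the first W after
#' the cysteine). CDR3 is the segment strictly between the two anchors.
#'
#' @param aaSeqs character vector of VHH amino-acid sequences.
#' @param cysWindow anchor search window for the cysteine (residues).
#' @param minLen,maxLen accepted CDR3 length bounds.
#' @return data.frame with `aa_seq`, `cdr3`, `cys_anchor_pos` and
#'   `trp_anchor_pos` (0-based anchor indices), and `status` (`ok`,
#'   `no_cys_anchor`, `no_trp_anchor`, or `anchors_crossed`; the last
#'   also flags CDR3 lengths outside `[minLen, maxLen]`).
#' @examples
#' extractCDR3("SAVYYCAKDRESWGQGTQVTVSS")$cdr3 # "AKDRES"
#' @export
extractCDR3 <- function(aaSeqs, cysWindow = 110L, minLen = 3L, maxLen = 40L) {
  n <- length(aaSeqs)
  cdr3 <- rep(NA_character_, n)
  cys <- rep(NA_integer_, n)
  trp <- rep(NA_integer_, n)
  status <- rep("ok", n)

  for (i in seq_len(n)) {
    s <- aaSeqs[i]
    # cysteine anchor: last motif match with C at position <= cysWindow
    m <- gregexpr("(?=[YFW][YFAVLI]C)", s, perl = TRUE)[[1]]
    cpos <- NA_integer_
    if (m[1] != -1L) {
      cand <- as.integer(m) + 2L            # 1-based C position
      cand <- cand[cand <= cysWindow]
      if (length(cand)) cpos <- cand[length(cand)]
    }
    if (is.na(cpos)) {
      cs <- gregexpr("C", s, fixed = TRUE)[[1]]
      if (cs[1] != -1L) {
        cand <- as.integer(cs)
        cand <- cand[cand <= cysWindow]
        if (length(cand)) cpos <- cand[length(cand)]
      }
    }
    if (is.na(cpos)) { status[i] <- "no_cys_anchor"; next }

    # tryptophan anchor: first WG.G at or after cpos + 4
    rest <- substr(s, cpos + 4L, nchar(s))
    w <- regexpr("WG.G", rest)
    wpos <- if (w[1] != -1L) cpos + 3L + as.integer(w) else NA_integer_
    if (is.na(wpos)) {
      w2 <- regexpr("W", substr(s, cpos + 1L, nchar(s)), fixed = TRUE)
      if (w2[1] != -1L) wpos <- cpos + as.integer(w2)
    }
    if (is.na(wpos)) { status[i] <- "no_trp_anchor"; next }

    len <- wpos - cpos - 1L
    if (len < minLen || len > maxLen) { status[i] <- "anchors_crossed"; next }
    cys[i] <- cpos - 1L     # report 0-based
    trp[i] <- wpos - 1L
    cdr3[i] <- substr(s, cpos + 1L, wpos - 1L)
  }
  data.frame(aa_seq = aaSeqs, cdr3 = cdr3, cys_anchor_pos = cys,
             trp_anchor_pos = trp, status = status)
}

#' Global-alignment identity of two CDR3 sequences
#'
#' Identity is matches / alignment length under a global alignment in
#' which every gap column (terminal included) counts as a mismatch.
#' Symmetric, and 1 for identical strings.
#'
#' @param a,b non-empty amino-acid strings (vectorized, recycled to the
#'   longer length).
#' @return numeric vector of identities in `[0, 1]`.
#' @examples
#' cdr3Identity("AKDRES", "AKDRET") # 5/6
#' @export
cdr3Identity <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty sequence")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  m <- .alignIdentityCpp(a, b, FALSE)
  as.numeric(m[, "matches"] / m[, "columns"])
}
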