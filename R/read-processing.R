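#' Read-processing parameters
#'
#' Defaults follow community-standard amplicon practice: minimum overlap
#' 20 nt, at most 10% mismatches in the overlap, at most 1.0 expected
#' errors per merged read, up to 2 primer mismatches within a 5 nt window
#' of either read end, and a minimum translated length of 90 aa.
#'
#' @param minOverlap minimum read-pair overlap (nt).
#' @param maxMismatchFrac maximum mismatch fraction within the overlap.
#' @param maxExpectedErrors expected-error ceiling for the quality filter.
#' @param maxPrimerMismatches IUPAC-aware mismatches tolerated per primer.
#' @param primerWindow how far from the read end a primer may start (nt).
#' @param minAALength minimum accepted VHH length (aa).
#' @param frameOffset nt offset of the codon frame after the forward
#'   primer 3' end (0 = the first base after the primer starts a codon).
#' @param primers list with `fwd`, `rev_short_IgG2`, `rev_long_IgG3`.
#' @return list of parameters for [processReads()].
#' @export
processParams <- function(minOverlap = 20L, maxMismatchFrac = 0.1,
                          maxExpectedErrors = 1.0, maxPrimerMismatches = 2L,
                          primerWindow = 5L, minAALength = 90L,
                          frameOffset = 0L, primers = defaultPrimers()) {
  list(minOverlap = as.integer(minOverlap), maxMismatchFrac = maxMismatchFrac,
       maxExpectedErrors = maxExpectedErrors,
       maxPrimerMismatches = as.integer(maxPrimerMismatches),
       primerWindow = as.integer(primerWindow),
       minAALength = as.integer(minAALength),
       frameOffset = as.integer(frameOffset), primers = primers)
}

#' Merge paired-end reads by best ungapped overlap
#'
#' Finds the ungapped suffix/prefix overlap of R1 with the reverse
#' complement of R2 that maximizes matched bases, requiring at least
#' `minOverlap` overlapping bases with a mismatch fraction of at most
#' `maxMismatchFrac`. At overlap mismatches the consensus takes the
#' higher-quality base; agreeing bases get combined quality. Pairs that
#' fail in the given orientation are retried with the mates swapped
#' (flipped sequencing orientation).
#'
#' @param r1,r2 character vectors of mate sequences.
#' @param q1,q2 matching Sanger-offset quality strings (defaults: Q40).
#' @param minOverlap,maxMismatchFrac see above.
#' @param tryBothOrientations retry swapped mates on failure.
#' @return data.frame with `merged` (logical), `seq`, `qual`,
#'   `overlap_len`, `mismatches_in_overlap`, `flipped`.
#' @examples
#' mergePairs("ACGTACGTAA", as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAString("GTACGTAACC"))), minOverlap = 8)
#' @export
mergePairs <- function(r1, r2, q1 = NULL, q2 = NULL, minOverlap = 20L,
                       maxMismatchFrac = 0.1, tryBothOrientations = TRUE) {
  if (is.null(q1)) q1 <- strrep("I", nchar(r1))
  if (is.null(q2)) q2 <- strrep("I", nchar(r2))
  if (any(nchar(r1) != nchar(q1)) || any(nchar(r2) != nchar(q2)))
    stop("sequence/quality length mismatch")
  if (any(nchar(r1) == 0L) || any(nchar(r2) == 0L))
    stop("empty mate sequence")
  res <- .mergeOverlapCpp(r1, q1, revComp(r2), revString(q2),
                          as.integer(minOverlap), maxMismatchFrac)
  flipped <- rep(FALSE, length(r1))
  if (tryBothOrientations && any(!res$merged)) {
    i <- which(!res$merged)
    res2 <- .mergeOverlapCpp(r2[i], q2[i], revComp(r1[i]), revString(q1[i]),
                             as.integer(minOverlap), maxMismatchFrac)
    hit <- res2$merged
    if (any(hit)) {
      j <- i[hit]
      res$merged[j] <- TRUE
      res$seq[j] <- res2$seq[hit]
      res$qual[j] <- res2$qual[hit]
      res$overlap[j] <- res2$overlap[hit]
      res$mismatches[j] <- res2$mismatches[hit]
      flipped[j] <- TRUE
    }
  }
  data.frame(merged = res$merged, seq = res$seq, qual = res$qual,
             overlap_len = res$overlap, mismatches_in_overlap = res$mismatches,
             flipped = flipped)
}

#' Expected sequencing errors of a quality string
#'
#' @param quals character vector of Sanger-offset (33) Phred quality
#'   strings.
#' @return numeric vector of `sum(10^(-Q/10))` per read.
#' @export
expectedErrors <- function(quals) .expectedErrorsCpp(quals)

#' Expected-error quality filter
#'
#' A read passes if its expected number of errors does not exceed
#' `maxExpectedErrors`.
#'
#' @param quals quality strings.
#' @param maxExpectedErrors threshold (default 1.0).
#' @return logical vector.
#' @export
qualityFilter <- function(quals, maxExpectedErrors = 1.0) {
  expectedErrors(quals) <= maxExpectedErrors
}

#' Locate and strip amplicon primers, classifying the hinge isotype
#'
#' The forward primer must occur (IUPAC-aware, up to
#' `maxPrimerMismatches` mismatches) within `primerWindow` nt of the 5'
#' end; the reverse-complemented site of one of the two hinge-specific
#' reverse primers within `primerWindow` nt of the 3' end. The better
#' matching reverse primer sets the hinge class (`short_IgG2` vs
#' `long_IgG3`); an exact tie is rejected as ambiguous. The returned
#' sequence spans the region strictly between the primers, shifted by
#' `frameOffset` nt so its first base starts a codon.
#'
#' @param seqs merged nucleotide sequences.
#' @param params a [processParams()] list.
#' @return data.frame with `trimmed`, `hinge`
#'   (`short_IgG2`/`long_IgG3`/`unassigned`), `reason` (NA when trimmed).
#' @export
trimAndClassify <- function(seqs, params = processParams()) {
  p <- params$primers
  n <- length(seqs)
  fwd <- .findPrimerCpp(seqs, p$fwd, params$maxPrimerMismatches,
                        FALSE, params$primerWindow)
  revS <- .findPrimerCpp(seqs, revComp(p$rev_short_IgG2),
                         params$maxPrimerMismatches, TRUE, params$primerWindow)
  revL <- .findPrimerCpp(seqs, revComp(p$rev_long_IgG3),
                         params$maxPrimerMismatches, TRUE, params$primerWindow)
  trimmed <- rep(NA_character_, n)
  hinge <- rep("unassigned", n)
  reason <- rep(NA_character_, n)

  noFwd <- is.na(fwd$pos)
  reason[noFwd] <- "no_fwd_primer"
  mmS <- ifelse(is.na(revS$mismatches), Inf, revS$mismatches)
  mmL <- ifelse(is.na(revL$mismatches), Inf, revL$mismatches)
  noRev <- !noFwd & is.infinite(mmS) & is.infinite(mmL)
  reason[noRev] <- "no_rev_primer"
  ambiguous <- !noFwd & !noRev & (mmS == mmL)
  reason[ambiguous] <- "ambiguous_rev_primer"

  ok <- !noFwd & !noRev & !ambiguous
  if (any(ok)) {
    useShort <- ok & (mmS < mmL)
    hinge[ok] <- ifelse(useShort[ok], "short_IgG2", "long_IgG3")
    start <- fwd$pos + nchar(p$fwd) + 1L + params$frameOffset
    end <- ifelse(useShort, revS$pos, revL$pos) # 0-based site start == 1-based insert end
    bad <- ok & (end < start)
    reason[bad] <- "no_rev_primer"
    hinge[bad] <- "unassigned"
    ok <- ok & !bad
    trimmed[ok] <- substr(seqs[ok], start[ok], end[ok])
  }
  data.frame(trimmed = trimmed, hinge = hinge, reason = reason)
}

#' Translate trimmed amplicons in the primer-anchored frame
#'
#' Standard-genetic-code translation in frame 0, truncating a trailing
#' partial codon. Sequences containing a stop codon are rejected
#' (`stop_codon`), and translations shorter than `minAALength` are
#' rejected (`too_short`). Ambiguous bases translate to `X`.
#'
#' @param nt character vector of trimmed nucleotide sequences.
#' @param minAALength minimum accepted amino-acid length.
#' @return data.frame with `aa` and `reason` (NA when accepted).
#' @examples
#' translateFrame0("ATGGCT", minAALength = 1) # "MA"
#' @export
translateFrame0 <- function(nt, minAALength = 90L) {
  n <- length(nt)
  aa <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(aa = aa, reason = reason))
  if (any(grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", nt)))
    stop("non-IUPAC character in nucleotide sequence")
  keep <- nchar(nt) %/% 3L * 3L
  trimmedNt <- substr(nt, 1L, keep)
  tr <- rep("", n)
  nonEmpty <- keep >= 3L
  if (any(nonEmpty)) {
    tr[nonEmpty] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(trimmedNt[nonEmpty]),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  hasStop <- grepl("*", tr, fixed = TRUE)
  reason[hasStop] <- "stop_codon"
  short <- !hasStop & nchar(tr) < minAALength
  reason[short] <- "too_short"
  okv <- !hasStop & !short
  aa[okv] <- tr[okv]
  data.frame(aa = aa, reason = reason)
}

#' Read a FASTQ mate pair
#'
#' @param r1Path,r2Path FASTQ file paths (Sanger offset 33, optionally
#'   gzipped).
#' @return list with `id`, `r1`, `q1`, `r2`, `q2` character vectors.
#' @export
readFastqPairs <- function(r1Path, r2Path) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    list(id = sub(" .*$", "", names(x)), seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1Path); b <- rd(r2Path)
  if (length(a$seq) != length(b$seq))
    stop("R1 and R2 read counts differ")
  list(id = a$id, r1 = unname(a$seq), q1 = unname(a$qual),
       r2 = unname(b$seq), q2 = unname(b$qual))
}

#' Process raw paired-end amplicon reads into VHH amino-acid sequences
#'
#' Runs merge -> expected-error filter -> primer trim + hinge
#' classification -> frame-0 translation, tracking per-stage attrition.
#'
#' @param r1Path,r2Path FASTQ paths of the mate files.
#' @param params a [processParams()] list.
#' @return data.frame with `read_id`, `aa_seq`, `hinge`,
#'   `rejected_reason` (exactly one of `aa_seq`/`rejected_reason` is
#'   non-NA per read), with an `attrition` attribute: a data.frame of
#'   (stage, count, fraction) summing the rejection reasons back to the
#'   input pair count.
#' @export
processReads <- function(r1Path, r2Path, params = processParams()) {
  rp <- readFastqPairs(r1Path, r2Path)
  n <- length(rp$id)
  aa <- rep(NA_character_, n)
  hinge <- rep("unassigned", n)
  reason <- rep(NA_character_, n)

  if (n > 0L) {
    mg <- mergePairs(rp$r1, rp$r2, rp$q1, rp$q2,
                     minOverlap = params$minOverlap,
                     maxMismatchFrac = params$maxMismatchFrac)
    reason[!mg$merged] <- "no_merge"

    idx <- which(mg$merged)
    if (length(idx)) {
      pass <- qualityFilter(mg$qual[idx], params$maxExpectedErrors)
      reason[idx[!pass]] <- "low_quality"
      idx <- idx[pass]
    }
    if (length(idx)) {
      # orient by the forward primer: a pair sequenced with the mates
      # swapped merges onto the reverse-complement strand
      fwdHit <- .findPrimerCpp(mg$seq[idx], params$primers$fwd,
                               params$maxPrimerMismatches, FALSE,
                               params$primerWindow)
      flip <- is.na(fwdHit$pos)
      if (any(flip)) {
        fi <- idx[flip]
        mg$seq[fi] <- revComp(mg$seq[fi])
        mg$qual[fi] <- revString(mg$qual[fi])
      }
      tc <- trimAndClassify(mg$seq[idx], params)
      bad <- is.na(tc$trimmed)
      reason[idx[bad]] <- tc$reason[bad]
      hinge[idx] <- tc$hinge
      keep <- idx[!bad]
      if (length(keep)) {
        tl <- translateFrame0(tc$trimmed[!bad], params$minAALength)
        badT <- is.na(tl$aa)
        reason[keep[badT]] <- tl$reason[badT]
        hinge[keep[badT]] <- "unassigned"
        aa[keep[!badT]] <- tl$aa[!badT]
      }
    }
  }

  out <- data.frame(read_id = rp$id, aa_seq = aa, hinge = hinge,
                    rejected_reason = reason)
  stages <- c("accepted", "no_merge", "low_quality", "no_fwd_primer",
              "no_rev_primer", "ambiguous_rev_primer", "stop_codon",
              "too_short")
  cnt <- c(sum(is.na(reason)),
           vapply(stages[-1], function(s) sum(reason == s, na.rm = TRUE),
                  integer(1)))
  attr(out, "attrition") <- data.frame(
    stage = c("input", stages),
    count = c(n, cnt),
    fraction = if (n > 0L) c(1, cnt / n) else c(1, rep(0, length(cnt))))
  out
}
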