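#' Dereplicate sequences into exact-match clonotypes
#'
#' @param aaSeqs character vector of amino-acid sequences.
#' @return named integer vector of counts (names are the distinct
#'   sequences, in decreasing count order; counts sum to the input
#'   length).
#' @examples
#' dereplicate(c("A", "A", "B")) # A=2, B=1
#' @export
dereplicate <- function(aaSeqs) {
  if (length(aaSeqs) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(aaSeqs)
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  sort(cnt, decreasing = TRUE, method = "radix")
}

#' Per-library sequencing summary
#'
#' The count/percentage statistics of the high-throughput sequencing
#' summary table: merged reads (the 100% denominator), single-occurrence
#' sequences, unique sequences, and the highest-frequency clone, each
#' with its percentage of merged reads rounded half-up to 2 decimals.
#'
#' @param counts named integer vector of clone counts (from
#'   [dereplicate()]).
#' @param library library name.
#' @param totalReads raw read-pair count before merging (optional).
#' @return one-row data.frame with `library`, `total_reads`, `merged`,
#'   `single_occurrence`, `unique_sequences`, `highest_frequency_count`
#'   and the three `_pct` columns.
#' @export
librarySummary <- function(counts, library = "library", totalReads = NA_integer_) {
  if (length(counts) == 0L || sum(counts) < 1L)
    stop("empty count table")
  merged <- sum(counts)
  single <- sum(counts == 1L)
  uniq <- length(counts)
  top <- max(counts)
  pct <- function(x) roundHalfUp(100 * x / merged, 2L)
  data.frame(library = library, total_reads = totalReads, merged = merged,
             single_occurrence = single, single_occurrence_pct = pct(single),
             unique_sequences = uniq, unique_sequences_pct = pct(uniq),
             highest_frequency_count = top, highest_frequency_pct = pct(top))
}

#' Amplification fold of a clone between round 0 and the final round
#'
#' `fold = (countFinal/mergedFinal) / (countR0eff/mergedR0)`, where a
#' clone unobserved at round 0 gets an effective count set by
#' `zeroPolicy` ("floor1": 1 read; "pseudo0.5": 0.5 reads) so folds stay
#' finite. A clone unobserved in the final round has fold 0.
#'
#' @param countFinal,countR0 integer clone counts (vectorized).
#' @param mergedFinal,mergedR0 merged-read totals of the two libraries.
#' @param zeroPolicy round-0 zero-count policy.
#' @return numeric vector of folds (>= 0).
#' @examples
#' amplificationFold(200, 1e4, 1, 1e5) # 2000
#' @export
amplificationFold <- function(countFinal, mergedFinal, countR0, mergedR0,
                              zeroPolicy = c("floor1", "pseudo0.5")) {
  zeroPolicy <- match.arg(zeroPolicy)
  if (any(countFinal < 0) || any(countR0 < 0))
    stop("negative counts")
  if (any(mergedFinal < 1) || any(mergedR0 < 1))
    stop("merged totals must be >= 1")
  floorCount <- if (zeroPolicy == "floor1") 1 else 0.5
  r0eff <- ifelse(countR0 > 0, countR0, floorCount)
  ifelse(countFinal == 0, 0,
         (countFinal / mergedFinal) / (r0eff / mergedR0))
}

#' Build a per-library clone table with frequencies and folds
#'
#' Joins the final-round dereplicated counts of one library against the
#' shared round-0 counts, computes frequencies (denominator: merged reads
#' of the respective library) and amplification folds.
#'
#' @param finalCounts named counts of the library's final round (from
#'   [dereplicate()]).
#' @param r0Counts named counts of the round-0 library.
#' @param library library name.
#' @param hinge optional named character vector mapping sequence ->
#'   hinge class.
#' @param zeroPolicy see [amplificationFold()].
#' @return data.frame with `aa_seq`, `count_r0`, `count_final`,
#'   `freq_r0`, `freq_final`, `fold`, `hinge`, `r0_floored`.
#' @export
buildCloneTable <- function(finalCounts, r0Counts, library = "library",
                            hinge = NULL, zeroPolicy = "floor1") {
  aa <- names(finalCounts)
  mergedFinal <- sum(finalCounts)
  mergedR0 <- sum(r0Counts)
  c0 <- as.integer(r0Counts[aa])
  c0[is.na(c0)] <- 0L
  fold <- amplificationFold(as.integer(finalCounts), mergedFinal, c0,
                            mergedR0, zeroPolicy)
  data.frame(
    library = library, aa_seq = aa,
    count_r0 = c0, count_final = as.integer(finalCounts),
    freq_r0 = c0 / mergedR0, freq_final = as.integer(finalCounts) / mergedFinal,
    fold = fold,
    hinge = if (is.null(hinge)) NA_character_ else unname(hinge[aa]),
    r0_floored = c0 == 0L)
}

#' Rank clones by amplification fold and select the top K
#'
#' Descending fold; ties broken by higher final frequency, then by
#' lexicographic amino-acid sequence (C locale). Clone ids are assigned
#' as `<library>_<rank>` starting at rank 1.
#'
#' @param cloneTable data.frame from [buildCloneTable()].
#' @param K number of clones to keep (all clones if fewer).
#' @return the top `min(K, n)` rows, ordered, with a `clone_id` column
#'   and a `rank` column prepended.
#' @export
rankAndSelect <- function(cloneTable, K = 50L) {
  stopifnot(K >= 1L)
  ord <- order(-cloneTable$fold, -cloneTable$freq_final, cloneTable$aa_seq,
               method = "radix")
  out <- cloneTable[ord, , drop = FALSE][seq_len(min(K, nrow(cloneTable))), ,
                                         drop = FALSE]
  out <- cbind(clone_id = sprintf("%s_%d", out$library, seq_len(nrow(out))),
               rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
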