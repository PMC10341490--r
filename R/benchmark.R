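#' Ground-truth recovery benchmark of the full pipeline
#'
#' Runs the simulator end to end (fixtures, read processing, ranking,
#' trees, grouping) and scores the result against the simulator's ground
#' truth:
#'
#' * `binder_recovery`: among spiked binders (weight > 1 for the target
#'   line) whose realized enrichment in the true counts is at least
#'   `minRealizedFold`, the fraction recovered in that library's top-K
#'   ranking.
#' * `specificity_match`: the fraction of reported candidates whose
#'   predicted specificity agrees with the representative clone's true
#'   binding-weight profile (a mono-specific call must name exactly the
#'   one line the clone binds; a multi-specific call must name a subset
#'   of the two or more lines it binds).
#' * `cross_reactive_flagged`: among true cross-reactive clones that
#'   reach the top-K of two or more libraries, the fraction whose CDR3
#'   group is flagged with multiplicity >= 2.
#'
#' @param config a [PanningConfig-class].
#' @param dir working directory for FASTQ fixtures and reports.
#' @param topK clones ranked per library.
#' @param minRealizedFold realized-enrichment floor defining a
#'   recoverable binder.
#' @param rounds optional named per-line round counts (see
#'   [makeFixtures()]).
#' @return list with the three rates, their denominators, and the
#'   underlying `pipeline` result, `fixtures`, and per-candidate
#'   `calls` data.frame.
#' @export
recoveryBenchmark <- function(config, dir = tempfile("vhhbench"), topK = 50L,
                              minRealizedFold = 10, rounds = NULL) {
  fx <- makeFixtures(config, dir, rounds = rounds)
  lines <- config@cellLines
  if (is.null(rounds)) rounds <- setNames(rep(config@rounds, length(lines)), lines)

  rc <- runConfig(
    libraries = data.frame(
      name = lines,
      fastq_r1 = vapply(lines, function(l) fx$files[[l]]$r1, character(1)),
      fastq_r2 = vapply(lines, function(l) fx$files[[l]]$r2, character(1)),
      round_index = as.integer(rounds[lines])),
    round0 = c(fx$files$round0$r1, fx$files$round0$r2),
    outputDir = file.path(dir, "reports"), topK = topK, seed = config@seed)
  res <- runPipeline(rc)

  truth <- read.table(fx$truth, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  w <- as.matrix(truth[, paste0("weight_", lines)])
  colnames(w) <- lines
  trueLines <- lapply(seq_len(nrow(truth)), function(i) lines[w[i, ] > 1])

  # binder recovery per library
  recovered <- 0L; recoverable <- 0L
  reads <- config@readsPerRound
  for (ln in lines) {
    cf <- truth[[paste0("count_final_", ln)]]
    c0 <- truth$count_round0
    realized <- ifelse(c0 > 0, (cf / reads) / (c0 / reads), Inf)
    spiked <- w[, ln] > 1 & cf > 0 & realized >= minRealizedFold
    topSeqs <- res$ranked$aa_seq[res$ranked$library == ln]
    recoverable <- recoverable + sum(spiked)
    recovered <- recovered + sum(truth$aa_seq[spiked] %in% topSeqs)
  }

  # map a reported clone back to its ground-truth clone
  mapTruth <- function(cloneId) {
    aa <- res$ranked$aa_seq[match(cloneId, res$ranked$clone_id)]
    i <- match(aa, truth$aa_seq)
    if (is.na(i)) {  # sequencing-error variant: fall back to the CDR3
      cdr3 <- res$ranked$cdr3[match(cloneId, res$ranked$clone_id)]
      if (!is.na(cdr3)) i <- match(cdr3, truth$cdr3)
    }
    i
  }

  cand <- res$candidates
  calls <- data.frame(group_id = cand$group_id, match = NA)
  for (k in seq_len(nrow(cand))) {
    i <- mapTruth(cand$representative[k])
    if (is.na(i)) { calls$match[k] <- FALSE; next }
    tl <- trueLines[[i]]
    predLibs <- strsplit(cand$libraries[k], ";")[[1]]
    calls$match[k] <- if (cand$predicted_specificity[k] == "mono_specific")
      length(tl) == 1L && identical(tl, predLibs)
    else
      length(tl) >= 2L && all(predLibs %in% tl)
  }

  # cross-reactive clones visible in >= 2 libraries' top-K
  crIdx <- which(vapply(trueLines, length, integer(1)) >= 2L)
  flagged <- 0L; visible <- 0L
  for (i in crIdx) {
    inLibs <- unique(res$ranked$library[res$ranked$aa_seq == truth$aa_seq[i]])
    if (length(inLibs) >= 2L) {
      visible <- visible + 1L
      g <- res$cdr3Groups[vapply(res$cdr3Groups$member_ids, function(ids)
        any(res$ranked$cdr3[match(ids, res$ranked$clone_id)] == truth$cdr3[i]),
        logical(1)), , drop = FALSE]
      if (nrow(g) && any(g$multiplicity >= 2L)) flagged <- flagged + 1L
    }
  }

  list(binder_recovery = if (recoverable) recovered / recoverable else NA_real_,
       n_recoverable = recoverable,
       specificity_match = if (nrow(calls)) mean(calls$match) else NA_real_,
       n_candidates = nrow(calls),
       cross_reactive_flagged = if (visible) flagged / visible else NA_real_,
       n_cross_visible = visible,
       calls = calls, pipeline = res, fixtures = fx)
}
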