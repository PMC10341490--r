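#' Generate a ground-truthed synthetic VHH repertoire
#'
#' Draws `nClones` distinct VHH clones on fixed framework scaffolds with
#' random CDR1/CDR2/CDR3 loops and a short (IgG2) or long (IgG3) hinge
#' tail. A `binderFraction` of clones receives a selection advantage
#' (binding weight > 1, drawn log-normally) for exactly one cell line, a
#' `crossReactiveFraction` for two or more lines; all remaining clones are
#' neutral (weight 1 everywhere). Nucleotide sequences are randomized
#' synonymous encodings flanked by the amplicon primer regions, so the
#' downstream read-processing stage sees realistic input.
#'
#' @param config a [PanningConfig-class].
#' @return a [VHHRepertoire-class]; deterministic given `config@seed`.
#' @examples
#' rep <- generateRepertoire(panningConfig(nClones = 50, seed = 7))
#' rep
#' @export
generateRepertoire <- function(config) {
  stopifnot(is(config, "PanningConfig"))
  validObject(config)
  set.seed(deriveSeed(config@seed, 1L))
  n <- config@nClones
  lines <- config@cellLines

  randLoop <- function(len) {
    paste(sample(.CDR_ALPHABET, len, replace = TRUE), collapse = "")
  }
  drawClone <- function() {
    cdr3 <- randLoop(sample(8:12, 1L))
    hinge <- sample(names(.HINGE), 1L)
    aa <- paste0(.FR1B[sample.int(2L, 1L)], randLoop(6L),
                 .FR2[sample.int(2L, 1L)], randLoop(7L),
                 .FR3[sample.int(2L, 1L)], cdr3, .FR4, .HINGE[[hinge]])
    list(aa = aa, cdr3 = cdr3, hinge = hinge)
  }

  seen <- new.env(hash = TRUE)
  aa <- character(n); cdr3 <- character(n); hinge <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cl <- drawClone()
      if (is.null(seen[[cl$aa]])) { seen[[cl$aa]] <- TRUE; break }
    }
    aa[i] <- cl$aa; cdr3[i] <- cl$cdr3; hinge[i] <- cl$hinge
  }

  primers <- defaultPrimers()
  revSite <- c(short_IgG2 = revComp(primers$rev_short_IgG2),
               long_IgG3 = revComp(primers$rev_long_IgG3))
  nt <- vapply(seq_len(n), function(i) {
    paste0(primers$fwd, .reverseTranslate(aa[i]), revSite[[hinge[i]]])
  }, character(1))

  nBind <- round(n * config@binderFraction)
  nCross <- round(n * config@crossReactiveFraction)
  w <- matrix(1, nrow = n, ncol = length(lines),
              dimnames = list(NULL, lines))
  if (nBind > 0) {
    target <- lines[rep_len(seq_along(lines), nBind)]
    for (i in seq_len(nBind))
      w[i, target[i]] <- rlnorm(1L, config@enrichmentMeanlog,
                                config@enrichmentSdlog)
  }
  if (nCross > 0) {
    for (k in seq_len(nCross)) {
      i <- nBind + k
      mult <- sample(2:min(3L, length(lines)), 1L)
      for (ln in sample(lines, mult))
        w[i, ln] <- rlnorm(1L, config@enrichmentMeanlog,
                           config@enrichmentSdlog)
    }
  }

  clones <- S4Vectors::DataFrame(
    clone_id = sprintf("C%05d", seq_len(n)),
    aa_seq = aa, nt_seq = nt, hinge = hinge, true_cdr3 = cdr3)
  rownames(w) <- clones$clone_id
  new("VHHRepertoire", clones = clones, weights = w, config = config)
}

#' Simulate subtractive panning rounds for one cell line
#'
#' Round-0 clone abundances are drawn from a skewed Dirichlet(alpha = 0.1)
#' law (few dominant clones, a long singleton tail) unless `baseCounts` is
#' supplied; each later round resamples `readsPerRound` reads
#' multinomially with probability proportional to the previous round's
#' frequency times the clone's binding weight for the target line.
#'
#' @param repertoire a [VHHRepertoire-class].
#' @param cellLine one of the configured cell-line names.
#' @param config a [PanningConfig-class]; defaults to the repertoire's own.
#' @param baseCounts optional integer vector of round-0 counts (one per
#'   clone), e.g. to share a single round-0 library across cell lines.
#' @param dirichletAlpha concentration of the round-0 abundance law.
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay (clones x rounds, every column summing to `readsPerRound`),
#'   clone metadata in `rowData`, the round index in `colData`, and the
#'   cell line in `metadata`.
#' @export
simulatePanning <- function(repertoire, cellLine, config = simConfig(repertoire),
                            baseCounts = NULL, dirichletAlpha = 0.1) {
  stopifnot(is(repertoire, "VHHRepertoire"))
  if (!cellLine %in% config@cellLines)
    stop("unknown cell line: ", cellLine)
  n <- nrow(repertoire@clones)
  reads <- config@readsPerRound
  set.seed(deriveSeed(config@seed, 10L + match(cellLine, config@cellLines)))

  if (is.null(baseCounts)) {
    p0 <- rgamma(n, shape = dirichletAlpha)
    if (sum(p0) <= 0) p0 <- rep(1, n)
    c0 <- as.integer(rmultinom(1L, reads, p0))
  } else {
    stopifnot(length(baseCounts) == n)
    c0 <- as.integer(baseCounts)
  }

  w <- bindingWeights(repertoire)[, cellLine]
  counts <- matrix(0L, nrow = n, ncol = config@rounds + 1L,
                   dimnames = list(cloneIds(repertoire),
                                   paste0("round", 0:config@rounds)))
  counts[, 1L] <- c0
  for (r in seq_len(config@rounds)) {
    p <- (counts[, r] / reads) * w
    if (sum(p) <= 0) stop("all clones extinct before round ", r)
    counts[, r + 1L] <- as.integer(rmultinom(1L, reads, p))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = repertoire@clones,
    colData = S4Vectors::DataFrame(round = 0:config@rounds),
    metadata = list(cell_line = cellLine, seed = config@seed))
}

#' Emit paired-end FASTQ for simulated panning rounds
#'
#' For every requested round, each clone contributes exactly its count of
#' read pairs: R1 is the 5' 300 nt of the amplicon and R2 the reverse
#' complement of the 3' 300 nt, so pairs overlap in the middle.
#' Per-base qualities follow a MiSeq-like four-level profile rescaled so
#' the mean per-base error probability equals the configured rate;
#' substitution errors are injected at each base's quality-implied
#' probability, and quality strings encode those probabilities (Sanger
#' offset 33). At rate 0 all bases are error-free Q40.
#'
#' @param counts a `SummarizedExperiment` from [simulatePanning()], or an
#'   integer matrix clones x rounds.
#' @param repertoire the [VHHRepertoire-class] the counts refer to.
#' @param config a [PanningConfig-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, typically the library name.
#' @param roundIdx integer vector of round indices to emit (default: all
#'   columns of `counts`).
#' @param readLength read length of the simulated pairs.
#' @param minOverlap amplicons longer than `2*readLength - minOverlap`
#'   abort with an error naming the offending clone.
#' @return data.frame with columns `round`, `r1`, `r2` (file paths).
#' @export
emitFastq <- function(counts, repertoire, config = simConfig(repertoire),
                      dir, prefix, roundIdx = NULL, readLength = 300L,
                      minOverlap = 20L) {
  m <- if (is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  stopifnot(nrow(m) == nrow(repertoire@clones))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(roundIdx))
    roundIdx <- as.integer(sub("^round", "", colnames(m)))

  ntAll <- repertoire@clones$nt_seq
  lenAll <- nchar(ntAll)
  tooLong <- which(lenAll > 2L * readLength - minOverlap & rowSums(m) > 0)
  if (length(tooLong))
    stop("amplicon too long for overlapping pairs: clone ",
         repertoire@clones$clone_id[tooLong[1L]])

  out <- data.frame(round = integer(), r1 = character(), r2 = character())
  for (r in roundIdx) {
    col <- paste0("round", r)
    cnt <- m[, col]
    set.seed(deriveSeed(config@seed,
                        1000L + sum(utf8ToInt(prefix)) %% 797L * 20L + r))
    idx <- rep.int(seq_along(cnt), cnt)
    if (length(idx)) idx <- sample(idx)
    amp <- ntAll[idx]
    L <- lenAll[idx]
    r1 <- .simReadsCpp(substr(amp, 1L, pmin(readLength, L)),
                       config@perBaseErrorRate)
    r2 <- .simReadsCpp(revComp(substr(amp, pmax(1L, L - readLength + 1L), L)),
                       config@perBaseErrorRate)
    ids <- sprintf("%s_r%d_%06d clone=%s", prefix, r, seq_along(idx),
                   repertoire@clones$clone_id[idx])
    f1 <- file.path(dir, sprintf("%s_round%d_R1.fastq", prefix, r))
    f2 <- file.path(dir, sprintf("%s_round%d_R2.fastq", prefix, r))
    writeReads <- function(rd, path) {
      x <- Biostrings::DNAStringSet(rd$seq)
      names(x) <- ids
      Biostrings::writeXStringSet(x, path, format = "fastq",
                                  qualities = Biostrings::BStringSet(rd$qual))
    }
    writeReads(r1, f1)
    writeReads(r2, f2)
    out <- rbind(out, data.frame(round = r, r1 = f1, r2 = f2))
  }
  out
}

#' Build a complete simulated panning fixture set
#'
#' Runs the simulator end to end: one repertoire, a single shared round-0
#' library, one enrichment trajectory per cell line, paired FASTQ for
#' round 0 and each library's final round, and a ground-truth TSV.
#'
#' @param config a [PanningConfig-class].
#' @param dir output directory.
#' @param rounds optional named integer vector of rounds per cell line
#'   (default: `config@rounds` for every line).
#' @return list with `repertoire`, `counts` (list of per-line
#'   SummarizedExperiments), `files` (per-library FASTQ paths incl. the
#'   shared `round0`), and `truth` (path of the ground-truth TSV).
#' @export
makeFixtures <- function(config, dir, rounds = NULL) {
  stopifnot(is(config, "PanningConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  repertoire <- generateRepertoire(config)
  lines <- config@cellLines
  if (is.null(rounds)) rounds <- setNames(rep(config@rounds, length(lines)), lines)
  stopifnot(all(lines %in% names(rounds)))

  # shared unselected round-0 library
  set.seed(deriveSeed(config@seed, 2L))
  p0 <- rgamma(config@nClones, shape = 0.1)
  c0 <- as.integer(rmultinom(1L, config@readsPerRound, p0))

  counts <- list()
  files <- list()
  r0mat <- matrix(c0, ncol = 1L,
                  dimnames = list(cloneIds(repertoire), "round0"))
  files$round0 <- emitFastq(r0mat, repertoire, config, dir, "round0")
  for (ln in lines) {
    cfg <- config
    cfg@rounds <- as.integer(rounds[[ln]])
    se <- simulatePanning(repertoire, ln, cfg, baseCounts = c0)
    counts[[ln]] <- se
    files[[ln]] <- emitFastq(se, repertoire, cfg, dir, ln,
                             roundIdx = cfg@rounds)
  }

  truth <- as.data.frame(repertoire@clones)
  colnames(truth)[colnames(truth) == "true_cdr3"] <- "cdr3"
  w <- bindingWeights(repertoire)
  for (ln in lines) truth[[paste0("weight_", ln)]] <- w[, ln]
  truth$count_round0 <- c0
  for (ln in lines)
    truth[[paste0("count_final_", ln)]] <-
      SummarizedExperiment::assay(counts[[ln]])[, rounds[[ln]] + 1L]
  truthPath <- file.path(dir, "ground_truth.tsv")
  write.table(truth, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)

  list(repertoire = repertoire, counts = counts, files = files,
       truth = truthPath)
}
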