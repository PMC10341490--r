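#' Assemble a pipeline run configuration
#'
#' @param libraries data.frame with columns `name`, `fastq_r1`,
#'   `fastq_r2`, `round_index` (>= 1; rounds may differ per library).
#' @param round0 character vector of length 2: the shared unselected
#'   round-0 FASTQ pair `(r1, r2)`.
#' @param outputDir directory the reports are written to.
#' @param topK clones kept per library after fold ranking.
#' @param clusterHomology tree-cluster homology threshold (default
#'   0.988).
#' @param cdr3Mode CDR3 grouping mode, `"exact"` or `"homology_0.98"`.
#' @param cdr3IdentityThreshold identity cut-off of the homology mode.
#' @param zeroPolicy round-0 zero-count policy of the fold.
#' @param rankEligibility `"observed_r0"` (default) ranks clones observed
#'   in the round-0 library; clones absent from round 0 carry a floored,
#'   baseline-free fold and are reported separately rather than competing
#'   for top-K slots, unless their final frequency reaches
#'   `novelMinFreq`. `"all"` ranks every clone.
#' @param novelMinFreq final-frequency threshold above which a
#'   round-0-unobserved clone is admitted to the ranking anyway. A clone
#'   at frequency f spawns any specific single-substitution sequencing
#'   variant at frequency of order f x (per-base error rate)/3, so a
#'   threshold at or above the per-base error rate cannot be reached by
#'   the error shoulder of even a fully dominant clone; the default
#'   (0.005) is set accordingly.
#' @param params read-processing parameters ([processParams()]).
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return validated config list for [runPipeline()].
#' @export
runConfig <- function(libraries, round0, outputDir, topK = 50L,
                      clusterHomology = 0.988,
                      cdr3Mode = c("exact", "homology_0.98"),
                      cdr3IdentityThreshold = 0.98,
                      zeroPolicy = "floor1",
                      rankEligibility = c("observed_r0", "all"),
                      novelMinFreq = 0.005,
                      params = processParams(), seed = 1L) {
  cdr3Mode <- match.arg(cdr3Mode)
  rankEligibility <- match.arg(rankEligibility)
  libraries <- as.data.frame(libraries)
  stopifnot(all(c("name", "fastq_r1", "fastq_r2", "round_index") %in%
                  colnames(libraries)),
            length(round0) == 2L, topK >= 1L)
  if (anyDuplicated(libraries$name)) stop("library names must be unique")
  if (any(libraries$round_index < 1L)) stop("round_index must be >= 1")
  list(libraries = libraries, round0 = round0, outputDir = outputDir,
       topK = as.integer(topK), clusterHomology = clusterHomology,
       cdr3Mode = cdr3Mode, cdr3IdentityThreshold = cdr3IdentityThreshold,
       zeroPolicy = zeroPolicy, rankEligibility = rankEligibility,
       novelMinFreq = novelMinFreq, params = params, seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Expects the same fields as [runConfig()]; `libraries` as a list of
#' `{name, fastq_r1, fastq_r2, round_index}` records and `round0` as
#' `{fastq_r1, fastq_r2}`.
#'
#' @param path YAML file.
#' @return config list for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  libs <- do.call(rbind, lapply(y$libraries, as.data.frame))
  args <- y[setdiff(names(y), c("libraries", "round0"))]
  do.call(runConfig, c(list(libraries = libs,
                            round0 = c(y$round0$fastq_r1, y$round0$fastq_r2)),
                       args))
}

# process one FASTQ pair and dereplicate accepted reads into clones
.processLibraryReads <- function(name, r1, r2, params) {
  for (p in c(r1, r2)) if (!file.exists(p)) stop("input FASTQ not found: ", p)
  pr <- processReads(r1, r2, params)
  acc <- pr[!is.na(pr$aa_seq), , drop = FALSE]
  counts <- dereplicate(acc$aa_seq)
  hinge <- if (nrow(acc)) vapply(split(acc$hinge, acc$aa_seq), function(h) {
    names(sort(table(h), decreasing = TRUE))[1L]
  }, character(1)) else setNames(character(0), character(0))
  list(name = name, processed = pr, counts = counts, hinge = hinge,
       attrition = attr(pr, "attrition"),
       total_reads = attr(pr, "attrition")$count[1L])
}

#' Run the full screening pipeline
#'
#' Read processing, clonotype dereplication, fold ranking, per-library
#' and combined neighbor-joining trees, homology clustering, cross-library
#' CDR3 grouping and the candidate report, writing every report file
#' plus a machine-readable run manifest into `outputDir`.
#'
#' @param config a [runConfig()] list.
#' @return (invisibly) list with `summary` (per-library sequencing
#'   summary), `ranked` (combined top-K table), `trees`, `clusters`,
#'   `cdr3Groups`, `candidates`, `attrition`, and `files` (paths
#'   written).
#' @export
runPipeline <- function(config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params

  r0 <- .processLibraryReads("round0", config$round0[1L], config$round0[2L],
                             params)
  libs <- lapply(seq_len(nrow(config$libraries)), function(i) {
    li <- config$libraries[i, ]
    .processLibraryReads(li$name, li$fastq_r1, li$fastq_r2, params)
  })
  names(libs) <- config$libraries$name

  summaries <- rbind(
    librarySummary(r0$counts, "round0", r0$total_reads),
    do.call(rbind, lapply(libs, function(l)
      librarySummary(l$counts, l$name, l$total_reads))))
  rownames(summaries) <- NULL

  floored <- list()
  ranked <- do.call(rbind, lapply(libs, function(l) {
    ct <- buildCloneTable(l$counts, r0$counts, l$name, l$hinge,
                          config$zeroPolicy)
    if (identical(config$rankEligibility, "observed_r0")) {
      keep <- !ct$r0_floored | ct$freq_final >= config$novelMinFreq
      drop <- ct[!keep, , drop = FALSE]
      floored[[l$name]] <<- drop[order(-drop$fold), , drop = FALSE]
      ct <- ct[keep, , drop = FALSE]
    }
    top <- rankAndSelect(ct, config$topK)
    ann <- extractCDR3(top$aa_seq)
    top$cdr3 <- ann$cdr3
    top$cdr3_status <- ann$status
    top
  }))
  rownames(ranked) <- NULL

  seqs <- setNames(ranked$aa_seq, ranked$clone_id)
  libOf <- setNames(ranked$library, ranked$clone_id)
  trees <- list()
  for (ln in names(libs)) {
    s <- seqs[libOf == ln]
    if (length(s) >= 3L) trees[[ln]] <- neighborJoining(distanceMatrix(s))
  }
  combinedD <- NULL
  clusters <- .emptyClusterFrame()
  if (length(seqs) >= 3L) {
    combinedD <- distanceMatrix(seqs)
    trees$combined <- neighborJoining(combinedD)
    clusters <- extractClusters(trees$combined, combinedD, libOf,
                                threshold = config$clusterHomology)
  }

  cdr3Groups <- groupByCDR3(ranked, mode = config$cdr3Mode,
                            identityThreshold = config$cdr3IdentityThreshold)
  candidates <- candidateReport(clusters, cdr3Groups, ranked)

  files <- .writePipelineOutputs(config, summaries, ranked, trees, clusters,
                                 cdr3Groups, candidates,
                                 c(list(round0 = r0), libs), floored)

  invisible(list(summary = summaries, ranked = ranked, trees = trees,
                 clusters = clusters, cdr3Groups = cdr3Groups,
                 candidates = candidates, floored = floored,
                 attrition = lapply(c(list(round0 = r0), libs),
                                    function(l) l$attrition),
                 files = files))
}

.writePipelineOutputs <- function(config, summaries, ranked, trees, clusters,
                                  cdr3Groups, candidates, allLibs,
                                  floored = list()) {
  out <- config$outputDir
  tsv <- function(df, name) {
    p <- file.path(out, name)
    dfw <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    write.table(dfw, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character(0)
  files <- c(files, tsv(summaries, "library_summary.tsv"))
  files <- c(files, tsv(ranked, "ranked_clones.tsv"))
  for (l in allLibs)
    files <- c(files, tsv(l$attrition, sprintf("attrition_%s.tsv", l$name)))
  if (length(floored)) {
    fl <- do.call(rbind, floored)
    rownames(fl) <- NULL
    files <- c(files, tsv(fl, "unranked_novel_clones.tsv"))
  }

  # accepted clonotypes per library, hinge-tagged
  for (l in allLibs) {
    if (length(l$counts) == 0L) next
    fa <- file.path(out, sprintf("accepted_%s.fasta", l$name))
    x <- Biostrings::AAStringSet(names(l$counts))
    names(x) <- sprintf("%s_c%d|count=%d|hinge=%s", l$name,
                        seq_along(l$counts), unname(l$counts),
                        sub("^(short_|long_)", "", l$hinge[names(l$counts)]))
    Biostrings::writeXStringSet(x, fa)
    files <- c(files, fa)
  }

  # top-K amino-acid FASTA with hinge and CDR3 tags
  fa <- file.path(out, "topk_clones.fasta")
  x <- Biostrings::AAStringSet(ranked$aa_seq)
  names(x) <- sprintf("%s|hinge=%s|cdr3=%s", ranked$clone_id,
                      sub("^(short_|long_)", "", ranked$hinge),
                      ifelse(is.na(ranked$cdr3), "NA", ranked$cdr3))
  Biostrings::writeXStringSet(x, fa)
  files <- c(files, fa)

  for (tn in names(trees)) {
    p <- file.path(out, sprintf("tree_%s.nwk", tn))
    writeNewick(trees[[tn]], p)
    files <- c(files, p)
  }
  files <- c(files, tsv(clusters, "clusters.tsv"))
  files <- c(files, tsv(cdr3Groups, "cdr3_groups.tsv"))
  if (any(cdr3Groups$cross_reactive))
    files <- c(files, tsv(cdr3GroupMatrix(cdr3Groups,
                                          unique(config$libraries$name)),
                          "cdr3_group_matrix.tsv"))
  files <- c(files, tsv(candidates, "candidates.tsv"))
  singles <- attr(candidates, "singletons")
  files <- c(files, tsv(singles, "singletons.tsv"))

  inputs <- c(config$round0, config$libraries$fastq_r1,
              config$libraries$fastq_r2)
  manifest <- list(
    package = "VHHscreen",
    version = as.character(utils::packageVersion("VHHscreen")),
    parameters = config[c("topK", "clusterHomology", "cdr3Mode",
                          "cdr3IdentityThreshold", "zeroPolicy", "seed")],
    read_params = config$params[setdiff(names(config$params), "primers")],
    primers = config$params$primers,
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(sort(files))))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  c(files, mp)
}
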