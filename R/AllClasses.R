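#' @import methods
NULL

#' Panning simulation configuration
#'
#' Parameters of the synthetic subtractive-panning experiment: repertoire
#' size and composition, the selection-advantage law, round structure,
#' sequencing depth and error rate. The defaults describe the simulated
#' study conditions used throughout the package: a 1,000-clone VHH
#' repertoire panned for 2 rounds against four tumor cell lines at
#' 100,000 reads per round with a 0.5% per-base substitution error rate.
#'
#' @slot nClones number of distinct VHH clones in the repertoire.
#' @slot binderFraction fraction of clones in (0,1) that bind exactly one
#'   cell line with selection advantage > 1.
#' @slot crossReactiveFraction fraction of clones binding two or more cell
#'   lines.
#' @slot enrichmentMeanlog,enrichmentSdlog meanlog/sdlog of the log-normal
#'   law the per-round selection advantage (binding weight) is drawn from.
#' @slot rounds number of selection rounds per library (>= 1).
#' @slot readsPerRound sequencing depth of every round, round 0 included.
#' @slot perBaseErrorRate per-base substitution probability on reads.
#' @slot seed integer seed; every stochastic step derives from it.
#' @slot cellLines names of the target cell lines.
#' @export
setClass("PanningConfig", representation(
  nClones = "integer",
  binderFraction = "numeric",
  crossReactiveFraction = "numeric",
  enrichmentMeanlog = "numeric",
  enrichmentSdlog = "numeric",
  rounds = "integer",
  readsPerRound = "integer",
  perBaseErrorRate = "numeric",
  seed = "integer",
  cellLines = "character"
))

setValidity("PanningConfig", function(object) {
  msg <- character()
  if (length(object@nClones) != 1L || object@nClones < 1L)
    msg <- c(msg, "nClones must be a single positive integer")
  for (f in c("binderFraction", "crossReactiveFraction")) {
    v <- slot(object, f)
    if (length(v) != 1L || v <= 0 || v >= 1)
      msg <- c(msg, sprintf("%s must lie in (0, 1)", f))
  }
  if (object@binderFraction + object@crossReactiveFraction >= 1)
    msg <- c(msg, "binderFraction + crossReactiveFraction must be < 1")
  if (object@enrichmentSdlog <= 0)
    msg <- c(msg, "enrichmentSdlog must be positive")
  if (object@rounds < 1L) msg <- c(msg, "rounds must be >= 1")
  if (object@readsPerRound < 1L) msg <- c(msg, "readsPerRound must be >= 1")
  if (object@perBaseErrorRate < 0 || object@perBaseErrorRate >= 1)
    msg <- c(msg, "perBaseErrorRate must lie in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(object@cellLines) < 1L || anyDuplicated(object@cellLines))
    msg <- c(msg, "cellLines must be non-empty and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PanningConfig
#'
#' @param nClones,binderFraction,crossReactiveFraction,rounds,readsPerRound,perBaseErrorRate,seed,cellLines
#'   see the class documentation.
#' @param enrichmentMeanlog,enrichmentSdlog log-normal parameters of the
#'   binding-weight draw (defaults meanlog 3, sdlog 0.5, i.e. median
#'   selection advantage about 20-fold per round for a binder).
#' @return a validated [PanningConfig-class] object.
#' @examples
#' cfg <- panningConfig(nClones = 100, readsPerRound = 1000, seed = 1)
#' @export
panningConfig <- function(nClones = 1000L, binderFraction = 0.02,
                          crossReactiveFraction = 0.005,
                          enrichmentMeanlog = 3, enrichmentSdlog = 0.5,
                          rounds = 2L, readsPerRound = 100000L,
                          perBaseErrorRate = 0.005, seed,
                          cellLines = c("S1T", "HepG2", "SKBR3", "KYSE520")) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  new("PanningConfig",
      nClones = as.integer(nClones), binderFraction = binderFraction,
      crossReactiveFraction = crossReactiveFraction,
      enrichmentMeanlog = enrichmentMeanlog, enrichmentSdlog = enrichmentSdlog,
      rounds = as.integer(rounds), readsPerRound = as.integer(readsPerRound),
      perBaseErrorRate = perBaseErrorRate, seed = as.integer(seed),
      cellLines = cellLines)
}

setMethod("show", "PanningConfig", function(object) {
  cat("PanningConfig:", object@nClones, "clones,",
      object@rounds, "round(s),", object@readsPerRound, "reads/round\n")
  cat("  binder fraction", object@binderFraction,
      "| cross-reactive fraction", object@crossReactiveFraction, "\n")
  cat("  weight ~ lognormal(", object@enrichmentMeanlog, ",",
      object@enrichmentSdlog, ") | error rate", object@perBaseErrorRate,
      "| seed", object@seed, "\n")
  cat("  cell lines:", paste(object@cellLines, collapse = ", "), "\n")
})

#' A ground-truthed synthetic VHH repertoire
#'
#' Holds the simulated clones (amino-acid and nucleotide sequences, hinge
#' isotype, true CDR3) together with the per-cell-line binding-weight
#' matrix that drives round-to-round selection.
#'
#' @slot clones a [S4Vectors::DataFrame] with columns `clone_id`, `aa_seq`,
#'   `nt_seq`, `hinge`, `true_cdr3`.
#' @slot weights numeric matrix, clones x cell lines, all entries >= 0; a
#'   weight > 1 means selection advantage on that line.
#' @slot config the [PanningConfig-class] the repertoire was drawn from.
#' @export
setClass("VHHRepertoire", representation(
  clones = "DataFrame",
  weights = "matrix",
  config = "PanningConfig"
))

setValidity("VHHRepertoire", function(object) {
  msg <- character()
  need <- c("clone_id", "aa_seq", "nt_seq", "hinge", "true_cdr3")
  if (!all(need %in% colnames(object@clones)))
    msg <- c(msg, paste("clones must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@clones) != nrow(object@weights))
    msg <- c(msg, "weights rows must match clone count")
  if (any(object@weights < 0)) msg <- c(msg, "binding weights must be >= 0")
  if (!all(object@config@cellLines %in% colnames(object@weights)))
    msg <- c(msg, "weights must have one column per configured cell line")
  if (length(msg) == 0L) {
    ok <- mapply(grepl, object@clones$true_cdr3, object@clones$aa_seq,
                 MoreArgs = list(fixed = TRUE))
    if (!all(ok)) msg <- c(msg, "every true_cdr3 must be a substring of aa_seq")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "VHHRepertoire", function(object) {
  w <- object@weights
  binder <- rowSums(w > 1)
  cat("VHHRepertoire with", nrow(object@clones), "clones\n")
  cat("  hinge:", sum(object@clones$hinge == "short_IgG2"), "short_IgG2 /",
      sum(object@clones$hinge == "long_IgG3"), "long_IgG3\n")
  cat("  binders:", sum(binder == 1L), "mono-specific,",
      sum(binder >= 2L), "cross-reactive,", sum(binder == 0L), "neutral\n")
})

#' @rdname VHHRepertoire-class
#' @param x a `VHHRepertoire`.
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))
#' @rdname VHHRepertoire-class
#' @export
setMethod("cloneIds", "VHHRepertoire", function(x) x@clones$clone_id)

#' @rdname VHHRepertoire-class
#' @export
setGeneric("aaSeqs", function(x) standardGeneric("aaSeqs"))
#' @rdname VHHRepertoire-class
#' @export
setMethod("aaSeqs", "VHHRepertoire", function(x) {
  out <- Biostrings::AAStringSet(x@clones$aa_seq)
  names(out) <- x@clones$clone_id
  out
})

#' @rdname VHHRepertoire-class
#' @export
setGeneric("ntSeqs", function(x) standardGeneric("ntSeqs"))
#' @rdname VHHRepertoire-class
#' @export
setMethod("ntSeqs", "VHHRepertoire", function(x) {
  out <- Biostrings::DNAStringSet(x@clones$nt_seq)
  names(out) <- x@clones$clone_id
  out
})

#' @rdname VHHRepertoire-class
#' @export
setGeneric("bindingWeights", function(x) standardGeneric("bindingWeights"))
#' @rdname VHHRepertoire-class
#' @export
setMethod("bindingWeights", "VHHRepertoire", function(x) x@weights)

#' @rdname VHHRepertoire-class
#' @export
setGeneric("hingeClass", function(x) standardGeneric("hingeClass"))
#' @rdname VHHRepertoire-class
#' @export
setMethod("hingeClass", "VHHRepertoire", function(x) x@clones$hinge)

#' @rdname VHHRepertoire-class
#' @export
setGeneric("trueCDR3", function(x) standardGeneric("trueCDR3"))
#' @rdname VHHRepertoire-class
#' @export
setMethod("trueCDR3", "VHHRepertoire", function(x) {
  stats::setNames(x@clones$true_cdr3, x@clones$clone_id)
})

#' @rdname VHHRepertoire-class
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
#' @rdname VHHRepertoire-class
#' @export
setMethod("simConfig", "VHHRepertoire", function(x) x@config)
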