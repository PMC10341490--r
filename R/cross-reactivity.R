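#' Group top-ranked clones by identical (or near-identical) CDR3
#'
#' In `exact` mode clones are hash-grouped on the CDR3 string; in
#' `homology_0.98` mode they are single-linkage grouped at CDR3 identity
#' >= 0.98 (see [cdr3Identity()]). Groups spanning two or more libraries
#' are flagged cross-reactive; groups are sorted by multiplicity (number
#' of libraries), then by their maximum member fold, and cross-reactive
#' groups are labeled X, Y, Z, XR4, ... in that order.
#'
#' @param rankedClones data.frame of per-library top-K clones with
#'   columns `clone_id`, `library`, `cdr3`, `fold`, `freq_final` (rows
#'   with `NA` CDR3 are excluded and counted).
#' @param mode grouping mode.
#' @param identityThreshold identity cut-off of the homology mode.
#' @return data.frame with one row per group: `group_id`,
#'   `cdr3_representative`, `multiplicity`, `libraries`
#'   (semicolon-joined), `n_members`, `max_fold`, `cross_reactive`,
#'   `members` and a `member_ids` list column; the excluded-clone count
#'   is in attribute `n_excluded`.
#' @export
groupByCDR3 <- function(rankedClones, mode = c("exact", "homology_0.98"),
                        identityThreshold = 0.98) {
  mode <- match.arg(mode)
  excl <- sum(is.na(rankedClones$cdr3))
  cl <- rankedClones[!is.na(rankedClones$cdr3), , drop = FALSE]
  n <- nrow(cl)
  if (n == 0L) {
    out <- data.frame(group_id = character(0), cdr3_representative = character(0),
                      multiplicity = integer(0), libraries = character(0),
                      n_members = integer(0), max_fold = numeric(0),
                      cross_reactive = logical(0), members = character(0),
                      member_ids = I(list()))
    attr(out, "n_excluded") <- excl
    return(out)
  }

  if (mode == "exact") {
    grp <- match(cl$cdr3, unique(cl$cdr3))
  } else {
    # single-linkage union-find over pairs at >= identityThreshold
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    uniq <- unique(cl$cdr3)
    ui <- match(cl$cdr3, uniq)
    nu <- length(uniq)
    reps <- match(seq_len(nu), ui)   # one clone per unique CDR3
    if (nu > 1L) {
      pairs <- which(upper.tri(matrix(0, nu, nu)), arr.ind = TRUE)
      idty <- cdr3Identity(uniq[pairs[, 1L]], uniq[pairs[, 2L]])
      link <- pairs[idty >= identityThreshold, , drop = FALSE]
      for (k in seq_len(nrow(link))) {
        a <- find(reps[link[k, 1L]]); b <- find(reps[link[k, 2L]])
        if (a != b) parent[b] <- a
      }
    }
    for (i in seq_len(n)) parent[i] <- find(reps[ui[i]])
    grp <- match(parent, unique(parent))
  }

  groups <- split(seq_len(n), grp)
  multiplicity <- vapply(groups, function(ix)
    length(unique(cl$library[ix])), integer(1))
  maxFold <- vapply(groups, function(ix) max(cl$fold[ix]), numeric(1))
  ord <- order(-multiplicity, -maxFold)
  groups <- groups[ord]
  multiplicity <- multiplicity[ord]
  maxFold <- maxFold[ord]
  crossReactive <- multiplicity >= 2L

  ids <- character(length(groups))
  crLabels <- c("X", "Y", "Z",
                if (sum(crossReactive) > 3L)
                  paste0("XR", 4:sum(crossReactive)))
  ids[crossReactive] <- crLabels[seq_len(sum(crossReactive))]
  ids[!crossReactive] <- paste0("G", seq_len(sum(!crossReactive)))

  rep3 <- vapply(groups, function(ix) cl$cdr3[ix[which.max(cl$fold[ix])]],
                 character(1))
  out <- data.frame(
    group_id = ids,
    cdr3_representative = rep3,
    multiplicity = multiplicity,
    libraries = vapply(groups, function(ix)
      paste(sort(unique(cl$library[ix])), collapse = ";"), character(1)),
    n_members = lengths(groups),
    max_fold = maxFold,
    cross_reactive = crossReactive,
    members = vapply(groups, function(ix)
      paste(cl$clone_id[ix], collapse = ";"), character(1)),
    member_ids = I(lapply(groups, function(ix) cl$clone_id[ix])))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excl
  out
}

#' Cross-library membership matrix of CDR3 groups
#'
#' One row per cross-reactive CDR3 group, one column per library,
#' listing the within-library ranks of its member clones (the layout of
#' an identical-CDR3s summary table).
#'
#' @param cdr3Groups output of [groupByCDR3()].
#' @param libraries library column order (default: those present).
#' @return data.frame, first column `group_id`.
#' @export
cdr3GroupMatrix <- function(cdr3Groups, libraries = NULL) {
  g <- cdr3Groups[cdr3Groups$cross_reactive, , drop = FALSE]
  if (is.null(libraries))
    libraries <- sort(unique(unlist(strsplit(g$libraries, ";"))))
  out <- data.frame(group_id = g$group_id)
  for (ln in libraries) {
    out[[ln]] <- vapply(g$member_ids, function(ids) {
      mine <- ids[startsWith(ids, paste0(ln, "_"))]
      paste(sub(".*_", "", mine), collapse = ", ")
    }, character(1))
  }
  out
}

#' Candidate mono- vs multi-specific binder report
#'
#' One row per tree cluster and per cross-reactive CDR3 group. Each
#' row's representative is its highest-fold member (ties: earliest
#' library name). CDR3-sharing evidence dominates tree-cluster purity: a
#' clone sitting in a mono-specific cluster but sharing a CDR3 across
#' libraries is assigned to the CDR3 group and reported multi-specific.
#' The same hierarchy applies to whole clusters: members of a homology
#' cluster are near-identical sequences, so a cluster containing clones
#' claimed by a cross-reactive CDR3 group is itself reported
#' multi-specific (its library list extended by the claiming groups'),
#' and a cluster whose members were all claimed is not emitted again.
#' Top-ranked clones belonging to neither kind of row are returned in
#' the `singletons` attribute, so every clone appears exactly once.
#'
#' @param clusters output of [extractClusters()] on the combined tree.
#' @param cdr3Groups output of [groupByCDR3()].
#' @param rankedClones the combined per-library top-K clone table.
#' @return data.frame with `group_id`, `group_type`
#'   (`tree_cluster`/`cdr3_group`), `representative`,
#'   `predicted_specificity`, `libraries`, `n_members`, `max_fold`,
#'   `members`, plus attributes `singletons` (data.frame) and
#'   `assignment` (named vector clone id -> row group id or
#'   "singleton").
#' @export
candidateReport <- function(clusters, cdr3Groups, rankedClones) {
  info <- rankedClones[, c("clone_id", "library", "fold")]
  rownames(info) <- info$clone_id

  pickRep <- function(ids) {
    sub <- info[ids, , drop = FALSE]
    sub <- sub[order(-sub$fold, sub$library, method = "radix"), , drop = FALSE]
    sub$clone_id[1L]
  }

  crg <- cdr3Groups[cdr3Groups$cross_reactive, , drop = FALSE]
  crClones <- unlist(crg$member_ids, use.names = FALSE)

  assignment <- setNames(rep("singleton", nrow(info)), info$clone_id)
  rows <- list()
  for (k in seq_len(nrow(crg))) {
    ids <- crg$member_ids[[k]]
    assignment[ids] <- crg$group_id[k]
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = crg$group_id[k], group_type = "cdr3_group",
      representative = pickRep(ids),
      predicted_specificity = "multi_specific",
      libraries = crg$libraries[k],
      n_members = length(ids), max_fold = max(info[ids, "fold"]),
      members = paste(ids, collapse = ";"))
  }
  for (k in seq_len(nrow(clusters))) {
    ids <- clusters$member_ids[[k]]
    primary <- setdiff(ids, crClones)
    if (length(primary) == 0L) next  # fully reported via its CDR3 group(s)
    assignment[primary] <- clusters$group_id[k]
    claimed <- setdiff(ids, primary)
    libs <- sort(unique(info[primary, "library"]))
    if (length(claimed)) {
      # the family shares a cross-library CDR3: CDR3 evidence dominates
      claimedLibs <- unlist(lapply(seq_len(nrow(crg)), function(g)
        if (any(crg$member_ids[[g]] %in% claimed))
          strsplit(crg$libraries[g], ";")[[1]] else character(0)))
      libs <- sort(unique(c(libs, claimedLibs)))
      spec <- "multi_specific"
    } else {
      spec <- if (length(libs) == 1L) "mono_specific" else "multi_specific"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = clusters$group_id[k], group_type = "tree_cluster",
      representative = pickRep(primary),
      predicted_specificity = spec,
      libraries = paste(libs, collapse = ";"),
      n_members = length(primary), max_fold = max(info[primary, "fold"]),
      members = paste(primary, collapse = ";"))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = character(0), group_type = character(0),
               representative = character(0),
               predicted_specificity = character(0), libraries = character(0),
               n_members = integer(0), max_fold = numeric(0),
               members = character(0))
  rownames(out) <- NULL
  singles <- rankedClones[assignment[rankedClones$clone_id] == "singleton", ,
                          drop = FALSE]
  attr(out, "singletons") <- singles
  attr(out, "assignment") <- assignment
  out
}
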