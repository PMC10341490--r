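#' Pairwise p-distance between amino-acid sequences
#'
#' `1 - identity`, where identity is matches over aligned columns under a
#' global alignment whose terminal gaps are free and excluded from the
#' column count (internal gaps count as mismatched columns).
#'
#' @param a,b non-empty amino-acid strings (vectorized).
#' @return numeric vector of distances in `[0, 1]`.
#' @examples
#' pairwiseDistance("AAAA", "AATA") # 0.25
#' @export
pairwiseDistance <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty sequence")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  m <- .alignIdentityCpp(a, b, TRUE)
  as.numeric(ifelse(m[, "columns"] > 0, 1 - m[, "matches"] / m[, "columns"], 1))
}

#' All-vs-all p-distance matrix
#'
#' @param seqs named character vector of amino-acid sequences (names
#'   become matrix labels).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(seqs) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  if (any(!nzchar(seqs))) stop("empty sequence")
  d <- .distMatrixCpp(unname(seqs), TRUE)
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

.quoteNewickLabel <- function(x) {
  bad <- grepl("[][ ,():;']",x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. At each
#' step the pair minimizing Q is joined; ties are broken by the smallest
#' (i, j) label-index pair, so trees are bit-reproducible. Limb lengths
#' use the standard formulas; a negative limb is clamped to 0 and the
#' deficit moved onto the sister limb (their sum stays equal to the
#' joined pair's distance, so additive matrices are recovered exactly).
#' The last three nodes are joined at a trifurcation, giving an unrooted
#' tree.
#'
#' @param d symmetric distance matrix with labels as dimnames (>= 3).
#' @return an [ape::phylo] tree.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighborJoining(d) # limbs 0, 2, 4
#' @export
neighborJoining <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels) || n < 3L) stop("need a labeled matrix with >= 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(diag(d) != 0) || any(d < 0) || any(!is.finite(d)))
    stop("distance matrix must be symmetric, finite, non-negative with zero diagonal")

  frag <- sprintf("VHHsTIP%d", seq_len(n))  # placeholder labels; restored below
  D <- d
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- unique(t(apply(idx, 1L, sort)))
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]

    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))

    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newFrag)
    D <- D2
  }

  dxy <- D[1, 2]; dxz <- D[1, 3]; dyz <- D[2, 3]
  a <- (dxy + dxz - dyz) / 2
  b <- (dxy + dyz - dxz) / 2
  c3 <- (dxz + dyz - dxy) / 2
  a <- max(a, 0); b <- max(b, 0); c3 <- max(c3, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(a), frag[2], fmt(b),
                 frag[3], fmt(c3))
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- labels[as.integer(sub("^VHHsTIP", "", tr$tip.label))]
  tr
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so trees
#' round-trip through the package's own interface.
#'
#' @param tree an `ape::phylo` object.
#' @param path output file; if `NULL`, the Newick string is returned.
#' @return `writeNewick`: the path (or string, invisibly the tree's
#'   text); `readNewick`: a `phylo`.
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  needQuote <- grepl("[][ ,():;']",labs)
  if (any(needQuote)) {
    ph <- sprintf("VHHsTIP%d", seq_along(labs))
    t2 <- tree
    t2$tip.label <- ifelse(needQuote, ph, labs)
    txt <- ape::write.tree(t2)
    for (i in which(needQuote))
      txt <- sub(ph[i], .quoteNewickLabel(labs[i]), txt, fixed = TRUE)
  } else {
    txt <- ape::write.tree(tree)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname writeNewick
#' @param x a Newick string or file path.
#' @export
readNewick <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x), collapse = "") else x
  toks <- regmatches(txt, gregexpr("'(?:[^']|'')*'", txt, perl = TRUE))[[1]]
  if (length(toks) == 0L) return(ape::read.tree(text = txt))
  ph <- sprintf("VHHsQ%dQ", seq_along(toks))
  for (i in seq_along(toks)) txt <- sub(toks[i], ph[i], txt, fixed = TRUE)
  tr <- ape::read.tree(text = txt)
  lab <- gsub("''", "'", substr(toks, 2L, nchar(toks) - 1L))
  idx <- match(tr$tip.label, ph)
  tr$tip.label[!is.na(idx)] <- lab[idx[!is.na(idx)]]
  tr
}

#' Homology clusters on a neighbor-joining tree
#'
#' Candidate clusters are the leaf sets on either side of every internal
#' edge of the unrooted tree (i.e. all maximal clades under every
#' possible rooting). A candidate is eligible when its minimum pairwise
#' homology (`1 - p-distance`) reaches `threshold` and it has at least
#' `minSize` members; overlapping eligible candidates are resolved by
#' preferring larger clades. Each cluster is labeled `mono_specific`
#' when all members come from one library, `mixed` otherwise.
#'
#' @param tree `phylo` with clone ids as tip labels.
#' @param d distance matrix over (at least) the tree's tip labels.
#' @param libraries named character vector clone id -> library of origin.
#' @param threshold minimum within-cluster homology (default 0.988, the
#'   reported cluster-calling homology).
#' @param minSize minimum cluster size.
#' @return data.frame with one row per cluster: `group_id` (A, B, ...),
#'   `n_members`, `specificity`, `min_pairwise_homology`,
#'   `library_composition` (e.g. `"S1T=3;HepG2=2"`), `members`
#'   (semicolon-joined) and a `member_ids` list column.
#' @export
extractClusters <- function(tree, d, libraries, threshold = 0.988,
                            minSize = 2L) {
  stopifnot(inherits(tree, "phylo"), threshold > 0, threshold <= 1)
  tips <- tree$tip.label
  stopifnot(all(tips %in% rownames(d)))
  if (!all(tips %in% names(libraries)))
    stop("library of origin missing for some clones")
  n <- length(tips)

  # leaf sets of both sides of every edge (pendant edges contribute the
  # complement of a single leaf)
  parts <- ape::prop.part(tree)
  cand <- list()
  for (p in parts) {
    s <- tips[p]
    if (length(s) < n) {
      cand[[length(cand) + 1L]] <- s
      cand[[length(cand) + 1L]] <- setdiff(tips, s)
    }
  }
  for (tp in tips) cand[[length(cand) + 1L]] <- setdiff(tips, tp)
  cand <- unique(lapply(cand, sort))
  cand <- Filter(function(s) length(s) >= minSize && length(s) < n, cand)
  if (length(cand) == 0L) return(.emptyClusterFrame())

  minHom <- vapply(cand, function(s) {
    1 - max(d[s, s])
  }, numeric(1))
  eligible <- which(minHom >= threshold)
  if (length(eligible) == 0L) return(.emptyClusterFrame())

  ord <- eligible[order(-lengths(cand[eligible]),
                        vapply(cand[eligible], `[`, character(1), 1L))]
  chosen <- list(); chosenHom <- numeric(0)
  used <- character(0)
  for (k in ord) {
    if (!any(cand[[k]] %in% used)) {
      chosen[[length(chosen) + 1L]] <- cand[[k]]
      chosenHom <- c(chosenHom, minHom[k])
      used <- c(used, cand[[k]])
    }
  }

  # X, Y, Z are reserved for cross-reactive CDR3 group labels
  pool <- setdiff(LETTERS, c("X", "Y", "Z"))
  ids <- make.unique(rep(pool, length.out = length(chosen)), sep = "")
  comp <- lapply(chosen, function(s) table(libraries[s]))
  data.frame(
    group_id = ids,
    n_members = lengths(chosen),
    specificity = vapply(comp, function(tb)
      if (sum(tb > 0) == 1L) "mono_specific" else "mixed", character(1)),
    min_pairwise_homology = chosenHom,
    library_composition = vapply(comp, function(tb)
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ";"),
      character(1)),
    members = vapply(chosen, paste, character(1), collapse = ";"),
    member_ids = I(chosen))
}

.emptyClusterFrame <- function() {
  data.frame(group_id = character(0), n_members = integer(0),
             specificity = character(0), min_pairwise_homology = numeric(0),
             library_composition = character(0), members = character(0),
             member_ids = I(list()))
}
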