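# Small simulated data sets shared across test files, built once per run.

.fixtureCache <- new.env(parent = emptyenv())

smallConfig <- function(seed = 42L, errorRate = 0.005, nClones = 150L,
                        reads = 5000L) {
  panningConfig(nClones = nClones, readsPerRound = reads, seed = seed,
                binderFraction = 0.04, crossReactiveFraction = 0.02,
                perBaseErrorRate = errorRate)
}

getFixture <- function(key, config) {
  if (is.null(.fixtureCache[[key]])) {
    dir <- file.path(tempdir(), paste0("vhhfx_", key))
    .fixtureCache[[key]] <- makeFixtures(config, dir)
  }
  .fixtureCache[[key]]
}

# build a clone-count multiset with prescribed marginals: merged total,
# number of singletons, number of unique clones, and top clone count
makeCountsWithMarginals <- function(merged, single, unique, top) {
  rest <- unique - single - 1L
  remaining <- merged - single - top
  if (rest == 0L) {
    stopifnot(remaining == 0L)
    counts <- c(rep(1L, single), top)
  } else {
    base <- remaining %/% rest
    extra <- remaining %% rest
    stopifnot(base >= 2L, base + (extra > 0L) <= top)
    counts <- c(rep(1L, single), top,
                rep(base + 1L, extra), rep(base, rest - extra))
  }
  setNames(as.integer(counts), sprintf("clone%06d", seq_along(counts)))
}

# a repertoire with hand-set binding weights (for closed-form selection tests)
repertoireWithWeights <- function(n, weights, seed = 5L, cellLines = "S1T") {
  cfg <- panningConfig(nClones = n, seed = seed, cellLines = cellLines,
                       readsPerRound = 10000L)
  rep <- generateRepertoire(cfg)
  w <- matrix(1, nrow = n, ncol = length(cellLines),
              dimnames = list(cloneIds(rep), cellLines))
  w[seq_along(weights), 1L] <- weights
  rep@weights <- w
  rep
}

# random additive distance matrix from a random tree with positive branches
randomAdditive <- function(nLeaves, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(nLeaves, br = function(n) stats::runif(n, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
}
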