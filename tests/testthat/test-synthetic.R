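test_that("repertoire composition follows the configured fractions and is reproducible", {
  cfg <- panningConfig(nClones = 200, binderFraction = 0.02,
                       crossReactiveFraction = 0.01, seed = 7,
                       readsPerRound = 1000)
  rep1 <- generateRepertoire(cfg)
  rep2 <- generateRepertoire(cfg)
  expect_identical(rep1@clones, rep2@clones)
  expect_identical(rep1@weights, rep2@weights)

  w <- bindingWeights(rep1)
  nBound <- rowSums(w > 1)
  expect_equal(nrow(rep1@clones), 200L)
  expect_equal(sum(nBound == 1L), 4L)   # 2% mono binders
  expect_equal(sum(nBound >= 2L), 2L)   # 1% cross-reactive
  expect_true(all(w >= 0))
})

test_that("clone nucleotide sequences translate back to the amino-acid truth", {
  cfg <- panningConfig(nClones = 40, seed = 3, readsPerRound = 1000)
  rep <- generateRepertoire(cfg)
  p <- defaultPrimers()
  for (i in seq_len(10)) {
    nt <- rep@clones$nt_seq[i]
    expect_identical(substr(nt, 1, nchar(p$fwd)), p$fwd)
    revLen <- if (rep@clones$hinge[i] == "short_IgG2")
      nchar(p$rev_short_IgG2) else nchar(p$rev_long_IgG3)
    insert <- substr(nt, nchar(p$fwd) + 1, nchar(nt) - revLen)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(insert)))
    expect_identical(aa, rep@clones$aa_seq[i])
    expect_true(grepl(rep@clones$true_cdr3[i], rep@clones$aa_seq[i],
                      fixed = TRUE))
  }
})

test_that("binding weights follow the configured log-normal law", {
  # with meanlog 3, sdlog 0.5 essentially every draw exceeds 1
  # (P = pnorm(3/0.5)); the mean of log-weights estimates meanlog
  cfg <- panningConfig(nClones = 2000, binderFraction = 0.5,
                       crossReactiveFraction = 0.001, seed = 11,
                       readsPerRound = 1000)
  rep <- generateRepertoire(cfg)
  w <- bindingWeights(rep)
  bw <- w[rowSums(w > 1) == 1L, ]
  bw <- bw[bw > 1]
  expect_gte(length(bw), 900L)
  expect_equal(mean(bw > 1), pnorm(3 / 0.5), tolerance = 1e-3)
  expect_lt(abs(mean(log(bw)) - 3), 3 * 0.5 / sqrt(length(bw)))
})

test_that("panning counts conserve depth and neutral selection does not drift", {
  cfg <- panningConfig(nClones = 50, binderFraction = 0.001,
                       crossReactiveFraction = 0.001, seed = 2,
                       readsPerRound = 20000, rounds = 3)
  rep <- generateRepertoire(cfg)
  expect_true(all(rowSums(bindingWeights(rep) > 1) == 0L)) # all neutral
  drift <- replicate(20, {
    cfg2 <- cfg; cfg2@seed <- cfg@seed + sample.int(1e6, 1)
    m <- SummarizedExperiment::assay(simulatePanning(rep, "S1T", cfg2))
    expect_true(all(colSums(m) == cfg@readsPerRound))
    (m[, 4] - m[, 1]) / cfg@readsPerRound
  })
  meanDrift <- rowMeans(drift)
  se <- apply(drift, 1, sd) / sqrt(ncol(drift))
  expect_lt(mean(abs(meanDrift)), 3 * mean(se))
})

test_that("selection advantage reweights frequencies as the closed form predicts", {
  rep <- repertoireWithWeights(2, weights = c(2, 1))
  cfg <- simConfig(rep); cfg@rounds <- 1L
  se <- simulatePanning(rep, "S1T", cfg, baseCounts = c(5000L, 5000L))
  f1 <- SummarizedExperiment::assay(se)[1, 2] / 10000
  expect_lt(abs(f1 - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / 10000))

  # rare clone, weight 10, two rounds: realized fold tracks the
  # deterministic expectation of repeated weighted resampling
  rep2 <- repertoireWithWeights(100, weights = 10, seed = 6)
  cfg2 <- simConfig(rep2); cfg2@rounds <- 2L
  base <- c(10L, rep(ceiling(9990 / 99), 99))
  base <- as.integer(round(base * 10000 / sum(base)))
  f0 <- base[1] / sum(base)
  f <- f0
  for (r in 1:2) f <- 10 * f / (10 * f + (1 - f))
  expected_fold <- f / f0
  se2 <- simulatePanning(rep2, "S1T", cfg2, baseCounts = base)
  realized <- SummarizedExperiment::assay(se2)[1, 3] / sum(base) / f0
  expect_lt(abs(realized - expected_fold) / expected_fold, 0.25)
  expect_error(simulatePanning(rep2, "NOT_A_LINE", cfg2), "unknown cell line")
})

test_that("emitted FASTQ matches the count table and the error model", {
  # error-free reads reconstruct the amplicons exactly
  cfg0 <- smallConfig(seed = 9, errorRate = 0, nClones = 30, reads = 400)
  rep <- generateRepertoire(cfg0)
  se <- simulatePanning(rep, "S1T", cfg0)
  dir <- tempfile()
  files <- emitFastq(se, rep, cfg0, dir, "lib", roundIdx = 0L)
  rp <- readFastqPairs(files$r1, files$r2)
  expect_length(rp$r1, 400L)
  mg <- mergePairs(rp$r1, rp$r2, rp$q1, rp$q2)
  expect_true(all(mg$merged))
  cloneOf <- sub(".*clone=", "", names(Biostrings::readDNAStringSet(
    files$r1, format = "fastq")))
  expect_identical(unname(mg$seq),
                   rep@clones$nt_seq[match(cloneOf, cloneIds(rep))])

  # substitution rate: mean mismatches per 300-nt read ~ Binomial(300, rate)
  cfgE <- smallConfig(seed = 9, errorRate = 0.01, nClones = 30, reads = 100)
  repE <- generateRepertoire(cfgE)
  cnt <- matrix(0L, nrow = 30, ncol = 1, dimnames = list(cloneIds(repE), "round0"))
  cnt[1, 1] <- 100L
  fE <- emitFastq(cnt, repE, cfgE, tempfile(), "one")
  r1 <- as.character(Biostrings::readDNAStringSet(fE$r1, format = "fastq"))
  ref <- substr(repE@clones$nt_seq[1], 1, 300)
  mm <- vapply(r1, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(ref, "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(mm) - 300 * 0.01), 3 * sqrt(300 * 0.01 * 0.99 / 100))

  # empty count table -> valid empty FASTQ pair
  empty <- matrix(0L, nrow = 30, ncol = 1,
                  dimnames = list(cloneIds(repE), "round0"))
  fz <- emitFastq(empty, repE, cfgE, tempfile(), "none")
  expect_true(file.exists(fz$r1) && file.exists(fz$r2))
  expect_length(Biostrings::readDNAStringSet(fz$r1, format = "fastq"), 0L)
})

test_that("FASTQ emission is byte-identical for a fixed seed and amplicon length is enforced", {
  cfg <- smallConfig(seed = 21, nClones = 20, reads = 200)
  rep <- generateRepertoire(cfg)
  se <- simulatePanning(rep, "S1T", cfg)
  f1 <- emitFastq(se, rep, cfg, tempfile(), "a", roundIdx = 2L)
  f2 <- emitFastq(se, rep, cfg, tempfile(), "a", roundIdx = 2L)
  expect_identical(unname(tools::md5sum(f1$r1)), unname(tools::md5sum(f2$r1)))
  cfgB <- cfg; cfgB@seed <- 22L
  repB <- generateRepertoire(cfgB)
  seB <- simulatePanning(repB, "S1T", cfgB)
  f3 <- emitFastq(seB, repB, cfgB, tempfile(), "a", roundIdx = 2L)
  expect_false(tools::md5sum(f1$r1) == tools::md5sum(f3$r1))

  repLong <- rep
  repLong@clones$nt_seq[1] <- strrep("ACGT", 160)  # 640 nt amplicon
  cntLong <- matrix(0L, nrow = 20, ncol = 1,
                    dimnames = list(cloneIds(rep), "round0"))
  cntLong[1, 1] <- 5L
  expect_error(emitFastq(cntLong, repLong, cfg, tempfile(), "x"),
               cloneIds(rep)[1])
})
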