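test_that("read pairs merge on their best ungapped overlap with quality-aware consensus", {
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  m <- mergePairs("ACGTACGTAA", rc("GTACGTAACC"), minOverlap = 8)
  expect_true(m$merged)
  expect_identical(m$seq, "ACGTACGTAACC")
  expect_identical(m$overlap_len, 8L)
  expect_identical(m$mismatches_in_overlap, 0L)

  # disagreement resolved toward the higher-quality base
  r1 <- "AAAATTTT"; r2rc <- "AAAGTTTT"   # mismatch at position 4
  m2 <- mergePairs(r1, rc(r2rc), q1 = strrep("I", 8), q2 = strrep("5", 8),
                   minOverlap = 8, maxMismatchFrac = 0.2,
                   tryBothOrientations = FALSE)
  expect_identical(m2$seq, r1)           # r1 has Q40 vs Q20
  m3 <- mergePairs(r1, rc(r2rc), q1 = strrep("5", 8), q2 = strrep("I", 8),
                   minOverlap = 8, maxMismatchFrac = 0.2,
                   tryBothOrientations = FALSE)
  expect_identical(m3$seq, r2rc)

  set.seed(1)
  a <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  expect_false(mergePairs(a, b, minOverlap = 20)$merged)
  expect_error(mergePairs("ACGT", "ACGT", q1 = "II"), "length mismatch")
})

test_that("flipped-orientation pairs merge onto the reverse strand and are re-oriented", {
  set.seed(7)
  amp <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  r1 <- substr(amp, 1, 50)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amp, 31, 80))))
  fwd <- mergePairs(r1, r2, minOverlap = 15)
  flp <- mergePairs(r2, r1, minOverlap = 15)
  expect_true(fwd$merged && flp$merged)
  expect_identical(fwd$seq, amp)
  expect_identical(flp$seq, VHHscreen:::revComp(amp))

  # at the pipeline level, swapping the mate files changes nothing:
  # merged reads are re-oriented by the forward primer before trimming
  cfg <- smallConfig(seed = 33, errorRate = 0, nClones = 60, reads = 2000)
  fx <- getFixture("errfree", cfg)
  f <- fx$files$round0
  straight <- processReads(f$r1, f$r2)
  swapped <- processReads(f$r2, f$r1)
  expect_identical(dereplicate(swapped$aa_seq[!is.na(swapped$aa_seq)]),
                   dereplicate(straight$aa_seq[!is.na(straight$aa_seq)]))
})

test_that("error-free simulated pairs merge perfectly back to their amplicons", {
  cfg <- smallConfig(seed = 33, errorRate = 0, nClones = 60, reads = 2000)
  fx <- getFixture("errfree", cfg)
  f <- fx$files$round0
  rp <- readFastqPairs(f$r1, f$r2)
  mg <- mergePairs(rp$r1, rp$r2, rp$q1, rp$q2)
  expect_identical(mean(mg$merged), 1)
  cloneOf <- sub(".*clone=", "", names(Biostrings::readDNAStringSet(
    f$r1, format = "fastq")))
  truth <- fx$repertoire@clones$nt_seq[match(cloneOf, cloneIds(fx$repertoire))]
  expect_identical(unname(mg$seq), truth)
})

test_that("expected errors are the Phred-implied error sum", {
  q40 <- strrep(rawToChar(as.raw(40 + 33)), 300)
  q10 <- strrep(rawToChar(as.raw(10 + 33)), 300)
  expect_equal(expectedErrors(q40), 300 * 1e-4)
  expect_true(qualityFilter(q40, 1.0))
  expect_equal(expectedErrors(q10), 300 * 0.1)
  expect_false(qualityFilter(q10, 1.0))
  # mixed-quality read, hand-summed: Q40, Q40, Q20, Q2
  mixed <- paste0("II5", rawToChar(as.raw(2 + 33)))
  expect_equal(expectedErrors(mixed),
               1e-4 + 1e-4 + 1e-2 + 10^(-0.2), tolerance = 1e-12)
})

test_that("raising the expected-error ceiling never rejects more reads", {
  cfg <- smallConfig(seed = 12, nClones = 40, reads = 1500)
  fx <- getFixture("noisy", cfg)
  rp <- readFastqPairs(fx$files$round0$r1, fx$files$round0$r2)
  mg <- mergePairs(rp$r1, rp$r2, rp$q1, rp$q2)
  quals <- mg$qual[mg$merged]
  passing <- vapply(c(0.25, 0.5, 1, 2, 4, 8),
                    function(t) sum(qualityFilter(quals, t)), numeric(1))
  expect_true(all(diff(passing) >= 0))
})

test_that("primers are located IUPAC-aware and set the hinge class", {
  p <- defaultPrimers()
  insert <- "ATGGCTAAAGGCGCTACCGGT"
  ampS <- paste0(p$fwd, insert, VHHscreen:::revComp(p$rev_short_IgG2))
  ampL <- paste0(p$fwd, insert, VHHscreen:::revComp(p$rev_long_IgG3))
  tc <- trimAndClassify(c(ampS, ampL))
  expect_identical(tc$hinge, c("short_IgG2", "long_IgG3"))
  expect_identical(tc$trimmed, c(insert, insert))

  noFwd <- paste0("TTTTTTTTTTTTTTTTTTTTTTTT", insert,
                  VHHscreen:::revComp(p$rev_short_IgG2))
  expect_identical(trimAndClassify(noFwd)$reason, "no_fwd_primer")
  noRev <- paste0(p$fwd, insert, "TTTTTTTTTTTTTTTTTTTTTT")
  expect_identical(trimAndClassify(noRev)$reason, "no_rev_primer")

  # IUPAC K = G/T
  mm <- VHHscreen:::iupacMismatches(c("AGGT", "AGTT", "AGCT"), "AGKT", c(0, 0, 0))
  expect_identical(mm, c(0L, 0L, 1L))
})

test_that("frame-0 translation rejects stops and short products", {
  expect_identical(translateFrame0("ATGGCT", minAALength = 1)$aa, "MA")
  expect_identical(translateFrame0("ATGGCTA", minAALength = 1)$aa, "MA") # partial codon dropped
  r <- translateFrame0("ATGTAAGCT", minAALength = 1)
  expect_true(is.na(r$aa))
  expect_identical(r$reason, "stop_codon")
  expect_identical(translateFrame0("ATG", minAALength = 5)$reason, "too_short")
  expect_error(translateFrame0("AT!GCT"), "non-IUPAC")
})

test_that("processing partitions every input read into accepted or one rejection reason", {
  cfg <- smallConfig(seed = 12, nClones = 40, reads = 1500)
  fx <- getFixture("noisy", cfg)
  pr <- processReads(fx$files$round0$r1, fx$files$round0$r2)
  att <- attr(pr, "attrition")
  expect_identical(att$count[1], 1500L)
  expect_identical(sum(att$count[-1]), att$count[1])
  expect_true(all(xor(is.na(pr$aa_seq), is.na(pr$rejected_reason))))
  # accepted reads carry a hinge class consistent with the ground truth
  acc <- pr[!is.na(pr$aa_seq), ]
  truthHinge <- setNames(fx$repertoire@clones$hinge,
                         fx$repertoire@clones$aa_seq)
  known <- acc$aa_seq %in% names(truthHinge)
  expect_gt(mean(acc$hinge[known] == truthHinge[acc$aa_seq[known]]), 0.999)
})

test_that("error-free processing reproduces the ground-truth clonotype counts", {
  cfg <- smallConfig(seed = 33, errorRate = 0, nClones = 60, reads = 2000)
  fx <- getFixture("errfree", cfg)
  pr <- processReads(fx$files$round0$r1, fx$files$round0$r2)
  expect_true(all(is.na(pr$rejected_reason)))
  got <- dereplicate(pr$aa_seq)
  truthCounts <- read.table(fx$truth, sep = "\t", header = TRUE)
  truthCounts <- truthCounts[truthCounts$count_round0 > 0, ]
  expect_identical(sort(names(got)), sort(truthCounts$aa_seq))
  expect_identical(unname(got[truthCounts$aa_seq]),
                   truthCounts$count_round0)
})
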