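# build a minimal ranked-clone table for grouping tests
rankedFixture <- function(libs, ranks, cdr3s, folds = NULL) {
  n <- length(libs)
  if (is.null(folds)) folds <- seq(n, 1)
  data.frame(clone_id = sprintf("%s_%d", libs, ranks), library = libs,
             rank = ranks, cdr3 = cdr3s, fold = folds,
             freq_final = folds / sum(folds), aa_seq = paste0("AA", seq_len(n)))
}

test_that("an identical CDR3 shared by three libraries forms one multiplicity-3 group", {
  shared <- "ARDLSTYEYDY"
  libs <- c(rep("S1T", 3), rep("HepG2", 6), rep("SKBR3", 6))
  ranks <- c(14, 24, 39, 5, 15, 17, 25, 27, 35, 8, 15, 16, 30, 31, 36)
  filler <- rankedFixture(c("S1T", "KYSE520"), c(1, 1),
                          c("AKNNNNNNN", "AKPPPPPPP"), folds = c(99, 98))
  rk <- rbind(rankedFixture(libs, ranks, rep(shared, 15)), filler)
  g <- groupByCDR3(rk, mode = "exact")
  cr <- g[g$cross_reactive, ]
  expect_identical(nrow(cr), 1L)
  expect_identical(cr$group_id, "X")
  expect_identical(cr$multiplicity, 3L)
  expect_identical(cr$libraries, "HepG2;S1T;SKBR3")
  expect_identical(cr$n_members, 15L)

  m <- cdr3GroupMatrix(g, c("S1T", "HepG2", "SKBR3", "KYSE520"))
  expect_identical(m$S1T, "14, 24, 39")
  expect_identical(m$HepG2, "5, 15, 17, 25, 27, 35")
  expect_identical(m$SKBR3, "8, 15, 16, 30, 31, 36")
  expect_identical(m$KYSE520, "")
})

test_that("unique CDR3s produce no cross-reactive group", {
  rk <- rankedFixture(c("S1T", "HepG2", "SKBR3"), 1:3,
                      c("AKAAAA", "AKCCCC", "AKDDDD"))
  g <- groupByCDR3(rk)
  expect_false(any(g$cross_reactive))
  expect_identical(nrow(g), 3L)
})

test_that("exact grouping equals brute-force all-pairs comparison", {
  set.seed(23)
  n <- 200
  pool <- replicate(60, paste(sample(LETTERS[1:20], 9, TRUE), collapse = ""))
  rk <- rankedFixture(sample(c("S1T", "HepG2", "SKBR3", "KYSE520"), n, TRUE),
                      seq_len(n), sample(pool, n, TRUE),
                      folds = runif(n, 1, 100))
  g <- groupByCDR3(rk, mode = "exact")

  # O(n^2) oracle: same group iff identical CDR3 string
  oracle <- outer(rk$cdr3, rk$cdr3, "==")
  got <- matrix(FALSE, n, n)
  idOf <- setNames(seq_len(n), rk$clone_id)
  for (k in seq_len(nrow(g))) {
    ix <- idOf[g$member_ids[[k]]]
    got[ix, ix] <- TRUE
  }
  expect_identical(got, oracle)
  # multiplicity equals a direct recount
  for (k in seq_len(nrow(g)))
    expect_identical(g$multiplicity[k],
                     length(unique(rk$library[idOf[g$member_ids[[k]]]])))
})

test_that("homology mode single-links CDR3s at 98% identity", {
  base <- paste(rep("ACDEFGHIKL", 5), collapse = "")  # 50 aa
  one <- paste0(substr(base, 1, 49), "V")             # 1 mismatch: 0.98
  two <- paste0(substr(base, 1, 48), "VV")            # 2 mismatches: 0.96
  rk <- rankedFixture(c("S1T", "HepG2", "SKBR3"), 1:3, c(base, one, two))
  g <- groupByCDR3(rk, mode = "homology_0.98")
  cr <- g[g$cross_reactive, ]
  expect_identical(nrow(cr), 1L)
  # `two` is within 0.98 of `one`? 49/50 = 0.98 yes -> single-linkage chains all three
  expect_identical(cr$n_members, 3L)

  far <- paste(rep("MNPQRSTVWY", 5), collapse = "")
  rk2 <- rankedFixture(c("S1T", "HepG2"), 1:2, c(base, far))
  expect_false(any(groupByCDR3(rk2, mode = "homology_0.98")$cross_reactive))
})

test_that("candidate report applies the CDR3-dominance rule and loses no clone", {
  # cluster of pure SKBR3 leaves -> SKBR3-specific candidate
  rk <- rankedFixture(c("SKBR3", "SKBR3", "S1T", "HepG2"), c(1, 2, 1, 1),
                      c("AKAAAA", "AKGGGG", "AKSHRD", "AKSHRD"),
                      folds = c(50, 40, 30, 20))
  clusters <- data.frame(group_id = "A", n_members = 2L,
                         specificity = "mono_specific",
                         min_pairwise_homology = 0.99,
                         library_composition = "SKBR3=2",
                         members = "SKBR3_1;SKBR3_2",
                         member_ids = I(list(c("SKBR3_1", "SKBR3_2"))))
  g <- groupByCDR3(rk)
  repn <- candidateReport(clusters, g, rk)
  mono <- repn[repn$group_type == "tree_cluster", ]
  expect_identical(mono$predicted_specificity, "mono_specific")
  expect_identical(mono$libraries, "SKBR3")
  expect_identical(mono$representative, "SKBR3_1")
  multi <- repn[repn$group_type == "cdr3_group", ]
  expect_identical(multi$predicted_specificity, "multi_specific")
  expect_identical(multi$libraries, "HepG2;S1T")

  asg <- attr(repn, "assignment")
  expect_setequal(names(asg), rk$clone_id)
  expect_identical(unname(asg[c("S1T_1", "HepG2_1")]), c("X", "X"))

  # dominance: a clone in a mono cluster that shares a CDR3 across
  # libraries is claimed by the CDR3 group
  rk2 <- rankedFixture(c("S1T", "S1T", "HepG2"), c(1, 2, 1),
                       c("AKZZZZ", "AKQQQQ", "AKZZZZ"),
                       folds = c(60, 50, 10))
  cl2 <- data.frame(group_id = "A", n_members = 2L,
                    specificity = "mono_specific",
                    min_pairwise_homology = 0.99,
                    library_composition = "S1T=2",
                    members = "S1T_1;S1T_2",
                    member_ids = I(list(c("S1T_1", "S1T_2"))))
  g2 <- groupByCDR3(rk2)
  repn2 <- candidateReport(cl2, g2, rk2)
  asg2 <- attr(repn2, "assignment")
  expect_identical(unname(asg2["S1T_1"]), "X")   # CDR3 evidence dominates
  expect_identical(unname(asg2["S1T_2"]), "A")
  xrow <- repn2[repn2$group_id == "X", ]
  expect_identical(xrow$predicted_specificity, "multi_specific")
  expect_true(grepl("S1T_1", xrow$members))
  # every clone lands in exactly one row or the singleton appendix
  counted <- sum(asg2 != "singleton") + nrow(attr(repn2, "singletons"))
  expect_identical(counted, nrow(rk2))
})
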