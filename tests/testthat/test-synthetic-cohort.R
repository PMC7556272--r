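test_that("planted covariance reproduces block structure exactly", {
  s <- cohortSpec(nRois = 4, nModules = 2, rhoIn = 0.5, rhoOut = 0,
                  hubRois = integer(0), hubBoost = 0)
  expected <- matrix(c(1, .5, 0, 0, .5, 1, 0, 0,
                       0, 0, 1, .5, 0, 0, .5, 1), 4, 4)
  expect_equal(unname(buildCovariance(s, "NC")), expected)
  s0 <- cohortSpec(nRois = 4, nModules = 2, rhoIn = 0, rhoOut = 0,
                   hubRois = integer(0), hubBoost = 0)
  expect_equal(unname(buildCovariance(s0, "NC")), diag(4))
})

test_that("hub boost raises cross-module entries and keeps the matrix PSD", {
  s <- cohortSpec(nRois = 4, nModules = 2, rhoIn = 0.6, rhoOut = 0.1,
                  hubRois = 1L, hubBoost = 0.2,
                  groupEffect = list(rhoIn = 0, rhoOut = 0, hubBoost = 0,
                                     splitModule = NA_integer_))
  m <- buildCovariance(s, "NC")
  expect_equal(unname(m[1, 3:4]), c(0.3, 0.3))
  expect_equal(unname(m[2, 3:4]), c(0.1, 0.1))
  expect_gte(min(eigen(m, symmetric = TRUE)$values), 0)
  # repaired default-size matrix is PSD with unit diagonal
  big <- buildCovariance(cohortSpec(), "MCI")
  expect_gte(min(eigen(big, symmetric = TRUE)$values), -1e-8)
  expect_equal(unname(diag(big)), rep(1, 116))
})

test_that("the case group's module split relabels half of module 1", {
  spec <- cohortSpec()
  gt <- generateCohort(cohortSpec(nPerGroup = 1, nTimepoints = 5)) |>
    groundTruth()
  pNC <- gt$partition$NC
  pMCI <- gt$partition$MCI
  expect_equal(max(pNC), 4)
  expect_equal(max(pMCI), 5)
  moved <- which(pNC != pMCI)
  expect_true(all(pNC[moved] == 1) && all(pMCI[moved] == 5))
})

test_that("identical seeds give bit-identical cohorts", {
  s <- cohortSpec(nPerGroup = 3, nRois = 12, nModules = 3, nTimepoints = 30)
  c1 <- generateCohort(s, seed = 7)
  c2 <- generateCohort(s, seed = 7)
  expect_identical(cohortMetadata(c1), cohortMetadata(c2))
  expect_identical(subjectTimeseries(c1, 5), subjectTimeseries(c2, 5))
  expect_error(generateCohort(cohortSpec(nTimepoints = 2)), "nTimepoints")
})

test_that("empirical correlations converge to the planted matrix at large T", {
  s <- cohortSpec(nPerGroup = 1, nRois = 12, nModules = 4, nTimepoints = 5000,
                  rhoIn = 0.6, rhoOut = 0.1, hubRois = integer(0),
                  hubBoost = 0,
                  groupEffect = list(rhoIn = 0, rhoOut = 0, hubBoost = 0,
                                     splitModule = NA_integer_))
  coh <- generateCohort(s, seed = 11)
  emp <- fcValues(computeFC(subjectTimeseries(coh, 1)))
  truth <- abs(buildCovariance(s, "NC"))
  diag(truth) <- 0
  expect_lt(max(abs(emp - truth)), 3 / sqrt(5000))
  # within-module |r| exceeds between-module |r| for every module pair
  p <- s@partitionTruth
  for (a in 1:4) {
    within <- emp[p == a, p == a]
    within <- mean(within[upper.tri(within)])
    for (b in setdiff(1:4, a)) {
      expect_gt(within, mean(emp[p == a, p == b]))
    }
  }
})

test_that("case-group scores shift in the clinically consistent direction", {
  s <- cohortSpec(nPerGroup = 150, nRois = 6, nModules = 2, nTimepoints = 10,
                  hubRois = integer(0), hubBoost = 0)
  meta <- cohortMetadata(generateCohort(s, seed = 13))
  mci <- meta$group == "MCI"
  expect_gt(mean(meta$ADAS13[mci]), mean(meta$ADAS13[!mci]))
  expect_gt(mean(meta$CDRSB[mci]), mean(meta$CDRSB[!mci]))
  expect_gt(mean(meta$FAQ[mci]), mean(meta$FAQ[!mci]))
  expect_lt(mean(meta$MMSE[mci]), mean(meta$MMSE[!mci]))
})

test_that("with zero group effect, score group tests stay at nominal level", {
  s <- nullCohortSpec(nPerGroup = 15, nRois = 6, nModules = 2,
                      nTimepoints = 10, hubRois = integer(0), hubBoost = 0)
  reject <- matrix(FALSE, 100, 4)
  for (r in 1:100) {
    meta <- cohortMetadata(generateCohort(s, seed = 5000 + r))
    mci <- meta$group == "MCI"
    for (k in 1:4) {
      sc <- meta[[c("ADAS13", "CDRSB", "MMSE", "FAQ")[k]]]
      reject[r, k] <- t.test(sc[mci], sc[!mci])$p.value < 0.05
    }
  }
  # non-significant in at least 90% of replicate cohorts, per score
  expect_true(all(colMeans(reject) <= 0.10))
})

test_that("cohorts round-trip through the plain-text writer", {
  s <- cohortSpec(nPerGroup = 2, nRois = 8, nModules = 2, nTimepoints = 15)
  coh <- generateCohort(s, seed = 17)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_equal(cohortMetadata(back), cohortMetadata(coh))
  expect_equal(subjectTimeseries(back, 3), subjectTimeseries(coh, 3))
  expect_equal(groundTruth(back)$partition$NC, groundTruth(coh)$partition$NC)
  expect_equal(groundTruth(back)$informativeFeatures,
               groundTruth(coh)$informativeFeatures)
})

test_that("ground truth marks a valid informative-feature set", {
  gt <- groundTruth(defaultCohort())
  expect_true(all(gt$informativeFeatures %in% 1:124))
  # scores, the four global metrics and the boosted-hub bc columns
  expect_true(all(1:8 %in% gt$informativeFeatures))
  expect_setequal(setdiff(gt$informativeFeatures, 1:8),
                  8 + groundTruth(defaultCohort())$hubs$NC)
})
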