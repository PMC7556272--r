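test_that("the normality gate routes Gaussian and skewed samples correctly", {
  gateOf <- function(gen) {
    vapply(1:100, function(r) {
      withr::with_seed(700 + r, normalityGate(gen()) == "normal")
    }, NA)
  }
  expect_gte(mean(gateOf(function() rnorm(100))), 0.9)
  expect_lte(mean(gateOf(function() rexp(100))), 0.1)
  expect_warning(g <- normalityGate(rep(2, 10)), "constant")
  expect_equal(g, "non-normal")
  expect_error(normalityGate(c(1, 2, 3)), "n >= 5")
})

test_that("demographics tests are chosen by the normality gate", {
  withr::with_seed(71, {
    meta <- data.frame(
      group = rep(c("NC", "MCI"), each = 40),
      gender = sample(c("M", "F"), 80, replace = TRUE),
      ADAS13 = rnorm(80, 12, 4), CDRSB = rexp(80, 1),
      MMSE = rnorm(80, 28, 1.5), FAQ = rexp(80, 0.5)
    )
  })
  tab <- demographicsTable(meta)
  expect_equal(tab$test[tab$variable == "ADAS13"], "t")
  expect_equal(tab$test[tab$variable == "CDRSB"], "wilcoxon")
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})

test_that("Fisher's exact test reproduces the reported gender comparison", {
  p <- fisherExact2x2(matrix(c(46, 36, 36, 57), 2, byrow = TRUE))
  expect_equal(round(p, 3), 0.024)
  expect_equal(fisherExact2x2(matrix(10, 2, 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)), 1)
})

test_that("enumeration agrees with the conditional-exact oracle on random tables", {
  withr::with_seed(72, {
    for (r in 1:200) {
      tab <- matrix(rpois(4, 8), 2, 2)
      expect_equal(fisherExact2x2(tab), fisher.test(tab)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("logistic group test behaves under no-signal and separation", {
  metric <- rep(seq(-2, 2, length.out = 20), 2)
  group <- rep(c("NC", "MCI"), each = 20)
  gender <- rep(rep(c("M", "F"), 10), 2)
  res <- logisticGroupTest(metric, group, gender)
  expect_lt(abs(res$coefficient), 1e-6)
  expect_gt(res$p_value, 0.99)
  expect_false(res$significant_unadjusted)
  # perfectly separating metric is flagged, p withheld
  sep <- logisticGroupTest(c(rnorm(20, -5), rnorm(20, 5)), group, gender)
  expect_true(sep$separation)
  expect_true(is.na(sep$p_value))
  expect_error(logisticGroupTest(metric, rep("NC", 40), gender), "both groups")
})

test_that("planted path-length decrease is detected across most sparsities", {
  coh <- defaultCohort()
  meta <- cohortMetadata(coh)
  fcs <- subjectFCs(coh)
  grid <- seq(0.1, 0.5, by = 0.05)
  hits <- vapply(grid, function(s) {
    L <- vapply(fcs, function(fc) {
      characteristicPathLength(thresholdBySparsity(fc, s))$L
    }, 0)
    logisticGroupTest(L, meta$group, meta$gender, "L", s)$p_value < 0.05
  }, NA)
  expect_gte(mean(hits), 0.8)
  # and the direction matches the planted effect: shorter paths in the case
  # group (raised between-module correlation)
  L16 <- vapply(fcs, function(fc) {
    characteristicPathLength(thresholdBySparsity(fc, 0.16))$L
  }, 0)
  expect_lt(mean(L16[meta$group == "MCI"]), mean(L16[meta$group == "NC"]))
})

test_that("logistic p-values are uniform under label permutation", {
  withr::with_seed(73, {
    metric <- rnorm(60)
    gender <- sample(c("M", "F"), 60, replace = TRUE)
    ps <- vapply(1:500, function(r) {
      group <- sample(rep(c("NC", "MCI"), each = 30))
      logisticGroupTest(metric, group, gender)$p_value
    }, 0)
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("partial correlation matches its definition and edge cases", {
  withr::with_seed(74, {
    x <- rnorm(50)
    z <- sample(c("M", "F"), 50, replace = TRUE)
  })
  expect_equal(partialCorrelation(x, x, z)$r_partial, 1)
  # constant covariate reduces to the plain Pearson correlation
  withr::with_seed(75, y <- 0.5 * x + rnorm(50))
  pc <- partialCorrelation(x, y, rep(1, 50))
  expect_equal(pc$r_partial, cor(x, y), tolerance = 1e-12)
  expect_error(partialCorrelation(x, rep(2, 50), z), "residual variance")
})

test_that("partial correlation is near zero for independent pairs", {
  small <- vapply(1:40, function(r) {
    withr::with_seed(760 + r, {
      x <- rnorm(1000)
      y <- rnorm(1000)
      z <- sample(c("M", "F"), 1000, replace = TRUE)
    })
    abs(partialCorrelation(x, y, z)$r_partial) < 0.1
  }, NA)
  expect_gte(mean(small), 0.95)
})

test_that("planted score-network coefficients are recovered with their sign", {
  sm <- defaultScoreModel()
  sm$ADAS13 <- list(intercept = 12, sd = 2, caseShift = 0, coef = -25,
                    property = "L")
  sm$MMSE <- list(intercept = 28, sd = 1, caseShift = 0, coef = 15,
                  property = "GE")
  spec <- nullCohortSpec(nPerGroup = 100, nRois = 20, nModules = 4,
                         nTimepoints = 80)
  spec@scoreModel <- sm
  coh <- generateCohort(spec, seed = 77)
  meta <- cohortMetadata(coh)
  L <- vapply(subjectFCs(coh), function(fc) {
    characteristicPathLength(thresholdBySparsity(fc, 0.16))$L
  }, 0)
  GE <- vapply(subjectFCs(coh), function(fc) {
    globalEfficiency(thresholdBySparsity(fc, 0.16))
  }, 0)
  pcL <- partialCorrelation(L, meta$ADAS13, meta$gender, "L", "ADAS13")
  pcG <- partialCorrelation(GE, meta$MMSE, meta$gender, "GE", "MMSE")
  expect_lt(pcL$r_partial, 0)
  expect_lt(pcL$p_value, 0.05)
  expect_gt(pcG$r_partial, 0)
})
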