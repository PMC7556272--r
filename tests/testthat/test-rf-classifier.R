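# small synthetic tables keep forest fits cheap; a planted predictor is a
# feature equal (or strongly related) to the class label
noiseTable <- function(n = 40, p = 30, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    featureTable(x, rep(c("NC", "MCI"), each = n / 2))
  })
}

smallGrid <- data.frame(numTrees = 100L, maxDepth = c(3L, 0L))

test_that("the feature table has the prescribed 124-column layout", {
  ft <- defaultFeatureTable()
  expect_equal(dim(ft$features), c(60, 124))
  expect_equal(colnames(ft$features)[1:8],
               c("ADAS13", "CDRSB", "MMSE", "FAQ", "C", "L", "GE", "SW"))
  expect_equal(colnames(ft$features)[9], "bc_1")
  expect_identical(ft$level, "subject")
  # columns 5..8 equal the subject's recomputed global metrics
  coh <- defaultCohort()
  net <- thresholdBySparsity(computeFC(subjectTimeseries(coh, 3)), 0.16)
  gm <- globalMetrics(net, nRandom = 10L, seed = 7 + 3)
  expect_equal(unname(ft$features[3, 5:8]),
               c(gm$C, gm$L, gm$GE, gm$SW))
  expect_equal(unname(ft$features[3, 9:124]),
               unname(nodeBetweenness(net)))
})

test_that("feature tables round-trip bit-identically through CSV", {
  ft <- defaultFeatureTable()
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, f)
  back <- readFeatureTable(f, sparsityValue = ft$sparsity)
  expect_identical(back$features, ft$features)
  expect_identical(back$labels, ft$labels)
})

test_that("layer-1 ranking finds a perfect predictor and is seed-stable noise otherwise", {
  ft <- noiseTable(seed = 81)
  x <- ft$features
  x[, 17] <- as.numeric(ft$labels == "MCI") + rnorm(nrow(x), 0, 0.01)
  perfect <- featureTable(x, as.character(ft$labels))
  rk <- rankFeaturesLayer1(perfect, seed = 5)
  expect_equal(rk$feature[1], "f17")
  expect_identical(rankFeaturesLayer1(perfect, seed = 5), rk)
  # pure-noise rankings are unstable: no feature dominates rank 1 across
  # replicate noise draws
  tops <- vapply(1:20, function(s) {
    rankFeaturesLayer1(noiseTable(seed = 820 + s), seed = s,
                       numTrees = 100L)$feature[1]
  }, "")
  expect_lt(max(table(tops)) / 20, 0.5)
  oneClass <- ft
  oneClass$labels <- factor(rep("NC", nrow(x)), levels = c("NC", "MCI"))
  expect_error(rankFeaturesLayer1(oneClass, seed = 1), "both classes")
})

test_that("nested CV is deterministic and internally consistent", {
  ft <- defaultFeatureTable()
  cv1 <- nestedCV(ft, topN = 10, seed = 9, grid = smallGrid)
  cv2 <- nestedCV(ft, topN = 10, seed = 9, grid = smallGrid)
  expect_identical(cv1, cv2)
  expect_true(all(vapply(cv1[c("accuracy", "sensitivity", "specificity",
                               "auc")], function(v) v >= 0 && v <= 1, NA)))
  expect_equal(nrow(cv1$ranking), 124)
  # pooled accuracy equals the fold-size-weighted mean of fold accuracies
  expect_equal(cv1$accuracy,
               sum(cv1$perFold$accuracy * cv1$perFold$n) / sum(cv1$perFold$n))
})

test_that("feature selection never sees outer-test labels", {
  ft <- noiseTable(n = 40, p = 30, seed = 83)
  folds <- rep(1:10, 4)
  cv <- nestedCV(ft, topN = 5, seed = 11, grid = smallGrid, folds = folds)
  swapped <- ft
  flipRow <- which(folds == 2)[1]
  lab <- as.character(swapped$labels)
  lab[flipRow] <- if (lab[flipRow] == "NC") "MCI" else "NC"
  swapped <- featureTable(swapped$features, lab)
  cvSwap <- nestedCV(swapped, topN = 5, seed = 11, grid = smallGrid,
                     folds = folds)
  expect_identical(cv$perFold$features[2], cvSwap$perFold$features[2])
})

test_that("the top-N sweep counts, orders and compares as specified", {
  ft <- noiseTable(n = 30, p = 40, seed = 84)
  sw <- sweepTopN(ft, nValues = 5:30, seed = 12,
                  grid = data.frame(numTrees = 50L, maxDepth = 3L))
  expect_length(sw$reports, 26)
  accs <- vapply(sw$reports, `[[`, 0, "accuracy")
  expect_equal(sw$best$accuracy, max(accs))
  expect_equal(sw$bestN, (5:30)[which.max(accs)])
})

test_that("scores-only classification uses the four score columns unchanged", {
  ft <- defaultFeatureTable()
  so1 <- compareScoresOnly(ft, seed = 13, grid = smallGrid)
  so2 <- compareScoresOnly(ft, seed = 13, grid = smallGrid)
  expect_identical(so1, so2)
  expect_equal(so1$topN, 4)
  expect_true(all(grepl("ADAS13;CDRSB;MMSE;FAQ", so1$perFold$features)))
})

test_that("missing or degenerate inputs fail loudly", {
  ft <- noiseTable(seed = 85)
  x <- ft$features
  x[2, 3] <- NA
  expect_error(featureTable(x, as.character(ft$labels)), "complete")
  expect_error(nestedCV(ft, topN = 100, seed = 1), "topN")
})
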