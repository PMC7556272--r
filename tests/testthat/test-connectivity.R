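test_that("connectivity equals the absolute Pearson correlation", {
  x <- c(1, 2, 3, 4)
  ts <- cbind(a = x, b = 2 * x + 1, c = -x)
  w <- fcValues(computeFC(ts))
  expect_equal(w[1, 2], 1)  # perfect linear dependence
  expect_equal(w[1, 3], 1)  # anti-correlation, absolute value
  # brute-force evaluation of the correlation formula on hand series
  ts2 <- cbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(4, 3, 2, 1))
  w2 <- fcValues(computeFC(ts2))
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(w2[i, j], abs(pearson(ts2[, i], ts2[, j])), tolerance = 1e-12)
  }
  expect_equal(diag(w2), setNames(rep(0, 3), rownames(w2)))
})

test_that("degenerate and invalid series are handled as specified", {
  ts <- cbind(rnorm(10), rep(1, 10), rnorm(10))
  expect_warning(fc <- computeFC(ts), "zero-variance")
  expect_equal(fcValues(fc)[2, ], setNames(rep(0, 3), roiNames(fc)))
  tsNA <- matrix(rnorm(20), 10, 2)
  tsNA[1, 1] <- NA
  expect_error(computeFC(tsNA), "non-finite")
  expect_error(computeFC(matrix(rnorm(4), 2, 2)), "3 timepoints")
})

test_that("connectivity is invariant to affine rescaling of a series", {
  withr::with_seed(3, ts <- matrix(rnorm(60), 15, 4))
  ts2 <- ts
  ts2[, 2] <- -3.7 * ts2[, 2] + 11
  expect_equal(fcValues(computeFC(ts)), fcValues(computeFC(ts2)),
               tolerance = 1e-12)
})

test_that("group mean network averages element-wise and is order-invariant", {
  withr::with_seed(5, fcs <- lapply(1:10, function(i) {
    computeFC(matrix(rnorm(200), 20, 10))
  }))
  expect_equal(fcValues(groupMeanNetwork(fcs[1])), fcValues(fcs[[1]]))
  m2 <- matrix(0, 3, 3); m2[1, 2] <- m2[2, 1] <- 0.2
  m4 <- matrix(0, 3, 3); m4[1, 2] <- m4[2, 1] <- 0.4
  avg <- groupMeanNetwork(list(FCMatrix(m2), FCMatrix(m4)))
  expect_equal(fcValues(avg)[1, 2], 0.3)
  # oracle recomputation
  oracle <- Reduce(`+`, lapply(fcs, fcValues)) / 10
  expect_equal(fcValues(groupMeanNetwork(fcs)), oracle, tolerance = 1e-12)
  expect_equal(fcValues(groupMeanNetwork(rev(fcs))),
               fcValues(groupMeanNetwork(fcs)))
  bad <- computeFC(matrix(rnorm(45), 15, 3))
  expect_error(groupMeanNetwork(c(fcs, list(bad))), "dimensions")
})

test_that("edge counts and the sparsity grid match their definitions", {
  expect_identical(edgeCountForSparsity(116, 0.16), 1067L)
  expect_identical(edgeCountForSparsity(116, 1.0), 6670L)
  expect_identical(edgeCountForSparsity(4, 0.5), 3L)
  g <- sparsityGrid()
  expect_length(g, 46)
  expect_equal(g[1], 0.05)
  expect_equal(g[length(g)], 0.50)
  expect_equal(diff(g), rep(0.01, 45))
})

test_that("thresholding keeps the strongest edges with deterministic ties", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- .9; w[1, 3] <- .7; w[1, 4] <- .2; w[2, 3] <- .5
  w[2, 4] <- .4; w[3, 4] <- .1
  w <- w + t(w)
  net <- thresholdBySparsity(FCMatrix(w), 0.5)
  a <- adjacency(net)
  expect_equal(sort(a[upper.tri(a)][a[upper.tri(a)] > 0]), c(.5, .7, .9))
  # all-equal weights: ties resolved by ascending (i, j) order
  we <- matrix(0.5, 4, 4); diag(we) <- 0
  ne <- thresholdBySparsity(FCMatrix(we), 0.5)
  ae <- adjacency(ne)
  expect_equal(unname(which(ae[1, ] > 0)), c(2L, 3L, 4L))
  expect_equal(sum(ae[2:4, 2:4]), 0)
  expect_error(thresholdBySparsity(FCMatrix(we), 0.01), "zero edges")
})

test_that("retained weights dominate discarded ones and edge sets nest", {
  net20 <- randomNet(20, 1.0, seed = 9)  # dense source
  fc <- FCMatrix(adjacency(net20))
  prev <- NULL
  for (s in sparsityGrid()[seq(1, 46, by = 5)]) {
    nt <- thresholdBySparsity(fc, s)
    a <- adjacency(nt)
    kept <- a[upper.tri(a)] > 0
    wAll <- fcValues(fc)[upper.tri(a)]
    expect_identical(sum(kept), edgeCountForSparsity(20, s))
    expect_gte(min(wAll[kept]), max(wAll[!kept]))
    if (!is.null(prev)) expect_true(all(a[prev] > 0))  # monotone nesting
    prev <- adjacency(nt) > 0
  }
})

test_that("isolated fraction counts zero-degree nodes", {
  expect_equal(isolatedFraction(randomNet(8, 1.0, seed = 2)), 0)
  a <- matrix(0, 4, 4); a[1, 2] <- a[1, 3] <- a[2, 3] <- 0.5
  net <- netFromAdjacency(a)
  expect_equal(isolatedFraction(net), 1 / 4)
  nr <- randomNet(15, 0.1, seed = 4)
  expect_equal(isolatedFraction(nr),
               mean(colSums(adjacency(nr) > 0) == 0))
})

test_that("connectivity matrices round-trip through CSV and MTX", {
  fc <- computeFC(matrix(rnorm(200), 20, 10))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "fc.csv")
  mtx <- file.path(dir, "fc.mtx")
  writeFC(fc, csv)
  writeFC(fc, mtx)
  expect_equal(fcValues(readFC(csv)), fcValues(fc), tolerance = 0)
  expect_equal(unname(fcValues(readFC(mtx, roiNames = roiNames(fc)))),
               unname(fcValues(fc)), tolerance = 1e-12)
})
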