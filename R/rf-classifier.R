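#' Per-subject feature table at one sparsity
#'
#' Assembles the 4 + 4 + N feature columns used for classification, in fixed
#' order: ADAS13, CDRSB, MMSE, FAQ, C, L, GE, SW, then one betweenness
#' column per region (raw per-subject bc on the individual network). With the
#' standard 116-region parcellation this yields 124 features.
#'
#' @param cohort a [Cohort-class]
#' @param sparsityValue network sparsity at which metrics are computed.
#' @param nRandomSW null networks per subject for small-worldness.
#' @param seed integer seed for the SW nulls.
#' @return A `FeatureTable`: list with `features` (numeric matrix, subjects x
#'   features), `labels` (factor, case level last), `sparsity`.
#' @export
buildFeatureTable <- function(cohort, sparsityValue = 0.16, nRandomSW = 100L,
                              seed = 1L) {
  meta <- cohortMetadata(cohort)
  nRoi <- ncol(subjectTimeseries(cohort, 1L))
  featNames <- c("ADAS13", "CDRSB", "MMSE", "FAQ", "C", "L", "GE", "SW",
                 paste0("bc_", seq_len(nRoi)))
  feats <- matrix(NA_real_, nSubjects(cohort), length(featNames),
                  dimnames = list(meta$subject_id, featNames))
  for (i in seq_len(nSubjects(cohort))) {
    net <- thresholdBySparsity(computeFC(subjectTimeseries(cohort, i)),
                               sparsityValue)
    gm <- globalMetrics(net, nRandom = nRandomSW, seed = seed + i)
    row <- c(as.numeric(meta[i, c("ADAS13", "CDRSB", "MMSE", "FAQ")]),
             gm$C, gm$L, gm$GE, gm$SW, as.numeric(nodeBetweenness(net)))
    if (anyNA(row) || any(!is.finite(row)))
      stop("missing metric for subject ", meta$subject_id[i], call. = FALSE)
    feats[i, ] <- row
  }
  featureTable(feats, meta$group, sparsityValue)
}

#' Construct a FeatureTable from a ready matrix
#'
#' @param features numeric matrix, subjects x features, no missing values.
#' @param labels group label per row (both classes present; case level
#'   `"MCI"` placed last when present).
#' @param sparsityValue sparsity the features were computed at.
#' @return A `FeatureTable` list.
#' @export
featureTable <- function(features, labels, sparsityValue = NA_real_) {
  features <- as.matrix(features)
  stopIfNot(!anyNA(features) && all(is.finite(features)),
            "features must be complete and finite")
  lev <- if ("MCI" %in% labels) c(setdiff(unique(labels), "MCI"), "MCI")
         else sort(unique(labels))
  labels <- factor(labels, levels = lev)
  stopIfNot(nlevels(labels) == 2L && all(table(labels) > 0L),
            "both classes must be present")
  structure(list(features = features, labels = labels,
                 sparsity = sparsityValue, level = "subject"),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d subjects x %d features (sparsity %s)\n",
              nrow(x$features), ncol(x$features), format(x$sparsity)))
  print(table(x$labels))
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' Full-precision text round trip: numbers are written with 17 significant
#' digits so a re-read table is bit-identical.
#'
#' @param ft a `FeatureTable`
#' @param file CSV path.
#' @return `writeFeatureTable()` the path invisibly; `readFeatureTable()` a
#'   `FeatureTable`.
#' @export
writeFeatureTable <- function(ft, file) {
  df <- data.frame(subject_id = rownames(ft$features),
                   group = as.character(ft$labels),
                   format(ft$features, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeFeatureTable
#' @param sparsityValue sparsity recorded in the rebuilt table.
#' @export
readFeatureTable <- function(file, sparsityValue = NA_real_) {
  df <- read.table(file, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$subject_id
  featureTable(m, df$group, sparsityValue)
}

#' Layer-1 feature ranking by random-forest importance
#'
#' Fits a seeded random forest on all features and ranks them by decreasing
#' importance. The default importance is permutation-based out-of-bag
#' accuracy loss; impurity-based ranking is available as an alternative.
#'
#' @param ft a `FeatureTable` (optionally row-subset via `rows`).
#' @param seed integer seed.
#' @param method `"permutation"` (OOB, default) or `"impurity"`.
#' @param numTrees forest size (default 500).
#' @param rows optional row indices to fit on (used inside nested CV).
#' @return data.frame: feature, importance, rank (ties broken by column
#'   order).
#' @export
rankFeaturesLayer1 <- function(ft, seed = 1L, method = c("permutation",
                                                         "impurity"),
                               numTrees = 500L, rows = NULL) {
  method <- match.arg(method)
  x <- ft$features
  y <- ft$labels
  if (!is.null(rows)) {
    x <- x[rows, , drop = FALSE]
    y <- droplevels(y[rows])
  }
  stopIfNot(length(unique(as.character(y))) == 2L,
            "layer-1 ranking needs both classes")
  fit <- ranger::ranger(
    x = as.data.frame(x), y = y, num.trees = numTrees,
    importance = if (method == "permutation") "permutation" else "impurity",
    seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = colnames(x)[ord], importance = unname(imp[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Default layer-2 hyperparameter grid
#'
#' Number of trees x maximum tree depth (0 = unbounded), searched by the
#' inner cross-validation loop.
#'
#' @return data.frame grid.
#' @export
defaultRfGrid <- function() {
  expand.grid(numTrees = c(100L, 200L, 500L), maxDepth = c(2L, 3L, 5L, 0L))
}

# stratified k-fold assignment; returns integer fold id per row
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (lev in levels(labels)) {
      ix <- which(labels == lev)
      folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  folds
}

# rank-based AUC of scores for the positive (second-level) class
aucFromScores <- function(scores, labels) {
  pos <- labels == levels(labels)[2L]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

fitRf <- function(x, y, numTrees, maxDepth, seed) {
  ranger::ranger(x = as.data.frame(x), y = y, num.trees = numTrees,
                 max.depth = if (maxDepth > 0L) maxDepth else NULL,
                 probability = TRUE, seed = seed, num.threads = 1L)
}

predictProb <- function(fit, x, posLevel) {
  pr <- predict(fit, data = as.data.frame(x), num.threads = 1L)$predictions
  pr[, posLevel]
}

#' Two-layer random forest under nested cross-validation
#'
#' Outer stratified 10-fold CV estimates performance; within each outer
#' training set, the layer-1 forest ranks the features, the top `topN` are
#' selected, and an inner stratified 5-fold grid search tunes the layer-2
#' forest (number of trees x maximum depth) before refitting on the full
#' outer-training set and predicting the held-out fold. Accuracy,
#' sensitivity and specificity are pooled over outer folds; AUC uses the
#' pooled out-of-fold class probabilities. Feature selection touches only
#' training rows unless `globalRanking = TRUE`, which ranks once on all rows
#' (optimistically biased; provided for comparison).
#'
#' @param ft a `FeatureTable`
#' @param topN number of layer-1 features fed to layer 2 (5..30 in the
#'   standard sweep).
#' @param seed integer seed; the whole report is deterministic given it.
#' @param globalRanking rank features once on the full table instead of per
#'   outer fold.
#' @param nOuter,nInner outer/inner fold counts (default 10 / 5).
#' @param grid hyperparameter grid, see [defaultRfGrid()].
#' @param rankMethod layer-1 importance type, see [rankFeaturesLayer1()].
#' @param skipRanking use all columns as-is (no layer-1 selection).
#' @param folds optional precomputed outer-fold assignment (integer per
#'   row), overriding the seeded stratified split.
#' @return A `CVReport`: list with pooled `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `perFold` bookkeeping (chosen hyperparameters and
#'   selected features per fold), the full-table layer-1 `ranking`, and the
#'   pooled out-of-fold probabilities.
#' @export
nestedCV <- function(ft, topN, seed = 1L, globalRanking = FALSE, nOuter = 10L,
                     nInner = 5L, grid = defaultRfGrid(),
                     rankMethod = "permutation", skipRanking = FALSE,
                     folds = NULL) {
  x <- ft$features
  y <- ft$labels
  n <- nrow(x)
  stopIfNot(n >= 20L, "need at least 20 subjects")
  if (!skipRanking)
    stopIfNot(topN >= 1L && topN <= ncol(x), "topN out of range")
  posLevel <- levels(y)[2L]
  if (is.null(folds)) folds <- stratifiedFolds(y, nOuter, seed)
  if (any(tapply(y, folds, function(v) length(unique(v))) < 2L))
    stop("stratification failure: an outer fold is missing a class",
         call. = FALSE)
  fullRanking <- if (!skipRanking)
    rankFeaturesLayer1(ft, seed = seed, method = rankMethod) else NULL

  oofProb <- rep(NA_real_, n)
  perFold <- vector("list", nOuter)
  for (f in sort(unique(folds))) {
    test <- which(folds == f)
    train <- which(folds != f)
    sel <- if (skipRanking) {
      colnames(x)
    } else if (globalRanking) {
      fullRanking$feature[seq_len(topN)]
    } else {
      rankFeaturesLayer1(ft, seed = seed + 100L * f, method = rankMethod,
                         rows = train)$feature[seq_len(topN)]
    }
    xt <- x[train, sel, drop = FALSE]
    yt <- droplevels(y[train])
    innerFolds <- stratifiedFolds(yt, nInner, seed + 1000L * f)
    gridAcc <- vapply(seq_len(nrow(grid)), function(gIdx) {
      accs <- vapply(sort(unique(innerFolds)), function(iv) {
        itr <- innerFolds != iv
        fit <- fitRf(xt[itr, , drop = FALSE], yt[itr],
                     grid$numTrees[gIdx], grid$maxDepth[gIdx],
                     seed + 7L * gIdx + iv)
        pr <- predictProb(fit, xt[!itr, , drop = FALSE], posLevel)
        mean((pr > 0.5) == (yt[!itr] == posLevel))
      }, 0)
      mean(accs)
    }, 0)
    best <- which.max(gridAcc)  # first max: fewer trees / shallower wins ties
    fit <- fitRf(xt, yt, grid$numTrees[best], grid$maxDepth[best],
                 seed + 13L * f)
    oofProb[test] <- predictProb(fit, x[test, sel, drop = FALSE], posLevel)
    perFold[[f]] <- data.frame(
      fold = f, n = length(test),
      numTrees = grid$numTrees[best], maxDepth = grid$maxDepth[best],
      accuracy = mean((oofProb[test] > 0.5) == (y[test] == posLevel)),
      features = paste(sel, collapse = ";"), stringsAsFactors = FALSE)
  }
  pred <- oofProb > 0.5
  truth <- y == posLevel
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  structure(list(
    sparsity = ft$sparsity, topN = if (skipRanking) ncol(x) else topN,
    accuracy = (tp + tn) / n,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    auc = aucFromScores(oofProb, y),
    perFold = do.call(rbind, perFold),
    ranking = fullRanking, oofProb = oofProb, folds = folds,
    seed = as.integer(seed), globalRanking = globalRanking
  ), class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf(paste0("CVReport (topN = %d, sparsity %s): accuracy %.3f, ",
                     "sensitivity %.3f, specificity %.3f, AUC %.3f\n"),
              x$topN, format(x$sparsity), x$accuracy, x$sensitivity,
              x$specificity, x$auc))
  invisible(x)
}

#' Sweep the number of selected features
#'
#' Runs [nestedCV()] for each candidate `topN` and marks the best report by
#' pooled accuracy (ties go to the smaller N).
#'
#' @param ft a `FeatureTable`
#' @param nValues candidate feature counts (default 5..30).
#' @param seed integer seed shared by all runs.
#' @param ... passed to [nestedCV()].
#' @return list with `reports` (one `CVReport` per N), `bestN`, `best`.
#' @export
sweepTopN <- function(ft, nValues = 5:30, seed = 1L, ...) {
  reports <- lapply(nValues, function(nv) nestedCV(ft, nv, seed = seed, ...))
  accs <- vapply(reports, `[[`, 0, "accuracy")
  bestIx <- which.max(accs)  # first max -> smallest N on ties
  list(reports = reports, nValues = nValues, bestN = nValues[bestIx],
       best = reports[[bestIx]])
}

#' Classification from cognitive scores alone
#'
#' Nested CV restricted to the four cognitive-score columns, with no layer-1
#' selection; the baseline against which network features are judged.
#'
#' @param ft a `FeatureTable` containing the score columns.
#' @param seed integer seed.
#' @param ... passed to [nestedCV()].
#' @return A `CVReport`.
#' @export
compareScoresOnly <- function(ft, seed = 1L, ...) {
  scoreCols <- c("ADAS13", "CDRSB", "MMSE", "FAQ")
  stopIfNot(all(scoreCols %in% colnames(ft$features)),
            "feature table lacks the cognitive-score columns")
  sub <- featureTable(ft$features[, scoreCols, drop = FALSE],
                      as.character(ft$labels), ft$sparsity)
  nestedCV(sub, topN = 4L, seed = seed, skipRanking = TRUE, ...)
}
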