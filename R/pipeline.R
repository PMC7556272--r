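#' Configuration for a full pipeline run
#'
#' One master seed determines every stochastic stage through fixed
#' per-stage offsets (cohort +1, group-level small-world nulls +2,
#' community/permutation +3, subject metrics +4, classifier +5), so an
#' identical configuration reproduces the run exactly.
#'
#' @param spec a [CohortSpec-class] for the synthetic cohort (or `NULL` when
#'   supplying `cohort` to [runFull()]).
#' @param masterSeed master integer seed.
#' @param grid sparsity sweep for group-level analyses.
#' @param featureSparsity the single sparsity at which nodal statistics,
#'   community crosswalks and classification are carried out.
#' @param nRandomSW null networks for group-level small-worldness.
#' @param nRandomSWSubject null networks per subject for the feature table.
#' @param nPerm permutations for the modularity test.
#' @param topNValues candidate feature counts for the classifier sweep.
#' @param rfGrid layer-2 hyperparameter grid.
#' @param globalRanking rank layer-1 features once on all rows (optimistically biased) instead of within each outer fold.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(spec = cohortSpec(), masterSeed = 42L,
                      grid = sparsityGrid(), featureSparsity = 0.16,
                      nRandomSW = 100L, nRandomSWSubject = 25L,
                      nPerm = 200L, topNValues = c(5L, 10L, 15L, 20L, 25L,
                                                   30L),
                      rfGrid = defaultRfGrid(), globalRanking = FALSE) {
  structure(list(spec = spec, masterSeed = as.integer(masterSeed),
                 grid = grid, featureSparsity = featureSparsity,
                 nRandomSW = as.integer(nRandomSW),
                 nRandomSWSubject = as.integer(nRandomSWSubject),
                 nPerm = as.integer(nPerm), topNValues = as.integer(topNValues),
                 rfGrid = rfGrid, globalRanking = globalRanking),
            class = "RunConfig")
}

# per-subject FC matrices split by group
subjectFCByGroup <- function(cohort) {
  meta <- cohortMetadata(cohort)
  fcs <- lapply(seq_len(nSubjects(cohort)),
                function(i) computeFC(subjectTimeseries(cohort, i)))
  split(fcs, meta$group)
}

#' Run the full three-scale analysis
#'
#' Executes every stage on a synthetic cohort (or a supplied one): cohort
#' generation, individual and group-level connectivity, the global-metric
#' sweep with small-world nulls, hub stability tables, modularity sweep with
#' a permutation test and a module crosswalk at the feature sparsity,
#' gender-adjusted group statistics and partial correlations, and the
#' two-layer random-forest classification with a top-N sweep plus the
#' scores-only baseline.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param cohort optional pre-built [Cohort-class]; by default one is
#'   generated from `config$spec`.
#' @param verbose print stage progress.
#' @return A `RunReport` list; every reported number is computed from the
#'   per-stage outputs it contains.
#' @export
runFull <- function(config = runConfig(), cohort = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ms <- config$masterSeed
  t0 <- Sys.time()

  say("stage 1/6: cohort")
  if (is.null(cohort)) cohort <- generateCohort(config$spec, seed = ms + 1L)
  meta <- cohortMetadata(cohort)
  groups <- sort(unique(meta$group))

  say("stage 2/6: connectivity")
  fcByGroup <- subjectFCByGroup(cohort)
  groupFC <- lapply(fcByGroup, groupMeanNetwork)

  say("stage 3/6: global metric sweep")
  sweep <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(config$grid, function(s) {
      net <- thresholdBySparsity(groupFC[[g]], s)
      gm <- globalMetrics(net, nRandom = config$nRandomSW,
                          seed = ms + 2L + round(1000 * s))
      data.frame(group = g, sparsity = s, C = gm$C, L = gm$L, GE = gm$GE,
                 SW = gm$SW, isolated = isolatedFraction(net),
                 unreachablePairFraction = gm$unreachablePairFraction,
                 stringsAsFactors = FALSE)
    }))
  }))

  say("stage 4/6: hubs and modules")
  hubTables <- lapply(groupFC, hubStability, grid = config$grid)
  moduleSweep <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(config$grid, function(s) {
      net <- thresholdBySparsity(groupFC[[g]], s)
      part <- detectModules(net, seed = ms + 3L, nRestarts = 10L)
      data.frame(group = g, sparsity = s, Q = part$Q,
                 nModules = part$nModules, stringsAsFactors = FALSE)
    }))
  }))
  netsAtFeature <- lapply(groupFC, thresholdBySparsity,
                          sparsity = config$featureSparsity)
  partitions <- lapply(netsAtFeature, detectModules, seed = ms + 3L)
  permTest <- lapply(netsAtFeature, permutationTestQ, nPerm = config$nPerm,
                     seed = ms + 3L)
  crosswalk <- moduleCrosswalk(partitions[[1L]], partitions[[2L]])

  say("stage 5/6: group statistics")
  demo <- demographicsTable(meta)
  ftab <- buildFeatureTable(cohort, config$featureSparsity,
                            nRandomSW = config$nRandomSWSubject,
                            seed = ms + 4L)
  globalNames <- c("C", "L", "GE", "SW")
  logit <- do.call(rbind, lapply(colnames(ftab$features)[-(1:4)],
    function(nm) {
      logisticGroupTest(ftab$features[, nm], meta$group, meta$gender,
                        metricName = nm,
                        sparsityValue = config$featureSparsity,
                        nComparisons = ncol(ftab$features) - 8L)
    }))
  pcorr <- do.call(rbind, lapply(globalNames, function(nm) {
    do.call(rbind, lapply(c("ADAS13", "CDRSB", "MMSE", "FAQ"), function(sc) {
      partialCorrelation(ftab$features[, nm], meta[[sc]], meta$gender,
                         metricName = nm, scoreName = sc,
                         sparsityValue = config$featureSparsity)
    }))
  }))

  say("stage 6/6: classification")
  sweepCls <- sweepTopN(ftab, nValues = config$topNValues,
                        seed = ms + 5L, grid = config$rfGrid,
                        globalRanking = config$globalRanking)
  scoresOnly <- compareScoresOnly(ftab, seed = ms + 5L, grid = config$rfGrid)

  structure(list(
    config = config, cohort = cohort, groupFC = groupFC,
    globalSweep = sweep, hubTables = hubTables, moduleSweep = moduleSweep,
    partitions = partitions, permTest = permTest, crosswalk = crosswalk,
    demographics = demo, featureTable = ftab, logistic = logit,
    partialCorr = pcorr, classifierSweep = sweepCls,
    scoresOnly = scoresOnly,
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport\n")
  cat(sprintf("  cohort: %d subjects\n", nSubjects(x$cohort)))
  cat(sprintf("  sweep: %d sparsities x %d groups\n",
              length(unique(x$globalSweep$sparsity)),
              length(unique(x$globalSweep$group))))
  for (g in names(x$permTest))
    cat(sprintf("  %s: Q = %.3f (perm p = %.3g), %d modules\n", g,
                x$permTest[[g]]$QObserved, x$permTest[[g]]$pValue,
                x$partitions[[g]]$nModules))
  cat(sprintf("  best classifier: topN = %d, accuracy %.3f (scores-only %.3f)\n",
              x$classifierSweep$bestN, x$classifierSweep$best$accuracy,
              x$scoresOnly$accuracy))
  invisible(x)
}

#' Plot metric-versus-sparsity curves from a run report
#'
#' @param report a `RunReport`
#' @param metric one of `"C"`, `"L"`, `"GE"`, `"SW"`.
#' @return invisibly, the plotted data.
#' @export
plotMetricSweep <- function(report, metric = c("C", "L", "GE", "SW")) {
  metric <- match.arg(metric)
  sw <- report$globalSweep
  groups <- unique(sw$group)
  cols <- c("black", "red3")
  plot(NULL, xlim = range(sw$sparsity), ylim = range(sw[[metric]]),
       xlab = "sparsity", ylab = metric,
       main = sprintf("%s across sparsities", metric))
  for (k in seq_along(groups)) {
    d <- sw[sw$group == groups[k], ]
    graphics::lines(d$sparsity, d[[metric]], col = cols[k], lwd = 2)
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   lwd = 2, bty = "n")
  invisible(sw[, c("group", "sparsity", metric)])
}
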