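#' Default clinical-score generative model
#'
#' One entry per score with fields `intercept` (control-group mean), `sd`
#' (residual noise SD), `caseShift` (additive mean shift in the case group),
#' `coef` and `property` (optional linear link to a subject-level network
#' property, one of `"group"`, `"C"`, `"L"`, `"GE"`; with `property = "group"`
#' the `coef` term is ignored and only `caseShift` carries signal).
#'
#' Defaults use clinically plausible group means/SDs for ADAS13, CDRSB, MMSE
#' and FAQ, with the case group impaired (higher ADAS13/CDRSB/FAQ, lower
#' MMSE).
#'
#' @return named list of per-score model parameters.
#' @export
defaultScoreModel <- function() {
  list(
    ADAS13 = list(intercept = 11.62, sd = 5.30, caseShift = 3.30,
                  coef = 0, property = "group"),
    CDRSB  = list(intercept = 0.13,  sd = 0.60, caseShift = 1.25,
                  coef = 0, property = "group"),
    MMSE   = list(intercept = 28.88, sd = 1.46, caseShift = -0.99,
                  coef = 0, property = "group"),
    FAQ    = list(intercept = 0.40,  sd = 1.93, caseShift = 2.75,
                  coef = 0, property = "group")
  )
}

#' Default case-group effect
#'
#' Additive deltas applied to the case (MCI) group's generative parameters:
#' a slightly raised between-module correlation (shorter paths / higher
#' efficiency), weakened hub boosts, and a split of planted module 1 into two
#' modules (community reorganisation).
#'
#' @return named list with `rhoIn`, `rhoOut`, `hubBoost`, `splitModule`.
#' @export
defaultGroupEffect <- function() {
  list(rhoIn = 0, rhoOut = 0.08, hubBoost = -0.1, splitModule = 1L)
}

#' Construct a CohortSpec
#'
#' @param nPerGroup subjects per group (default 30).
#' @param nRois number of regions (default 116).
#' @param nTimepoints time-series length (default 135).
#' @param nModules number of equal-size planted modules used when
#'   `partitionTruth` is not supplied (default 4).
#' @param partitionTruth integer module label per region (contiguous 1..M).
#' @param rhoIn,rhoOut within-/between-module correlations.
#' @param hubRois indices of planted hub regions.
#' @param hubBoost added cross-module correlation for hub rows/columns.
#' @param groupEffect case-group deltas, see [defaultGroupEffect()].
#' @param scoreModel clinical-score model, see [defaultScoreModel()].
#' @param genderProb named probability of male per group.
#' @param arCoef lag-1 autocorrelation of the series (default 0, white noise).
#' @param seed default seed for [generateCohort()].
#' @return A validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nPerGroup = 5, nRois = 20, nModules = 4)
#' @export
cohortSpec <- function(nPerGroup = 30L, nRois = 116L, nTimepoints = 135L,
                       nModules = 4L, partitionTruth = NULL,
                       rhoIn = 0.4, rhoOut = 0.1,
                       hubRois = NULL, hubBoost = 0.3,
                       groupEffect = defaultGroupEffect(),
                       scoreModel = defaultScoreModel(),
                       genderProb = c(NC = 46 / 82, MCI = 36 / 93),
                       arCoef = 0, seed = 1L) {
  nRois <- as.integer(nRois)
  if (is.null(partitionTruth)) {
    partitionTruth <- sort(rep_len(seq_len(nModules), nRois))
  }
  if (is.null(hubRois)) {
    # default: one hub near the centre of each planted block
    centres <- tapply(seq_len(nRois), partitionTruth, function(ix) {
      ix[ceiling(length(ix) / 2)]
    })
    hubRois <- sort(as.integer(centres))
  }
  ge <- utils::modifyList(defaultGroupEffect(), groupEffect)
  new("CohortSpec", nPerGroup = as.integer(nPerGroup), nRois = nRois,
      nTimepoints = as.integer(nTimepoints),
      partitionTruth = as.integer(partitionTruth),
      rhoIn = rhoIn, rhoOut = rhoOut, hubRois = as.integer(hubRois),
      hubBoost = hubBoost, groupEffect = ge, scoreModel = scoreModel,
      genderProb = genderProb, arCoef = arCoef, seed = as.integer(seed))
}

#' A CohortSpec with all group effects removed
#'
#' Convenience constructor for calibration studies: both groups share the
#' same covariance and score distributions, so any downstream group test
#' operates under its null.
#'
#' @param ... passed to [cohortSpec()].
#' @return A [CohortSpec-class] whose groups are exchangeable.
#' @export
nullCohortSpec <- function(...) {
  sm <- defaultScoreModel()
  for (nm in names(sm)) sm[[nm]]$caseShift <- 0
  cohortSpec(...,
             groupEffect = list(rhoIn = 0, rhoOut = 0, hubBoost = 0,
                                splitModule = NA_integer_),
             scoreModel = sm)
}

# partition actually used for a group's covariance (case group may split one
# planted module into two: second half of the module becomes label M+1)
groupPartition <- function(spec, group) {
  p <- spec@partitionTruth
  sm <- spec@groupEffect$splitModule
  if (group == "MCI" && !is.na(sm)) {
    ix <- which(p == sm)
    if (length(ix) >= 2L) {
      half <- ix[seq.int(ceiling(length(ix) / 2) + 1L, length(ix))]
      p[half] <- max(p) + 1L
    }
  }
  p
}

# effective scalar parameters for a group
groupParams <- function(spec, group) {
  ge <- spec@groupEffect
  case <- group == "MCI"
  list(
    rhoIn = spec@rhoIn + if (case) ge$rhoIn else 0,
    rhoOut = spec@rhoOut + if (case) ge$rhoOut else 0,
    hubBoost = max(0, spec@hubBoost + if (case) ge$hubBoost else 0)
  )
}

#' Ground-truth correlation matrix for one group
#'
#' Builds the planted block-correlation matrix: `rhoIn` within modules,
#' `rhoOut` between modules, plus `hubBoost` added to the cross-module
#' rows/columns of hub regions (clipped below 1). The case group's additive
#' deltas (and module split) are applied first. If hub boosts break positive
#' semi-definiteness, the matrix is repaired by clipping negative eigenvalues
#' at zero and rescaling to unit diagonal.
#'
#' @param spec a [CohortSpec-class]
#' @param group `"NC"` (control) or `"MCI"` (case)
#' @return N x N correlation matrix with unit diagonal.
#' @examples
#' s <- cohortSpec(nRois = 4, nModules = 2, rhoIn = 0.5, rhoOut = 0,
#'                 hubRois = integer(0), hubBoost = 0)
#' buildCovariance(s, "NC")
#' @export
buildCovariance <- function(spec, group = c("NC", "MCI")) {
  group <- match.arg(group)
  validObject(spec)
  n <- spec@nRois
  p <- groupPartition(spec, group)
  pars <- groupParams(spec, group)
  same <- outer(p, p, "==")
  sigma <- matrix(pars$rhoOut, n, n)
  sigma[same] <- pars$rhoIn
  if (length(spec@hubRois) && pars$hubBoost > 0) {
    for (h in spec@hubRois) {
      cross <- !same[h, ]
      sigma[h, cross] <- pmin(sigma[h, cross] + pars$hubBoost, 0.99)
      sigma[cross, h] <- sigma[h, cross]
    }
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    lam <- pmax(ev$values, 0)
    sigma <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(sigma))
    sigma <- sigma / outer(d, d)
    diag(sigma) <- 1
    sigma <- (sigma + t(sigma)) / 2
    lamMin <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (lamMin < -1e-8)
      stop(sprintf("covariance not PSD after repair (min eigenvalue %.3e)",
                   lamMin), call. = FALSE)
  }
  dimnames(sigma) <- list(defaultRoiNames(n), defaultRoiNames(n))
  sigma
}

# symmetric square root of a PSD matrix (works when the repaired matrix is
# singular, where a Cholesky factor would not exist)
covarianceRoot <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  ev$vectors %*% (sqrt(lam) * t(ev$vectors))
}

# draw one T x N series with stationary correlation sigma (via its symmetric
# root) and optional AR(1) temporal structure
drawTimeseries <- function(nT, sigmaRoot, arCoef) {
  n <- ncol(sigmaRoot)
  z <- matrix(rnorm(nT * n), nT, n) %*% sigmaRoot
  if (arCoef != 0) {
    sc <- sqrt(1 - arCoef^2)
    for (t in seq.int(2L, nT)) {
      z[t, ] <- arCoef * z[t - 1L, ] + sc * z[t, ]
    }
  }
  z
}

# subject-level network property used by the score model
subjectProperty <- function(ts, property, refSparsity = 0.16) {
  if (property == "group") return(0)
  fc <- computeFC(ts)
  net <- thresholdBySparsity(fc, refSparsity)
  switch(property,
    C  = clusteringCoefficient(net),
    L  = characteristicPathLength(net)$L,
    GE = globalEfficiency(net),
    stop("unknown score-model property: ", property)
  )
}

#' Generate a synthetic two-group cohort
#'
#' Draws `2 * nPerGroup` subjects. Each subject's time series is sampled
#' i.i.d. over time (or AR(1) if `arCoef != 0`) from a zero-mean Gaussian
#' with the group's planted correlation matrix ([buildCovariance()]); gender
#' is Bernoulli with the per-group male probability; each cognitive score is
#' `intercept + coef * property + caseShift * I(case) + noise`. The same seed
#' reproduces the cohort bit-for-bit.
#'
#' @param spec a [CohortSpec-class]
#' @param seed integer seed (defaults to the spec's seed).
#' @return A [Cohort-class]; its [groundTruth()] records per-group module
#'   partitions, per-group hub sets and the feature-table column indices that
#'   carry group signal by construction.
#' @examples
#' coh <- generateCohort(cohortSpec(nPerGroup = 3, nRois = 12, nModules = 3,
#'                                  nTimepoints = 40))
#' nSubjects(coh)
#' @export
generateCohort <- function(spec, seed = spec@seed) {
  validObject(spec)
  stopIfNot(spec@nTimepoints >= 3L,
            "nTimepoints must be >= 3 (correlation undefined otherwise)")
  groups <- c("NC", "MCI")
  roots <- lapply(groups, function(g) covarianceRoot(buildCovariance(spec, g)))
  names(roots) <- groups
  scoreNames <- c("ADAS13", "CDRSB", "MMSE", "FAQ")
  needsProperty <- any(vapply(spec@scoreModel[scoreNames], function(m) {
    m$property != "group" && m$coef != 0
  }, logical(1)))

  subjects <- withSeed(seed, {
    out <- vector("list", 2L * spec@nPerGroup)
    k <- 0L
    for (g in groups) {
      for (i in seq_len(spec@nPerGroup)) {
        k <- k + 1L
        ts <- drawTimeseries(spec@nTimepoints, roots[[g]], spec@arCoef)
        colnames(ts) <- defaultRoiNames(spec@nRois)
        gender <- if (rbinom(1L, 1L, spec@genderProb[[g]]) == 1L) "M" else "F"
        scores <- setNames(numeric(4), scoreNames)
        for (nm in scoreNames) {
          m <- spec@scoreModel[[nm]]
          prop <- if (needsProperty && m$property != "group" && m$coef != 0)
            subjectProperty(ts, m$property) else 0
          scores[[nm]] <- m$intercept + m$coef * prop +
            m$caseShift * (g == "MCI") + rnorm(1L, 0, m$sd)
        }
        out[[k]] <- list(id = sprintf("S%03d", k), group = g, gender = gender,
                         scores = as.list(scores), timeseries = ts)
      }
    }
    out
  })

  meta <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "id"),
    group = vapply(subjects, `[[`, "", "group"),
    gender = vapply(subjects, `[[`, "", "gender"),
    stringsAsFactors = FALSE
  )
  for (nm in scoreNames)
    meta[[nm]] <- vapply(subjects, function(s) s$scores[[nm]], 0)

  gt <- makeGroundTruth(spec)
  new("Cohort", subjects = subjects, metadata = meta, groundTruth = gt,
      spec = spec)
}

# which feature-table columns carry group signal by construction
makeGroundTruth <- function(spec) {
  ge <- spec@groupEffect
  scoreNames <- c("ADAS13", "CDRSB", "MMSE", "FAQ")
  scoreInf <- which(vapply(spec@scoreModel[scoreNames],
                           function(m) m$caseShift != 0, logical(1)))
  topoChanged <- ge$rhoIn != 0 || ge$rhoOut != 0 ||
    (!is.na(ge$splitModule)) || ge$hubBoost != 0
  globalInf <- if (topoChanged) 5:8 else integer(0)  # C, L, GE, SW
  bcInf <- if (ge$hubBoost != 0) 8L + spec@hubRois else integer(0)
  hubs <- list(NC = spec@hubRois,
               MCI = if (groupParams(spec, "MCI")$hubBoost > 0)
                 spec@hubRois else integer(0))
  list(
    partition = list(NC = groupPartition(spec, "NC"),
                     MCI = groupPartition(spec, "MCI")),
    hubs = hubs,
    informativeFeatures = sort(unique(c(scoreInf, globalInf, bcInf)))
  )
}

#' Write / read a cohort as plain-text files
#'
#' `writeCohort()` writes one tab-separated T x N time-series file per subject
#' (header = ROI names), a `metadata.tsv` table and a `ground_truth.json`
#' (which also embeds the generating parameters). `readCohort()` reverses it.
#'
#' @param cohort a [Cohort-class]
#' @param dir output directory (created if needed).
#' @return `writeCohort()` the directory path, invisibly; `readCohort()` a
#'   [Cohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort@subjects) {
    write.table(format(s$timeseries, digits = 17, trim = TRUE, scientific = TRUE),
                file.path(dir, paste0(s$id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(cohort@metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- cohort@spec
  payload <- list(
    groundTruth = cohort@groundTruth,
    spec = list(nPerGroup = spec@nPerGroup, nRois = spec@nRois,
                nTimepoints = spec@nTimepoints,
                partitionTruth = spec@partitionTruth, rhoIn = spec@rhoIn,
                rhoOut = spec@rhoOut, hubRois = spec@hubRois,
                hubBoost = spec@hubBoost, groupEffect = spec@groupEffect,
                scoreModel = spec@scoreModel,
                genderProb = as.list(spec@genderProb),
                arCoef = spec@arCoef, seed = spec@seed)
  )
  jsonlite::write_json(payload, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  payload <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                 simplifyVector = TRUE)
  sp <- payload$spec
  ge <- as.list(sp$groupEffect)
  if (is.null(ge$splitModule) || length(ge$splitModule) == 0L)
    ge$splitModule <- NA_integer_
  spec <- cohortSpec(nPerGroup = sp$nPerGroup, nRois = sp$nRois,
                     nTimepoints = sp$nTimepoints,
                     partitionTruth = sp$partitionTruth,
                     rhoIn = sp$rhoIn, rhoOut = sp$rhoOut,
                     hubRois = sp$hubRois, hubBoost = sp$hubBoost,
                     groupEffect = ge,
                     scoreModel = lapply(sp$scoreModel, as.list),
                     genderProb = unlist(sp$genderProb),
                     arCoef = sp$arCoef, seed = sp$seed)
  meta <- read.table(file.path(dir, "metadata.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(meta)), function(i) {
    ts <- as.matrix(read.table(file.path(dir, paste0(meta$subject_id[i], ".tsv")),
                               sep = "\t", header = TRUE, check.names = FALSE))
    list(id = meta$subject_id[i], group = meta$group[i],
         gender = meta$gender[i],
         scores = as.list(meta[i, c("ADAS13", "CDRSB", "MMSE", "FAQ")]),
         timeseries = ts)
  })
  gt <- payload$groundTruth
  gt$partition <- lapply(gt$partition, as.integer)
  gt$hubs <- lapply(gt$hubs, as.integer)
  gt$informativeFeatures <- as.integer(gt$informativeFeatures)
  new("Cohort", subjects = subjects, metadata = meta, groundTruth = gt,
      spec = spec)
}
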