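#' Functional connectivity matrix
#'
#' An N x N symmetric matrix of absolute Pearson correlations between
#' regional time series, with a zero diagonal (self-connections excluded).
#' This is the weighted adjacency of the fully connected functional network
#' before sparsity thresholding.
#'
#' @slot values numeric N x N matrix; symmetric, zero diagonal, entries in
#'   \[0, 1\].
#' @slot roiNames character vector of N region labels.
#' @export
setClass("FCMatrix",
  slots = c(values = "matrix", roiNames = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v) || nrow(v) != ncol(v))
      return("values must be a square numeric matrix")
    if (length(object@roiNames) != nrow(v))
      return("roiNames length must match matrix dimension")
    if (any(!is.finite(v))) return("values must be finite")
    if (max(abs(v - t(v))) > 1e-10) return("values must be symmetric")
    if (any(diag(v) != 0)) return("diagonal must be exactly 0")
    if (min(v) < 0 || max(v) > 1) return("entries must lie in [0, 1]")
    TRUE
  }
)

#' Construct an FCMatrix
#'
#' @param values symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @param roiNames optional region labels; defaults to the matrix dimnames or
#'   generated labels.
#' @return An [FCMatrix-class] object.
#' @export
FCMatrix <- function(values, roiNames = NULL) {
  if (is.null(roiNames)) {
    roiNames <- colnames(values)
    if (is.null(roiNames)) roiNames <- defaultRoiNames(ncol(values))
  }
  values <- (values + t(values)) / 2  # remove numeric asymmetry
  diag(values) <- 0
  dimnames(values) <- list(roiNames, roiNames)
  new("FCMatrix", values = values, roiNames = roiNames)
}

#' @describeIn FCMatrix-class number of regions
#' @param x,object an `FCMatrix`
#' @export
setMethod("dim", "FCMatrix", function(x) dim(x@values))

#' Accessors for connectivity objects
#'
#' `fcValues()` returns the raw matrix, `roiNames()` the region labels,
#' `adjacency()` the (thresholded) weighted adjacency matrix and
#' `sparsity()` the retained edge fraction.
#'
#' @param object an [FCMatrix-class] or [ThresholdedNetwork-class]
#' @name connectivity-accessors
NULL

#' @rdname connectivity-accessors
#' @export
setGeneric("fcValues", function(object) standardGeneric("fcValues"))
#' @rdname connectivity-accessors
#' @export
setMethod("fcValues", "FCMatrix", function(object) object@values)

#' @rdname connectivity-accessors
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))
#' @rdname connectivity-accessors
#' @export
setMethod("roiNames", "FCMatrix", function(object) object@roiNames)

setMethod("show", "FCMatrix", function(object) {
  cat("FCMatrix with", nrow(object@values), "ROIs\n")
  w <- object@values[upper.tri(object@values)]
  cat(sprintf("  |r| range [%.3f, %.3f], mean %.3f\n",
              min(w), max(w), mean(w)))
})

#' Sparsity-thresholded weighted network
#'
#' A weighted undirected network obtained from an [FCMatrix-class] by keeping
#' the strongest K edges, where K corresponds to the requested sparsity
#' (fraction of all possible edges). Retained edges keep their connectivity
#' weight; discarded entries are zero.
#'
#' @slot adjacency numeric N x N symmetric matrix, zero diagonal.
#' @slot sparsity numeric in (0, 1\]; the requested edge fraction.
#' @slot retainedEdges integer; number of retained (upper-triangle) edges.
#' @slot roiNames character region labels.
#' @export
setClass("ThresholdedNetwork",
  slots = c(adjacency = "matrix", sparsity = "numeric",
            retainedEdges = "integer", roiNames = "character"),
  validity = function(object) {
    a <- object@adjacency
    if (nrow(a) != ncol(a)) return("adjacency must be square")
    if (any(!is.finite(a)) || min(a) < 0) return("weights must be finite, >= 0")
    if (max(abs(a - t(a))) > 1e-10) return("adjacency must be symmetric")
    if (any(diag(a) != 0)) return("diagonal must be 0")
    k <- sum(a[upper.tri(a)] > 0)
    if (k != object@retainedEdges)
      return("retainedEdges does not match nonzero upper-triangle count")
    if (object@sparsity <= 0 || object@sparsity > 1)
      return("sparsity must lie in (0, 1]")
    TRUE
  }
)

#' @rdname connectivity-accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname connectivity-accessors
#' @export
setMethod("adjacency", "ThresholdedNetwork", function(object) object@adjacency)

#' @rdname connectivity-accessors
#' @export
setGeneric("sparsity", function(object) standardGeneric("sparsity"))
#' @rdname connectivity-accessors
#' @export
setMethod("sparsity", "ThresholdedNetwork", function(object) object@sparsity)

#' @rdname connectivity-accessors
#' @export
setMethod("roiNames", "ThresholdedNetwork", function(object) object@roiNames)

#' @describeIn ThresholdedNetwork-class number of nodes
#' @param x,object a `ThresholdedNetwork`
#' @export
setMethod("dim", "ThresholdedNetwork", function(x) dim(x@adjacency))

setMethod("show", "ThresholdedNetwork", function(object) {
  cat(sprintf("ThresholdedNetwork: %d nodes, %d edges (sparsity %.2f)\n",
              nrow(object@adjacency), object@retainedEdges, object@sparsity))
})

#' Simulation parameters for a synthetic two-group cohort
#'
#' Defines the ground-truth network structure (planted correlation modules,
#' hub regions, group-dependent topology differences) and the clinical-score
#' model used by [generateCohort()]. Regional time series are drawn from a
#' zero-mean multivariate Gaussian whose correlation matrix has `rhoIn` within
#' planted modules, `rhoOut` between modules, and an additional `hubBoost` on
#' the cross-module rows/columns of hub regions. The case group receives the
#' additive `groupEffect` deltas (and, optionally, a split of one planted
#' module into two, emulating a reorganised community structure).
#'
#' @slot nPerGroup integer subjects per group.
#' @slot nRois integer number of regions.
#' @slot nTimepoints integer time-series length.
#' @slot partitionTruth integer module label (contiguous 1..M) per region.
#' @slot rhoIn within-module correlation in \[0, 1).
#' @slot rhoOut between-module correlation in \[0, rhoIn).
#' @slot hubRois integer indices of planted hub regions.
#' @slot hubBoost added cross-module correlation on hub rows/columns.
#' @slot groupEffect named list of additive deltas for the case group:
#'   `rhoIn`, `rhoOut`, `hubBoost` (numbers) and `splitModule` (module id to
#'   split in two for the case group, or `NA`).
#' @slot scoreModel per-score generative model (see [defaultScoreModel()]).
#' @slot genderProb named numeric, probability of male per group.
#' @slot arCoef lag-1 autocorrelation of the time series (0 = white noise).
#' @slot seed default integer seed for [generateCohort()].
#' @export
setClass("CohortSpec",
  slots = c(nPerGroup = "integer", nRois = "integer", nTimepoints = "integer",
            partitionTruth = "integer", rhoIn = "numeric", rhoOut = "numeric",
            hubRois = "integer", hubBoost = "numeric", groupEffect = "list",
            scoreModel = "list", genderProb = "numeric", arCoef = "numeric",
            seed = "integer"),
  validity = function(object) {
    p <- object@partitionTruth
    if (length(p) != object@nRois) return("partitionTruth length != nRois")
    if (!identical(sort(unique(p)), seq_len(max(p))))
      return("partitionTruth labels must be contiguous 1..M")
    if (object@rhoIn < 0 || object@rhoIn >= 1) return("rhoIn must be in [0,1)")
    if (object@rhoOut < 0 || object@rhoOut > object@rhoIn)
      return("rhoOut must be in [0, rhoIn]")
    if (object@hubBoost < 0 || object@hubBoost >= 1 - object@rhoOut)
      return("hubBoost must be in [0, 1 - rhoOut)")
    if (length(object@hubRois) &&
        (min(object@hubRois) < 1 || max(object@hubRois) > object@nRois))
      return("hubRois out of range")
    if (any(object@genderProb < 0 | object@genderProb > 1))
      return("genderProb must be probabilities")
    if (!all(c("NC", "MCI") %in% names(object@genderProb)))
      return("genderProb must be named for both groups")
    scores <- c("ADAS13", "CDRSB", "MMSE", "FAQ")
    if (!all(scores %in% names(object@scoreModel)))
      return("scoreModel must cover ADAS13, CDRSB, MMSE, FAQ")
    if (abs(object@arCoef) >= 1) return("arCoef must be in (-1, 1)")
    TRUE
  }
)

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0(
    "CohortSpec: %d+%d subjects, %d ROIs x %d timepoints\n",
    "  %d planted modules, rhoIn=%.2f, rhoOut=%.2f, %d hubs (boost %.2f)\n"),
    object@nPerGroup, object@nPerGroup, object@nRois, object@nTimepoints,
    max(object@partitionTruth), object@rhoIn, object@rhoOut,
    length(object@hubRois), object@hubBoost))
})

#' Synthetic cohort container
#'
#' Holds the generated subjects (one regional time-series matrix each), the
#' per-subject metadata table (group, gender, four cognitive scores) and the
#' generative ground truth used by parameter-recovery tests.
#'
#' @slot subjects list of per-subject records (id, group, gender, scores,
#'   timeseries).
#' @slot metadata data.frame with one row per subject.
#' @slot groundTruth list: per-group module partitions, per-group hub sets and
#'   `informativeFeatures`, the indices (in the 124-column feature-table
#'   order) that carry group signal by construction.
#' @slot spec the [CohortSpec-class] used.
#' @export
setClass("Cohort",
  slots = c(subjects = "list", metadata = "data.frame",
            groundTruth = "list", spec = "CohortSpec"),
  validity = function(object) {
    if (length(object@subjects) != nrow(object@metadata))
      return("metadata rows must match number of subjects")
    for (s in object@subjects) {
      ts <- s$timeseries
      if (!all(is.finite(ts))) return("time series must be finite")
      if (!all(is.finite(unlist(s$scores))) || length(s$scores) != 4L)
        return("all four scores must be present and finite")
    }
    TRUE
  }
)

#' @describeIn Cohort-class number of subjects
#' @param object a `Cohort`
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))
#' @rdname Cohort-class
#' @export
setMethod("nSubjects", "Cohort", function(object) length(object@subjects))

#' @describeIn Cohort-class subject metadata table
#' @export
setGeneric("cohortMetadata", function(object) standardGeneric("cohortMetadata"))
#' @rdname Cohort-class
#' @export
setMethod("cohortMetadata", "Cohort", function(object) object@metadata)

#' @describeIn Cohort-class generative ground truth
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname Cohort-class
#' @export
setMethod("groundTruth", "Cohort", function(object) object@groundTruth)

#' Extract one subject's time-series matrix
#'
#' @param object a [Cohort-class]
#' @param i subject index or id
#' @return T x N numeric matrix.
#' @export
setGeneric("subjectTimeseries",
           function(object, i) standardGeneric("subjectTimeseries"))
#' @rdname subjectTimeseries
#' @export
setMethod("subjectTimeseries", "Cohort", function(object, i) {
  if (is.character(i)) i <- match(i, object@metadata$subject_id)
  object@subjects[[i]]$timeseries
})

setMethod("show", "Cohort", function(object) {
  tab <- table(object@metadata$group)
  cat(sprintf("Cohort: %d subjects (%s)\n", nSubjects(object),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d ROIs x %d timepoints per subject\n",
              ncol(object@subjects[[1]]$timeseries),
              nrow(object@subjects[[1]]$timeseries)))
})
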