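#' Absolute-correlation functional connectivity
#'
#' Computes the N x N matrix of absolute Pearson correlations between the
#' columns of a T x N time-series matrix; the diagonal (self-connection) is
#' set to zero. A zero-variance column yields zero connectivity for that
#' region with a warning (degenerate, not fatal); missing values are an
#' error.
#'
#' @param timeseries T x N numeric matrix (T >= 3), columns = regions.
#' @param roiNames optional region labels (default: column names).
#' @return An [FCMatrix-class].
#' @examples
#' ts <- matrix(rnorm(40), 10, 4)
#' computeFC(ts)
#' @export
computeFC <- function(timeseries, roiNames = NULL) {
  timeseries <- as.matrix(timeseries)
  stopIfNot(nrow(timeseries) >= 3L, "need at least 3 timepoints")
  if (any(!is.finite(timeseries))) stop("time series contain non-finite values")
  sds <- apply(timeseries, 2L, sd)
  degenerate <- sds == 0
  r <- suppressWarnings(abs(cor(timeseries)))
  if (any(degenerate)) {
    warning(sprintf("%d zero-variance ROI(s); their connectivity set to 0",
                    sum(degenerate)))
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  r <- pmin(r, 1)  # guard against rounding just above 1
  diag(r) <- 0
  FCMatrix(r, roiNames = roiNames %||% colnames(timeseries))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-level mean connectivity
#'
#' Element-wise arithmetic mean of individual connectivity matrices; the
#' group-level network summarises the connectivity backbone of a group.
#'
#' @param fcs nonempty list of [FCMatrix-class] objects with identical
#'   dimensions and region labels.
#' @return An [FCMatrix-class].
#' @export
groupMeanNetwork <- function(fcs) {
  stopIfNot(length(fcs) >= 1L, "need at least one FCMatrix")
  ref <- fcs[[1L]]
  for (fc in fcs) {
    stopIfNot(is(fc, "FCMatrix"), "all elements must be FCMatrix objects")
    stopIfNot(identical(dim(fc), dim(ref)) &&
                identical(roiNames(fc), roiNames(ref)),
              "all FCMatrix objects must share dimensions and ROI names")
  }
  m <- Reduce(`+`, lapply(fcs, fcValues)) / length(fcs)
  FCMatrix(m, roiNames = roiNames(ref))
}

#' Edge count at a given sparsity
#'
#' K = round(s * n(n-1)/2) with half-to-even rounding, i.e. the number of
#' retained edges when a fraction `sparsity` of all possible edges is kept.
#'
#' @param nRois number of nodes.
#' @param sparsity fraction in (0, 1\].
#' @return integer edge count.
#' @examples
#' edgeCountForSparsity(116, 0.16)  # 1067
#' @export
edgeCountForSparsity <- function(nRois, sparsity) {
  stopIfNot(sparsity > 0 && sparsity <= 1, "sparsity must lie in (0, 1]")
  as.integer(round(sparsity * nRois * (nRois - 1) / 2))
}

#' The standard sparsity grid
#'
#' Sparsities from 5\% to 50\% in steps of 1\% (46 values), the range over
#' which all metric sweeps are evaluated.
#'
#' @return numeric vector of length 46.
#' @export
sparsityGrid <- function() seq.int(5L, 50L) / 100

#' Threshold a connectivity matrix at a target sparsity
#'
#' Keeps exactly K strongest upper-triangle weights (K from
#' [edgeCountForSparsity()]) with their original connectivity values; all
#' other entries become zero. Ties at the cutoff are broken deterministically
#' by ascending (i, j) lexicographic order.
#'
#' @param fc an [FCMatrix-class]
#' @param sparsity fraction in (0, 1\].
#' @return A [ThresholdedNetwork-class].
#' @export
thresholdBySparsity <- function(fc, sparsity) {
  stopIfNot(is(fc, "FCMatrix"), "fc must be an FCMatrix")
  n <- nrow(fc@values)
  k <- edgeCountForSparsity(n, sparsity)
  stopIfNot(k >= 1L, "sparsity yields zero edges")
  pairs <- upperPairs(n)
  w <- fc@values[pairs]
  ord <- order(-w, pairs[, 1L], pairs[, 2L])
  keep <- ord[seq_len(k)]
  adj <- matrix(0, n, n, dimnames = dimnames(fc@values))
  adj[pairs[keep, , drop = FALSE]] <- w[keep]
  adj <- adj + t(adj)
  new("ThresholdedNetwork", adjacency = adj, sparsity = sparsity,
      retainedEdges = as.integer(sum(adj[upper.tri(adj)] > 0)),
      roiNames = fc@roiNames)
}

#' Fraction of isolated nodes
#'
#' Proportion of nodes with zero degree in a thresholded network; at low
#' sparsities some regions lose all their connections.
#'
#' @param net a [ThresholdedNetwork-class]
#' @return fraction in \[0, 1\].
#' @export
isolatedFraction <- function(net) {
  stopIfNot(is(net, "ThresholdedNetwork"), "net must be a ThresholdedNetwork")
  mean(rowSums(net@adjacency > 0) == 0)
}

#' Write / read connectivity matrices
#'
#' CSV stores the dense matrix with ROI names as header; MTX writes the
#' upper-triangle nonzero entries in Matrix Market coordinate format.
#'
#' @param x an [FCMatrix-class] or [ThresholdedNetwork-class]
#' @param file output path; format chosen by extension (`.csv` or `.mtx`).
#' @return `writeFC()` the path invisibly; `readFC()` an [FCMatrix-class].
#' @export
writeFC <- function(x, file) {
  m <- if (is(x, "FCMatrix")) fcValues(x) else adjacency(x)
  if (grepl("\\.mtx$", file)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), file)
  } else {
    write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                file, sep = ",", quote = FALSE,
                row.names = FALSE, col.names = colnames(m))
  }
  invisible(file)
}

#' @rdname writeFC
#' @param roiNames optional labels when reading from MTX (which stores none).
#' @export
readFC <- function(file, roiNames = NULL) {
  if (grepl("\\.mtx$", file)) {
    m <- as.matrix(Matrix::readMM(file))
    m <- pmax(m, t(m))
  } else {
    m <- as.matrix(read.table(file, sep = ",", header = TRUE,
                              check.names = FALSE))
  }
  FCMatrix(m, roiNames = roiNames)
}
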