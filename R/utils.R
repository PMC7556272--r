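#' @importFrom methods new validObject is slot
#' @importFrom stats cor rnorm rbinom pt lm resid sd glm binomial coef
#'   dhyper t.test wilcox.test setNames predict
#' @importFrom utils write.table read.table head
#' @useDynLib TriScaleNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# run expr under a temporary seed, restoring RNG state afterwards
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

defaultRoiNames <- function(n) sprintf("ROI%03d", seq_len(n))

# upper-triangle index pairs (i < j) of an n x n matrix, column-major order
upperPairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
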