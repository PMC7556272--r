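#' Weighted betweenness centrality
#'
#' Shortest-path betweenness on 1/w edge lengths (Brandes accumulation;
#' equal-length paths counted with fractional multiplicity; endpoints
#' excluded; each unordered pair counted once).
#'
#' @param net a [ThresholdedNetwork-class]
#' @return named numeric vector of raw betweenness values (one per region).
#' @export
nodeBetweenness <- function(net) {
  g <- asIgraph(net)
  wts <- igraph::E(g)$weight
  bc <- igraph::betweenness(g, directed = FALSE,
                            weights = if (length(wts)) 1 / wts else NULL)
  setNames(as.numeric(bc), net@roiNames)
}

#' Mean-normalised betweenness
#'
#' BC_i = bc_i / mean(bc); by construction mean(BC) = 1, so hub criteria are
#' comparable across sparsities and networks.
#'
#' @param bc nonnegative betweenness vector with positive mean.
#' @return normalised vector.
#' @export
normalizeBC <- function(bc) {
  m <- mean(bc)
  stopIfNot(m > 0, "all betweenness values are zero (no paths)")
  bc / m
}

#' Identify hub regions
#'
#' Hubs are regions whose normalised betweenness exceeds the threshold
#' (strictly greater). The default 2.5 is a strict criterion; 1.5 and 2 are
#' common laxer alternatives.
#'
#' @param BC normalised betweenness vector.
#' @param threshold hub cutoff (default 2.5).
#' @return integer indices of hub regions (named if `BC` is named).
#' @export
identifyHubs <- function(BC, threshold = 2.5) {
  which(BC > threshold)
}

#' Hub identification across the sparsity sweep
#'
#' For each sparsity: threshold, compute betweenness, normalise, flag hubs.
#' The resulting region x sparsity table supports "stable hub" summaries
#' (e.g. hub at two-thirds or more of the sparsities).
#'
#' @param fc an [FCMatrix-class] (typically a group-level network).
#' @param grid sparsity values (default [sparsityGrid()]).
#' @param threshold hub cutoff (default 2.5).
#' @return logical matrix, regions x sparsities; columns named by sparsity.
#' @export
hubStability <- function(fc, grid = sparsityGrid(), threshold = 2.5) {
  n <- nrow(fcValues(fc))
  out <- matrix(FALSE, n, length(grid),
                dimnames = list(roiNames(fc), sprintf("%.2f", grid)))
  for (k in seq_along(grid)) {
    net <- thresholdBySparsity(fc, grid[k])
    bc <- nodeBetweenness(net)
    if (mean(bc) > 0) {
      out[identifyHubs(normalizeBC(bc), threshold), k] <- TRUE
    }
  }
  # hub tables are a group-level analysis; per-subject bc (which feeds the
  # group statistics and the classifier) never passes through here
  attr(out, "level") <- "group"
  out
}
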