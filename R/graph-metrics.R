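# igraph view of a thresholded network (keeps isolated vertices)
asIgraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Edge-length matrix of a weighted network
#'
#' Maps connectivity weights to lengths for shortest-path computations:
#' length(i, j) = 1 / w(i, j) for retained edges, +Inf otherwise. Stronger
#' functional coupling means a shorter topological distance.
#'
#' @param net a [ThresholdedNetwork-class] with weights in (0, 1\].
#' @return N x N numeric matrix (Inf for absent edges, 0 diagonal).
#' @export
edgeLengths <- function(net) {
  a <- net@adjacency
  len <- matrix(Inf, nrow(a), ncol(a), dimnames = dimnames(a))
  nz <- a > 0
  len[nz] <- 1 / a[nz]
  diag(len) <- 0
  len
}

#' Mean weighted clustering coefficient
#'
#' Onnela's weighted clustering per node,
#' C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3) with
#' weights normalised by the network maximum (w' = w / max w), so C lies in
#' \[0, 1\]. Nodes of degree < 2 contribute 0; C is the mean over all nodes.
#'
#' @param net a [ThresholdedNetwork-class]
#' @return mean clustering coefficient.
#' @export
clusteringCoefficient <- function(net) {
  w <- net@adjacency
  mx <- max(w)
  stopIfNot(mx > 0, "empty network")
  a <- (w / mx)^(1 / 3)
  num <- diag(a %*% a %*% a)
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

# all-pairs shortest-path distances on 1/w edge lengths
shortestDistances <- function(net) {
  g <- asIgraph(net)
  wts <- igraph::E(g)$weight
  igraph::distances(g, weights = 1 / wts, algorithm = "dijkstra")
}

#' Characteristic path length
#'
#' Mean shortest-path distance (on 1/w edge lengths) over all ordered
#' reachable node pairs i != j. Because thresholded networks can contain
#' isolated regions at low sparsity, the fraction of unreachable pairs is
#' reported alongside rather than propagating infinite distances.
#'
#' @param net a [ThresholdedNetwork-class]
#' @return list with `L` and `unreachablePairFraction`.
#' @export
characteristicPathLength <- function(net) {
  d <- shortestDistances(net)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  stopIfNot(any(reach), "no reachable node pairs")
  list(L = mean(off[reach]), unreachablePairFraction = mean(!reach))
}

#' Global efficiency
#'
#' GE = mean over ordered node pairs of 1/d(i, j), with 1/Inf = 0 for
#' unreachable pairs; robust to disconnected nodes.
#'
#' @param net a [ThresholdedNetwork-class]
#' @return global efficiency in \[0, 1\] for weights in \[0, 1\].
#' @export
globalEfficiency <- function(net) {
  d <- shortestDistances(net)
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Degree-preserving rewiring null model
#'
#' Maslov-Sneppen double-edge swaps: repeatedly pick two edges (a,b), (c,d)
#' and replace them with (a,d), (c,b) when this creates neither self-loops
#' nor multi-edges. Each node's degree is preserved exactly and edge weights
#' travel with their swapped edge, so the weight multiset is preserved too.
#'
#' @param net a [ThresholdedNetwork-class] with >= 2 edges.
#' @param seed integer seed.
#' @param swapsPerEdge attempted swaps per edge (default 10).
#' @return A rewired [ThresholdedNetwork-class]. If no swap succeeded (e.g. a
#'   triangle admits none) the input topology is returned with a warning.
#' @export
rewirePreservingDegree <- function(net, seed = 1L, swapsPerEdge = 10) {
  n <- nrow(net@adjacency)
  pairs <- upperPairs(n)
  w <- net@adjacency[pairs]
  keep <- w > 0
  ei <- pairs[keep, 1L]
  ej <- pairs[keep, 2L]
  wk <- w[keep]
  stopIfNot(length(wk) >= 2L, "need at least 2 edges to rewire")
  attempts <- as.integer(round(swapsPerEdge * length(wk)))
  res <- withSeed(seed, .rewireEdgesCpp(ei, ej, wk, n, attempts))
  if (res$nSwaps == 0L && attempts > 0L)
    warning("no valid edge swap found; returning the input topology")
  adj <- matrix(0, n, n, dimnames = dimnames(net@adjacency))
  adj[cbind(res$i, res$j)] <- res$w
  adj <- adj + t(adj)
  new("ThresholdedNetwork", adjacency = adj, sparsity = net@sparsity,
      retainedEdges = net@retainedEdges, roiNames = net@roiNames)
}

#' Small-worldness
#'
#' SW = (C / <C_rand>) / (L / <L_rand>), where the reference values average
#' the clustering coefficient and characteristic path length of `nRandom`
#' degree-preserving rewired null networks (seeds `seed + 1 .. seed +
#' nRandom`). SW > 1 indicates small-world organisation: more clustered than
#' a random network of the same degree sequence at comparable path length.
#'
#' @param net a [ThresholdedNetwork-class]
#' @param nRandom number of null networks (1000 in the full analysis).
#' @param seed integer seed.
#' @param swapsPerEdge attempted swaps per edge for each null.
#' @return SW value; attribute `nDropped` counts nulls with undefined L.
#' @export
smallWorldness <- function(net, nRandom = 1000L, seed = 1L,
                           swapsPerEdge = 10) {
  cObs <- clusteringCoefficient(net)
  lObs <- characteristicPathLength(net)$L
  cNull <- lNull <- rep(NA_real_, nRandom)
  for (r in seq_len(nRandom)) {
    null <- suppressWarnings(
      rewirePreservingDegree(net, seed = seed + r,
                             swapsPerEdge = swapsPerEdge))
    cNull[r] <- clusteringCoefficient(null)
    lNull[r] <- tryCatch(characteristicPathLength(null)$L,
                         error = function(e) NA_real_)
  }
  ok <- is.finite(lNull) & is.finite(cNull)
  stopIfNot(any(ok), "all null networks had undefined path length")
  sw <- (cObs / mean(cNull[ok])) / (lObs / mean(lNull[ok]))
  attr(sw, "nDropped") <- sum(!ok)
  sw
}

#' All scale-I global metrics of a network
#'
#' @param net a [ThresholdedNetwork-class]
#' @param nRandom null networks for small-worldness (default 100; set to
#'   1000 for the full analysis, or 0 to skip SW).
#' @param seed integer seed for the nulls.
#' @return list with `C`, `L`, `GE`, `SW`, `unreachablePairFraction`,
#'   `nRandom`.
#' @export
globalMetrics <- function(net, nRandom = 100L, seed = 1L) {
  cpl <- characteristicPathLength(net)
  list(
    C = clusteringCoefficient(net),
    L = cpl$L,
    GE = globalEfficiency(net),
    SW = if (nRandom > 0) as.numeric(smallWorldness(net, nRandom, seed))
         else NA_real_,
    unreachablePairFraction = cpl$unreachablePairFraction,
    nRandom = as.integer(nRandom)
  )
}
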