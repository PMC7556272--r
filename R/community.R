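#' Weighted Newman modularity of a partition
#'
#' Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) * delta(c_i, c_j) with node
#' strengths s and total edge weight m (resolution 1).
#'
#' @param net a [ThresholdedNetwork-class]
#' @param assignment integer module label per node.
#' @return modularity Q in \[-1, 1\].
#' @export
modularityQ <- function(net, assignment) {
  stopIfNot(length(assignment) == nrow(net@adjacency),
            "assignment must label every node")
  m <- sum(net@adjacency) / 2
  stopIfNot(m > 0, "network has zero total weight")
  g <- asIgraph(net)
  igraph::modularity(g, membership = as.integer(assignment),
                     weights = igraph::E(g)$weight)
}

# renumber modules so label 1 contains the lowest node index, label 2 the
# next-lowest node not yet covered, etc.
canonicalLabels <- function(assignment) {
  firstSeen <- unique(assignment)
  match(assignment, firstSeen)
}

#' Community detection by multi-restart Louvain
#'
#' Seeded greedy modularity maximisation (Louvain, resolution 1) repeated
#' `nRestarts` times; the best-Q partition is returned with canonical labels
#' (module 1 contains the lowest region index).
#'
#' @param net a [ThresholdedNetwork-class] with at least one edge.
#' @param seed integer seed.
#' @param nRestarts number of seeded restarts (default 20).
#' @return A `ModularPartition`: list with `assignment`, `Q`, `nModules`,
#'   `sparsity`, `seed`.
#' @export
detectModules <- function(net, seed = 1L, nRestarts = 20L) {
  stopIfNot(net@retainedEdges >= 1L, "network has no edges")
  g <- asIgraph(net)
  wts <- igraph::E(g)$weight
  best <- NULL
  for (r in seq_len(nRestarts)) {
    memb <- withSeed(seed + r - 1L, {
      igraph::membership(igraph::cluster_louvain(g, weights = wts))
    })
    q <- modularityQ(net, as.integer(memb))
    if (is.null(best) || q > best$Q) {
      best <- list(assignment = as.integer(memb), Q = q)
    }
  }
  assignment <- canonicalLabels(best$assignment)
  structure(
    list(assignment = setNames(assignment, net@roiNames), Q = best$Q,
         nModules = max(assignment), sparsity = net@sparsity,
         seed = as.integer(seed)),
    class = "ModularPartition"
  )
}

#' @export
print.ModularPartition <- function(x, ...) {
  cat(sprintf("ModularPartition: %d modules, Q = %.4f (sparsity %.2f)\n",
              x$nModules, x$Q, x$sparsity))
  print(table(module = x$assignment))
  invisible(x)
}

#' Permutation test of modular structure
#'
#' Tests whether the observed modularity exceeds what matched random
#' networks achieve. Each null randomises the network (degree-preserving
#' rewiring by default, or weight shuffling on the fixed topology), re-runs
#' community detection with the same settings as the observed network, and
#' records the best Q. p = (1 + #\{Q_null >= Q_obs\}) / (1 + nPerm).
#'
#' @param net a [ThresholdedNetwork-class]
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param nRestarts Louvain restarts used for the observed network and every
#'   null alike (default 5; equal treatment keeps the null p uniform).
#' @param nullModel `"rewire"` (default) or `"shuffle"` (permute edge
#'   weights on the fixed topology).
#' @return A `PermutationResult`: list with `QObserved`, `QNull`, `pValue`,
#'   `nPerm`.
#' @export
permutationTestQ <- function(net, nPerm = 1000L, seed = 1L, nRestarts = 5L,
                             nullModel = c("rewire", "shuffle")) {
  nullModel <- match.arg(nullModel)
  if (nPerm < 19L) warning("nPerm < 19: attainable p floor exceeds 0.05")
  qObs <- detectModules(net, seed = seed, nRestarts = nRestarts)$Q
  qNull <- numeric(nPerm)
  for (k in seq_len(nPerm)) {
    null <- if (nullModel == "rewire") {
      suppressWarnings(rewirePreservingDegree(net, seed = seed + k))
    } else {
      shuffleWeights(net, seed = seed + k)
    }
    qNull[k] <- detectModules(null, seed = seed + k,
                              nRestarts = nRestarts)$Q
  }
  p <- (1 + sum(qNull >= qObs)) / (1 + nPerm)
  structure(list(QObserved = qObs, QNull = qNull, pValue = p,
                 nPerm = as.integer(nPerm)),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("Permutation test: Q = %.4f vs %d nulls (mean %.4f), p = %.4g\n",
              x$QObserved, x$nPerm, mean(x$QNull), x$pValue))
  invisible(x)
}

# permute edge weights over the fixed retained topology
shuffleWeights <- function(net, seed = 1L) {
  n <- nrow(net@adjacency)
  pairs <- upperPairs(n)
  w <- net@adjacency[pairs]
  nz <- which(w > 0)
  wNew <- w
  wNew[nz] <- withSeed(seed, sample(w[nz]))
  adj <- matrix(0, n, n, dimnames = dimnames(net@adjacency))
  adj[pairs] <- wNew
  adj <- adj + t(adj)
  new("ThresholdedNetwork", adjacency = adj, sparsity = net@sparsity,
      retainedEdges = net@retainedEdges, roiNames = net@roiNames)
}

#' Cross-tabulate two module partitions
#'
#' Contingency table of region counts between a reference partition and an
#' alternate one (e.g. control vs case group), plus a per-flow listing of
#' which reference-module regions land in which alternate module.
#'
#' @param pRef,pAlt `ModularPartition` objects (or bare label vectors) over
#'   the same region set.
#' @return list with `table` (reference x alternate counts) and `flows`
#'   (data.frame: refModule, altModule, n, rois).
#' @export
moduleCrosswalk <- function(pRef, pAlt) {
  aRef <- if (inherits(pRef, "ModularPartition")) pRef$assignment else pRef
  aAlt <- if (inherits(pAlt, "ModularPartition")) pAlt$assignment else pAlt
  stopIfNot(length(aRef) == length(aAlt),
            "partitions must cover the same region set")
  rois <- names(aRef) %||% defaultRoiNames(length(aRef))
  tab <- table(reference = aRef, alternate = aAlt)
  flows <- do.call(rbind, lapply(sort(unique(aRef)), function(rm) {
    do.call(rbind, lapply(sort(unique(aAlt[aRef == rm])), function(am) {
      ix <- which(aRef == rm & aAlt == am)
      data.frame(refModule = rm, altModule = am, n = length(ix),
                 rois = paste(rois[ix], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(table = tab, flows = flows)
}
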