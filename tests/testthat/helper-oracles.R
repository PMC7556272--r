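# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's (and igraph's) code paths:
# exhaustive triple loops, Floyd-Warshall, simple-path enumeration and the
# direct modularity double sum.

# random weighted undirected network on n nodes at roughly the given density
randomNet <- function(n, density = 0.4, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2)
    w <- w + t(w)
  })
  fc <- FCMatrix(w)
  thresholdBySparsity(fc, density)
}

lengthsOf <- function(adj) {
  len <- ifelse(adj > 0, 1 / adj, Inf)
  diag(len) <- 0
  len
}

# exhaustive Onnela clustering: triple loop over ordered (j, h) neighbours
oracleClustering <- function(adj) {
  n <- nrow(adj)
  wh <- adj / max(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(adj[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h &&
          adj[i, j] > 0 && adj[i, h] > 0 && adj[j, h] > 0) {
        acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    ci[i] <- acc / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths by Floyd-Warshall on 1/w lengths
oracleDistances <- function(adj) {
  d <- lengthsOf(adj)
  n <- nrow(adj)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oraclePathLength <- function(adj) {
  d <- oracleDistances(adj)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracleEfficiency <- function(adj) {
  d <- oracleDistances(adj)
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

# betweenness by exhaustive simple-path enumeration (feasible for n <= 8)
oracleBetweenness <- function(adj) {
  n <- nrow(adj)
  len <- lengthsOf(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
    best <- Inf
    paths <- list()
    rec <- function(v, visited, d) {
      if (d > best + 1e-9) return()
      if (v == t) {
        if (d < best - 1e-9) {
          best <<- d
          paths <<- list(visited)
        } else if (abs(d - best) <= 1e-9) {
          paths[[length(paths) + 1L]] <<- visited
        }
        return()
      }
      for (u in which(adj[v, ] > 0)) {
        if (!(u %in% visited)) rec(u, c(visited, u), d + len[v, u])
      }
    }
    rec(s, s, 0)
    if (length(paths)) {
      inner <- unlist(lapply(paths, function(p) setdiff(p, c(s, t))))
      if (length(inner)) {
        tab <- table(inner)
        ix <- as.integer(names(tab))
        bc[ix] <- bc[ix] + as.numeric(tab) / length(paths)
      }
    }
  }
  bc
}

# weighted Newman modularity by the direct double sum
oracleModularity <- function(adj, assign) {
  m2 <- sum(adj)  # 2m
  s <- unname(rowSums(adj))
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (assign[i] == assign[j]) q <- q + adj[i, j] - s[i] * s[j] / m2
  }
  q / m2
}

# network built directly from an adjacency matrix (bypasses thresholding)
netFromAdjacency <- function(adj, sparsityValue = 0.5) {
  adj <- pmax(adj, t(adj))
  diag(adj) <- 0
  new("ThresholdedNetwork", adjacency = adj, sparsity = sparsityValue,
      retainedEdges = as.integer(sum(adj[upper.tri(adj)] > 0)),
      roiNames = sprintf("ROI%03d", seq_len(nrow(adj))))
}

# unit-weight graphs used across tests
triangleNet <- function() {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[1, 3] <- a[2, 3] <- 1
  netFromAdjacency(a)
}

pathNet3 <- function() {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 3] <- 1
  netFromAdjacency(a)
}

starNet <- function(n = 5) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- 1
  netFromAdjacency(a)
}

twoCliquesNet <- function() {
  a <- matrix(0, 6, 6)
  for (i in 1:2) for (j in (i + 1):3) a[i, j] <- 1
  for (i in 4:5) for (j in (i + 1):6) a[i, j] <- 1
  netFromAdjacency(a)
}
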