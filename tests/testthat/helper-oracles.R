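# Independent brute-force oracles for graph measures.
#
# Matrix-power oracle: on an unweighted graph, walks of minimal length are
# exactly the geodesics, so d(i,j) is the smallest p with (A^p)[i,j] > 0
# and the geodesic count is that entry of A^p. Through-node counts follow
# by splitting a geodesic at the interior node. Everything here is plain
# integer matrix arithmetic, independent of igraph and of the package's
# BFS code.

oracle_geodesics <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  np <- matrix(0, n, n)
  diag(d) <- 0
  P <- diag(n)
  for (p in seq_len(n - 1)) {
    P <- P %*% A
    new <- is.infinite(d) & P > 0
    d[new] <- p
    np[new] <- P[new]
  }
  diag(np) <- 0
  list(d = d, n_paths = np)
}

oracle_betweenness <- function(A) {
  g <- oracle_geodesics(A)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    # geodesics j-k through i split at i: n(j,i) * n(i,k) of them when
    # d(j,i) + d(i,k) = d(j,k)
    through <- outer(g$n_paths[, i], g$n_paths[i, ]) *
      (outer(g$d[, i], g$d[i, ], `+`) == g$d)
    frac <- through / pmax(g$n_paths, 1)
    frac[i, ] <- 0
    frac[, i] <- 0
    sum(frac[upper.tri(frac)])
  }, numeric(1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) {
      return(0)
    }
    sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_L <- function(A) {
  d <- oracle_geodesics(A)$d
  dv <- d[upper.tri(d)]
  mean(dv[is.finite(dv)])
}

# Literal DFS enumeration of every simple path between two nodes; the
# geodesics are the paths of minimal length. Exponential — tiny graphs only.
dfs_paths <- function(A, from, to) {
  n <- nrow(A)
  paths <- list()
  walk <- function(v, visited) {
    if (v == to) {
      paths[[length(paths) + 1]] <<- visited
      return()
    }
    for (w in which(A[v, ] == 1)) {
      if (!(w %in% visited)) walk(w, c(visited, w))
    }
  }
  walk(from, from)
  paths
}

dfs_geodesics <- function(A, from, to) {
  paths <- dfs_paths(A, from, to)
  if (length(paths) == 0) {
    return(list(d = Inf, n = 0))
  }
  lens <- vapply(paths, length, integer(1)) - 1L
  list(d = min(lens), n = sum(lens == min(lens)))
}

# adjacency matrix from an edge-presence bitmask over the upper triangle
graph_from_mask <- function(n, mask) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(intToBits(mask))[seq_len(n * (n - 1) / 2)]
  A + t(A)
}

random_adjacency <- function(n, k) {
  A <- matrix(0L, n, n)
  pairs <- which(upper.tri(A))
  A[sample(pairs, k)] <- 1L
  A + t(A)
}

# quick path to an fc_network from a bare adjacency matrix
as_net <- function(A) {
  dimnames(A) <- list(paste0("n", seq_len(nrow(A))), paste0("n", seq_len(nrow(A))))
  eegnets::build_threshold(ifelse(A == 1, 0.9, -0.9), 0)
}
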