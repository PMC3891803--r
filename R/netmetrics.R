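as_igraph <- function(net) {
  adj_igraph(net$adjacency)
}

adj_igraph <- function(A) {
  ut <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  igraph::make_graph(t(ut), n = nrow(A), directed = FALSE)
}

# every measure from one igraph build; the workhorse behind node_metrics,
# global_metrics and pipeline_metrics
network_measures <- function(A) {
  g <- adj_igraph(A)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[!is.finite(cl)] <- 0
  d <- igraph::distances(g)
  dv <- d[upper.tri(d)]
  fin <- is.finite(dv)
  btw <- as.numeric(igraph::betweenness(g, directed = FALSE))
  list(
    degree = as.numeric(igraph::degree(g)),
    clustering = cl,
    betweenness = btw,
    L = if (any(fin)) mean(dv[fin]) else NA_real_,
    connected_pair_fraction = mean(fin)
  )
}

#' Geodesic structure of a network
#'
#' Breadth-first computation of the pairwise geodesic distances (minimum
#' link counts; `Inf` for disconnected pairs) and of the number of
#' distinct geodesics between every pair.
#'
#' @param net An `fc_network`.
#' @return List with `d` (N x N distance matrix) and `n_paths` (N x N
#'   geodesic-count matrix; 0 on the diagonal and for disconnected pairs).
#' @export
geodesics <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  d <- matrix(Inf, n, n, dimnames = dimnames(A))
  np <- matrix(0, n, n, dimnames = dimnames(A))
  nbrs <- apply(A == 1, 1, which, simplify = FALSE)
  for (s in seq_len(n)) {
    dist_s <- rep(Inf, n)
    sigma <- rep(0, n)
    dist_s[s] <- 0
    sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nbrs[[v]]) {
          if (is.infinite(dist_s[w])) {
            dist_s[w] <- dist_s[v] + 1
            nxt <- c(nxt, w)
            sigma[w] <- sigma[v]
          } else if (dist_s[w] == dist_s[v] + 1) {
            sigma[w] <- sigma[w] + sigma[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist_s
    np[s, ] <- sigma
  }
  np[is.infinite(d)] <- 0
  diag(np) <- 0
  list(d = d, n_paths = np)
}

#' Geodesics between j and k passing through an interior node i
#'
#' Counts the shortest paths between every pair that have `i` strictly in
#' their interior: a geodesic j-k passes through i exactly when
#' `d(j,i) + d(i,k) = d(j,k)`, in `n(j,i) * n(i,k)` ways.
#'
#' @param net An `fc_network`.
#' @param i Node index or label.
#' @return N x N matrix of through-`i` geodesic counts (rows j, cols k).
#' @export
geodesics_through <- function(net, i) {
  g <- geodesics(net)
  i <- node_index(net, i)
  through <- outer(g$n_paths[, i], g$n_paths[i, ]) *
    (outer(g$d[, i], g$d[i, ], `+`) == g$d)
  through[i, ] <- 0
  through[, i] <- 0
  diag(through) <- 0
  through
}

node_index <- function(net, i) {
  if (is.character(i)) {
    idx <- match(i, rownames(net$adjacency))
    if (is.na(idx)) abort(sprintf("Unknown electrode label '%s'.", i))
    idx
  } else {
    as.integer(i)
  }
}

#' Per-node graph measures
#'
#' Degree `k_i` (link count), clustering coefficient `C_i` (realized
#' fraction of the `k_i (k_i - 1) / 2` possible links among the
#' neighbors; 0 by convention when `k_i < 2`) and betweenness `B_i` (sum
#' over unordered node pairs of the fraction of their geodesics with `i`
#' in the interior; unnormalized).
#'
#' @param net An `fc_network`.
#' @return A tibble with columns `node`, `degree`, `clustering`,
#'   `betweenness` plus the network's metadata columns.
#' @export
node_metrics <- function(net) {
  m <- network_measures(net$adjacency)
  tibble::tibble(
    trial = net$trial_id, condition = net$condition,
    window_start_ms = net$window_start_ms, K = net$K,
    node = rownames(net$adjacency) %||% as.character(seq_len(nrow(net$adjacency))),
    degree = m$degree,
    clustering = m$clustering,
    betweenness = m$betweenness
  )
}

#' Average path length over connected pairs
#'
#' Mean geodesic length over the unordered node pairs at finite distance.
#' Sparse networks on 20 nodes can be disconnected, so the fraction of
#' connected pairs is always reported alongside; an edgeless network has
#' no connected pair and raises an error.
#'
#' @param net An `fc_network`.
#' @return List with `L` and `connected_pair_fraction`.
#' @export
avg_path_length <- function(net) {
  d <- igraph::distances(as_igraph(net))
  dv <- d[upper.tri(d)]
  fin <- is.finite(dv)
  if (!any(fin)) abort("Average path length undefined: no connected pair.")
  list(
    L = mean(dv[fin]),
    connected_pair_fraction = mean(fin)
  )
}

#' Clustering coefficient of one node
#' @param net An `fc_network`.
#' @param i Node index or label.
#' @return `C_i` in `[0, 1]`.
#' @export
clustering <- function(net, i) {
  node_metrics(net)$clustering[node_index(net, i)]
}

#' Betweenness of one node
#' @param net An `fc_network`.
#' @param i Node index or label.
#' @return `B_i >= 0` (unordered-pair, unnormalized convention).
#' @export
betweenness <- function(net, i) {
  node_metrics(net)$betweenness[node_index(net, i)]
}

#' Whole-network summary measures
#'
#' @param net An `fc_network`.
#' @return One-row tibble: metadata, `L`, `C_avg`, `B_avg`,
#'   `connected_pair_fraction`.
#' @export
global_metrics <- function(net) {
  m <- network_measures(net$adjacency)
  if (is.na(m$L)) abort("Average path length undefined: no connected pair.")
  tibble::tibble(
    trial = net$trial_id, condition = net$condition,
    window_start_ms = net$window_start_ms, K = net$K,
    L = m$L, C_avg = mean(m$clustering), B_avg = mean(m$betweenness),
    connected_pair_fraction = m$connected_pair_fraction
  )
}

#' Long metric table for a collection of networks
#'
#' @param nets List of `fc_network`.
#' @return Tibble with one row per (network, node): trial,
#'   window_start_ms, condition, K, node, degree, clustering, betweenness.
#' @export
metric_table <- function(nets) {
  purrr::map_dfr(nets, node_metrics)
}

#' Global metric table for a collection of networks
#' @param nets List of `fc_network`.
#' @return Tibble with one row per network.
#' @export
global_metric_table <- function(nets) {
  purrr::map_dfr(nets, global_metrics)
}

#' Erdos-Renyi baseline for the global measures
#'
#' Samples G(N, K) graphs — uniform over graphs with exactly `K` links —
#' and summarizes the distribution of average path length, clustering and
#' betweenness, the reference against which functional networks are
#' judged (e.g. for small-worldness).
#'
#' @param N Nodes (default 20).
#' @param K Links; may be a vector (one baseline per density).
#' @param reps Replicates per density.
#' @param seed Optional RNG seed.
#' @return List with `replicates` (tibble: K, rep, L, C_avg, B_avg,
#'   connected_pair_fraction) and `summary` (mean and sd per K).
#' @export
er_baseline <- function(N = 20, K = 50, reps = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(K > N * (N - 1) / 2)) abort("K exceeds the number of node pairs.")
  replicates <- purrr::map_dfr(K, function(k) {
    purrr::map_dfr(seq_len(reps), function(r) {
      g <- igraph::sample_gnm(N, k)
      adj <- as.matrix(igraph::as_adjacency_matrix(g))
      net <- new_fc_network(adj, k, "er")
      dplyr::mutate(
        dplyr::select(global_metrics(net), -"trial", -"condition",
          -"window_start_ms"
        ),
        rep = r, .before = 1
      )
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(replicates, .data$K),
    dplyr::across(c("L", "C_avg", "B_avg"), list(mean = mean, sd = sd)),
    .groups = "drop"
  )
  list(replicates = replicates, summary = summary)
}

#' Small-world ratio against an Erdos-Renyi baseline
#'
#' `(C / C_ER) / (L / L_ER)`: clustering well above and path length close
#' to the matched random graph gives a ratio above 1.
#'
#' @param C_avg,L Empirical average clustering and path length.
#' @param er Baseline from [er_baseline()] at the matching K (single
#'   density).
#' @return The ratio (numeric).
#' @export
small_world_ratio <- function(C_avg, L, er) {
  s <- er$summary
  if (nrow(s) != 1) abort("er_baseline must cover exactly the matching K.")
  (C_avg / s$C_avg_mean) / (L / s$L_mean)
}
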