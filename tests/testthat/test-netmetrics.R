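path4 <- function() {
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- 1L
  as_net(A + t(A))
}

cycle4 <- function() {
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[1, 4] <- 1L
  as_net(A + t(A))
}

complete_net <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  as_net(A)
}

test_that("geodesic distances and path counts match hand enumeration", {
  g <- geodesics(complete_net(20))
  expect_true(all(g$d[upper.tri(g$d)] == 1))

  p <- geodesics(path4())
  expect_equal(p$d[1, 4], 3)
  expect_equal(p$n_paths[1, 4], 1)

  c4 <- geodesics(cycle4())
  expect_equal(c4$d[1, 3], 2)
  expect_equal(c4$n_paths[1, 3], 2) # via node 2 and via node 4
  thru2 <- geodesics_through(cycle4(), 2)
  expect_equal(thru2[1, 3], 1)
})

test_that("average path length covers connected pairs and reports their fraction", {
  expect_equal(avg_path_length(complete_net(20))$L, 1)
  # path on 4 nodes: lengths 1+2+3+1+2+1 over 6 pairs
  expect_equal(avg_path_length(path4())$L, 10 / 6)
  # two disjoint triangles
  A <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  }
  tri2 <- as_net(A)
  apl <- avg_path_length(tri2)
  expect_equal(apl$L, 1)
  expect_equal(apl$connected_pair_fraction, 6 / 15)
  # edgeless graph: L undefined
  expect_error(avg_path_length(as_net(matrix(0L, 3, 3))), "no connected pair")
})

test_that("clustering follows the neighbor-link-fraction definition", {
  expect_equal(clustering(complete_net(3), 1), 1)
  star <- matrix(0L, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1L
  expect_equal(clustering(as_net(star), 1), 0)
  # node 1 with neighbors 2,3,4 and one link 2-3 among them
  A <- matrix(0L, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 1L
  A[2, 3] <- A[3, 2] <- 1L
  expect_equal(clustering(as_net(A), 1), 1 / 3)
})

test_that("betweenness counts geodesic fractions over unordered pairs", {
  expect_equal(betweenness(complete_net(20), 5), 0)
  # path a-b-c: the single geodesic {a,c} passes through b
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[2, 3] <- 1L
  expect_equal(betweenness(as_net(A + t(A)), 2), 1)
  # 4-cycle: one of the two {1,3} geodesics passes through 2
  expect_equal(betweenness(cycle4(), 2), 1 / 2)
  # star center: every leaf pair's unique geodesic crosses it
  n <- 8
  star <- matrix(0L, n, n)
  star[1, 2:n] <- star[2:n, 1] <- 1L
  expect_equal(betweenness(as_net(star), 1), (n - 1) * (n - 2) / 2)
  expect_equal(betweenness(as_net(star), 3), 0) # degree-1 node
})

test_that("global metrics summarize the node measures", {
  gm <- global_metrics(complete_net(10))
  expect_equal(c(gm$L, gm$C_avg, gm$B_avg), c(1, 1, 0))
  net <- as_net(random_adjacency(12, 20))
  nm <- node_metrics(net)
  gm2 <- global_metrics(net)
  expect_equal(gm2$B_avg, mean(nm$betweenness))
  expect_equal(gm2$C_avg, mean(nm$clustering))
})

test_that("package measures agree exactly with matrix-power and DFS oracles", {
  set.seed(77)
  # dense sweep of small graphs plus random 20-node graphs
  cases <- c(
    lapply(1:60, function(i) graph_from_mask(4, sample(0:63, 1))),
    lapply(1:60, function(i) graph_from_mask(5, sample(0:1023, 1))),
    lapply(1:60, function(i) graph_from_mask(6, sample(0:32767, 1))),
    lapply(1:40, function(i) random_adjacency(20, sample(20:120, 1)))
  )
  for (A in cases) {
    net <- as_net(A)
    nm <- node_metrics(net)
    expect_equal(nm$degree, rowSums(A), ignore_attr = TRUE)
    expect_equal(nm$clustering, oracle_clustering(A))
    expect_equal(nm$betweenness, oracle_betweenness(A), tolerance = 1e-12)
    og <- oracle_geodesics(A)
    pg <- geodesics(net)
    expect_equal(pg$d, og$d, ignore_attr = TRUE)
    expect_equal(pg$n_paths, og$n_paths, ignore_attr = TRUE)
    if (any(A == 1)) expect_equal(avg_path_length(net)$L, oracle_L(A))
  }
  # literal DFS path enumeration on a handful of 5-node graphs
  for (i in 1:10) {
    A <- graph_from_mask(5, sample(0:1023, 1))
    og <- oracle_geodesics(A)
    for (j in 1:4) {
      for (k in (j + 1):5) {
        dg <- dfs_geodesics(A, j, k)
        expect_equal(og$d[j, k], dg$d)
        expect_equal(og$n_paths[j, k], dg$n)
      }
    }
  }
})

test_that("handshake and betweenness conservation hold on constructed networks", {
  set.seed(55)
  for (i in 1:20) {
    C <- matrix(0, 20, 20)
    C[upper.tri(C)] <- runif(190, -1, 1)
    C <- C + t(C)
    diag(C) <- 1
    K <- sample(c(20, 30, 50, 70, 120), 1)
    net <- build_fixed_links(C, K)
    nm <- node_metrics(net)
    expect_equal(sum(nm$degree), 2 * K)
    # each geodesic of length d contributes d - 1 interior crossings
    d <- geodesics(net)$d
    dv <- d[upper.tri(d)]
    expect_equal(
      sum(nm$betweenness),
      sum(dv[is.finite(dv)] - 1),
      tolerance = 1e-9
    )
    expect_true(all(nm$clustering[nm$degree < 2] == 0))
    expect_true(all(nm$betweenness[nm$degree <= 1] == 0))
  }
})

test_that("Erdos-Renyi baseline reproduces known limits", {
  er <- er_baseline(N = 10, K = 45, reps = 5, seed = 1)
  expect_true(all(er$replicates$L == 1))
  expect_true(all(er$replicates$C_avg == 1))

  er2 <- er_baseline(N = 20, K = 50, reps = 60, seed = 2)
  # expected ER clustering equals the edge density
  dens <- 50 / 190
  expect_lt(
    abs(mean(er2$replicates$C_avg) - dens),
    3 * sd(er2$replicates$C_avg)
  )
  expect_error(er_baseline(N = 5, K = 11), "exceeds")
})
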