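test_that("rank-sum test handles identity, separation and small-sample exactness", {
  # identical multisets: every arrangement is at least as extreme
  expect_equal(wilcoxon_rank(c(1, 5, 5, 9), c(1, 5, 5, 9)), 1)
  # fully separated samples of 3: the 2 most extreme of the 20 arrangements
  expect_equal(wilcoxon_rank(c(1, 2, 3), c(10, 11, 12)), 2 / 20)
  expect_equal(wilcoxon_rank(c(10, 11, 12), c(1, 2, 3)), 2 / 20)
  expect_error(wilcoxon_rank(numeric(0), 1:3), "non-empty")
})

test_that("exact enumeration matches the classical distribution when tie-free", {
  set.seed(61)
  for (i in 1:20) {
    a <- sample(1:100, sample(2:5, 1))
    b <- sample(101:200, sample(2:5, 1)) - runif(1) * 100
    if (anyDuplicated(c(a, b))) next
    ours <- wilcoxon_rank(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("normal approximation stays near the exact p for small samples", {
  set.seed(62)
  for (i in 1:50) {
    a <- rnorm(5)
    b <- rnorm(7)
    expect_lt(
      abs(wilcoxon_rank(a, b) - wilcoxon_rank(a, b, exact_max = 0)),
      0.05
    )
  }
  # heavy ties coarsen the exact distribution; the approximation stays sane
  for (i in 1:50) {
    a <- sample(1:6, 5, replace = TRUE)
    b <- sample(1:8, 6, replace = TRUE)
    expect_lt(
      abs(wilcoxon_rank(a, b) - wilcoxon_rank(a, b, exact_max = 0)),
      0.1
    )
  }
})

test_that("rank-sum type-I error is calibrated at the 5% level", {
  set.seed(63)
  reject <- vapply(seq_len(1000), function(i) {
    wilcoxon_rank(rnorm(15), rnorm(15)) < 0.05
  }, logical(1))
  rate <- mean(reject)
  band <- 2.58 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})

make_metric_table <- function(n_trials = 8, windows = c(0, 43.3),
                              ks = c(30, 50, 70), nodes = labels20,
                              seed = 1, shift_node = NULL, shift = 0) {
  set.seed(seed)
  grid <- expand.grid(
    trial = seq_len(2 * n_trials), window_start_ms = windows, K = ks,
    node = nodes, stringsAsFactors = FALSE
  )
  grid$condition <- ifelse(grid$trial <= n_trials, "BM", "SM")
  m <- nrow(grid)
  tab <- tibble::as_tibble(grid)
  tab$degree <- rnorm(m, 5)
  tab$clustering <- runif(m)
  tab$betweenness <- rexp(m)
  if (!is.null(shift_node)) {
    sel <- tab$node == shift_node & tab$condition == "SM"
    tab$degree[sel] <- tab$degree[sel] + shift
  }
  tab
}

test_that("condition comparison applies the Bonferroni and robustness rules", {
  tab <- make_metric_table(shift_node = "F7", shift = 6)
  cmp <- compare_conditions(tab, comparison_config(density_grid = c(30, 50, 70)))
  out <- tidy(cmp)
  expect_equal(nrow(out), 20 * 3 * 2 * 3) # electrodes x metrics x windows x K
  expect_true(all(out$p >= 0 & out$p <= 1))
  # the planted shift is found, in the right direction
  f7 <- dplyr::filter(out, electrode == "F7", metric == "degree")
  expect_true(all(f7$bonferroni_pass))
  expect_true(all(f7$robust_pass))
  expect_true(all(f7$direction == "SM"))
  # structural invariant: robust-pass requires >= min_densities passes
  agg <- dplyr::summarise(
    dplyr::group_by(out, electrode, metric, window_start_ms),
    n_pass = sum(bonferroni_pass), robust = any(robust_pass),
    .groups = "drop"
  )
  expect_true(all(agg$n_pass[agg$robust] >= 3))
  expect_true(all(agg$n_pass[!agg$robust] < 3))
  g <- glance(cmp)
  expect_equal(g$bonferroni_alpha, 0.05 / 20)
})

test_that("robust spans collapse consecutive significant windows", {
  tab <- make_metric_table(
    windows = c(0, 43.3, 86.7, 500),
    shift_node = "Pz", shift = 6
  )
  cmp <- compare_conditions(tab, comparison_config(density_grid = c(30, 50, 70)))
  spans <- robust_spans(cmp)
  pz <- dplyr::filter(spans, electrode == "Pz", metric == "degree")
  expect_equal(nrow(pz), 2) # 0-86.7 contiguous, 500 separate
  expect_equal(sort(pz$from_ms), c(0, 500))
})

test_that("comparison rejects mismatched or empty designs", {
  tab <- make_metric_table()
  expect_error(
    compare_conditions(dplyr::filter(tab, condition == "BM")),
    "2 conditions"
  )
  lop <- dplyr::filter(tab, !(condition == "SM" & K == 70))
  expect_error(compare_conditions(lop), "different windows or density")
  expect_error(
    compare_conditions(tab[0, ]),
    "2 conditions|Empty"
  )
})

test_that("paired mode runs as a sensitivity analysis", {
  tab <- make_metric_table(shift_node = "O2", shift = 6)
  cmp <- compare_conditions(
    tab, comparison_config(density_grid = c(30, 50, 70), paired = TRUE)
  )
  o2 <- dplyr::filter(tidy(cmp), electrode == "O2", metric == "degree")
  expect_true(all(o2$p < 0.05))
})

test_that("first-neighbor counts tally direct links per condition", {
  C <- matrix(0.5, 20, 20)
  diag(C) <- 1
  dimnames(C) <- list(labels20, labels20)
  complete <- build_threshold(C, 0, condition = "BM")
  nets <- rep(list(complete), 10)
  counts <- first_neighbors(nets, "F7")
  expect_equal(nrow(counts), 19)
  expect_true(all(counts$count == 10))

  # planted edge lists: tally must match a direct count
  set.seed(71)
  planted <- lapply(1:50, function(i) {
    net <- build_fixed_links(rand_corr(seed = i), 40)
    net$condition <- if (i <= 25) "BM" else "SM"
    net
  })
  counts2 <- first_neighbors(planted, "Cz")
  direct <- sapply(c("BM", "SM"), function(cond) {
    rowSums(sapply(
      planted[vapply(planted, `[[`, character(1), "condition") == cond],
      function(net) net$adjacency["Cz", ]
    ))
  })
  for (r in seq_len(nrow(counts2))) {
    expect_equal(
      counts2$count[r],
      unname(direct[counts2$electrode[r], counts2$condition[r]])
    )
  }
  expect_error(first_neighbors(nets, "XX"), "Unknown target")
})

test_that("isolated target yields zero neighbor counts", {
  C <- rand_corr(seed = 5)
  C["F7", ] <- -0.99
  C[, "F7"] <- -0.99
  diag(C) <- 1
  nets <- lapply(1:5, function(i) build_fixed_links(C, 30, condition = "BM"))
  counts <- first_neighbors(nets, "F7")
  expect_true(all(counts$count == 0))
})

test_that("baseline comparison runs the identical pipeline and stays null", {
  cfg <- synth_config(n_blocks = 1, n_reps = 8, epoch_s = 0.45, seed = 31)
  base <- generate_trials(cfg)
  cmp <- baseline_check(base, comparison_config(density_grid = c(30, 50, 70)))
  expect_s3_class(cmp, "fc_comparison")
  expect_false(any(tidy(cmp)$robust_pass))
})
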