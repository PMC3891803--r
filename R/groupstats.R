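#' Configuration for the two-condition comparison
#'
#' The dual significance criterion: a local (per-electrode) difference
#' counts only if (1) its rank-test p-value clears the Bonferroni
#' threshold `alpha_fw / n_electrodes` and (2) it does so at
#' `min_densities` or more distinct link densities for the same
#' electrode, metric and window.
#'
#' @param density_grid Link counts at which networks are built (default
#'   `c(20, 30, 40, 50, 60, 70, 80)`, seven densities spanning the 30/50/70
#'   operating points).
#' @param alpha_fw Family-wise level (default 0.05).
#' @param n_electrodes Number of simultaneous electrode tests (default 20,
#'   giving the 0.05/20 = 0.0025 Bonferroni threshold).
#' @param min_densities Number of densities at which significance must
#'   recur (default 3).
#' @param paired Use a paired signed-rank test instead of the two-sample
#'   rank-sum (sensitivity analysis; requires equal trial counts).
#' @return A list of class `fc_comparison_config`.
#' @export
comparison_config <- function(density_grid = c(20, 30, 40, 50, 60, 70, 80),
                              alpha_fw = 0.05, n_electrodes = 20,
                              min_densities = 3, paired = FALSE) {
  if (min_densities > length(density_grid)) {
    abort("min_densities cannot exceed the number of densities.")
  }
  if (alpha_fw <= 0 || alpha_fw >= 1) abort("alpha_fw must be in (0, 1).")
  structure(
    list(
      density_grid = density_grid, alpha_fw = alpha_fw,
      n_electrodes = n_electrodes, min_densities = min_densities,
      paired = paired
    ),
    class = "fc_comparison_config"
  )
}

#' Bonferroni-corrected per-electrode alpha
#' @param cfg A [comparison_config()].
#' @return `alpha_fw / n_electrodes`.
#' @export
bonferroni_alpha <- function(cfg = comparison_config()) {
  cfg$alpha_fw / cfg$n_electrodes
}

compare_p <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) abort("Paired mode needs equal sample sizes.")
    d <- a - b
    if (all(d == 0)) {
      return(1)
    }
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  } else {
    wilcoxon_rank(a, b)
  }
}

direction_call <- function(a, b, conds) {
  ma <- median(a)
  mb <- median(b)
  if (ma > mb) conds[1] else if (mb > ma) conds[2] else "none"
}

#' Compare two conditions' network metrics electrode by electrode
#'
#' Runs one rank test per (electrode, metric, window, link density) on the
#' trial-level local measures, applies the Bonferroni threshold
#' `alpha_fw / n_electrodes` and the multi-density robustness rule, and
#' calls the direction from the sample medians. If a global metric table
#' is supplied, global measures are tested per (metric, window, density)
#' at the uncorrected `alpha_fw`.
#'
#' @param metrics Long local metric table as from [metric_table()] —
#'   columns trial, condition, window_start_ms, K, node, degree,
#'   clustering, betweenness — containing both conditions.
#' @param cfg A [comparison_config()].
#' @param global_metrics Optional table from [global_metric_table()].
#' @return An object of class `fc_comparison`; see [tidy.fc_comparison()].
#' @export
compare_conditions <- function(metrics, cfg = comparison_config(),
                               global_metrics = NULL) {
  conds <- sort(unique(metrics$condition))
  if (length(conds) != 2) {
    abort(sprintf("Need exactly 2 conditions, found %d.", length(conds)))
  }
  cover <- dplyr::summarise(
    dplyr::group_by(metrics, .data$condition),
    windows = list(sort(unique(.data$window_start_ms))),
    ks = list(sort(unique(.data$K))),
    .groups = "drop"
  )
  if (nrow(metrics) == 0 || length(cover$windows[[1]]) == 0) {
    abort("Empty window set: nothing to compare.")
  }
  if (!identical(cover$windows[[1]], cover$windows[[2]]) ||
    !identical(cover$ks[[1]], cover$ks[[2]])) {
    abort("Conditions cover different windows or density grids.")
  }
  long <- tidyr::pivot_longer(metrics,
    cols = c("degree", "clustering", "betweenness"),
    names_to = "metric", values_to = "value"
  )
  local <- dplyr::summarise(
    dplyr::group_by(
      long, .data$node, .data$metric, .data$window_start_ms, .data$K
    ),
    p = compare_p(
      .data$value[.data$condition == conds[1]],
      .data$value[.data$condition == conds[2]],
      paired = cfg$paired
    ),
    direction = direction_call(
      .data$value[.data$condition == conds[1]],
      .data$value[.data$condition == conds[2]], conds
    ),
    .groups = "drop"
  )
  local$bonferroni_pass <- local$p < bonferroni_alpha(cfg)
  robust <- dplyr::summarise(
    dplyr::group_by(local, .data$node, .data$metric, .data$window_start_ms),
    n_pass = sum(.data$bonferroni_pass),
    .groups = "drop"
  )
  robust$robust_pass <- robust$n_pass >= cfg$min_densities
  local <- dplyr::left_join(
    local, robust,
    by = c("node", "metric", "window_start_ms")
  )
  glob <- NULL
  if (!is.null(global_metrics)) {
    glong <- tidyr::pivot_longer(global_metrics,
      cols = c("L", "C_avg", "B_avg"),
      names_to = "metric", values_to = "value"
    )
    glob <- dplyr::summarise(
      dplyr::group_by(glong, .data$metric, .data$window_start_ms, .data$K),
      p = compare_p(
        .data$value[.data$condition == conds[1]],
        .data$value[.data$condition == conds[2]],
        paired = cfg$paired
      ),
      .groups = "drop"
    )
    glob$pass <- glob$p < cfg$alpha_fw
  }
  structure(
    list(local = local, global = glob, conditions = conds, config = cfg),
    class = "fc_comparison"
  )
}

#' @export
print.fc_comparison <- function(x, ...) {
  cat(sprintf(
    "<fc_comparison> %s vs %s: %d local tests, %d robust finding(s)\n",
    x$conditions[1], x$conditions[2], nrow(x$local),
    nrow(dplyr::distinct(
      dplyr::filter(x$local, .data$robust_pass),
      .data$node, .data$metric, .data$window_start_ms
    ))
  ))
  invisible(x)
}

#' Tidy a condition comparison
#'
#' @param x An `fc_comparison`.
#' @param ... Unused.
#' @return The local significance map: one row per (electrode, metric,
#'   window, K) with `p`, `bonferroni_pass`, `n_pass`, `robust_pass` and
#'   `direction`.
#' @export
#' @method tidy fc_comparison
tidy.fc_comparison <- function(x, ...) {
  dplyr::select(
    x$local, electrode = "node", "metric", "window_start_ms", "K",
    "p", "bonferroni_pass", "robust_pass", "direction"
  )
}

#' One-line summary of a condition comparison
#'
#' @param x An `fc_comparison`.
#' @param ... Unused.
#' @return One-row tibble: number of local tests, Bonferroni passes,
#'   robust (electrode, metric, window) findings, and the Bonferroni
#'   threshold used.
#' @export
#' @method glance fc_comparison
glance.fc_comparison <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$local),
    n_bonferroni_pass = sum(x$local$bonferroni_pass),
    n_robust = nrow(dplyr::distinct(
      dplyr::filter(x$local, .data$robust_pass),
      .data$node, .data$metric, .data$window_start_ms
    )),
    bonferroni_alpha = bonferroni_alpha(x$config),
    min_densities = x$config$min_densities
  )
}

#' Robust findings as contiguous window spans
#'
#' Collapses the significance map to one row per (electrode, metric) run
#' of consecutive robust windows, the form in which time-resolved local
#' differences are reported.
#'
#' @param x An `fc_comparison`.
#' @param step_ms Window step used, to define contiguity (default inferred
#'   from the map).
#' @return Tibble: electrode, metric, from_ms, to_ms, n_windows, direction.
#' @export
robust_spans <- function(x, step_ms = NULL) {
  hits <- dplyr::distinct(
    dplyr::filter(x$local, .data$robust_pass),
    .data$node, .data$metric, .data$window_start_ms, .data$direction
  )
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      electrode = character(), metric = character(),
      from_ms = numeric(), to_ms = numeric(), n_windows = integer(),
      direction = character()
    ))
  }
  if (is.null(step_ms)) {
    ws <- sort(unique(x$local$window_start_ms))
    step_ms <- if (length(ws) > 1) min(diff(ws)) else 1
  }
  hits <- dplyr::arrange(hits, .data$node, .data$metric, .data$window_start_ms)
  hits <- dplyr::mutate(
    dplyr::group_by(hits, .data$node, .data$metric),
    run = cumsum(c(1, diff(.data$window_start_ms) > step_ms * 1.5))
  )
  dplyr::summarise(
    dplyr::group_by(hits, electrode = .data$node, .data$metric, .data$run),
    from_ms = min(.data$window_start_ms),
    to_ms = max(.data$window_start_ms),
    n_windows = dplyr::n(),
    direction = names(sort(table(.data$direction), decreasing = TRUE))[1],
    .groups = "drop"
  )[, c("electrode", "metric", "from_ms", "to_ms", "n_windows", "direction")]
}

#' First-neighbor co-occurrence counts for a target electrode
#'
#' Across a collection of networks, counts per condition how many times
#' each other electrode is directly linked to the target.
#'
#' @param nets List of `fc_network` sharing one montage.
#' @param target Electrode label.
#' @return Tibble: electrode, condition, count, n_networks.
#' @export
first_neighbors <- function(nets, target) {
  labels <- rownames(nets[[1]]$adjacency)
  if (!target %in% labels) {
    abort(sprintf("Unknown target electrode '%s'.", target))
  }
  rows <- purrr::map_dfr(nets, function(net) {
    tibble::tibble(
      electrode = labels,
      condition = net$condition,
      linked = net$adjacency[target, ]
    )
  })
  rows <- dplyr::filter(rows, .data$electrode != target)
  dplyr::summarise(
    dplyr::group_by(rows, .data$electrode, .data$condition),
    count = sum(.data$linked),
    n_networks = dplyr::n(),
    .groups = "drop"
  )
}

#' Pre-stimulus control comparison
#'
#' Runs the identical correlation - network - metrics - statistics
#' pipeline on pre-stimulus (baseline) epochs; under a correct setup no
#' electrode should show a robust difference there.
#'
#' @param baseline An `eeg_trialset` of pre-stimulus epochs with both
#'   condition labels.
#' @param cfg A [comparison_config()].
#' @param wc A [window_config()].
#' @return An `fc_comparison`.
#' @export
baseline_check <- function(baseline, cfg = comparison_config(),
                           wc = window_config(fs = baseline$fs)) {
  mt <- pipeline_metrics(baseline, wc, cfg$density_grid)
  compare_conditions(mt$local, cfg, global_metrics = mt$global)
}
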