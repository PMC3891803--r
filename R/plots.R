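#' Plot global metric time courses by condition
#'
#' One panel per (measure, link count), time on the x axis, one line per
#' condition with a trial-averaged mean and ribbon (+/- 1 SE).
#'
#' @param global_metrics Table from [global_metric_table()].
#' @param measures Which of `L`, `C_avg`, `B_avg` to show.
#' @return A ggplot.
#' @export
plot_global_timecourse <- function(global_metrics,
                                   measures = c("L", "C_avg", "B_avg")) {
  long <- tidyr::pivot_longer(global_metrics,
    cols = dplyr::all_of(measures),
    names_to = "measure", values_to = "value"
  )
  summ <- dplyr::summarise(
    dplyr::group_by(
      long, .data$condition, .data$window_start_ms, .data$K, .data$measure
    ),
    mean = mean(.data$value),
    se = sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(
    .data$window_start_ms, .data$mean,
    color = .data$condition, fill = .data$condition
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      alpha = 0.25, color = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$measure),
      cols = ggplot2::vars(.data$K), scales = "free_y"
    ) +
    ggplot2::labs(
      x = "window start (ms)", y = NULL,
      color = "condition", fill = "condition"
    ) +
    ggplot2::theme_minimal()
}

#' Significance map of a condition comparison
#'
#' Electrode x time tile map marking where a metric's difference passes
#' the dual (Bonferroni + multi-density) criterion.
#'
#' @param object An `fc_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot fc_comparison
autoplot.fc_comparison <- function(object, ...) {
  hits <- dplyr::distinct(
    dplyr::filter(object$local, .data$robust_pass),
    .data$node, .data$metric, .data$window_start_ms, .data$direction
  )
  base <- dplyr::distinct(object$local, .data$node, .data$window_start_ms)
  p <- ggplot2::ggplot(base, ggplot2::aes(.data$window_start_ms, .data$node)) +
    ggplot2::geom_tile(fill = "grey95", color = "white")
  if (nrow(hits) > 0) {
    p <- p + ggplot2::geom_tile(
      data = hits, ggplot2::aes(fill = .data$metric), alpha = 0.85
    )
  }
  p +
    ggplot2::labs(
      x = "window start (ms)", y = "electrode", fill = "metric",
      title = sprintf(
        "Robust local differences: %s vs %s",
        object$conditions[1], object$conditions[2]
      )
    ) +
    ggplot2::theme_minimal()
}

#' First-neighbor histogram for a target electrode
#'
#' Per-condition counts of how often each electrode was a first neighbor
#' of the target across a set of networks.
#'
#' @param counts Tibble from [first_neighbors()].
#' @param target Target label (for the title).
#' @return A ggplot.
#' @export
plot_first_neighbors <- function(counts, target = NULL) {
  ggplot2::ggplot(counts, ggplot2::aes(
    .data$electrode, .data$count,
    fill = .data$condition
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "electrode", y = "times counted as first neighbor",
      fill = "condition",
      title = if (is.null(target)) NULL else sprintf("First neighbors of %s", target)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Lag-correlation diagnostic plot
#'
#' @param profile Tibble from [lag_correlation()] (optionally stacked
#'   with a `pair` column).
#' @return A ggplot.
#' @export
plot_lag_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$lag_ms, .data$rho))
  if ("pair" %in% names(profile)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$pair))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "lag (ms)", y = "Spearman correlation") +
    ggplot2::theme_minimal()
}
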