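#' Rank-transform a vector
#'
#' Ranks 1..n with ties given the average of the ranks they span
#' (midranks), the transform under which Spearman correlation is the
#' Pearson correlation of the ranked series.
#'
#' @param x Numeric vector.
#' @return Numeric vector of ranks.
#' @export
rank_transform <- function(x) {
  if (length(x) < 1) abort("Cannot rank an empty vector.")
  rank(x, ties.method = "average")
}

#' Spearman correlation of two vectors
#'
#' Pearson correlation of the midrank-transformed series. A constant
#' vector has no rank variation, so the coefficient is undefined and an
#' error is raised; [sliding_correlation()] instead records such pairs as
#' missing.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("Need at least 3 samples.")
  if (var(x) == 0 || var(y) == 0) {
    abort("Spearman correlation undefined for a constant input.")
  }
  cor(x, y, method = "spearman")
}

#' Sliding-window configuration
#'
#' Window and step are given in milliseconds and converted once to sample
#' counts by round-half-up; at 600 Hz the defaults give a 200-sample
#' window stepped by 26 samples.
#'
#' @param window_ms Window length in ms (default 333).
#' @param step_ms Step between consecutive window starts in ms
#'   (default 43.3).
#' @param fs Sampling rate in Hz.
#' @return A list of class `fc_window_config` with elements `window_ms`,
#'   `step_ms`, `fs`, `window_n`, `step_n`.
#' @export
window_config <- function(window_ms = 333, step_ms = 43.3, fs = 600) {
  window_n <- round_half_up(window_ms * fs / 1000)
  step_n <- round_half_up(step_ms * fs / 1000)
  if (window_n < 3) abort("Window must span at least 3 samples.")
  if (step_n < 1) abort("Step must be at least 1 sample.")
  structure(
    list(
      window_ms = window_ms, step_ms = step_ms, fs = fs,
      window_n = window_n, step_n = step_n
    ),
    class = "fc_window_config"
  )
}

# window start samples (0-based) for a trial of n samples
window_starts <- function(n, wc) {
  if (wc$window_n > n) {
    abort(sprintf(
      "Window of %d samples does not fit in a %d-sample trial.",
      wc$window_n, n
    ))
  }
  seq(0, n - wc$window_n, by = wc$step_n)
}

#' Sliding-window zero-lag Spearman correlation of one trial
#'
#' For each window (starting at sample 0 and advancing by the step while
#' fully inside the trial) the N x N Spearman correlation matrix over
#' simultaneous samples is computed. A channel that is constant within a
#' window yields undefined coefficients; those entries are stored as `NA`
#' (with one warning) and are excluded from link ranking downstream.
#'
#' @param trial Channels x samples matrix with channel row names.
#' @param wc A [window_config()].
#' @param trial_id Integer identifier carried into the output.
#' @param condition Condition label carried into the output.
#' @return An object of class `fc_tensor`: list with `rho` (N x N x W
#'   array), `start_ms` (window starts relative to trial onset), `labels`,
#'   `trial_id`, `condition`, `wc`.
#' @export
sliding_correlation <- function(trial, wc = window_config(),
                                trial_id = 1L, condition = NA_character_) {
  trial <- as.matrix(trial)
  labels <- rownames(trial)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(trial)))
  starts <- window_starts(ncol(trial), wc)
  n_const <- 0L
  rho <- vapply(starts, function(s) {
    seg <- t(trial[, (s + 1):(s + wc$window_n), drop = FALSE])
    const <- apply(seg, 2, function(v) v[1] == min(v) && v[1] == max(v))
    r <- suppressWarnings(cor(seg, method = "spearman"))
    if (any(const)) {
      n_const <<- n_const + sum(const)
      r[const, ] <- NA_real_
      r[, const] <- NA_real_
    }
    diag(r) <- 1
    r
  }, matrix(0, nrow(trial), nrow(trial)))
  if (n_const > 0) {
    warn(sprintf(
      "%d constant channel-window(s): their pairs are recorded as missing.",
      n_const
    ))
  }
  dimnames(rho) <- list(labels, labels, NULL)
  structure(
    list(
      rho = rho, start_ms = starts * 1000 / wc$fs, labels = labels,
      trial_id = as.integer(trial_id), condition = condition, wc = wc
    ),
    class = "fc_tensor"
  )
}

#' @export
print.fc_tensor <- function(x, ...) {
  cat(sprintf(
    "<fc_tensor> trial %d (%s): %d channels, %d windows (%g ms / %g ms)\n",
    x$trial_id, x$condition %||% "?", length(x$labels), length(x$start_ms),
    x$wc$window_ms, x$wc$step_ms
  ))
  invisible(x)
}

#' @export
#' @method tidy fc_tensor
tidy.fc_tensor <- function(x, ...) {
  n <- length(x$labels)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  purrr::map_dfr(seq_along(x$start_ms), function(w) {
    tibble::tibble(
      trial = x$trial_id,
      condition = x$condition,
      window_start_ms = x$start_ms[w],
      electrode_i = x$labels[ut[, 1]],
      electrode_j = x$labels[ut[, 2]],
      rho = x$rho[, , w][ut]
    )
  })
}

#' Write / read a correlation tensor as long-format TSV
#'
#' The long format (trial, window_start_ms, electrode_i, electrode_j,
#' rho) round-trips exactly through [read_tensor()]. For a compact
#' binary cache of many tensors, `saveRDS()`/`readRDS()` on the objects
#' themselves is the natural route.
#'
#' @param x An `fc_tensor`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_tensor <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tensor
#' @param wc The [window_config()] the tensor was computed with (stored
#'   alongside on read-back for downstream steps).
#' @export
read_tensor <- function(path, wc = window_config()) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      trial = readr::col_integer(), condition = readr::col_character(),
      window_start_ms = readr::col_double(),
      electrode_i = readr::col_character(),
      electrode_j = readr::col_character(),
      rho = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  labels <- unique(c(tab$electrode_i, tab$electrode_j))
  starts <- sort(unique(tab$window_start_ms))
  n <- length(labels)
  rho <- array(NA_real_, c(n, n, length(starts)),
    dimnames = list(labels, labels, NULL)
  )
  ii <- match(tab$electrode_i, labels)
  jj <- match(tab$electrode_j, labels)
  ww <- match(tab$window_start_ms, starts)
  rho[cbind(ii, jj, ww)] <- tab$rho
  rho[cbind(jj, ii, ww)] <- tab$rho
  for (w in seq_along(starts)) diag(rho[, , w]) <- 1
  structure(
    list(
      rho = rho, start_ms = starts, labels = labels,
      trial_id = tab$trial[1], condition = tab$condition[1], wc = wc
    ),
    class = "fc_tensor"
  )
}

#' Rank correlation as a function of lag
#'
#' Spearman correlation between `x(t)` and `y(t + lag)` for every integer
#' sample lag within `max_lag_ms`. Positive lag means `y` is advanced
#' relative to `x`. Used as the diagnostic that dependence peaks at lag
#' zero, justifying zero-lag networks.
#'
#' @param x,y Numeric vectors of equal length.
#' @param max_lag_ms Maximum lag magnitude in ms.
#' @param fs Sampling rate in Hz.
#' @return A tibble with `lag_ms` and `rho`.
#' @export
lag_correlation <- function(x, y, max_lag_ms = 50, fs = 600) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  max_lag <- round_half_up(max_lag_ms * fs / 1000)
  n <- length(x)
  if (max_lag >= n) abort("Maximum lag must be shorter than the series.")
  lags <- seq(-max_lag, max_lag)
  rho <- vapply(lags, function(l) {
    if (l >= 0) {
      spearman_rho(x[1:(n - l)], y[(1 + l):n])
    } else {
      spearman_rho(x[(1 - l):n], y[1:(n + l)])
    }
  }, numeric(1))
  tibble::tibble(lag_ms = lags * 1000 / fs, rho = rho)
}

#' Sliding correlation over a whole trial set
#'
#' @param ts An `eeg_trialset`.
#' @param wc A [window_config()]; its `fs` is overridden by the trial
#'   set's sampling rate.
#' @return A list of `fc_tensor`, one per trial.
#' @export
trialset_correlation <- function(ts, wc = window_config(fs = ts$fs)) {
  wc <- window_config(wc$window_ms, wc$step_ms, fs = ts$fs)
  purrr::imap(ts$trials, function(tr, i) {
    sliding_correlation(tr, wc, trial_id = i, condition = ts$condition[i])
  })
}
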