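#' Preprocessing configuration
#'
#' @param band_lo_hz,band_hi_hz Passband edges in Hz (defaults 0.5 and 50,
#'   the broadband setting under which the functional correlation analysis
#'   is run).
#' @param artifact_threshold_uV Absolute-amplitude rejection threshold in
#'   microvolts; any trial in which any channel exceeds it is dropped.
#' @return A list of class `eeg_preprocess_config`.
#' @export
preprocess_config <- function(band_lo_hz = 0.5, band_hi_hz = 50,
                              artifact_threshold_uV = 100) {
  if (band_lo_hz <= 0 || band_hi_hz <= band_lo_hz) {
    abort("Need 0 < band_lo_hz < band_hi_hz.")
  }
  if (artifact_threshold_uV <= 0) abort("artifact_threshold_uV must be > 0.")
  structure(
    list(
      band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
      artifact_threshold_uV = artifact_threshold_uV
    ),
    class = "eeg_preprocess_config"
  )
}

#' Zero-phase bandpass filter
#'
#' Applies a 4th-order Butterworth bandpass forward and backward
#' (zero-phase), so the filter cannot shift one channel relative to
#' another and zero-lag correlations are undistorted. The passband
#' excludes DC, so the mean is removed.
#'
#' @param rec An `eeg_recording`.
#' @param cfg An [preprocess_config()].
#' @return A filtered `eeg_recording` with identical channel order.
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (cfg$band_hi_hz >= nyq) {
    abort(sprintf(
      "Band edge %g Hz is not below the Nyquist frequency %g Hz.",
      cfg$band_hi_hz, nyq
    ))
  }
  bf <- signal::butter(2, c(cfg$band_lo_hz, cfg$band_hi_hz) / nyq,
    type = "pass"
  )
  # demean first: the passband excludes DC anyway, and removing the mean
  # up front avoids the slow start-up transient of the 0.5 Hz edge
  filt <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x - mean(x))))
  new_recording(filt, labels = rownames(rec$data), fs = rec$fs)
}

# same filter applied to a channels x samples matrix (used by synth)
bandpass_matrix <- function(mat, fs, lo = 0.5, hi = 50) {
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  t(apply(mat, 1, function(x) signal::filtfilt(bf, x)))
}

#' Threshold-based artifact rejection
#'
#' Drops every trial in which any channel's absolute amplitude exceeds the
#' threshold at any sample. Rejection is idempotent; the number of dropped
#' trials is attached as attribute `n_rejected` and reported via message.
#'
#' @param ts An `eeg_trialset`.
#' @param cfg An [preprocess_config()].
#' @return The cleaned `eeg_trialset`.
#' @export
reject_artifacts <- function(ts, cfg = preprocess_config()) {
  stopifnot(inherits(ts, "eeg_trialset"))
  keep <- vapply(
    ts$trials, function(m) max(abs(m)) <= cfg$artifact_threshold_uV,
    logical(1)
  )
  out <- subset_trials(ts, keep)
  attr(out, "n_rejected") <- sum(!keep)
  if (sum(!keep) > 0) {
    message(sprintf(
      "reject_artifacts: dropped %d of %d trials (>|%g| uV).",
      sum(!keep), length(keep), cfg$artifact_threshold_uV
    ))
  }
  if (length(out$trials) == 0) {
    warn("All trials rejected; returning an empty trial set.")
  }
  out
}

# Hann-tapered periodogram of one trial, averaged over channels.
# Returns power at the discrete frequencies k * fs / n, k = 0..floor(n/2).
trial_periodogram <- function(mat, fs) {
  n <- ncol(mat)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  w <- w / sqrt(mean(w^2))
  tapered <- sweep(mat, 2, w, `*`)
  spec <- abs(stats::mvfft(t(tapered)))^2 / n
  k <- seq_len(floor(n / 2) + 1)
  list(freq = (k - 1) * fs / n, power = rowMeans(spec[k, , drop = FALSE]))
}

#' Per-frequency power comparison between two conditions
#'
#' The pre-analysis check that the two conditions do not differ in power
#' spectrum: per trial, a Hann-tapered periodogram is computed per channel
#' and averaged over channels; at each frequency bin in `[f_lo, f_hi]` the
#' two conditions' per-trial powers are compared with the two-sample rank
#' test ([wilcoxon_rank()]).
#'
#' @param ts An `eeg_trialset` with exactly two condition labels.
#' @param f_lo,f_hi Frequency range in Hz (defaults 0 and 50).
#' @return A tibble with `freq_hz` and `p_value`.
#' @export
spectrum_compare <- function(ts, f_lo = 0, f_hi = 50) {
  conds <- unique(ts$condition)
  if (length(conds) != 2) {
    abort(sprintf("Need exactly 2 conditions, found %d.", length(conds)))
  }
  counts <- table(ts$condition)
  if (any(counts < 2)) {
    abort(sprintf(
      "Condition '%s' has %d trial(s); need at least 2 per condition.",
      names(counts)[which.min(counts)], min(counts)
    ))
  }
  pgs <- lapply(ts$trials, trial_periodogram, fs = ts$fs)
  freq <- pgs[[1]]$freq
  pow <- vapply(pgs, `[[`, numeric(length(freq)), "power")
  keep <- which(freq >= f_lo & freq <= f_hi)
  a <- ts$condition == conds[1]
  p <- vapply(keep, function(k) {
    wilcoxon_rank(pow[k, a], pow[k, !a])
  }, numeric(1))
  tibble::tibble(freq_hz = freq[keep], p_value = p)
}
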