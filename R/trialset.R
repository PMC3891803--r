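#' Construct an epoched trial set
#'
#' @param trials List of channels x samples matrices, all with identical
#'   dimensions and channel order.
#' @param condition Character vector of condition labels, one per trial.
#' @param onset Integer vector of onset samples (0-based) in the source
#'   recording, or `NA` for synthetic trials.
#' @param labels Channel labels.
#' @param fs Sampling rate in Hz.
#' @param epoch_s Epoch length in seconds.
#' @return An object of class `eeg_trialset`.
#' @export
new_trial_set <- function(trials, condition, onset = rep(NA_integer_, length(trials)),
                          labels, fs, epoch_s = length(trials[[1]][1, ]) / fs) {
  stopifnot(is.list(trials), length(trials) == length(condition))
  if (length(trials) > 0) {
    dims <- vapply(trials, dim, integer(2))
    if (any(dims[1, ] != length(labels)) || length(unique(dims[2, ])) > 1) {
      abort("All trials must share channel count and sample count.")
    }
    trials <- lapply(trials, function(m) {
      dimnames(m) <- list(labels, NULL)
      m
    })
  }
  structure(
    list(
      trials = trials, condition = as.character(condition),
      onset = as.integer(onset), labels = as.character(labels),
      fs = as.numeric(fs), epoch_s = as.numeric(epoch_s)
    ),
    class = "eeg_trialset"
  )
}

#' @export
print.eeg_trialset <- function(x, ...) {
  cat(sprintf(
    "<eeg_trialset> %d trials (%s) x %d channels x %.3g s @ %g Hz\n",
    length(x$trials),
    paste(sprintf("%s: %d", names(table(x$condition)), table(x$condition)),
      collapse = ", "
    ),
    length(x$labels), x$epoch_s, x$fs
  ))
  invisible(x)
}

#' @export
length.eeg_trialset <- function(x) length(x$trials)

#' Number of samples per epoch
#' @param ts An `eeg_trialset`.
#' @return Integer sample count.
#' @export
epoch_samples <- function(ts) {
  if (length(ts$trials) > 0) ncol(ts$trials[[1]]) else round_half_up(ts$epoch_s * ts$fs)
}

# round-half-up, so 1.3 s x 600 Hz is exactly 780 samples and .5 cases are
# deterministic across platforms (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Cut a recording into fixed-length trials
#'
#' Each trial covers the half-open sample range
#' `[onset, onset + round(epoch_length_s * fs))`, onsets 0-based.
#'
#' @param rec An `eeg_recording`.
#' @param onsets Integer vector of 0-based onset samples.
#' @param labels Condition label per onset.
#' @param epoch_length_s Epoch length in seconds (default 1.3).
#' @return An `eeg_trialset`.
#' @export
epoch <- function(rec, onsets, labels, epoch_length_s = 1.3) {
  stopifnot(inherits(rec, "eeg_recording"), length(onsets) == length(labels))
  n <- round_half_up(epoch_length_s * rec$fs)
  if (n < 1) abort("Epoch length shorter than one sample.")
  total <- ncol(rec$data)
  ends <- onsets + n
  bad <- which(onsets < 0 | ends > total)
  if (length(bad) > 0) {
    abort(sprintf(
      "Trial %d (onset %d) overruns the recording (needs samples up to %d of %d).",
      bad[1], onsets[bad[1]], ends[bad[1]], total
    ))
  }
  trials <- lapply(seq_along(onsets), function(i) {
    rec$data[, (onsets[i] + 1):(onsets[i] + n), drop = FALSE]
  })
  new_trial_set(trials, labels, as.integer(onsets),
    labels = rownames(rec$data),
    fs = rec$fs, epoch_s = epoch_length_s
  )
}

#' Serialize a trial set to a directory
#'
#' Writes one TSV per trial plus a JSON manifest carrying the sampling
#' rate, channel labels, conditions and any rejection log.
#'
#' @param ts An `eeg_trialset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_set <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ts$trials)) {
    tab <- tibble::as_tibble(ts$trials[[i]],
      .name_repair = ~ paste0("s", seq_along(.x))
    )
    tab <- dplyr::bind_cols(tibble::tibble(channel = ts$labels), tab)
    readr::write_tsv(tab, file.path(dir, sprintf("trial_%04d.tsv", i)),
      progress = FALSE
    )
  }
  manifest <- list(
    fs = ts$fs, epoch_s = ts$epoch_s, labels = ts$labels,
    condition = ts$condition, onset = ts$onset,
    n_rejected = attr(ts, "n_rejected") %||% 0L
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a trial set written by [write_trial_set()]
#' @param dir Directory containing `trial_*.tsv` and `manifest.json`.
#' @return An `eeg_trialset`.
#' @export
read_trial_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  files <- sort(list.files(dir, pattern = "^trial_\\d+\\.tsv$", full.names = TRUE))
  trials <- lapply(files, function(f) {
    tab <- readr::read_tsv(f,
      col_types = readr::cols(
        channel = readr::col_character(), .default = readr::col_double()
      ),
      progress = FALSE, show_col_types = FALSE
    )
    as.matrix(tab[, -1, drop = FALSE])
  })
  new_trial_set(trials, manifest$condition, manifest$onset,
    labels = manifest$labels, fs = manifest$fs, epoch_s = manifest$epoch_s
  )
}

#' Keep a subset of trials
#' @param ts An `eeg_trialset`.
#' @param idx Integer or logical index over trials.
#' @return An `eeg_trialset`.
#' @export
subset_trials <- function(ts, idx) {
  new_trial_set(ts$trials[idx], ts$condition[idx], ts$onset[idx],
    labels = ts$labels, fs = ts$fs, epoch_s = ts$epoch_s
  )
}
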