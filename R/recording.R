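#' Construct a multichannel recording
#'
#' A recording is a channels x samples numeric matrix in microvolts plus a
#' sampling rate. Channel labels (row names) must be unique; ordering is
#' meaningful and preserved by every operation.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param labels Character vector of channel labels, one per row.
#' @param fs Sampling rate in Hz.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, labels = rownames(data), fs = 600) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) {
    abort("Channel labels are required (supply `labels` or row names).")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) {
    abort(sprintf(
      "Got %d labels for %d channel rows.", length(labels), nrow(data)
    ))
  }
  if (anyDuplicated(labels)) {
    abort(paste0(
      "Duplicate channel label(s): ",
      paste(unique(labels[duplicated(labels)]), collapse = ", ")
    ))
  }
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  dimnames(data) <- list(labels, NULL)
  structure(list(data = data, fs = as.numeric(fs)), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat(" channels:", paste(rownames(x$data), collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @method tidy eeg_recording
tidy.eeg_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble::tibble(
    channel = rep(rownames(x$data), each = n),
    time_s = rep(seq_len(n) - 1, times = nrow(x$data)) / x$fs,
    value = as.vector(t(x$data))
  )
}

#' Read a recording from disk
#'
#' CSV/TSV files hold one channel per row with a leading `channel` label
#' column and one column per sample; the sampling rate is not stored in the
#' file and must be supplied. EDF files carry labels and sampling rate in
#' their header.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"` or `"edf"`; default guesses from the
#'   extension.
#' @param fs Sampling rate in Hz, required for csv/tsv; ignored for EDF.
#' @return An `eeg_recording`.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "csv", "tsv", "edf"),
                           fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "tsv", txt = "tsv", edf = "edf",
      abort(sprintf("Cannot guess format from extension '.%s'.", ext))
    )
  }
  if (format == "edf") {
    return(read_edf(path))
  }
  if (is.null(fs)) {
    abort("`fs` is required when reading csv/tsv recordings.")
  }
  delim <- if (format == "csv") "," else "\t"
  tab <- suppressWarnings(readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(
      channel = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )) # parse issues re-reported below with row/column detail
  if (!"channel" %in% names(tab)) {
    abort("Recording file must have a leading 'channel' column.")
  }
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Non-numeric value at file row %d, column %d of '%s'.",
      probs$row[1], probs$col[1], path
    ))
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  new_recording(mat, labels = tab$channel, fs = fs)
}

#' Write a recording to CSV/TSV
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- tibble::as_tibble(rec$data, .name_repair = ~ paste0("s", seq_along(.x)))
  tab <- dplyr::bind_cols(tibble::tibble(channel = rownames(rec$data)), tab)
  if (format == "csv") {
    readr::write_csv(tab, path, progress = FALSE)
  } else {
    readr::write_tsv(tab, path, progress = FALSE)
  }
  invisible(path)
}

# Minimal EDF reader: fixed-layout ASCII header, one or more data records of
# int16 samples per signal, mapped to physical units by the per-signal
# calibration. Assumes a uniform sampling rate across signals.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8) # version
  hdr(80); hdr(80) # patient / recording id
  hdr(8); hdr(8) # start date / time
  header_bytes <- as.integer(hdr(8))
  hdr(44) # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- field(16)
  field(80); field(8) # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80) # prefiltering
  spr <- as.integer(field(8)) # samples per record per signal
  field(32) # reserved
  stopifnot(header_bytes == 256 + ns * 256)
  if (length(unique(spr)) != 1) {
    abort("EDF signals with differing sampling rates are not supported.")
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      cols <- ((r - 1) * spr[s] + 1):(r * spr[s])
      out[s, cols] <- raw * gain[s] + offset[s]
    }
  }
  new_recording(out, labels = labels, fs = spr[1] / record_dur)
}

#' Read trial annotations
#'
#' A 3-column TSV (`onset_sample`, `condition`, `block`) marking stimulus
#' onsets within a recording.
#'
#' @param path File path.
#' @return A tibble with the three columns, onset as integer (0-based).
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      onset_sample = readr::col_integer(),
      condition = readr::col_character(),
      block = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("onset_sample", "condition", "block") %in% names(tab))) {
    abort("Annotations need columns onset_sample, condition, block.")
  }
  tab
}
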