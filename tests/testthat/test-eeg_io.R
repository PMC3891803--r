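test_that("csv/tsv recordings round-trip exactly", {
  rec <- toy_recording(n = 50)
  for (fmt in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_recording(rec, path, fmt)
    back <- read_recording(path, fmt, fs = 600)
    expect_identical(rownames(back$data), labels20)
    expect_equal(back$data, rec$data, tolerance = 1e-12)
    expect_equal(back$fs, 600)
  }
})

test_that("malformed recording files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("channel,s1,s2", "Fz,1,2", "Fz,3,4"), path)
  expect_error(read_recording(path, "csv", fs = 600), "Duplicate")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("channel,s1,s2", "Fz,1,oops", "Cz,3,4"), path2)
  expect_error(read_recording(path2, "csv", fs = 600), "row")

  expect_error(
    new_recording(matrix(0, 2, 3), labels = c("a")),
    "2 channel rows"
  )
  expect_error(new_recording(matrix(0, 1, 3), labels = "a", fs = 0), "fs")
})

test_that("EDF recordings are read with header labels, rate and scaling", {
  # synthesize a 2-channel EDF byte-by-byte, independent of the reader
  path <- withr::local_tempfile(fileext = ".edf")
  ns <- 2L
  spr <- 30L
  fs <- 600
  con <- file(path, "wb")
  pad <- function(x, w) writeChar(formatC(x, width = -w), con, w, eos = NULL)
  pad("0", 8)
  pad("patient", 80)
  pad("recording", 80)
  pad("01.01.26", 8)
  pad("00.00.00", 8)
  pad(as.character(256 + ns * 256), 8)
  pad("", 44)
  pad("2", 8) # 2 records
  pad(format(spr / fs), 8) # record duration (s)
  pad(as.character(ns), 4)
  for (lab in c("Fp1", "Cz")) pad(lab, 16)
  for (i in 1:ns) pad("AgAgCl", 80)
  for (i in 1:ns) pad("uV", 8)
  for (i in 1:ns) pad("-100", 8) # physical min
  for (i in 1:ns) pad("100", 8)
  for (i in 1:ns) pad("-2048", 8) # digital min
  for (i in 1:ns) pad("2047", 8)
  for (i in 1:ns) pad("HP:0.5Hz", 80)
  for (i in 1:ns) pad(as.character(spr), 8)
  for (i in 1:ns) pad("", 32)
  set.seed(3)
  digital <- matrix(sample(-2048:2047, ns * spr * 2), nrow = ns)
  for (r in 1:2) {
    for (s in 1:ns) {
      cols <- ((r - 1) * spr + 1):(r * spr)
      writeBin(as.integer(digital[s, cols]), con, size = 2, endian = "little")
    }
  }
  close(con)

  rec <- read_recording(path, "edf")
  expect_identical(rownames(rec$data), c("Fp1", "Cz"))
  expect_equal(rec$fs, fs)
  gain <- 200 / 4095
  expect_equal(rec$data, digital * gain + (-100 - gain * -2048),
    ignore_attr = TRUE, tolerance = 1e-9
  )
})

test_that("epoching cuts exact half-open windows and checks bounds", {
  rec <- toy_recording(n = 2000)
  ts <- epoch(rec, onsets = c(0, 780), labels = c("BM", "SM"))
  expect_equal(epoch_samples(ts), 780) # 1.3 s x 600 Hz
  expect_identical(ts$trials[[1]], rec$data[, 1:780])
  expect_identical(ts$trials[[2]], rec$data[, 781:1560])

  onsets <- seq(0, by = 10, length.out = 100)
  rec2 <- toy_recording(n = 1000 + 780)
  ts2 <- epoch(rec2, onsets, rep(c("BM", "SM"), 50), epoch_length_s = 0.05)
  expect_equal(unname(table(ts2$condition)), c(50L, 50L), ignore_attr = TRUE)

  expect_error(
    epoch(rec, onsets = ncol(rec$data) - 1, labels = "BM"),
    "overruns"
  )
})

test_that("epoching at contiguous onsets partitions the recording", {
  rec <- toy_recording(n = 780 * 3)
  ts <- epoch(rec, onsets = c(0, 780, 1560), labels = c("A", "B", "A"))
  expect_identical(do.call(cbind, ts$trials), rec$data)
})

test_that("trial sets round-trip through the per-trial TSV serialization", {
  ts <- toy_trialset(n_trials = 3, n = 40)
  dir <- withr::local_tempdir()
  write_trial_set(ts, dir)
  back <- read_trial_set(dir)
  expect_equal(back$condition, ts$condition)
  expect_equal(back$fs, ts$fs)
  expect_equal(back$trials, ts$trials, tolerance = 1e-10)
})

test_that("bandpass keeps in-band tones, removes out-of-band and DC", {
  fs <- 600
  dur <- 30
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  mk <- function(f) {
    new_recording(matrix(sin(2 * pi * f * t), 1), labels = "Cz", fs = fs)
  }
  # oracle: amplitude ratio at the tone's own FFT bin
  tone_gain <- function(f) {
    bin <- f * dur + 1
    abs(fft(bandpass(mk(f))$data[1, ])[bin]) / abs(fft(mk(f)$data[1, ])[bin])
  }
  expect_lt(tone_gain(0.1), 0.05)
  expect_equal(tone_gain(10), 1, tolerance = 0.05)
  # DC removal
  dc <- bandpass(new_recording(matrix(1, 1, length(t)), labels = "Cz", fs = fs))
  expect_lt(max(abs(dc$data)), 1e-9)
  # all-zero in, all-zero out
  z <- bandpass(new_recording(matrix(0, 2, 100), labels = c("a", "b"), fs = fs))
  expect_true(all(z$data == 0))
  expect_error(
    bandpass(mk(10), preprocess_config(band_hi_hz = 300)),
    "Nyquist"
  )
})

test_that("bandpass is linear", {
  fs <- 600
  set.seed(5)
  x <- matrix(rnorm(300), 1)
  y <- matrix(rnorm(300), 1)
  rec <- function(m) new_recording(m, labels = "Cz", fs = fs)
  lhs <- bandpass(rec(2 * x - 3 * y))$data
  rhs <- 2 * bandpass(rec(x))$data - 3 * bandpass(rec(y))$data
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("artifact rejection drops only over-threshold trials, idempotently", {
  ts <- toy_trialset(n_trials = 4, n = 100)
  ts$trials <- lapply(ts$trials, function(m) pmin(pmax(m, -50), 50))
  ts$trials[[2]][5, 10] <- 500 # spike
  expect_message(clean <- reject_artifacts(ts), "dropped 1 of 4")
  expect_length(clean$trials, 3)
  expect_equal(attr(clean, "n_rejected"), 1)
  expect_identical(clean$trials[[2]], ts$trials[[3]])

  # within-threshold data pass untouched; rejection is idempotent
  again <- reject_artifacts(clean)
  expect_equal(again$trials, clean$trials)
  expect_equal(attr(again, "n_rejected"), 0)

  expect_warning(
    empty <- reject_artifacts(ts, preprocess_config(artifact_threshold_uV = 1e-3)),
    "All trials rejected"
  )
  expect_length(empty$trials, 0)
})

test_that("spectrum comparison is calibrated under the null and localizes power effects", {
  # identical generating process for both conditions: ~5% of bins significant
  set.seed(11)
  ts <- toy_trialset(n_trials = 40, n = 300)
  res <- spectrum_compare(ts, 0, 50)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  frac <- mean(res$p_value < 0.05)
  # binomial band around 0.05 (bins are approximately independent here)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)))

  # doubled 10 Hz power in one condition shows up at the 10 Hz bin
  fs <- 600
  n <- 600
  tt <- seq_len(n) / fs
  set.seed(12)
  trials <- lapply(1:20, function(i) {
    m <- matrix(rnorm(20 * n), 20, n)
    rownames(m) <- labels20
    if (i > 10) m <- m + matrix(sin(2 * pi * 10 * tt + runif(1) * 2 * pi), 20, n, byrow = TRUE) * 2
    m
  })
  ts2 <- new_trial_set(trials, rep(c("BM", "SM"), each = 10),
    labels = labels20, fs = fs, epoch_s = 1
  )
  res2 <- spectrum_compare(ts2, 0, 50)
  # Hann taper spreads the tone into the adjacent bins
  expect_true(res2$freq_hz[which.min(res2$p_value)] %in% c(9, 10, 11))
  expect_lt(res2$p_value[res2$freq_hz == 10], 1e-3)

  # a condition compared with itself: every p = 1 under midrank ties
  ts3 <- toy_trialset(n_trials = 4, n = 200)
  ts3$trials <- ts3$trials[c(1, 2, 1, 2)]
  ts3$condition <- c("BM", "BM", "SM", "SM")
  expect_true(all(spectrum_compare(ts3, 0, 50)$p_value == 1))

  expect_error(
    spectrum_compare(subset_trials(ts, 1:3), 0, 50),
    "at least 2"
  )
})
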