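# small in-code fixtures shared across test files

labels20 <- montage_1020()$label

# random symmetric correlation-like matrix with unit diagonal
rand_corr <- function(n = 20, seed = 1) {
  set.seed(seed)
  C <- matrix(0, n, n)
  C[upper.tri(C)] <- runif(n * (n - 1) / 2, -1, 1)
  C <- C + t(C)
  diag(C) <- 1
  dimnames(C) <- list(labels20[1:n], labels20[1:n])
  C
}

# deterministic 20 x n "recording" matrix with mild channel structure
toy_recording <- function(n = 780, fs = 600, seed = 99) {
  set.seed(seed)
  common <- rnorm(n)
  mat <- t(vapply(seq_along(labels20), function(i) {
    0.5 * common + rnorm(n)
  }, numeric(n)))
  new_recording(mat, labels = labels20, fs = fs)
}

toy_trialset <- function(n_trials = 6, n = 780, fs = 600, seed = 99) {
  set.seed(seed)
  trials <- lapply(seq_len(n_trials), function(i) {
    m <- matrix(rnorm(20 * n), 20, n)
    rownames(m) <- labels20
    m
  })
  new_trial_set(trials,
    condition = rep(c("BM", "SM"), length.out = n_trials),
    labels = labels20, fs = fs, epoch_s = n / fs
  )
}
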