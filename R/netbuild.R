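#' Build a functional network with a fixed number of links
#'
#' Links exactly the `K` electrode pairs with the highest correlation.
#' Ranking uses the signed correlation value by default (the "highest
#' correlated" pairs); set `absolute = TRUE` to rank by magnitude. Ties at
#' the K-th value are broken by lexicographic pair order in montage order,
#' so the result is deterministic. Pairs whose correlation is missing
#' (constant channel in the window) can never be linked and shrink the
#' eligible pool.
#'
#' @param C Symmetric correlation matrix with unit diagonal (`NA` allowed
#'   off-diagonal for invalid pairs).
#' @param K Number of links to keep.
#' @param absolute Rank by `|rho|` instead of signed value.
#' @param window_start_ms,trial_id,condition Metadata carried through.
#' @return An object of class `fc_network`: list with binary `adjacency`
#'   (0/1, zero diagonal, symmetric), `K`, `mode`, metadata.
#' @export
build_fixed_links <- function(C, K, absolute = FALSE,
                              window_start_ms = NA_real_,
                              trial_id = NA_integer_,
                              condition = NA_character_) {
  C <- as.matrix(C)
  n <- nrow(C)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  vals <- C[ut]
  if (absolute) vals <- abs(vals)
  valid <- !is.na(vals)
  if (K > sum(valid)) {
    abort(sprintf(
      "K = %d exceeds the %d valid electrode pairs%s.",
      K, sum(valid),
      if (is.na(window_start_ms)) "" else sprintf(" (window %g ms)", window_start_ms)
    ))
  }
  if (K < 0) abort("K must be non-negative.")
  # order: value descending, then lexicographic (i, j) pair order;
  # which(upper.tri) is column-major so sort explicitly on (i, j)
  ord <- order(-vals, ut[, 1], ut[, 2], na.last = TRUE)
  pick <- ord[seq_len(K)]
  adj <- matrix(0L, n, n, dimnames = dimnames(C))
  adj[ut[pick, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  new_fc_network(adj, K, "fixed_links", window_start_ms, trial_id, condition)
}

#' Build a functional network with a fixed correlation threshold
#'
#' Links every pair whose correlation strictly exceeds `r_threshold`; the
#' resulting link count varies across windows, which is the instability
#' the fixed-link criterion avoids.
#'
#' @inheritParams build_fixed_links
#' @param r_threshold Correlation cutoff in `(-1, 1)` (boundary values
#'   give the complete / empty graph).
#' @return An `fc_network` with `K` equal to the realized link count.
#' @export
build_threshold <- function(C, r_threshold,
                            window_start_ms = NA_real_,
                            trial_id = NA_integer_,
                            condition = NA_character_) {
  C <- as.matrix(C)
  adj <- ifelse(!is.na(C) & C > r_threshold, 1L, 0L)
  diag(adj) <- 0L
  dimnames(adj) <- dimnames(C)
  new_fc_network(
    adj, sum(adj[upper.tri(adj)]), "threshold",
    window_start_ms, trial_id, condition
  )
}

new_fc_network <- function(adjacency, K, mode, window_start_ms = NA_real_,
                           trial_id = NA_integer_, condition = NA_character_) {
  stopifnot(isSymmetric(unname(adjacency)), all(diag(adjacency) == 0))
  structure(
    list(
      adjacency = adjacency, K = as.integer(K), mode = mode,
      window_start_ms = window_start_ms, trial_id = as.integer(trial_id),
      condition = condition
    ),
    class = "fc_network"
  )
}

#' @export
print.fc_network <- function(x, ...) {
  cat(sprintf(
    "<fc_network> %d nodes, %d links (%s mode)%s\n",
    nrow(x$adjacency), x$K, x$mode,
    if (is.na(x$window_start_ms)) "" else sprintf(", window %g ms", x$window_start_ms)
  ))
  invisible(x)
}

#' @export
#' @method tidy fc_network
tidy.fc_network <- function(x, ...) {
  ut <- which(upper.tri(x$adjacency) & x$adjacency == 1, arr.ind = TRUE)
  labels <- rownames(x$adjacency) %||% as.character(seq_len(nrow(x$adjacency)))
  tibble::tibble(
    trial = x$trial_id, condition = x$condition,
    window_start_ms = x$window_start_ms,
    electrode_i = labels[ut[, 1]], electrode_j = labels[ut[, 2]]
  )
}

#' Networks for every window of a correlation tensor
#'
#' @param tensor An `fc_tensor`.
#' @param K Link count (fixed-links mode) — may be a vector to build one
#'   network per density.
#' @param mode `"fixed_links"` or `"threshold"`.
#' @param r_threshold Cutoff for threshold mode.
#' @param absolute Passed to [build_fixed_links()].
#' @return A list of `fc_network` (over windows, then densities).
#' @export
build_networks <- function(tensor, K = 50, mode = c("fixed_links", "threshold"),
                           r_threshold = NULL, absolute = FALSE) {
  mode <- match.arg(mode)
  out <- list()
  for (w in seq_along(tensor$start_ms)) {
    C <- tensor$rho[, , w]
    if (mode == "fixed_links") {
      for (k in K) {
        out[[length(out) + 1]] <- build_fixed_links(
          C, k, absolute,
          window_start_ms = tensor$start_ms[w],
          trial_id = tensor$trial_id, condition = tensor$condition
        )
      }
    } else {
      out[[length(out) + 1]] <- build_threshold(
        C, r_threshold,
        window_start_ms = tensor$start_ms[w],
        trial_id = tensor$trial_id, condition = tensor$condition
      )
    }
  }
  out
}

#' Stability contrast between the two network criteria
#'
#' For one correlation tensor, reports per window the mean off-diagonal
#' correlation, the link count under the threshold criterion and the
#' (constant) link count under the fixed-link criterion, plus the
#' across-window variance of each count. Fluctuating global
#' synchronization makes the threshold-mode count fluctuate while the
#' fixed-link count is constant by construction.
#'
#' @param tensor An `fc_tensor`.
#' @param K Fixed link count (default 50).
#' @param r_threshold Threshold-mode cutoff (default the tensor's median
#'   off-diagonal correlation, so the two modes match in typical density).
#' @return A list with `per_window` (tibble: window_start_ms, mean_rho,
#'   K_threshold, K_fixed) and `variance` (tibble: mode, var_K).
#' @export
criterion_stability <- function(tensor, K = 50, r_threshold = NULL) {
  if (length(tensor$start_ms) < 2) abort("Need at least 2 windows.")
  n <- length(tensor$labels)
  ut <- upper.tri(matrix(0, n, n))
  offdiag <- apply(tensor$rho, 3, function(C) C[ut], simplify = FALSE)
  if (is.null(r_threshold)) {
    r_threshold <- median(unlist(offdiag), na.rm = TRUE)
  }
  per_window <- tibble::tibble(
    window_start_ms = tensor$start_ms,
    mean_rho = vapply(offdiag, mean, numeric(1), na.rm = TRUE),
    K_threshold = vapply(
      offdiag, function(v) sum(v > r_threshold, na.rm = TRUE), numeric(1)
    ),
    K_fixed = K
  )
  list(
    per_window = per_window,
    r_threshold = r_threshold,
    variance = tibble::tibble(
      mode = c("fixed_links", "threshold"),
      var_K = c(var(per_window$K_fixed), var(per_window$K_threshold))
    )
  )
}

#' Write networks as an edge list TSV plus JSON header
#'
#' @param nets List of `fc_network`.
#' @param path Output TSV path; the JSON header is written alongside with
#'   extension `.json`.
#' @return `path` invisibly.
#' @export
write_networks <- function(nets, path) {
  edges <- purrr::map_dfr(nets, tidy)
  readr::write_tsv(edges, path, progress = FALSE)
  hdr <- list(
    N = nrow(nets[[1]]$adjacency),
    K = unique(vapply(nets, `[[`, integer(1), "K")),
    mode = unique(vapply(nets, `[[`, character(1), "mode"))
  )
  jsonlite::write_json(hdr, sub("\\.tsv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
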