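#' Standard 20-electrode 10-20 montage
#'
#' Returns the 20-channel subset of the international 10-20 system
#' (Fp1...O2) with flat 2-D scalp coordinates from the usual azimuthal
#' projection: the vertex Cz sits at the origin and the outer ring
#' (Fp1, F7, T3, T5, O1, Oz, ... ) on the unit circle, so distances are in
#' units of head radius.
#'
#' @param labels Optional character vector to subset/reorder the montage.
#' @return A tibble with columns `label`, `x`, `y`.
#' @examples
#' montage_1020()
#' @export
montage_1020 <- function(labels = NULL) {
  # EEGLAB-style polar coordinates (angle clockwise from nasion, radius
  # as fraction of the rim), rim rescaled to radius 1.
  polar <- tibble::tribble(
    ~label, ~angle, ~radius,
    "Fp1", -18, 1, "Fp2", 18, 1,
    "F7", -54, 1, "F3", -39, 0.652, "Fz", 0, 0.501,
    "F4", 39, 0.652, "F8", 54, 1,
    "T3", -90, 1, "C3", -90, 0.501, "Cz", 0, 0,
    "C4", 90, 0.501, "T4", 90, 1,
    "T5", -126, 1, "P3", -141, 0.652, "Pz", 180, 0.501,
    "P4", 141, 0.652, "T6", 126, 1,
    "O1", -162, 1, "Oz", 180, 1, "O2", 162, 1
  )
  out <- dplyr::transmute(
    polar,
    label = .data$label,
    x = .data$radius * sinpi(.data$angle / 180),
    y = .data$radius * cospi(.data$angle / 180)
  )
  if (!is.null(labels)) {
    missing <- setdiff(labels, out$label)
    if (length(missing) > 0) {
      abort(paste0(
        "Unknown electrode label(s): ", paste(missing, collapse = ", ")
      ))
    }
    out <- out[match(labels, out$label), ]
  }
  out
}

#' Pairwise scalp distances for a montage
#'
#' @param montage A tibble as returned by [montage_1020()].
#' @return A symmetric matrix of Euclidean distances (head-radius units)
#'   with zero diagonal, dimnames set to the electrode labels.
#' @export
montage_distances <- function(montage = montage_1020()) {
  d <- as.matrix(stats::dist(cbind(montage$x, montage$y)))
  dimnames(d) <- list(montage$label, montage$label)
  d
}
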