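#' Normalised root-mean-square displacement error
#'
#' `NRMSE = sqrt(sum((pred - label)^2) / N) * 100 * N / sum(label)`, i.e. the
#' RMSE normalised by the mean ground-truth displacement, in percent.
#'
#' @param predicted,label numeric matrices of equal shape (axial
#'   displacement and its ground truth).
#' @export
nrmse <- function(predicted, label) {
  predicted <- as.matrix(predicted); label <- as.matrix(label)
  if (!all(dim(predicted) == dim(label))) stop("nrmse: shape mismatch")
  m <- mean(label)
  if (m == 0) stop("nrmse: zero-mean label, normalisation undefined")
  100 * sqrt(mean((predicted - label)^2)) / m
}

#' Elastographic signal-to-noise ratio
#'
#' `SNRe = mu / sigma`, the mean over the (population) standard deviation of
#' the strain image, optionally restricted to a region of interest.
#'
#' @param strain a [strain_field()] or matrix.
#' @param roi optional logical matrix or index set selecting the ROI
#'   (default: whole image).
#' @export
snre <- function(strain, roi = NULL) {
  v <- strain_values(strain)
  x <- if (is.null(roi)) as.numeric(v) else as.numeric(v[roi])
  if (length(x) < 2) stop("snre: need at least 2 pixels")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("snre: constant strain (degenerate)")
  mean(x) / s
}

#' Per-step similarity and consistency scores of a sequence
#'
#' Motion-compensated quality metrics, reusing the training criteria with
#' positive sign: per consecutive pair, similarity is the LNCC between the
#' earlier frame and the warped later frame; from the second pair onward,
#' consistency is the LNCC between the previous strain map and the warped
#' current one. High values indicate accurate tracking and temporally stable
#' elastograms.
#'
#' @param frames a frame sequence (`N` frames).
#' @param displacements list of `N - 1` [displacement_field()]s.
#' @param strains optional list of `N - 1` strain maps (computed with
#'   [lsq_strain()] from the displacements if omitted).
#' @param weights a [loss_weights()] providing the LNCC window.
#' @param strain_window LSQSE window when strains are derived here.
#' @return data frame with one row per step (`similarity`, `consistency`).
#' @export
sequence_scores <- function(frames, displacements, strains = NULL,
                            weights = loss_weights(), strain_window = 43L) {
  fr <- sequence_frames(frames)
  n <- length(fr)
  if (length(displacements) != n - 1L)
    stop("sequence_scores: need one displacement per consecutive pair")
  if (is.null(strains))
    strains <- lapply(displacements, function(d)
      lsq_strain(as_displacement_field(d)$axial, strain_window))
  sim <- cons <- rep(NA_real_, n - 1L)
  for (t in seq_len(n - 1L)) {
    d <- as_displacement_field(displacements[[t]])
    wp <- warp_image(normalize_frame(fr[[t + 1L]]), d)
    sim[t] <- lncc(normalize_frame(fr[[t]]), wp$image, weights$lncc_window,
                   wp$mask, weights$epsilon)
    if (t > 1L) {
      ws <- warp_image(strain_values(strains[[t]]), d)
      # degenerate (constant) strain maps have no valid NCC windows -> NA
      cons[t] <- tryCatch(
        lncc(strain_values(strains[[t - 1L]]), ws$image,
             weights$lncc_window, ws$mask, weights$epsilon),
        error = function(e) NA_real_)
    }
  }
  data.frame(step = seq_len(n - 1L), similarity = sim, consistency = cons)
}

#' Target registration error
#'
#' Mean Euclidean distance (pixels) between last-frame landmarks and their
#' first-frame counterparts mapped through the displacement field. The field
#' must map first-frame coordinates into the last frame (for multi-frame
#' sequences, compose the consecutive-pair predictions with
#' [compose_displacements()]); the field is sampled bilinearly at each
#' landmark.
#'
#' @param landmarks a data frame (or matrix) with columns
#'   `first_axial, first_lateral, last_axial, last_lateral` in 0-based sample
#'   coordinates, one row per landmark pair (the standard protocol uses 8).
#' @param displacement [displacement_field()] from first- to last-frame
#'   coordinates.
#' @return mean TRE in pixels.
#' @export
tre <- function(landmarks, displacement) {
  lm <- as.data.frame(landmarks)
  need <- c("first_axial", "first_lateral", "last_axial", "last_lateral")
  if (!all(need %in% names(lm))) {
    if (ncol(lm) >= 4) names(lm)[1:4] <- need
    else stop("tre: need 4 landmark coordinate columns")
  }
  d <- as_displacement_field(displacement)
  h <- nrow(d$axial); w <- ncol(d$axial)
  if (any(lm$first_axial < 0 | lm$first_axial > h - 1 |
          lm$first_lateral < 0 | lm$first_lateral > w - 1 |
          lm$last_axial < 0 | lm$last_axial > h - 1 |
          lm$last_lateral < 0 | lm$last_lateral > w - 1))
    stop("tre: landmark outside the frame grid")
  sample_field <- function(f, y, x) {
    i0 <- pmin(pmax(floor(y), 0), h - 2); j0 <- pmin(pmax(floor(x), 0), w - 2)
    fy <- y - i0; fx <- x - j0
    f11 <- f[cbind(i0 + 1, j0 + 1)]; f21 <- f[cbind(i0 + 2, j0 + 1)]
    f12 <- f[cbind(i0 + 1, j0 + 2)]; f22 <- f[cbind(i0 + 2, j0 + 2)]
    (1 - fy) * (1 - fx) * f11 + fy * (1 - fx) * f21 +
      (1 - fy) * fx * f12 + fy * fx * f22
  }
  my <- lm$first_axial + sample_field(d$axial, lm$first_axial, lm$first_lateral)
  mx <- lm$first_lateral + sample_field(d$lateral, lm$first_axial, lm$first_lateral)
  mean(sqrt((my - lm$last_axial)^2 + (mx - lm$last_lateral)^2))
}

#' Cumulative displacement NRMSE of a predicted sequence
#'
#' Composes the consecutive-pair predictions into first-frame-to-frame-t
#' displacements and scores each against the analytic ground truth,
#' mirroring the per-compression-level evaluation protocol of
#' increasing-compression sequences.
#'
#' @param displacements list of per-pair [displacement_field()]s.
#' @param ground_truth per-step ground truth list from [simulate_sequence()].
#' @return data frame with per-step `nrmse` (axial, percent).
#' @export
sequence_nrmse <- function(displacements, ground_truth) {
  stopifnot(length(displacements) == length(ground_truth))
  out <- numeric(length(displacements))
  cum <- NULL
  for (t in seq_along(displacements)) {
    d <- as_displacement_field(displacements[[t]])
    cum <- if (is.null(cum)) d else compose_displacements(d, cum)
    out[t] <- nrmse(cum$axial, ground_truth[[t]]$displacement$axial)
  }
  data.frame(step = seq_along(out), nrmse = out)
}
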