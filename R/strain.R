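#' Strain fields
#'
#' Axial strain maps derived from an axial displacement field. Values are
#' dimensionless; the package reports compressive strain as positive (the raw
#' axial derivative of displacement is negated), so a stiff inclusion appears
#' as a low-strain region in a compressed phantom.
#'
#' @param values numeric matrix of strain values.
#' @param window_length axial extent (samples) of the estimator that produced
#'   the map; 3 for plain gradient.
#' @export
strain_field <- function(values, window_length = NA_integer_) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("strain_field: non-finite values")
  structure(list(values = values, window_length = window_length),
            class = "strain_field")
}

strain_values <- function(s) if (inherits(s, "strain_field")) s$values else as.matrix(s)

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field %d x %d> mean %.4f (window %s)\n",
              nrow(x$values), ncol(x$values), mean(x$values),
              as.character(x$window_length)))
  invisible(x)
}

# Coefficient matrix of the column-wise least-squares slope: strain = -K %*% u.
# Row y holds the OLS slope weights (i - mean(i)) / sum((i - mean(i))^2) over
# the centered window, shrunk one-sided at the borders. Cached per (H, L).
lsq_coef_matrix <- function(h, window_length) {
  key <- sprintf("lsqK_%d_%d", h, window_length)
  K <- .elastnet_cache[[key]]
  if (!is.null(K)) return(K)
  hw <- (window_length - 1L) %/% 2L
  K <- matrix(0, h, h)
  for (y in seq_len(h)) {
    idx <- max(1L, y - hw):min(h, y + hw)
    ic <- idx - mean(idx)
    K[y, idx] <- ic / sum(ic^2)
  }
  .elastnet_cache[[key]] <- K
  K
}

#' Least-squares strain estimator (LSQSE)
#'
#' Per scan line, the strain at depth y is the slope of an ordinary
#' least-squares line fitted to axial displacement over a centered axial
#' window, negated so compression is positive. Windowed regression averages
#' out displacement jitter and is the standard way to raise the elastographic
#' SNR over direct differentiation. Borders use shrunken one-sided windows.
#'
#' @param axial_displacement numeric matrix (axial samples x scan lines), or a
#'   [displacement_field()] whose axial channel is used.
#' @param window_length odd integer >= 3, axial window in samples. The source
#'   publication does not state its value; the default 43 is this package's
#'   recorded choice and is echoed into every run configuration.
#' @return a [strain_field()].
#' @export
lsq_strain <- function(axial_displacement, window_length = 43L) {
  u <- if (inherits(axial_displacement, "displacement_field"))
    axial_displacement$axial else as.matrix(axial_displacement)
  window_length <- as.integer(window_length)
  if (window_length %% 2L == 0L) stop("lsq_strain: window_length must be odd")
  if (window_length < 3L) stop("lsq_strain: window_length must be >= 3")
  if (window_length > nrow(u)) stop("lsq_strain: window longer than axial extent")
  K <- lsq_coef_matrix(nrow(u), window_length)
  strain_field(-(K %*% u), window_length)
}

# Adjoint of lsq_strain for backpropagation: g_u = -t(K) %*% g_s.
lsq_strain_adj <- function(g_strain, window_length) {
  K <- lsq_coef_matrix(nrow(g_strain), as.integer(window_length))
  -(t(K) %*% g_strain)
}

#' Plain-gradient strain (reference estimator)
#'
#' Negated central finite difference of axial displacement along depth, with
#' one-sided differences at the borders. Noisy in practice; kept as the
#' reference against which the least-squares estimator is compared.
#'
#' @inheritParams lsq_strain
#' @export
gradient_strain <- function(axial_displacement) {
  u <- if (inherits(axial_displacement, "displacement_field"))
    axial_displacement$axial else as.matrix(axial_displacement)
  h <- nrow(u)
  if (h < 2L) stop("gradient_strain: need at least two axial samples")
  g <- matrix(0, h, ncol(u))
  if (h > 2L) g[2:(h - 1), ] <- (u[3:h, ] - u[1:(h - 2), ]) / 2
  g[1, ] <- u[2, ] - u[1, ]
  g[h, ] <- u[h, ] - u[h - 1, ]
  strain_field(-g, 3L)
}
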