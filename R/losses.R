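#' Loss weights and windows for unsupervised training
#'
#' The training objective is
#' `L_total = L_sim + alpha * L_reg + beta * L_cons`, combining image
#' similarity, strain-smoothness regularisation and temporal strain
#' consistency. Defaults follow the published setting: `alpha = 5`,
#' `beta = 0.2` (with `beta` forced to zero for the feed-forward variant,
#' which has no previous strain estimate).
#'
#' @param alpha non-negative weight of the smoothness term.
#' @param beta non-negative weight of the consistency term.
#' @param lncc_window odd `c(h, w)` window of the local NCC; the window size
#'   is not stated in the source publication, 15x15 is this package's default.
#' @param epsilon variance guard added to the LNCC denominator.
#' @param strain_window LSQSE window used when strain maps are needed inside
#'   the loss (consistency term).
#' @export
loss_weights <- function(alpha = 5, beta = 0.2, lncc_window = c(15L, 15L),
                         epsilon = 1e-5, strain_window = 43L) {
  stopifnot(alpha >= 0, beta >= 0, epsilon > 0,
            length(lncc_window) == 2, all(lncc_window %% 2 == 1))
  structure(list(alpha = alpha, beta = beta,
                 lncc_window = as.integer(lncc_window),
                 epsilon = epsilon, strain_window = as.integer(strain_window)),
            class = "loss_weights")
}

# Local moments shared by lncc value and gradient. Windows slide with stride 1
# and must lie fully inside the image; windows touching a masked (invalid)
# pixel or with standard deviation below epsilon are skipped.
lncc_moments <- function(a, b, window, mask, epsilon) {
  h <- nrow(a); w <- ncol(a)
  wh <- window[1]; ww <- window[2]
  if (wh > h || ww > w) stop("lncc: window larger than image")
  n <- wh * ww
  rh <- (wh - 1L) %/% 2L; rw <- (ww - 1L) %/% 2L
  rows <- (rh + 1L):(h - rh); cols <- (rw + 1L):(w - rw)
  sa <- en_boxfilter(a, wh, ww)[rows, cols, drop = FALSE]
  sb <- en_boxfilter(b, wh, ww)[rows, cols, drop = FALSE]
  sab <- en_boxfilter(a * b, wh, ww)[rows, cols, drop = FALSE]
  saa <- en_boxfilter(a * a, wh, ww)[rows, cols, drop = FALSE]
  sbb <- en_boxfilter(b * b, wh, ww)[rows, cols, drop = FALSE]
  mua <- sa / n; mub <- sb / n
  cab <- sab - n * mua * mub
  va <- pmax(saa - n * mua^2, 0)
  vb <- pmax(sbb - n * mub^2, 0)
  keep <- sqrt(va / n) >= epsilon & sqrt(vb / n) >= epsilon
  if (!is.null(mask)) {
    mok <- en_boxfilter(mask, wh, ww)[rows, cols, drop = FALSE]
    keep <- keep & (mok > n - 0.5)
  }
  list(rows = rows, cols = cols, n = n, mua = mua, mub = mub,
       cab = cab, va = va, vb = vb, keep = keep)
}

#' Local normalised cross-correlation
#'
#' Mean over sliding windows (stride 1, computed with box-filtered local
#' moments) of the windowed NCC
#' `sum((W1 - mu1) * (W2 - mu2)) / (N * sigma1 * sigma2 + epsilon)`,
#' an intensity-affine-invariant similarity in `[-1, 1]`. Windows containing
#' a masked pixel, or with local standard deviation below `epsilon`, are
#' excluded from the average.
#'
#' @param a,b numeric matrices of equal shape.
#' @param window odd `c(h, w)` window size.
#' @param mask optional validity matrix (1 = valid), e.g. from [warp_image()].
#' @param epsilon variance guard.
#' @return scalar LNCC value.
#' @export
lncc <- function(a, b, window = c(15L, 15L), mask = NULL, epsilon = 1e-5) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("lncc: shape mismatch")
  m <- lncc_moments(a, b, as.integer(window), mask, epsilon)
  if (!any(m$keep)) stop("lncc: no valid windows (unusable overlap)")
  ncc <- m$cab / (sqrt(m$va * m$vb) + epsilon)
  mean(ncc[m$keep])
}

# lncc value together with its gradient with respect to b. The per-window
# coefficients are scattered back to pixels with a second box filter (the box
# filter is its own adjoint for stride-1 windows).
lncc_with_grad_b <- function(a, b, window, mask, epsilon) {
  h <- nrow(a); w <- ncol(a)
  m <- lncc_moments(a, b, as.integer(window), mask, epsilon)
  if (!any(m$keep)) stop("lncc: no valid windows (unusable overlap)")
  den <- sqrt(m$va * m$vb) + epsilon
  ncc <- m$cab / den
  M <- sum(m$keep)
  value <- sum(ncc[m$keep]) / M
  alpha <- ifelse(m$keep, 1 / den, 0)
  beta <- ifelse(m$keep, m$cab * m$va / (pmax(sqrt(m$va * m$vb), epsilon^2) * den^2), 0)
  pad <- function(x) {
    full <- matrix(0, h, w)
    full[m$rows, m$cols] <- x
    full
  }
  wh <- window[1]; ww <- window[2]
  boxa <- en_boxfilter(pad(alpha), wh, ww)
  boxam <- en_boxfilter(pad(alpha * m$mua), wh, ww)
  boxb <- en_boxfilter(pad(beta), wh, ww)
  boxbm <- en_boxfilter(pad(beta * m$mub), wh, ww)
  gb <- (a * boxa - boxam - b * boxb + boxbm) / M
  list(value = value, grad_b = gb)
}

#' Image similarity loss
#'
#' `-LNCC(pre, warp(post, displacement))`: the negative local normalised
#' cross-correlation between the pre-compression frame and the
#' motion-compensated post-compression frame. Minimal value is -1, attained
#' when the displacement exactly compensates the deformation.
#'
#' @param pre,post numeric matrices (RF frames).
#' @param displacement [displacement_field()] predicted for the pair.
#' @param weights a [loss_weights()].
#' @export
similarity_loss <- function(pre, post, displacement, weights = loss_weights()) {
  wp <- warp_image(post, displacement)
  -lncc(pre, wp$image, weights$lncc_window, wp$mask, weights$epsilon)
}

# similarity loss + gradient w.r.t. the displacement channels
similarity_loss_grad <- function(pre, post, displacement, weights) {
  d <- as_displacement_field(displacement)
  r <- en_warp(array(as.matrix(post), c(dim(d$axial), 1L)), d$axial, d$lateral)
  lg <- lncc_with_grad_b(as.matrix(pre), r$out[, , 1], weights$lncc_window,
                         r$mask, weights$epsilon)
  bw <- en_warp_bwd(array(as.matrix(post), c(dim(d$axial), 1L)),
                    d$axial, d$lateral,
                    array(-lg$grad_b, c(dim(d$axial), 1L)))
  list(value = -lg$value, g_axial = bw$gdy, g_lateral = bw$gdx)
}

# interior second differences of a matrix: d2y, d2x, and the mixed partial
# (central first differences applied twice; the two application orders
# coincide for central stencils and are both counted).
second_diffs <- function(u) {
  h <- nrow(u); w <- ncol(u)
  if (h < 3 || w < 3) stop("smoothness_loss: grid too small")
  i <- 2:(h - 1); j <- 2:(w - 1)
  d2y <- u[i - 1, j] - 2 * u[i, j] + u[i + 1, j]
  d2x <- u[i, j - 1] - 2 * u[i, j] + u[i, j + 1]
  dxy <- (u[i + 1, j + 1] - u[i + 1, j - 1] - u[i - 1, j + 1] + u[i - 1, j - 1]) / 4
  list(i = i, j = j, d2y = d2y, d2x = d2x, dxy = dxy)
}

#' Strain-smoothness (regularisation) loss
#'
#' L1 norm of the strain spatial gradient: since strain is the first
#' derivative of displacement, this is the mean over interior pixels of the
#' absolute second-order derivatives of the predicted axial displacement,
#' `|d2u/dx2| + |dxdy u| + |d2u/dy2| + |dydx u|`. Vanishes exactly on affine
#' displacement fields (constant strain). Averaged (not summed) over pixels so
#' `alpha` transfers across image sizes.
#'
#' @param displacement [displacement_field()] or axial-displacement matrix.
#' @param weights a [loss_weights()] (unused beyond signature symmetry).
#' @param include_lateral also penalise the lateral channel (off by default;
#'   the published objective regularises the axial displacement).
#' @export
smoothness_loss <- function(displacement, weights = loss_weights(),
                            include_lateral = FALSE) {
  d <- if (inherits(displacement, "displacement_field")) displacement
       else displacement_field(as.matrix(displacement))
  term <- function(u) {
    s <- second_diffs(u)
    mean(abs(s$d2x) + abs(s$d2y) + 2 * abs(s$dxy))
  }
  v <- term(d$axial)
  if (include_lateral) v <- v + term(d$lateral)
  v
}

smoothness_loss_grad <- function(u) {
  s <- second_diffs(u)
  h <- nrow(u); w <- ncol(u)
  npix <- length(s$d2y)
  g <- matrix(0, h, w)
  add <- function(g, di, dj, m) {
    g[s$i + di, s$j + dj] <- g[s$i + di, s$j + dj] + m
    g
  }
  sy <- sign(s$d2y) / npix
  g <- add(g, -1L, 0L, sy); g <- add(g, 0L, 0L, -2 * sy); g <- add(g, 1L, 0L, sy)
  sx <- sign(s$d2x) / npix
  g <- add(g, 0L, -1L, sx); g <- add(g, 0L, 0L, -2 * sx); g <- add(g, 0L, 1L, sx)
  sm <- 2 * sign(s$dxy) / (4 * npix)   # both mixed-order terms
  g <- add(g, 1L, 1L, sm); g <- add(g, -1L, -1L, sm)
  g <- add(g, 1L, -1L, -sm); g <- add(g, -1L, 1L, -sm)
  list(value = mean(abs(s$d2x) + abs(s$d2y) + 2 * abs(s$dxy)), grad = g)
}

#' Temporal strain-consistency loss
#'
#' `-LNCC(S_prev, warp(S_curr, displacement))`: successive strain estimates of
#' a sequence should depict the same stiffness pattern once motion-compensated
#' with the current spatial transformation. Used only for the recurrent
#' variant (`beta = 0` for the feed-forward network).
#'
#' @param strain_prev,strain_curr [strain_field()]s (or matrices) of the
#'   previous and current step.
#' @param displacement current-step [displacement_field()].
#' @param weights a [loss_weights()].
#' @export
consistency_loss <- function(strain_prev, strain_curr, displacement,
                             weights = loss_weights()) {
  wp <- warp_image(strain_values(strain_curr), displacement)
  -lncc(strain_values(strain_prev), wp$image, weights$lncc_window, wp$mask,
        weights$epsilon)
}

# consistency loss + gradients w.r.t. current strain map and displacement;
# the previous strain is treated as a fixed target.
consistency_loss_grad <- function(strain_prev, strain_curr, displacement,
                                  weights) {
  d <- as_displacement_field(displacement)
  sc <- strain_values(strain_curr)
  r <- en_warp(array(sc, c(dim(sc), 1L)), d$axial, d$lateral)
  lg <- lncc_with_grad_b(strain_values(strain_prev), r$out[, , 1],
                         weights$lncc_window, r$mask, weights$epsilon)
  bw <- en_warp_bwd(array(sc, c(dim(sc), 1L)), d$axial, d$lateral,
                    array(-lg$grad_b, c(dim(sc), 1L)))
  list(value = -lg$value, g_strain = bw$gimg[, , 1],
       g_axial = bw$gdy, g_lateral = bw$gdx)
}

#' Combine loss terms
#'
#' Exact weighted sum `total = sim + alpha * reg + beta * cons`, keeping the
#' parts for logging. A positive `beta` requires a consistency value: the
#' first pair of a sequence, and the feed-forward variant, have no previous
#' strain, so `beta` must be zero there.
#'
#' @param sim,reg scalar similarity and regularisation losses.
#' @param cons scalar consistency loss, or `NULL` when no previous strain
#'   exists.
#' @param weights a [loss_weights()].
#' @return list of class `loss_breakdown` with `sim`, `reg`, `cons`, `total`.
#' @export
total_loss <- function(sim, reg, cons = NULL, weights = loss_weights()) {
  if (is.null(cons) || is.na(cons)) {
    if (weights$beta > 0)
      stop("total_loss: beta > 0 but no previous strain/consistency value")
    cons <- 0
  }
  structure(list(sim = sim, reg = reg, cons = cons,
                 total = sim + weights$alpha * reg + weights$beta * cons),
            class = "loss_breakdown")
}
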