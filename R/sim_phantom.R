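#' Phantom specification for the quasi-static compression simulator
#'
#' Describes a speckle phantom imaged under monotonically increasing axial
#' compression: grid size, scatterer density, stiff inclusions, the cumulative
#' strain applied at each step, lateral probe drift, additive noise, and the
#' separable point-spread function of the convolution speckle model.
#'
#' The deformation model is analytic: local axial strain is the applied
#' average strain modulated by Gaussian "stiffness bumps" centred on the
#' inclusions, so displacement, strain and their inverses have closed forms
#' and serve as an exact test oracle (in place of finite-element phantoms).
#'
#' @param grid_shape `c(axial_samples, lateral_lines)`.
#' @param scatterer_density scatterers per pixel (> 0).
#' @param inclusions list of inclusions, each
#'   `c(center_axial, center_lateral, radius, strain_contrast)` in normalised
#'   `[0, 1]` coordinates; `strain_contrast` in `(0, 1]` is the ratio of
#'   inclusion-centre strain to background strain (stiff inclusions strain
#'   less).
#' @param strain_schedule non-decreasing cumulative average axial strains
#'   (fractions, each in `[0, 0.10]`); the sequence has
#'   `length(strain_schedule) + 1` frames. The default, 0.5% to 4.5% in 0.5%
#'   steps, yields the canonical 10-frame increasing-compression sequence.
#' @param lateral_drift maximal lateral probe translation (samples), reached
#'   at the last step.
#' @param noise_sigma additive Gaussian noise std, relative to the std of the
#'   clean RF frame.
#' @param psf `c(center_cycles_per_sample, axial_sigma, lateral_sigma)` of the
#'   cosine-modulated Gaussian point-spread function. The default 0.25
#'   cycles/sample emulates a 5 MHz pulse sampled at 20 MHz.
#' @param poisson_ratio lateral expansion ratio of the near-incompressible
#'   tissue model.
#' @param seed integer seed making the rendered sequence reproducible.
#' @export
phantom_spec <- function(grid_shape = c(1024L, 128L),
                         scatterer_density = 1.5,
                         inclusions = list(c(0.5, 0.5, 0.15, 0.5)),
                         strain_schedule = seq(0.005, 0.045, by = 0.005),
                         lateral_drift = 0.5,
                         noise_sigma = 0.05,
                         psf = c(0.25, 2, 1.5),
                         poisson_ratio = 0.495,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 2))
    stop("phantom_spec: invalid grid_shape")
  if (scatterer_density < 0) stop("phantom_spec: scatterer_density must be >= 0")
  if (is.unsorted(strain_schedule))
    stop("phantom_spec: strain_schedule must be non-decreasing")
  if (any(strain_schedule < 0 | strain_schedule > 0.10))
    stop("phantom_spec: strains must lie in [0, 0.10]")
  for (inc in inclusions) {
    if (length(inc) != 4) stop("phantom_spec: inclusion needs 4 components")
    if (inc[3] <= 0) stop("phantom_spec: inclusion radius must be > 0")
    if (inc[4] <= 0 || inc[4] > 1)
      stop("phantom_spec: strain_contrast must be in (0, 1]")
  }
  structure(list(grid_shape = grid_shape,
                 scatterer_density = scatterer_density,
                 inclusions = inclusions,
                 strain_schedule = as.numeric(strain_schedule),
                 lateral_drift = lateral_drift,
                 noise_sigma = noise_sigma,
                 psf = psf,
                 poisson_ratio = poisson_ratio,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Random phantom specification
#'
#' Draws one or two stiff inclusions with random positions, radii and strain
#' contrast, emulating phantoms with inclusions of 40-60 kPa in a softer
#' background.
#'
#' @param seed integer seed.
#' @param grid_shape passed to [phantom_spec()].
#' @param ... further arguments passed to [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, grid_shape = c(1024L, 128L), ...) {
  with_seed(seed, {
    k <- sample(1:2, 1)
    inclusions <- lapply(seq_len(k), function(i)
      c(runif(1, 0.25, 0.75), runif(1, 0.25, 0.75),
        runif(1, 0.08, 0.18), runif(1, 0.4, 0.7)))
    phantom_spec(grid_shape = grid_shape, inclusions = inclusions,
                 seed = seed, ...)
  })
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample a random scatterer population
#'
#' Positions are continuous 0-based sample coordinates, uniform over the grid;
#' reflectivities are standard normal. The count is
#' `round(density * axial * lateral)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (defaults to the spec's).
#' @return list with `positions` (n x 2 matrix, axial/lateral) and
#'   `amplitudes`.
#' @export
sample_scatterers <- function(spec, seed = spec$seed) {
  if (spec$scatterer_density < 0) stop("sample_scatterers: invalid density")
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  n <- round(spec$scatterer_density * h * w)
  with_seed(seed, {
    pos <- cbind(axial = runif(n, 0, h - 1), lateral = runif(n, 0, w - 1))
    list(positions = pos, amplitudes = rnorm(n))
  })
}

# Closed-form deformation model. Local strain at normalised position (ny, nx):
#   eps = s * (1 - sum_k (1 - contrast_k) * exp(-d_k^2 / (2 r_k^2)))
# and axial displacement is its exact depth integral (error function form).
# `y`, `x` are continuous 0-based sample coordinates; vectorised.
analytic_eval <- function(spec, s, frac, y, x, what = c("disp", "strain")) {
  what <- match.arg(what)
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  ny <- y / (h - 1); nx <- x / (w - 1)
  if (what == "strain") {
    mod <- rep(1, length(ny))
    for (inc in spec$inclusions) {
      d2 <- (ny - inc[1])^2 + (nx - inc[2])^2
      mod <- mod - (1 - inc[4]) * exp(-d2 / (2 * inc[3]^2))
    }
    return(s * mod)
  }
  u <- s * y
  for (inc in spec$inclusions) {
    r <- inc[3]
    lat <- exp(-(nx - inc[2])^2 / (2 * r^2))
    # integral of exp(-(t - cy)^2 / (2 r^2)) dt from 0 to ny, in sample units
    iy <- (h - 1) * r * sqrt(2 * pi) *
      (pnorm((ny - inc[1]) / r) - pnorm((0 - inc[1]) / r))
    u <- u - s * (1 - inc[4]) * lat * iy
  }
  ulat <- spec$lateral_drift * frac +
    spec$poisson_ratio * s * (x - (w - 1) / 2)
  cbind(axial = u, lateral = ulat)
}

# invert the forward scatterer motion p -> p + u(p): given rest positions,
# nothing to invert; given compressed target = rest mapping see
# simulate_sequence. Here: solve q + u(q) = p for q by fixed-point iteration
# (the strain magnitudes involved make this a strong contraction).
analytic_inverse <- function(spec, s, frac, y, x, iters = 8L) {
  qy <- y; qx <- x
  for (i in seq_len(iters)) {
    u <- analytic_eval(spec, s, frac, qy, qx, "disp")
    qy <- y - u[, 1]
    qx <- x - u[, 2]
  }
  cbind(axial = qy, lateral = qx)
}

#' Ground-truth displacement and strain at a compression level
#'
#' Evaluates the analytic deformation model on the pixel grid. The returned
#' displacement lives on the reference (uncompressed) grid and maps it into
#' the compressed frame, so `warp_image(compressed_frame, displacement)`
#' reconstructs the reference frame; the returned strain is the exact local
#' axial strain (positive = compression).
#'
#' @param spec a [phantom_spec()].
#' @param cumulative_strain average axial strain in `[0, 0.10]`.
#' @param step_fraction position of this step in the sequence (0..1), used for
#'   the lateral drift term; defaults to `cumulative_strain` relative to the
#'   schedule maximum.
#' @return list with `displacement` ([displacement_field()]) and `strain`
#'   ([strain_field()]).
#' @export
analytic_displacement <- function(spec, cumulative_strain,
                                  step_fraction = NULL) {
  if (cumulative_strain < 0 || cumulative_strain > 0.10)
    stop("analytic_displacement: cumulative_strain out of [0, 0.10]")
  if (is.null(step_fraction)) {
    mx <- if (length(spec$strain_schedule)) max(spec$strain_schedule) else 0
    step_fraction <- if (mx > 0) cumulative_strain / mx else 0
  }
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  g <- expand.grid(y = 0:(h - 1), x = 0:(w - 1))
  u <- analytic_eval(spec, cumulative_strain, step_fraction, g$y, g$x, "disp")
  eps <- analytic_eval(spec, cumulative_strain, step_fraction, g$y, g$x, "strain")
  list(displacement = displacement_field(matrix(u[, 1], h, w),
                                         matrix(u[, 2], h, w)),
       strain = strain_field(matrix(eps, h, w)))
}

#' Render an RF frame from a scatterer population
#'
#' Deposits scatterer reflectivities on the grid by bilinear splatting and
#' convolves with a separable cosine-modulated Gaussian point-spread function
#' `h(y, x) = cos(2 pi f_c y) exp(-y^2 / 2 s_y^2) exp(-x^2 / 2 s_x^2)`,
#' a standard convolution speckle model for linear-array RF data. Additive
#' Gaussian noise is scaled by the clean frame's standard deviation.
#'
#' @param scatterers output of [sample_scatterers()] (positions may have been
#'   displaced).
#' @param spec a [phantom_spec()].
#' @param add_noise add the spec's noise (uses the current RNG stream).
#' @return numeric matrix (axial samples x scan lines).
#' @export
render_rf <- function(scatterers, spec, add_noise = spec$noise_sigma > 0) {
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  grid <- en_splat(scatterers$positions[, 1], scatterers$positions[, 2],
                   scatterers$amplitudes, h, w)
  fc <- spec$psf[1]; sy <- spec$psf[2]; sx <- spec$psf[3]
  ly <- ceiling(4 * sy); lx <- ceiling(3 * sx)
  ky <- cos(2 * pi * fc * (-ly:ly)) * exp(-(-ly:ly)^2 / (2 * sy^2))
  kx <- exp(-(-lx:lx)^2 / (2 * sx^2))
  x <- array(grid, c(h, w, 1L))
  x <- en_conv2d(x, array(ky, c(length(ky), 1L, 1L, 1L)), 0)
  x <- en_conv2d(x, array(kx, c(1L, length(kx), 1L, 1L)), 0)
  rf <- x[, , 1]
  if (add_noise && spec$noise_sigma > 0) {
    rf <- rf + rnorm(length(rf), sd = spec$noise_sigma * sd(rf))
  }
  rf
}

#' Simulate an RF sequence under increasing compression
#'
#' Frame 1 is rendered from the rest-state scatterers; frame `t + 1` from the
#' same scatterers moved by the closed-form deformation at cumulative strain
#' `strain_schedule[t]` (the speckle pattern is re-rendered after moving the
#' scatterers, so genuine speckle decorrelation under compression is present).
#' Ground truth stores, per compression step, the cumulative
#' reference-to-frame displacement, the consecutive-pair displacement, and the
#' analytic strain.
#'
#' @param spec a [phantom_spec()].
#' @return list with `frames` (list of RF matrices, length
#'   `length(strain_schedule) + 1`), `ground_truth` (per-step list with
#'   `displacement`, `pair_displacement`, `strain`), and `spec`.
#' @export
simulate_sequence <- function(spec) {
  sc <- sample_scatterers(spec, spec$seed)
  h <- spec$grid_shape[1]; w <- spec$grid_shape[2]
  Tn <- length(spec$strain_schedule)
  with_seed(spec$seed + 1L, {
    frames <- vector("list", Tn + 1L)
    gt <- vector("list", Tn)
    frames[[1]] <- render_rf(sc, spec)
    g <- expand.grid(y = 0:(h - 1), x = 0:(w - 1))
    for (t in seq_len(Tn)) {
      s <- spec$strain_schedule[t]
      frac <- t / Tn
      u <- analytic_eval(spec, s, frac, sc$positions[, 1], sc$positions[, 2],
                         "disp")
      moved <- list(positions = cbind(sc$positions[, 1] + u[, 1],
                                      sc$positions[, 2] + u[, 2]),
                    amplitudes = sc$amplitudes)
      frames[[t + 1L]] <- render_rf(moved, spec)
      cum <- analytic_displacement(spec, s, frac)
      if (t == 1L) {
        pair <- cum$displacement
      } else {
        sp <- spec$strain_schedule[t - 1L]; fp <- (t - 1) / Tn
        # reference grid of frame t-1: rest point q with q + u_{t-1}(q) = p
        q <- analytic_inverse(spec, sp, fp, g$y, g$x)
        uq <- analytic_eval(spec, s, frac, q[, 1], q[, 2], "disp")
        pair <- displacement_field(
          matrix(q[, 1] + uq[, 1] - g$y, h, w),
          matrix(q[, 2] + uq[, 2] - g$x, h, w))
      }
      gt[[t]] <- list(displacement = cum$displacement,
                      pair_displacement = pair,
                      strain = cum$strain)
    }
    list(frames = frames, ground_truth = gt, spec = spec)
  })
}
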