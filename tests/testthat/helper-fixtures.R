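# Shared fixtures and independent oracles used across test files.

# small phantom spec for fast simulator tests
tiny_spec <- function(seed = 7, noise = 0.05, ...) {
  phantom_spec(grid_shape = c(64L, 64L),
               inclusions = list(c(0.5, 0.5, 0.15, 0.5)),
               strain_schedule = seq(0.005, 0.045, by = 0.005),
               noise_sigma = noise, lateral_drift = 0.3, seed = seed, ...)
}

# memoise one noiseless and one noisy simulated sequence per session
fixture_env <- new.env()
get_sim <- function(noise = 0) {
  key <- paste0("sim_", noise)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- simulate_sequence(tiny_spec(noise = noise))
  fixture_env[[key]]
}

# brute-force sliding-window NCC (the printed formula, one window at a time)
lncc_oracle <- function(a, b, wh, ww, eps = 1e-5) {
  h <- nrow(a); w <- ncol(a)
  rh <- (wh - 1) / 2; rw <- (ww - 1) / 2
  vals <- c()
  for (i in (rh + 1):(h - rh)) for (j in (rw + 1):(w - rw)) {
    wa <- a[(i - rh):(i + rh), (j - rw):(j + rw)]
    wb <- b[(i - rh):(i + rh), (j - rw):(j + rw)]
    n <- length(wa)
    sa <- sqrt(mean((wa - mean(wa))^2)); sb <- sqrt(mean((wb - mean(wb))^2))
    if (sa < eps || sb < eps) next
    vals <- c(vals, sum((wa - mean(wa)) * (wb - mean(wb))) / (n * sa * sb + eps))
  }
  mean(vals)
}

# per-window ordinary least squares slope (explicit solve, column-wise)
lsq_oracle <- function(u, L) {
  h <- nrow(u); hw <- (L - 1) / 2
  out <- matrix(0, h, ncol(u))
  for (j in seq_len(ncol(u))) for (y in seq_len(h)) {
    idx <- max(1, y - hw):min(h, y + hw)
    fit <- stats::lm.fit(cbind(1, idx), u[idx, j])
    out[y, j] <- -fit$coefficients[2]
  }
  out
}

# exhaustive integer-shift NCC block matching between two frames
block_match_oracle <- function(f0, f1, bh = 32, bw = 16, search = 4) {
  h <- nrow(f0); w <- ncol(f0)
  res <- list()
  # keep the whole search range inside the frame for every block
  for (i0 in seq(1 + search, h - bh + 1 - search, by = bh)) {
   for (j0 in seq(1, w - bw + 1, by = bw)) {
    blk <- f0[i0:(i0 + bh - 1), j0:(j0 + bw - 1)]
    best <- -Inf; bdy <- 0
    for (dy in -search:search) {
      i1 <- i0 + dy
      if (i1 < 1 || i1 + bh - 1 > h) next
      cand <- f1[i1:(i1 + bh - 1), j0:(j0 + bw - 1)]
      v <- suppressWarnings(stats::cor(as.numeric(blk), as.numeric(cand)))
      if (is.finite(v) && v > best) { best <- v; bdy <- dy }
    }
    res[[length(res) + 1]] <- c(ci = i0 + (bh - 1) / 2, cj = j0 + (bw - 1) / 2,
                                dy = bdy)
   }
  }
  do.call(rbind, res)
}

rand_field <- function(h, w, scale = 1, seed = NULL, smooth = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  f <- matrix(rnorm(h * w), h, w)
  if (smooth) {
    k <- stats::dnorm(-3:3, sd = 1.5); k <- k / sum(k)
    f <- apply(f, 2, function(col) stats::filter(col, k, circular = TRUE))
    f <- t(apply(f, 1, function(row) stats::filter(row, k, circular = TRUE)))
  }
  f * scale
}
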