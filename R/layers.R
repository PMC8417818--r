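# Layer primitives with explicit forward caches and hand-derived backward
# passes. Feature maps are H x W x C arrays; parameters live in flat named
# lists so the optimiser can treat the model as a vector of tensors.

lrelu_fwd <- function(x, slope) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg)
}

lrelu_bwd <- function(cache, gy, slope) {
  gx <- gy
  gx[cache$neg] <- slope * gy[cache$neg]
  gx
}

# Batch normalisation over the spatial extent of each channel (the training
# unit is a single sequence, so per-forward spatial statistics are used).
bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, d), xhat = xhat, invstd = invstd, dim = d)
}

bn_bwd <- function(cache, gamma, gy) {
  d <- cache$dim; n <- d[1] * d[2]
  gym <- matrix(gy, n, d[3])
  dgamma <- colSums(gym * cache$xhat)
  dbeta <- colSums(gym)
  gxh <- sweep(gym, 2, gamma, `*`)
  m1 <- colMeans(gxh)
  m2 <- colMeans(gxh * cache$xhat)
  gx <- sweep(gxh, 2, m1) - sweep(cache$xhat, 2, m2, `*`)
  gx <- sweep(gx, 2, cache$invstd, `*`)
  list(gx = array(gx, d), dgamma = dgamma, dbeta = dbeta)
}

# Bilinear-additive upsampling (no parameters): 2x bilinear upsample followed
# by channel-group averaging (cin = r * cout) or channel repetition
# (cout = r * cin).
addup_fwd <- function(x, cout) {
  d <- dim(x); cin <- d[3]
  y <- en_resize_bilinear(x, 2L * d[1], 2L * d[2])
  if (cin == cout) return(y)
  if (cin %% cout == 0L) {
    r <- cin %/% cout
    out <- array(0, c(2L * d[1], 2L * d[2], cout))
    for (c in seq_len(cout)) {
      acc <- y[, , (c - 1L) * r + 1L]
      if (r > 1L) for (q in 2:r) acc <- acc + y[, , (c - 1L) * r + q]
      out[, , c] <- acc / r
    }
    return(out)
  }
  if (cout %% cin == 0L) {
    r <- cout %/% cin
    out <- array(0, c(2L * d[1], 2L * d[2], cout))
    for (c in seq_len(cin))
      for (q in seq_len(r)) out[, , (c - 1L) * r + q] <- y[, , c]
    return(out)
  }
  stop("additive upsampling: incompatible channel counts")
}

addup_bwd <- function(gy, d_in) {
  cin <- d_in[3]; cout <- dim(gy)[3]
  if (cin == cout) {
    gmid <- gy
  } else if (cin %% cout == 0L) {
    r <- cin %/% cout
    gmid <- array(0, c(dim(gy)[1], dim(gy)[2], cin))
    for (c in seq_len(cout))
      for (q in seq_len(r)) gmid[, , (c - 1L) * r + q] <- gy[, , c] / r
  } else {
    r <- cout %/% cin
    gmid <- array(0, c(dim(gy)[1], dim(gy)[2], cin))
    for (c in seq_len(cin)) {
      acc <- gy[, , (c - 1L) * r + 1L]
      if (r > 1) for (q in 2:r) acc <- acc + gy[, , (c - 1L) * r + q]
      gmid[, , c] <- acc
    }
  }
  en_resize_bilinear_adj(gmid, d_in[1], d_in[2])
}

concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One convolutional LSTM step
#'
#' Applies the convolutional LSTM gate equations to a feature grid: the
#' input, forget and output gates and the cell candidate are convolutions of
#' the input stacked with the previous hidden state,
#' `i,f,o = sigmoid(x * Wx. + h * Wh. + b)`,
#' `c_cand = tanh(x * Wxc + h * Whc + bc)`,
#' `c_t = c_prev (*) f + i (*) c_cand`, `h_t = o (*) tanh(c_t)`
#' (convolution `*`, Hadamard `(*)`). The four gate convolutions are fused in
#' one kernel of output depth `4 * hidden`, ordered (i, f, o, candidate).
#'
#' @param x input feature array (H x W x Cx).
#' @param state list with `h` and `c` arrays (H x W x Ch), or `NULL` for the
#'   zero state at a sequence start.
#' @param w,b fused gate convolution kernel `(k, k, Cx + Ch, 4 Ch)` and bias.
#' @return list with `h`, `c` (new state) and `cache` for backpropagation.
#' @export
conv_lstm_step <- function(x, state, w, b) {
  d <- dim(x); ch <- dim(w)[4] %/% 4L
  if (dim(w)[3] != d[3] + ch) stop("conv_lstm_step: input/state shape mismatch")
  if (is.null(state))
    state <- list(h = array(0, c(d[1], d[2], ch)), c = array(0, c(d[1], d[2], ch)))
  if (!all(dim(state$h) == c(d[1], d[2], ch)))
    stop("conv_lstm_step: input/state shape mismatch")
  xin <- concat3(x, state$h)
  z <- en_conv2d(xin, w, b)
  ii <- sigmoid(z[, , seq_len(ch), drop = FALSE])
  ff <- sigmoid(z[, , ch + seq_len(ch), drop = FALSE])
  oo <- sigmoid(z[, , 2L * ch + seq_len(ch), drop = FALSE])
  cc <- tanh(z[, , 3L * ch + seq_len(ch), drop = FALSE])
  cnew <- state$c * ff + ii * cc
  tc <- tanh(cnew)
  h <- oo * tc
  list(h = h, c = cnew,
       cache = list(xin = xin, i = ii, f = ff, o = oo, cc = cc,
                    c_prev = state$c, tc = tc, cx = d[3], ch = ch))
}

conv_lstm_bwd <- function(cache, w, dh, dc_in) {
  ch <- cache$ch
  dc <- dc_in + dh * cache$o * (1 - cache$tc^2)
  do_ <- dh * cache$tc
  di <- dc * cache$cc
  dcc <- dc * cache$i
  df <- dc * cache$c_prev
  dc_prev <- dc * cache$f
  dz <- array(0, c(dim(dh)[1], dim(dh)[2], 4L * ch))
  dz[, , seq_len(ch)] <- di * cache$i * (1 - cache$i)
  dz[, , ch + seq_len(ch)] <- df * cache$f * (1 - cache$f)
  dz[, , 2L * ch + seq_len(ch)] <- do_ * cache$o * (1 - cache$o)
  dz[, , 3L * ch + seq_len(ch)] <- dcc * (1 - cache$cc^2)
  bw <- en_conv2d_bwd(cache$xin, w, dz)
  list(dx = bw$gx[, , seq_len(cache$cx), drop = FALSE],
       dh_prev = bw$gx[, , cache$cx + seq_len(ch), drop = FALSE],
       dc_prev = dc_prev, gw = bw$gw, gb = bw$gb)
}
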