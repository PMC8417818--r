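#' Network configuration
#'
#' Describes the displacement-estimation network: a shared encoder of four
#' down-sampling residual blocks, and either a feed-forward decoder with
#' learned up-sampling and residual refinement units (`usenet`) or a decoder
#' of convolutional LSTM units that carries temporal state across a frame
#' sequence (`reusenet`). Every decoder level (bottleneck + four up-sampling
#' levels) emits a two-channel displacement head whose output is rescaled to
#' the input grid and summed.
#'
#' The `reference` preset uses encoder channels (16, 32, 64, 128) and convLSTM
#' hidden channels (64, 64, 32, 32, 32); channel widths were calibrated so the
#' trainable parameter counts land on the published model sizes (about 0.8
#' million for the feed-forward network and 1.5 million for the recurrent
#' one). The `tiny` preset (encoder 4, 8, 16, 32) is for CPU-scale experiments
#' and tests.
#'
#' @param variant `"usenet"` (feed-forward) or `"reusenet"` (recurrent).
#' @param preset `"reference"` or `"tiny"`, or `NULL` to use the explicit
#'   channel arguments.
#' @param encoder_channels four increasing channel widths of the encoder
#'   blocks.
#' @param lstm_channels five convLSTM hidden widths (bottleneck + 4 decoder
#'   levels); only used by `reusenet`.
#' @param kernel_size odd convolution kernel size (default 3).
#' @param leaky_slope negative slope of the leaky ReLU.
#' @export
network_config <- function(variant = c("usenet", "reusenet"),
                           preset = "reference",
                           encoder_channels = NULL,
                           lstm_channels = NULL,
                           kernel_size = 3L,
                           leaky_slope = 0.1) {
  variant <- match.arg(variant)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("reference", "tiny"))
    if (is.null(encoder_channels))
      encoder_channels <- if (preset == "reference") c(16L, 32L, 64L, 128L)
                          else c(4L, 8L, 16L, 32L)
    if (is.null(lstm_channels))
      lstm_channels <- if (preset == "reference") c(64L, 64L, 32L, 32L, 32L)
                       else c(16L, 16L, 8L, 8L, 8L)
  }
  encoder_channels <- as.integer(encoder_channels)
  lstm_channels <- as.integer(lstm_channels)
  if (length(encoder_channels) != 4L || any(encoder_channels <= 0))
    stop("network_config: need 4 positive encoder channel widths")
  if (variant == "reusenet" && (length(lstm_channels) != 5L ||
                                any(lstm_channels <= 0)))
    stop("network_config: need 5 positive convLSTM channel widths")
  if (kernel_size %% 2L != 1L) stop("network_config: kernel size must be odd")
  cfg <- structure(list(variant = variant,
                        encoder_channels = encoder_channels,
                        lstm_channels = lstm_channels,
                        kernel_size = as.integer(kernel_size),
                        leaky_slope = leaky_slope),
                   class = "network_config")
  # decoder level output widths mirror the encoder skips (deep to shallow)
  skips <- rev(encoder_channels)
  if (variant == "reusenet") {
    prev <- lstm_channels[1:4]
    ok <- (prev %% skips == 0L) | (skips %% prev == 0L)
    if (!all(ok))
      stop("network_config: lstm_channels incompatible with additive upsampling")
  }
  cfg
}

he_init <- function(dims) {
  array(rnorm(prod(dims), sd = sqrt(2 / (dims[1] * dims[2] * dims[3]))), dims)
}

# Build the flat named parameter list for a configuration.
init_params <- function(config, seed = 1L) {
  with_seed(seed, {
    k <- config$kernel_size
    e <- config$encoder_channels
    P <- list()
    cin <- 2L
    for (i in 1:4) {
      p <- sprintf("enc%d", i)
      P[[paste0(p, ".conv1.w")]] <- he_init(c(k, k, cin, e[i]))
      P[[paste0(p, ".conv1.b")]] <- numeric(e[i])
      P[[paste0(p, ".bn1.gamma")]] <- rep(1, e[i])
      P[[paste0(p, ".bn1.beta")]] <- numeric(e[i])
      P[[paste0(p, ".conv2.w")]] <- he_init(c(k, k, e[i], e[i]))
      P[[paste0(p, ".conv2.b")]] <- numeric(e[i])
      P[[paste0(p, ".bn2.gamma")]] <- rep(1, e[i])
      P[[paste0(p, ".bn2.beta")]] <- numeric(e[i])
      P[[paste0(p, ".proj.w")]] <- he_init(c(1L, 1L, cin, e[i]))
      P[[paste0(p, ".proj.b")]] <- numeric(e[i])
      cin <- e[i]
    }
    skips <- rev(e)                      # decoder level widths
    if (config$variant == "usenet") {
      din <- e[4]                        # bottleneck width
      for (i in 1:4) {
        dout <- skips[i]
        P[[sprintf("up%d.w", i)]] <- he_init(c(2L, 2L, din, dout))
        P[[sprintf("up%d.b", i)]] <- numeric(dout)
        P[[sprintf("res%d.conv1.w", i)]] <- he_init(c(k, k, dout, dout))
        P[[sprintf("res%d.conv1.b", i)]] <- numeric(dout)
        P[[sprintf("res%d.bn1.gamma", i)]] <- rep(1, dout)
        P[[sprintf("res%d.bn1.beta", i)]] <- numeric(dout)
        P[[sprintf("res%d.conv2.w", i)]] <- he_init(c(k, k, dout, dout))
        P[[sprintf("res%d.conv2.b", i)]] <- numeric(dout)
        P[[sprintf("res%d.bn2.gamma", i)]] <- rep(1, dout)
        P[[sprintf("res%d.bn2.beta", i)]] <- numeric(dout)
        din <- dout
      }
      headch <- c(e[4], skips)
    } else {
      g <- config$lstm_channels
      P[["lstm0.w"]] <- he_init(c(k, k, e[4] + g[1], 4L * g[1]))
      P[["lstm0.b"]] <- rep(c(0, 1, 0, 0), each = g[1])  # forget bias 1
      for (i in 1:4) {
        P[[sprintf("up%d.w", i)]] <- he_init(c(2L, 2L, g[i], skips[i]))
        P[[sprintf("up%d.b", i)]] <- numeric(skips[i])
        P[[sprintf("lstm%d.w", i)]] <- he_init(c(k, k, skips[i] + g[i + 1], 4L * g[i + 1]))
        P[[sprintf("lstm%d.b", i)]] <- rep(c(0, 1, 0, 0), each = g[i + 1])
      }
      headch <- g
    }
    # displacement heads: zero-initialised so the untrained model predicts the
    # identity transform (standard in unsupervised registration)
    for (i in 0:4) {
      P[[sprintf("head%d.w", i)]] <- array(0, c(k, k, headch[i + 1], 2L))
      P[[sprintf("head%d.b", i)]] <- numeric(2L)
    }
    P
  })
}

#' Create a displacement-estimation model
#'
#' @param config a [network_config()].
#' @param seed seed for weight initialisation.
#' @return object of class `elastnet_model` holding the configuration and the
#'   named parameter tensors.
#' @export
elastnet_model <- function(config, seed = 1L) {
  structure(list(config = config, params = init_params(config, seed)),
            class = "elastnet_model")
}

#' @export
print.elastnet_model <- function(x, ...) {
  cat(sprintf("<elastnet_model %s> %s parameters\n", x$config$variant,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Number of trainable scalars (convolution kernels, biases, batch-norm affine
#' terms) of a model or configuration.
#'
#' @param x an `elastnet_model` or a [network_config()].
#' @export
count_parameters <- function(x) {
  P <- if (inherits(x, "elastnet_model")) x$params else init_params(x)
  sum(vapply(P, length, integer(1)))
}

normalize_frame <- function(x) {
  x <- as.matrix(x)
  (x - mean(x)) / (sd(x) + 1e-8)
}

# ---------------------------------------------------------------------------
# encoder

enc_fwd <- function(P, cfg, x) {
  skips <- vector("list", 4L)
  caches <- vector("list", 4L)
  for (i in 1:4) {
    p <- sprintf("enc%d", i)
    c1 <- en_conv2d(x, P[[paste0(p, ".conv1.w")]], P[[paste0(p, ".conv1.b")]])
    b1 <- bn_fwd(c1, P[[paste0(p, ".bn1.gamma")]], P[[paste0(p, ".bn1.beta")]])
    a1 <- lrelu_fwd(b1$y, cfg$leaky_slope)
    c2 <- en_conv2d(a1$y, P[[paste0(p, ".conv2.w")]], P[[paste0(p, ".conv2.b")]])
    b2 <- bn_fwd(c2, P[[paste0(p, ".bn2.gamma")]], P[[paste0(p, ".bn2.beta")]])
    px <- en_conv2d(x, P[[paste0(p, ".proj.w")]], P[[paste0(p, ".proj.b")]])
    a2 <- lrelu_fwd(b2$y + px, cfg$leaky_slope)
    pl <- en_maxpool2(a2$y)
    skips[[i]] <- a2$y
    caches[[i]] <- list(x = x, b1 = b1, a1 = a1, b2 = b2, a2 = a2,
                        idx = pl$idx, hin = dim(a2$y)[1], win = dim(a2$y)[2])
    x <- pl$y
  }
  list(skips = skips, bottleneck = x, caches = caches)
}

enc_bwd <- function(P, cfg, ec, gskips, gbot, G) {
  g <- gbot
  for (i in 4:1) {
    p <- sprintf("enc%d", i)
    cc <- ec$caches[[i]]
    g <- en_maxpool2_bwd(cc$idx, g, cc$hin, cc$win)
    g <- g + gskips[[i]]
    gs <- lrelu_bwd(cc$a2, g, cfg$leaky_slope)
    bb2 <- bn_bwd(cc$b2, P[[paste0(p, ".bn2.gamma")]], gs)
    gadd(G, paste0(p, ".bn2.gamma"), bb2$dgamma)
    gadd(G, paste0(p, ".bn2.beta"), bb2$dbeta)
    cb2 <- en_conv2d_bwd(cc$a1$y, P[[paste0(p, ".conv2.w")]], bb2$gx)
    gadd(G, paste0(p, ".conv2.w"), cb2$gw)
    gadd(G, paste0(p, ".conv2.b"), cb2$gb)
    ga1 <- lrelu_bwd(cc$a1, cb2$gx, cfg$leaky_slope)
    bb1 <- bn_bwd(cc$b1, P[[paste0(p, ".bn1.gamma")]], ga1)
    gadd(G, paste0(p, ".bn1.gamma"), bb1$dgamma)
    gadd(G, paste0(p, ".bn1.beta"), bb1$dbeta)
    cb1 <- en_conv2d_bwd(cc$x, P[[paste0(p, ".conv1.w")]], bb1$gx)
    gadd(G, paste0(p, ".conv1.w"), cb1$gw)
    gadd(G, paste0(p, ".conv1.b"), cb1$gb)
    pb <- en_conv2d_bwd(cc$x, P[[paste0(p, ".proj.w")]], gs)
    gadd(G, paste0(p, ".proj.w"), pb$gw)
    gadd(G, paste0(p, ".proj.b"), pb$gb)
    g <- cb1$gx + pb$gx
  }
  g
}

# gradient accumulator: G is an environment mapping parameter name -> array
gadd <- function(G, name, val) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

# Heads: per-level two-channel displacement, resized to the input grid and
# summed. A field expressed on a 1/2^k grid carries a 2^k value scale when
# brought to the input grid (rescale_displacement); here that scale is folded
# into the head weights (head convolution effectively uses w * 2^k), which
# leaves the function class unchanged but gives every level's parameters the
# same leverage on the output — adaptive optimisers take same-sized steps per
# coordinate, so uncorrected coarse heads would move the field 16x harder.
heads_fwd <- function(P, feats, H, W) {
  U <- array(0, c(H, W, 2L))
  hc <- vector("list", 5L)
  for (i in 0:4) {
    f <- en_conv2d(feats[[i + 1L]], P[[sprintf("head%d.w", i)]],
                   P[[sprintf("head%d.b", i)]])
    U <- U + en_resize_bilinear(f, H, W)
    hc[[i + 1L]] <- dim(f)
  }
  list(U = U, dims = hc)
}

heads_bwd <- function(P, feats, dims, dU, G) {
  gfeats <- vector("list", 5L)
  for (i in 0:4) {
    d <- dims[[i + 1L]]
    gf <- en_resize_bilinear_adj(dU, d[1], d[2])
    hb <- en_conv2d_bwd(feats[[i + 1L]], P[[sprintf("head%d.w", i)]], gf)
    gadd(G, sprintf("head%d.w", i), hb$gw)
    gadd(G, sprintf("head%d.b", i), hb$gb)
    gfeats[[i + 1L]] <- hb$gx
  }
  gfeats
}

# ---------------------------------------------------------------------------
# USENet

usenet_fwd <- function(P, cfg, x0) {
  H <- dim(x0)[1]; W <- dim(x0)[2]
  ec <- enc_fwd(P, cfg, x0)
  skips <- rev(ec$skips)               # deep to shallow
  feats <- vector("list", 5L)
  dcache <- vector("list", 4L)
  feats[[1]] <- ec$bottleneck
  for (i in 1:4) {
    prev <- feats[[i]]
    dout <- dim(skips[[i]])[3]
    tc <- en_tconv2(prev, P[[sprintf("up%d.w", i)]], P[[sprintf("up%d.b", i)]])
    au <- addup_fwd(prev, dout)
    x <- tc + au + skips[[i]]
    c1 <- en_conv2d(x, P[[sprintf("res%d.conv1.w", i)]],
                    P[[sprintf("res%d.conv1.b", i)]])
    b1 <- bn_fwd(c1, P[[sprintf("res%d.bn1.gamma", i)]],
                 P[[sprintf("res%d.bn1.beta", i)]])
    a1 <- lrelu_fwd(b1$y, cfg$leaky_slope)
    c2 <- en_conv2d(a1$y, P[[sprintf("res%d.conv2.w", i)]],
                    P[[sprintf("res%d.conv2.b", i)]])
    b2 <- bn_fwd(c2, P[[sprintf("res%d.bn2.gamma", i)]],
                 P[[sprintf("res%d.bn2.beta", i)]])
    a2 <- lrelu_fwd(x + b2$y, cfg$leaky_slope)
    feats[[i + 1L]] <- a2$y
    dcache[[i]] <- list(prev = prev, x = x, b1 = b1, a1 = a1, b2 = b2, a2 = a2)
  }
  hf <- heads_fwd(P, feats, H, W)
  list(U = hf$U, ec = ec, feats = feats, dcache = dcache, hdims = hf$dims)
}

usenet_bwd <- function(P, cfg, fw, dU, G) {
  gfeats <- heads_bwd(P, fw$feats, fw$hdims, dU, G)
  gskips_rev <- vector("list", 4L)
  g <- gfeats[[5L]]
  for (i in 4:1) {
    dc <- fw$dcache[[i]]
    if (i < 4) g <- g + gfeats[[i + 1L]]
    gr <- lrelu_bwd(dc$a2, g, cfg$leaky_slope)
    gx <- gr                                       # residual branch
    bb2 <- bn_bwd(dc$b2, P[[sprintf("res%d.bn2.gamma", i)]], gr)
    gadd(G, sprintf("res%d.bn2.gamma", i), bb2$dgamma)
    gadd(G, sprintf("res%d.bn2.beta", i), bb2$dbeta)
    cb2 <- en_conv2d_bwd(dc$a1$y, P[[sprintf("res%d.conv2.w", i)]], bb2$gx)
    gadd(G, sprintf("res%d.conv2.w", i), cb2$gw)
    gadd(G, sprintf("res%d.conv2.b", i), cb2$gb)
    ga1 <- lrelu_bwd(dc$a1, cb2$gx, cfg$leaky_slope)
    bb1 <- bn_bwd(dc$b1, P[[sprintf("res%d.bn1.gamma", i)]], ga1)
    gadd(G, sprintf("res%d.bn1.gamma", i), bb1$dgamma)
    gadd(G, sprintf("res%d.bn1.beta", i), bb1$dbeta)
    cb1 <- en_conv2d_bwd(dc$x, P[[sprintf("res%d.conv1.w", i)]], bb1$gx)
    gadd(G, sprintf("res%d.conv1.w", i), cb1$gw)
    gadd(G, sprintf("res%d.conv1.b", i), cb1$gb)
    gx <- gx + cb1$gx
    gskips_rev[[i]] <- gx
    tb <- en_tconv2_bwd(dc$prev, P[[sprintf("up%d.w", i)]], gx)
    gadd(G, sprintf("up%d.w", i), tb$gw)
    gadd(G, sprintf("up%d.b", i), tb$gb)
    g <- tb$gx + addup_bwd(gx, dim(dc$prev))
  }
  g <- g + gfeats[[1L]]
  enc_bwd(P, cfg, fw$ec, rev(gskips_rev), g, G)
}

# ---------------------------------------------------------------------------
# ReUSENet (one time step; state threads across consecutive pairs)

reusenet_step_fwd <- function(P, cfg, x0, state) {
  H <- dim(x0)[1]; W <- dim(x0)[2]
  ec <- enc_fwd(P, cfg, x0)
  skips <- rev(ec$skips)
  feats <- vector("list", 5L)
  lcache <- vector("list", 5L)
  upcache <- vector("list", 4L)
  newstate <- vector("list", 5L)
  st <- conv_lstm_step(ec$bottleneck, state[[1L]], P[["lstm0.w"]], P[["lstm0.b"]])
  feats[[1L]] <- st$h
  lcache[[1L]] <- st$cache
  newstate[[1L]] <- list(h = st$h, c = st$c)
  for (i in 1:4) {
    prev <- feats[[i]]
    dout <- dim(skips[[i]])[3]
    tc <- en_tconv2(prev, P[[sprintf("up%d.w", i)]], P[[sprintf("up%d.b", i)]])
    au <- addup_fwd(prev, dout)
    x <- tc + au + skips[[i]]
    st <- conv_lstm_step(x, state[[i + 1L]], P[[sprintf("lstm%d.w", i)]],
                         P[[sprintf("lstm%d.b", i)]])
    feats[[i + 1L]] <- st$h
    lcache[[i + 1L]] <- st$cache
    newstate[[i + 1L]] <- list(h = st$h, c = st$c)
    upcache[[i]] <- list(prev = prev, x = x)
  }
  hf <- heads_fwd(P, feats, H, W)
  list(U = hf$U, ec = ec, feats = feats, lcache = lcache, upcache = upcache,
       hdims = hf$dims, state = newstate)
}

# backward for one time step; dh_next/dc_next carry temporal gradients from
# step t+1; returns the same for step t-1.
reusenet_step_bwd <- function(P, cfg, fw, dU, dh_next, dc_next, G) {
  gfeats <- heads_bwd(P, fw$feats, fw$hdims, dU, G)
  dh_prev <- vector("list", 5L)
  dc_prev <- vector("list", 5L)
  gskips_rev <- vector("list", 4L)
  gh <- vector("list", 5L)
  for (i in 1:5) {
    gh[[i]] <- gfeats[[i]]
    if (!is.null(dh_next[[i]])) gh[[i]] <- gh[[i]] + dh_next[[i]]
  }
  for (i in 4:1) {
    nm <- sprintf("lstm%d", i)
    lb <- conv_lstm_bwd(fw$lcache[[i + 1L]], P[[paste0(nm, ".w")]],
                        gh[[i + 1L]],
                        if (is.null(dc_next[[i + 1L]])) 0 else dc_next[[i + 1L]])
    gadd(G, paste0(nm, ".w"), lb$gw)
    gadd(G, paste0(nm, ".b"), lb$gb)
    dh_prev[[i + 1L]] <- lb$dh_prev
    dc_prev[[i + 1L]] <- lb$dc_prev
    gx <- lb$dx
    gskips_rev[[i]] <- gx
    prev <- fw$upcache[[i]]$prev
    tb <- en_tconv2_bwd(prev, P[[sprintf("up%d.w", i)]], gx)
    gadd(G, sprintf("up%d.w", i), tb$gw)
    gadd(G, sprintf("up%d.b", i), tb$gb)
    gh[[i]] <- gh[[i]] + tb$gx + addup_bwd(gx, dim(prev))
  }
  lb <- conv_lstm_bwd(fw$lcache[[1L]], P[["lstm0.w"]], gh[[1L]],
                      if (is.null(dc_next[[1L]])) 0 else dc_next[[1L]])
  gadd(G, "lstm0.w", lb$gw)
  gadd(G, "lstm0.b", lb$gb)
  dh_prev[[1L]] <- lb$dh_prev
  dc_prev[[1L]] <- lb$dc_prev
  enc_bwd(P, cfg, fw$ec, rev(gskips_rev), lb$dx, G)
  list(dh_prev = dh_prev, dc_prev = dc_prev)
}

# ---------------------------------------------------------------------------
# public forward passes

prep_pair <- function(pre, post, normalize) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post))) stop("frames must share shape")
  if (any(dim(pre) %% 16L != 0L))
    stop("frame dimensions must be divisible by 16 (pad the input)")
  if (normalize) { pre <- normalize_frame(pre); post <- normalize_frame(post) }
  array(c(pre, post), c(dim(pre), 2L))
}

#' Feed-forward displacement estimation (USENet)
#'
#' Runs the feed-forward encoder-decoder on a pre/post-compression RF frame
#' pair (stacked as two input channels) and returns the dense displacement
#' field mapping the pre-compression grid into the post-compression frame.
#'
#' @param model an `elastnet_model` with variant `usenet`.
#' @param pre,post RF frames (matrices of equal shape, dimensions divisible
#'   by 16).
#' @param normalize standardise each frame to zero mean / unit variance (the
#'   convention under which the models are trained).
#' @return a [displacement_field()].
#' @export
usenet_forward <- function(model, pre, post, normalize = TRUE) {
  stopifnot(inherits(model, "elastnet_model"), model$config$variant == "usenet")
  x0 <- prep_pair(pre, post, normalize)
  fw <- usenet_fwd(model$params, model$config, x0)
  displacement_field(fw$U[, , 1], fw$U[, , 2])
}

#' Recurrent displacement estimation (ReUSENet)
#'
#' Processes a temporal RF sequence pairwise: for each consecutive pair the
#' encoder features feed a convolutional LSTM decoder whose hidden and cell
#' state persist across the sequence, letting the network exploit the
#' intermediate frames when the total compression is large. Returns one
#' displacement field per consecutive pair (`N` frames give `N - 1` fields).
#'
#' @param model an `elastnet_model` with variant `reusenet`.
#' @param frames list of RF frames, or an `rf_sequence`.
#' @param state initial decoder state (list of per-level `h`/`c`), or `NULL`
#'   for the zero state at a sequence start.
#' @param normalize standardise each frame.
#' @return list with `displacements` (list of [displacement_field()]) and
#'   `state` (final convLSTM state, reusable for streaming).
#' @export
reusenet_forward <- function(model, frames, state = NULL, normalize = TRUE) {
  stopifnot(inherits(model, "elastnet_model"),
            model$config$variant == "reusenet")
  frames <- sequence_frames(frames)
  if (length(frames) < 2L) stop("reusenet_forward: need at least 2 frames")
  if (is.null(state)) state <- vector("list", 5L)
  disp <- vector("list", length(frames) - 1L)
  for (t in 2:length(frames)) {
    x0 <- prep_pair(frames[[t - 1L]], frames[[t]], normalize)
    fw <- reusenet_step_fwd(model$params, model$config, x0, state)
    state <- fw$state
    disp[[t - 1L]] <- displacement_field(fw$U[, , 1], fw$U[, , 2])
  }
  list(displacements = disp, state = state)
}

# accept an rf_sequence, a list of matrices, or a 3D array
sequence_frames <- function(x) {
  if (inherits(x, "rf_sequence")) return(x$frames)
  if (is.list(x) && !is.null(x$frames)) return(x$frames)
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3]), function(t) x[, , t]))
  if (is.list(x)) return(x)
  stop("cannot interpret object as a frame sequence")
}
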