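test_that("convLSTM step reproduces the gate closed forms at zero weights", {
  g <- 3L                       # hidden channels
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  w0 <- array(0, c(3, 3, 2 + g, 4 * g)); b0 <- numeric(4 * g)
  st <- conv_lstm_step(x, NULL, w0, b0)
  # sigma(0) = 0.5, tanh(0) = 0: c_t = 0, h_t = 0
  expect_equal(max(abs(st$c)), 0)
  expect_equal(max(abs(st$h)), 0)
  expect_equal(range(st$cache$i), c(0.5, 0.5))
  expect_equal(range(st$cache$f), c(0.5, 0.5))
  expect_equal(range(st$cache$o), c(0.5, 0.5))
  # with a previous cell state c: c_t = 0.5 c, h_t = 0.5 tanh(0.5 c)
  cprev <- array(rnorm(8 * 8 * g), c(8, 8, g))
  st2 <- conv_lstm_step(x, list(h = array(0, c(8, 8, g)), c = cprev), w0, b0)
  expect_equal(st2$c, 0.5 * cprev, tolerance = 1e-12)
  expect_equal(st2$h, 0.5 * tanh(0.5 * cprev), tolerance = 1e-12)
})

test_that("convLSTM step matches a scalar transcription of the six equations", {
  set.seed(51)
  # 1x1 grid, 1x1 kernels: convolutions collapse to scalar products
  x <- array(rnorm(1), c(1, 1, 1))
  h0 <- array(rnorm(1), c(1, 1, 1)); c0 <- array(rnorm(1), c(1, 1, 1))
  w <- array(rnorm(8), c(1, 1, 2, 4)); b <- rnorm(4)
  st <- conv_lstm_step(x, list(h = h0, c = c0), w, b)
  sig <- function(z) 1 / (1 + exp(-z))
  zi <- x[1] * w[1, 1, 1, 1] + h0[1] * w[1, 1, 2, 1] + b[1]
  zf <- x[1] * w[1, 1, 1, 2] + h0[1] * w[1, 1, 2, 2] + b[2]
  zo <- x[1] * w[1, 1, 1, 3] + h0[1] * w[1, 1, 2, 3] + b[3]
  zc <- x[1] * w[1, 1, 1, 4] + h0[1] * w[1, 1, 2, 4] + b[4]
  ct <- c0[1] * sig(zf) + sig(zi) * tanh(zc)
  ht <- sig(zo) * tanh(ct)
  expect_equal(st$c[1], ct, tolerance = 1e-6)
  expect_equal(st$h[1], ht, tolerance = 1e-6)
})

test_that("convLSTM gates stay in (0,1) and the cell state grows boundedly", {
  set.seed(52)
  g <- 4L
  w <- array(rnorm(3 * 3 * (3 + g) * 4 * g, sd = 0.5), c(3, 3, 3 + g, 4 * g))
  b <- rnorm(4 * g)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  state <- NULL
  for (t in 1:5) {
    st <- conv_lstm_step(x, state, w, b)
    expect_true(all(st$cache$i > 0 & st$cache$i < 1))
    expect_true(all(st$cache$f > 0 & st$cache$f < 1))
    expect_true(all(st$cache$o > 0 & st$cache$o < 1))
    cprev <- if (is.null(state)) array(0, dim(st$c)) else state$c
    expect_true(all(abs(st$c) <= abs(cprev) + 1 + 1e-12))
    state <- list(h = st$h, c = st$c)
  }
  expect_error(conv_lstm_step(x, list(h = x, c = x), w, b), "shape mismatch")
})

test_that("encoder halves resolution per level and the residual path is traceable", {
  cfg <- network_config("usenet", preset = "tiny")
  m <- elastnet_model(cfg, seed = 1)
  x0 <- array(rnorm(64 * 48 * 2), c(64, 48, 2))
  ec <- elastnet:::enc_fwd(m$params, cfg, x0)
  for (k in 1:4) {
    expect_equal(dim(ec$skips[[k]])[1:2], c(64, 48) / 2^(k - 1))
    expect_equal(dim(ec$skips[[k]])[3], cfg$encoder_channels[k])
  }
  expect_equal(dim(ec$bottleneck)[1:2], c(4, 3))
  # all-zero input stays finite
  ec0 <- elastnet:::enc_fwd(m$params, cfg, array(0, c(64, 48, 2)))
  expect_true(all(is.finite(ec0$bottleneck)))
  # zero conv weights: block output = leaky-relu of the 1x1 projection, pooled
  P <- m$params
  P[["enc1.conv1.w"]][] <- 0; P[["enc1.conv2.w"]][] <- 0
  P[["enc1.conv1.b"]][] <- 0; P[["enc1.conv2.b"]][] <- 0
  P[["enc1.bn1.beta"]][] <- 0; P[["enc1.bn2.beta"]][] <- 0
  xa <- array(abs(rnorm(32 * 32 * 2)), c(32, 32, 2))
  ec1 <- elastnet:::enc_fwd(P, cfg, xa)
  px <- elastnet:::en_conv2d(xa, P[["enc1.proj.w"]], P[["enc1.proj.b"]])
  lr <- px; lr[px < 0] <- cfg$leaky_slope * px[px < 0]
  expect_equal(ec1$skips[[1]], lr, tolerance = 1e-12)
})

test_that("parameter counting matches hand arithmetic and the published sizes", {
  # single 3x3 conv 2 -> 16 with bias: 2*16*9 + 16 = 304
  P1 <- list(w = array(0, c(3, 3, 2, 16)), b = numeric(16))
  expect_equal(sum(vapply(P1, length, integer(1))), 304)
  nu <- count_parameters(network_config("usenet"))
  nr <- count_parameters(network_config("reusenet"))
  expect_equal(nu / 1e6, 0.8, tolerance = 0.1)
  expect_equal(nr / 1e6, 1.5, tolerance = 0.1)
})

test_that("USENet contract: shapes, zero-head start, translation covariance", {
  cfg <- network_config("usenet", preset = "tiny")
  m <- elastnet_model(cfg, seed = 3)
  set.seed(53)
  pre <- matrix(rnorm(64 * 64), 64, 64); post <- matrix(rnorm(64 * 64), 64, 64)
  d <- usenet_forward(m, pre, post)
  expect_equal(dim(d$axial), c(64, 64))
  # heads are zero-initialised: identity transform at the start
  expect_equal(max(abs(d$axial)), 0)
  expect_equal(max(abs(d$lateral)), 0)
  expect_error(usenet_forward(m, pre[1:60, ], post[1:60, ]), "divisible by 16")
})

test_that("both networks are translation-covariant away from borders", {
  # image the same speckle content through two crops offset by one full
  # pooling period (16 samples) and compare the fields in the deep interior
  spec <- phantom_spec(grid_shape = c(192L, 64L),
                       inclusions = list(c(0.5, 0.5, 0.15, 0.5)),
                       strain_schedule = 0.01, noise_sigma = 0,
                       lateral_drift = 0, seed = 7)
  sim <- simulate_sequence(spec)
  F1 <- sim$frames[[1]]; F2 <- sim$frames[[2]]
  core <- 49:80; lat <- 17:48
  m <- elastnet_model(network_config("usenet", preset = "tiny"), seed = 3)
  set.seed(54)
  for (i in 0:4) {
    nm <- sprintf("head%d.w", i)
    m$params[[nm]][] <- rnorm(length(m$params[[nm]]), sd = 0.002)
  }
  d1 <- usenet_forward(m, F1[1:128, ], F2[1:128, ])
  d2 <- usenet_forward(m, F1[17:144, ], F2[17:144, ])
  expect_lt(max(abs(d2$axial[core, lat] - d1$axial[core + 16, lat])), 0.1)
  mr <- elastnet_model(network_config("reusenet", preset = "tiny"), seed = 4)
  set.seed(55)
  for (i in 0:4) {
    nm <- sprintf("head%d.w", i)
    mr$params[[nm]][] <- rnorm(length(mr$params[[nm]]), sd = 0.01)
  }
  r1 <- reusenet_forward(mr, list(F1[1:128, ], F2[1:128, ]))$displacements[[1]]
  r2 <- reusenet_forward(mr, list(F1[17:144, ], F2[17:144, ]))$displacements[[1]]
  expect_lt(max(abs(r2$axial[core, lat] - r1$axial[core + 16, lat])), 0.1)
})

test_that("ReUSENet contract: one field per pair, state dependence, zero-state fallback", {
  cfg <- network_config("reusenet", preset = "tiny")
  m <- elastnet_model(cfg, seed = 4)
  set.seed(55); ({
    for (i in 0:4) {
      nm <- sprintf("head%d.w", i)
      m$params[[nm]][] <- rnorm(length(m$params[[nm]]), sd = 0.05)
    }
  })
  set.seed(56)
  fr <- lapply(1:4, function(i) matrix(rnorm(32 * 32), 32, 32))
  out <- reusenet_forward(m, fr)
  expect_length(out$displacements, 3)
  expect_equal(dim(out$displacements[[1]]$axial), c(32, 32))
  expect_error(reusenet_forward(m, fr[1]), "at least 2")
  # recurrence: the same pair fed twice gives different outputs unless the
  # state is reset
  twice <- reusenet_forward(m, list(fr[[1]], fr[[2]], fr[[2]]))
  rep1 <- reusenet_forward(m, list(fr[[1]], fr[[2]]))
  again <- reusenet_forward(m, list(fr[[1]], fr[[2]]), state = twice$state)
  expect_false(isTRUE(all.equal(rep1$displacements[[1]]$axial,
                                again$displacements[[1]]$axial)))
  # forcing the state to zero at every step degrades to a feed-forward pass
  z <- NULL
  for (t in 2:4) {
    r <- reusenet_forward(m, list(fr[[t - 1]], fr[[t]]), state = NULL)
    expect_true(all(is.finite(r$displacements[[1]]$axial)))
  }
})

test_that("network backward passes agree with finite differences", {
  cfgu <- network_config("usenet", preset = NULL,
                         encoder_channels = c(2, 4, 8, 8))
  m <- elastnet_model(cfgu, seed = 5)
  set.seed(57); ({
    for (i in 0:4) {
      nm <- sprintf("head%d.w", i)
      m$params[[nm]][] <- rnorm(length(m$params[[nm]]), sd = 0.1)
    }
  })
  H <- 32; W <- 16
  set.seed(58)
  x0 <- array(rnorm(H * W * 2), c(H, W, 2))
  R <- array(rnorm(H * W * 2), c(H, W, 2))
  fw <- elastnet:::usenet_fwd(m$params, cfgu, x0)
  G <- new.env()
  elastnet:::usenet_bwd(m$params, cfgu, fw, R, G)
  f <- function(P) sum(elastnet:::usenet_fwd(P, cfgu, x0)$U * R)
  set.seed(59)
  for (nm in sample(grep("\\.w$|gamma", names(m$params), value = TRUE), 8)) {
    P2 <- m$params; k <- sample(length(P2[[nm]]), 1); eps <- 1e-5
    P2[[nm]][k] <- P2[[nm]][k] + eps; fp <- f(P2)
    P2[[nm]][k] <- P2[[nm]][k] - 2 * eps; fm <- f(P2)
    num <- (fp - fm) / (2 * eps)
    expect_lt(abs(num - G[[nm]][k]), 1e-3 * max(1, abs(num)))
  }
  # recurrent variant with backpropagation through time over 3 frames
  cfgr <- network_config("reusenet", preset = NULL,
                         encoder_channels = c(2, 4, 4, 8),
                         lstm_channels = c(4, 4, 2, 2, 2))
  mr <- elastnet_model(cfgr, seed = 6)
  set.seed(60); ({
    for (i in 0:4) {
      nm <- sprintf("head%d.w", i)
      mr$params[[nm]][] <- rnorm(length(mr$params[[nm]]), sd = 0.1)
    }
  })
  set.seed(61)
  frames <- lapply(1:3, function(i) matrix(rnorm(H * W), H, W))
  Rs <- lapply(1:2, function(i) array(rnorm(H * W * 2), c(H, W, 2)))
  run <- function(P) {
    state <- vector("list", 5); tot <- 0
    for (t in 2:3) {
      x0 <- elastnet:::prep_pair(frames[[t - 1]], frames[[t]], TRUE)
      fw <- elastnet:::reusenet_step_fwd(P, cfgr, x0, state)
      state <- fw$state
      tot <- tot + sum(fw$U * Rs[[t - 1]])
    }
    tot
  }
  state <- vector("list", 5); fws <- list()
  for (t in 2:3) {
    x0 <- elastnet:::prep_pair(frames[[t - 1]], frames[[t]], TRUE)
    fws[[t - 1]] <- elastnet:::reusenet_step_fwd(mr$params, cfgr, x0, state)
    state <- fws[[t - 1]]$state
  }
  G <- new.env()
  dh <- vector("list", 5); dc <- vector("list", 5)
  for (t in 2:1) {
    r <- elastnet:::reusenet_step_bwd(mr$params, cfgr, fws[[t]], Rs[[t]],
                                      dh, dc, G)
    dh <- r$dh_prev; dc <- r$dc_prev
  }
  set.seed(62)
  for (nm in sample(grep("lstm|up|head", names(mr$params), value = TRUE), 8)) {
    P2 <- mr$params; k <- sample(length(P2[[nm]]), 1); eps <- 1e-5
    P2[[nm]][k] <- P2[[nm]][k] + eps; fp <- run(P2)
    P2[[nm]][k] <- P2[[nm]][k] - 2 * eps; fm <- run(P2)
    num <- (fp - fm) / (2 * eps)
    expect_lt(abs(num - G[[nm]][k]), 1e-3 * max(1, abs(num)))
  }
})

test_that("ten optimisation steps suffice to keep an identical pair aligned", {
  sim <- get_sim(0)
  fr <- sim$frames[[1]]
  cfg <- network_config("usenet", preset = "tiny")
  m <- elastnet_model(cfg, seed = 7)
  w <- loss_weights(beta = 0, lncc_window = c(11L, 11L))
  for (it in 1:10) {
    r <- elastnet:::item_grad_usenet(m$params, cfg,
                                     list(frames = list(fr, fr)), w)
    r$G <- elastnet:::clip_grads(r$G, 5)
    m$params <- elastnet:::sgd_step(m$params, r$G, 1e-4)
  }
  d <- usenet_forward(m, fr, fr)
  expect_lt(similarity_loss(elastnet:::normalize_frame(fr),
                            elastnet:::normalize_frame(fr), d, w), -0.95)
})
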