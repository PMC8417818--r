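test_that("LNCC matches self/anti-correlation and the per-window oracle", {
  set.seed(31)
  A <- matrix(rnorm(625), 25, 25)
  expect_equal(lncc(A, A, c(9, 9)), 1, tolerance = 1e-4)
  expect_equal(lncc(A, -A, c(9, 9)), -1, tolerance = 1e-4)
  a <- matrix(sample(1:20, 25, TRUE), 5, 5)
  b <- matrix(sample(1:20, 25, TRUE), 5, 5)
  expect_equal(lncc(a, b, c(3, 3)), lncc_oracle(a, b, 3, 3), tolerance = 1e-6)
  a7 <- matrix(rnorm(49), 7, 7); b7 <- matrix(rnorm(49), 7, 7)
  expect_equal(lncc(a7, b7, c(5, 3)), lncc_oracle(a7, b7, 5, 3),
               tolerance = 1e-6)
})

test_that("LNCC is invariant to positive affine intensity transforms", {
  set.seed(32)
  A <- matrix(rnorm(400), 20, 20); B <- matrix(rnorm(400), 20, 20)
  base <- lncc(A, B, c(7, 7))
  expect_equal(lncc(3 * A + 10, B, c(7, 7)), base, tolerance = 1e-3)
  expect_equal(lncc(A, 0.5 * B - 2, c(7, 7)), base, tolerance = 1e-3)
})

test_that("LNCC skips degenerate windows and errors with no usable overlap", {
  expect_error(lncc(matrix(1, 9, 9), matrix(1, 9, 9), c(3, 3)),
               "unusable overlap")
  set.seed(33)
  A <- matrix(rnorm(81), 9, 9)
  m0 <- matrix(0, 9, 9)
  expect_error(lncc(A, A, c(3, 3), mask = m0), "unusable overlap")
})

test_that("similarity loss rewards exact motion compensation", {
  set.seed(34)
  pre <- matrix(rnorm(32 * 32), 32, 32)
  w <- loss_weights(lncc_window = c(9L, 9L))
  z <- displacement_field(matrix(0, 32, 32))
  expect_equal(similarity_loss(pre, pre, z, w), -1, tolerance = 1e-3)
  # post = pre shifted deeper by 4 rows: sampling the post frame 4 samples
  # below each reference pixel (displacement +4) compensates exactly
  post <- rbind(matrix(rnorm(4 * 32), 4, 32), pre[1:28, ])
  d4 <- displacement_field(matrix(4, 32, 32))
  expect_equal(similarity_loss(pre, post, d4, w), -1, tolerance = 1e-3)
  # independent speckle: NCC concentrates near zero
  vals <- sapply(1:20, function(s) {
    set.seed(100 + s)
    similarity_loss(matrix(rnorm(1024), 32, 32), matrix(rnorm(1024), 32, 32),
                    z, w)
  })
  expect_lt(max(abs(vals)), 0.1)
})

test_that("smoothness loss vanishes on affine fields and matches the stencil oracle", {
  h <- 12; w <- 10
  aff <- outer(0:(h - 1), 0:(w - 1), function(y, x) 1.5 + 0.2 * y - 0.7 * x)
  expect_equal(smoothness_loss(displacement_field(aff)), 0, tolerance = 1e-12)
  expect_equal(smoothness_loss(displacement_field(matrix(0, h, w))), 0)
  # u = y^2: only |d2y u| = 2 contributes at every interior pixel
  expect_equal(smoothness_loss(displacement_field(matrix((0:(h - 1))^2, h, w))), 2)
  # random field vs an explicit finite-difference loop
  set.seed(35)
  u <- matrix(rnorm(h * w), h, w)
  acc <- 0; n <- 0
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    d2y <- u[i - 1, j] - 2 * u[i, j] + u[i + 1, j]
    d2x <- u[i, j - 1] - 2 * u[i, j] + u[i, j + 1]
    dxy <- (u[i + 1, j + 1] - u[i + 1, j - 1] - u[i - 1, j + 1] + u[i - 1, j - 1]) / 4
    acc <- acc + abs(d2y) + abs(d2x) + 2 * abs(dxy); n <- n + 1
  }
  expect_equal(smoothness_loss(displacement_field(u)), acc / n,
               tolerance = 1e-12)
})

test_that("consistency loss behaves like a motion-compensated strain NCC", {
  set.seed(36)
  s1 <- rand_field(32, 32, 1, seed = 37)
  w <- loss_weights(lncc_window = c(9L, 9L))
  z <- displacement_field(matrix(0, 32, 32))
  expect_equal(consistency_loss(s1, s1, z, w), -1, tolerance = 1e-3)
  # shifted copy + exact shift
  s2 <- rbind(s1[30:32, ], s1[1:29, ])
  d3 <- displacement_field(matrix(3, 32, 32))
  expect_equal(consistency_loss(s1, s2, d3, w), -1, tolerance = 1e-3)
  # equal-power independent noise attenuates the correlation but far from -1
  vals <- sapply(1:10, function(k) {
    set.seed(200 + k)
    sa <- rand_field(32, 32, 1); sb <- sa + rand_field(32, 32, 1)
    consistency_loss(sa, sb, z, w)
  })
  expect_true(all(vals > -0.8))
})

test_that("total loss is the exact weighted sum with the published defaults", {
  w <- loss_weights()
  expect_equal(w$alpha, 5)
  expect_equal(w$beta, 0.2)
  bl <- total_loss(-1, 0, -1, w)
  expect_equal(bl$total, -1.2)
  expect_equal(bl$total, bl$sim + w$alpha * bl$reg + w$beta * bl$cons)
  w0 <- loss_weights(beta = 0)
  expect_equal(total_loss(-0.5, 0.1, NULL, w0)$total, -0.5 + 5 * 0.1)
  expect_equal(total_loss(-0.5, 0.1, -0.9, w0)$total,
               total_loss(-0.5, 0.1, 123, w0)$total)   # cons ignored at beta 0
  expect_error(total_loss(-0.5, 0.1, NULL, w), "beta")
})

test_that("loss gradients agree with finite differences on a 16x16 toy", {
  set.seed(38)
  pre <- matrix(rnorm(256), 16, 16); post <- matrix(rnorm(256), 16, 16)
  dax <- rand_field(16, 16, 0.5, seed = 39)
  dlat <- rand_field(16, 16, 0.5, seed = 40)
  w <- loss_weights(lncc_window = c(7L, 7L), strain_window = 5L)
  sg <- elastnet:::similarity_loss_grad(pre, post,
                                        displacement_field(dax, dlat), w)
  set.seed(41)
  ks <- sample(256, 10)
  num <- sapply(ks, function(k) {
    dp <- dax; dp[k] <- dp[k] + 1e-5; dm <- dax; dm[k] <- dm[k] - 1e-5
    (similarity_loss(pre, post, displacement_field(dp, dlat), w) -
       similarity_loss(pre, post, displacement_field(dm, dlat), w)) / 2e-5
  })
  expect_lt(max(abs(num - sg$g_axial[ks]) / (abs(num) + 1e-3)), 1e-3)
  rg <- elastnet:::smoothness_loss_grad(dax)
  numr <- sapply(ks, function(k) {
    dp <- dax; dp[k] <- dp[k] + 1e-6; dm <- dax; dm[k] <- dm[k] - 1e-6
    (smoothness_loss(displacement_field(dp)) -
       smoothness_loss(displacement_field(dm))) / 2e-6
  })
  expect_lt(max(abs(numr - rg$grad[ks]) / (abs(numr) + 1e-3)), 1e-3)
  sprev <- rand_field(16, 16, 1, seed = 42)
  scurr_of <- function(dv) lsq_strain(dv, w$strain_window)
  cl <- function(dv) consistency_loss(sprev, scurr_of(dv),
                                      displacement_field(dv, dlat), w)
  cg <- elastnet:::consistency_loss_grad(sprev, scurr_of(dax),
                                         displacement_field(dax, dlat), w)
  full_g <- cg$g_axial + elastnet:::lsq_strain_adj(cg$g_strain, w$strain_window)
  numc <- sapply(ks, function(k) {
    dp <- dax; dp[k] <- dp[k] + 1e-5; dm <- dax; dm[k] <- dm[k] - 1e-5
    (cl(dp) - cl(dm)) / 2e-5
  })
  expect_lt(max(abs(numc - full_g[ks]) / (abs(numc) + 1e-3)), 1e-3)
})

test_that("direct optimisation of a free-form displacement descends the objective", {
  # free-form gradient descent with a smoothed update (demons-style) and
  # backtracking line search; the total objective must fall monotonically
  sim <- get_sim(0)
  pre <- elastnet:::normalize_frame(sim$frames[[1]])
  post <- elastnet:::normalize_frame(sim$frames[[6]])
  w <- loss_weights(beta = 0, lncc_window = c(11L, 11L))
  # free-form field parameterised on a 16x16 control grid (bilinear upsample)
  up <- function(C) {
    r <- elastnet:::en_resize_bilinear(C, 64L, 64L)
    r[, , 1] <- r[, , 1] * 4; r[, , 2] <- r[, , 2] * 4
    r
  }
  down <- function(G) {
    g <- elastnet:::en_resize_bilinear_adj(G, 16L, 16L)
    g[, , 1] <- g[, , 1] * 4; g[, , 2] <- g[, , 2] * 4
    g
  }
  total_of <- function(U) {
    d <- displacement_field(U[, , 1], U[, , 2])
    similarity_loss(pre, post, d, w) + w$alpha * smoothness_loss(d, w)
  }
  C <- array(0, c(16, 16, 2))
  cur <- total_of(up(C))
  losses <- numeric(51); losses[1] <- cur
  lr <- 8
  for (it in 1:50) {
    U <- up(C)
    d <- displacement_field(U[, , 1], U[, , 2])
    sg <- elastnet:::similarity_loss_grad(pre, post, d, w)
    rg <- elastnet:::smoothness_loss_grad(U[, , 1])
    G <- array(0, dim(U))
    G[, , 1] <- sg$g_axial + w$alpha * rg$grad
    G[, , 2] <- sg$g_lateral
    gC <- down(G)
    repeat {
      cand <- C - lr * gC
      val <- total_of(up(cand))
      if (val <= cur || lr < 1e-7) break
      lr <- lr / 2
    }
    if (val <= cur) { C <- cand; cur <- val; lr <- lr * 1.5 }
    losses[it + 1] <- cur
  }
  expect_true(all(diff(losses) <= 0))      # monotone descent, no stall
  expect_lt(losses[51], losses[1] - 0.2)   # and substantive progress
})
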