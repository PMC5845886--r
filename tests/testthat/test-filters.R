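# linear filtering primitives and pointwise nonlinearities

test_that("conv3d matches the brute-force loop oracle", {
  set.seed(10)
  x <- small_noise(shape = c(8L, 8L), frames = 20L, seed = 10)
  w <- array(rnorm(1 * 1 * 4 * 3 * 3), c(1, 1, 4, 3, 3))
  expect_lt(maxabs(conv3d(x, kernel3d(w)), brute_conv3d(x$values, w)), 1e-6)
  # multichannel, even-sized spatial kernel (tie toward earlier indices)
  xm <- video_tensor(array(rnorm(2 * 10 * 5 * 5), c(1, 2, 10, 5, 5)), 0.001)
  wm <- array(rnorm(3 * 2 * 2 * 2 * 3), c(3, 2, 2, 2, 3))
  expect_lt(maxabs(conv3d(xm, kernel3d(wm)), brute_conv3d(xm$values, wm)), 1e-6)
})

test_that("conv3d special kernels: delta identity and channel permutation", {
  x <- small_noise(seed = 11)
  expect_identical(conv3d(x, kernel3d(array(1, c(1, 1, 1, 1, 1))))$values, x$values)
  # RGB -> (G, B, R) channel swap
  rgb <- video_tensor(array(rnorm(3 * 8 * 4 * 4), c(1, 3, 8, 4, 4)), 0.001)
  kp <- array(0, c(3, 3, 1, 1, 1))
  kp[1, 2, , , ] <- 1; kp[2, 3, , , ] <- 1; kp[3, 1, , , ] <- 1
  y <- conv3d(rgb, kernel3d(kp))
  expect_identical(y$values[, 1, , , ], rgb$values[, 2, , , ])
  expect_identical(y$values[, 2, , , ], rgb$values[, 3, , , ])
  expect_identical(y$values[, 3, , , ], rgb$values[, 1, , , ])
  expect_error(conv3d(x, kernel3d(kp)), "channel mismatch.*3.*1")
})

test_that("conv3d is linear and causal", {
  w <- kernel3d(array(rnorm(3 * 3 * 3), c(1, 1, 3, 3, 3)))
  x <- small_noise(seed = 12); y <- small_noise(seed = 13)
  lhs <- conv3d(video_tensor(2 * x$values - 3 * y$values, x$dt), w)
  rhs <- 2 * conv3d(x, w)$values - 3 * conv3d(y, w)$values
  expect_lt(maxabs(lhs, rhs), 1e-6)
  # causality: perturbing frame k never changes frames < k
  for (l in list(layer_conv3d(w), layer_iir(iir_filter(c(0.5, 0.2), c(-0.4))),
                 layer_exp_smooth(0.01))) {
    reset_state(l); y0 <- layer_forward(l, x)
    xp <- x$values; xp[1, 1, 10, 2, 2] <- xp[1, 1, 10, 2, 2] + 5
    reset_state(l); y1 <- layer_forward(l, video_tensor(xp, x$dt))
    expect_identical(y0$values[, , 1:9, , ], y1$values[, , 1:9, , ])
  }
})

test_that("iir_temporal realizes the recursion and its special cases", {
  x <- small_noise(seed = 14)
  expect_identical(iir_temporal(x, iir_filter(b = 1))$values, x$values)
  # geometric decay filter equals dense convolution with the sampled exponential
  dt <- 1e-3; tau <- 0.01; lam <- exp(-dt / tau)
  imp <- wrap_video(array(c(1, rep(0, 59)), c(60, 1, 1)), dt)
  y1 <- iir_temporal(imp, iir_filter(b = 1 - lam, a = -lam))
  ker <- rev((1 - lam) * lam^(0:59))
  y2 <- conv3d(imp, kernel3d(array(ker, c(60, 1, 1))))
  expect_lt(sqrt(sum((y1$values - y2$values)^2) / sum(y2$values^2)), 1e-8)
  # any FIR filter equals conv3d with the matching 1x1xMx1x1 kernel
  b <- rnorm(5)
  yf <- iir_temporal(x, iir_filter(b = b))
  yc <- conv3d(x, kernel3d(array(rev(b), c(5, 1, 1))))
  expect_lt(maxabs(yf, yc), 1e-12)
})

test_that("iir stability check flags unstable feedback", {
  expect_true(iir_stable(iir_filter(b = 1, a = -0.9)))
  expect_false(iir_stable(iir_filter(b = 1, a = -1.1)))
  expect_true(iir_stable(iir_filter(b = rnorm(4))))
})

test_that("exp_smooth has unit DC gain and the closed-form step response", {
  v <- wrap_video(array(3.7, c(400, 2, 2)), dt = 0.001)
  y <- exp_smooth(v, 0.01)
  expect_lt(abs(y$values[1, 1, 400, 1, 1] - 3.7), 1e-6)
  step <- wrap_video(array(1, c(50, 1, 1)), 0.001)
  lam <- exp(-0.001 / 0.01)
  expect_lt(max(abs(exp_smooth(step, 0.01)$values[1, 1, , 1, 1] - (1 - lam^(1:50)))), 1e-12)
  # tau << dt: output ~ input
  x <- small_noise(seed = 15)
  expect_lt(maxabs(exp_smooth(x, x$dt / 1000), x), 1e-6)
  expect_error(exp_smooth(x, -1), "tau")
})

test_that("recursive Gaussian matches the dense oracle and preserves DC", {
  const <- wrap_video(array(1, c(1, 20, 20)), 0.001)
  expect_lt(maxabs(recursive_gaussian2d(const, 2, method = "recursive"), const), 1e-6)
  imp <- array(0, c(1, 33, 33)); imp[1, 17, 17] <- 1
  vi <- wrap_video(imp, 0.001)
  expect_lt(maxabs(recursive_gaussian2d(vi, 2, method = "recursive"),
                   recursive_gaussian2d(vi, 2, method = "dense")), 1e-3)
  # anisotropic, input supported away from the borders
  a <- array(0, c(1, 41, 41))
  set.seed(16); a[1, 17:25, 17:25] <- rnorm(81)
  va <- wrap_video(a, 0.001)
  expect_lt(maxabs(recursive_gaussian2d(va, 3, 1, method = "recursive"),
                   recursive_gaussian2d(va, 3, 1, method = "dense")), 1e-3)
  expect_error(recursive_gaussian2d(vi, 0), "sigma")
})

test_that("softconv is the explicit sum of its branches", {
  x <- small_noise(seed = 17)
  ks <- list(matrix(rnorm(9), 3), matrix(rnorm(9), 3))
  y <- softconv(x, c(0.002, 0.03), ks)
  manual <- conv3d(exp_smooth(x, 0.002), kernel3d(ks[[1]]))$values +
    conv3d(exp_smooth(x, 0.03), kernel3d(ks[[2]]))$values
  expect_identical(y$values, manual)
  # K = 1, tiny tau, delta kernel ~ identity
  y2 <- softconv(x, x$dt / 1000, list(matrix(1, 1, 1)))
  expect_lt(maxabs(y2, x), 1e-5)
  expect_true(all(softconv(x, c(0.01, 0.02), list(matrix(0, 3, 3), matrix(0, 3, 3)))$values == 0))
  expect_error(layer_softconv(c(0.02, 0.01), ks), "increasing")
})

test_that("pointwise nonlinearities compute their defining maps", {
  v <- video_tensor(array(c(-1, 0, 2, 0.4, 0.6, -2, 3, 0, 0), c(1, 3, 3)), 0.001)
  hw <- apply_nonlinearity(v, "half_wave")$values
  expect_equal(as.numeric(hw[1, 1, 1, , 1]), c(0, 0, 2))
  sq <- apply_nonlinearity(v, "square")$values
  expect_equal(as.numeric(sq[1, 1, 1, , 2]), c(0.4^2, 0.6^2, 4))
  th <- apply_nonlinearity(v, nonlinearity_spec("threshold", theta = 0.5))$values
  expect_equal(as.numeric(th[1, 1, 1, , 2]), c(0, 1, 0))
  expect_error(nonlinearity_spec("frobnicate"))
  # threshold without surrogate cannot provide gradients
  l <- layer_nonlinearity(nonlinearity_spec("threshold", surrogate_width = NA))
  x <- small_noise(seed = 18)
  layer_forward(l, x, record = TRUE)
  expect_error(layer_backward(l, x$values), "surrogate")
})

test_that("recursive filters agree with their truncated dense impulse responses", {
  # property: sampled impulse response convolution reproduces the filter
  dt <- 1e-3
  filt <- iir_filter(b = c(0.3, 0.1), a = c(-0.7, 0.12))
  expect_true(iir_stable(filt))
  L <- 120L
  imp <- wrap_video(array(c(1, rep(0, L - 1L)), c(L, 1, 1)), dt)
  h <- iir_temporal(imp, filt)$values[1, 1, , 1, 1]
  expect_lt(abs(h[L]), 1e-10)  # tail mass truncated
  x <- small_noise(shape = c(3L, 3L), frames = L, seed = 19)
  y1 <- iir_temporal(x, filt)
  y2 <- conv3d(x, kernel3d(array(rev(h), c(L, 1, 1))))
  expect_lt(sqrt(sum((y1$values - y2$values)^2) / sum(y1$values^2)), 1e-6)
})
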