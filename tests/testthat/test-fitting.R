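# gradients, optimizers, diagnostics

test_that("loss_mse is the elementwise mean of squared differences", {
  a <- small_noise(seed = 40); b <- small_noise(seed = 41)
  expect_equal(loss_mse(a, a), 0)
  expect_equal(loss_mse(a, video_tensor(a$values - 2, a$dt)), 4)
  expect_equal(loss_mse(a, b), sum((a$values - b$values)^2) / length(a$values))
  expect_error(loss_mse(a, video_tensor(array(0, c(1, 1, 3, 2, 2)), 1e-3)),
               "shape mismatch")
})

test_that("gradients vanish at a stationary point and match the analytic form", {
  x <- small_noise(seed = 42)
  m <- model_LN(array(rnorm(3 * 3 * 3, 0, 0.3), c(3, 3, 3)), "linear")
  reset_state(m)
  y <- layer_forward(m, x)
  pg <- param_gradients(m, x, y)
  expect_lt(max(abs(pg$gradients[[1]])), 1e-10)
  # pure convolution under MSE: kernel gradient is the cross-correlation of the
  # residual with the input (brute-force oracle, loops only)
  yt <- small_noise(seed = 43)
  pg <- param_gradients(m, x, yt)
  res <- 2 * (pg$output$values - yt$values) / length(yt$values)
  w <- get_parameter(m, "stage1.linear.weight")
  dw <- dim(w); d <- dim(x$values)
  gw_oracle <- array(0, dw)
  cx <- (dw[4] + 1) %/% 2; cy <- (dw[5] + 1) %/% 2
  for (j in 1:dw[3]) for (u in 1:dw[4]) for (v in 1:dw[5]) {
    acc <- 0
    for (k in 1:d[3]) for (xx in 1:d[4]) for (yy in 1:d[5]) {
      kk <- k + j - dw[3]; xs <- xx + u - cx; ys <- yy + v - cy
      if (kk >= 1 && kk <= d[3] && xs >= 1 && xs <= d[4] && ys >= 1 && ys <= d[5])
        acc <- acc + res[1, 1, k, xx, yy] * x$values[1, 1, kk, xs, ys]
    }
    gw_oracle[1, 1, j, u, v] <- acc
  }
  expect_lt(max(abs(pg$gradients[[1]] - gw_oracle)), 1e-6)
})

test_that("analytic gradients match central finite differences per parameter class", {
  x <- small_noise(seed = 44)
  y <- small_noise(seed = 45)
  models <- list(
    kernel = model_LN(array(rnorm(2 * 3 * 3, 0, 0.3), c(2, 3, 3)), "half_wave"),
    tau = sequential_model(e = layer_exp_smooth(0.015),
                           n = layer_nonlinearity("tanh")),
    nl = sequential_model(n = layer_nonlinearity(
      nonlinearity_spec("sigmoid", theta = 0.1, slope = 2))),
    ganglion = sequential_model(g = layer_ganglion(ganglion_params())))
  for (nm in names(models)) {
    ga <- param_gradients(models[[nm]], x, y)$gradients
    gf <- param_gradients_fd(models[[nm]], x, y)
    for (p in names(ga)) {
      expect_lt(rel_err(ga[[p]], gf[[p]]), 1e-4,
                label = sprintf("%s / %s", nm, p))
    }
  }
  # bipolar parameters on an input scaled to its operating range
  xb <- small_noise(shape = c(8L, 8L), frames = 40L, seed = 46, level = 50)
  yb <- small_noise(shape = c(8L, 8L), frames = 40L, seed = 47, level = 0.5)
  mb <- layer_bipolar(bipolar_params())
  ga <- param_gradients(mb, xb, yb)$gradients
  gf <- param_gradients_fd(mb, xb, yb, step = 1e-5)
  expect_lt(rel_err(ga$g_leak, gf$g_leak), 1e-4)
  expect_lt(rel_err(ga$lambda_bip, gf$lambda_bip), 1e-4)
})

test_that("fit: zero learning rate leaves parameters and loss untouched", {
  x <- small_noise(seed = 48); y <- small_noise(seed = 49)
  m <- model_LN(array(rnorm(9, 0, 0.3), c(1, 3, 3)), "linear")
  p0 <- get_param_vector(m)
  r <- fit(m, x, y, optimizer_spec(method = "gradient_descent", lr = 0,
                                   max_steps = 3))
  expect_identical(get_param_vector(m), p0)
  expect_true(all(abs(diff(r$loss_trace)) < 1e-14))
})

test_that("fit records a trace and aborts on divergence", {
  x <- small_noise(seed = 50); y <- small_noise(seed = 51)
  m <- model_LN(array(rnorm(9, 0, 0.3), c(1, 3, 3)), "linear")
  r <- fit(m, x, y, optimizer_spec(method = "adaptive", lr = 0.05, max_steps = 5))
  expect_equal(length(r$loss_trace), r$steps + 1)
  expect_equal(nrow(r$par_trace), r$steps + 1)
  expect_lt(r$loss_trace[length(r$loss_trace)], r$loss_trace[1])
  m2 <- model_LN(array(rnorm(9, 0, 0.3), c(1, 3, 3)), "linear")
  expect_error(fit(m2, x, y, optimizer_spec(method = "gradient_descent",
                                            lr = 1e6, max_steps = 20)),
               "diverged")
})

test_that("quasi-Newton solves a small linear problem to ~0 within one outer step", {
  x <- small_noise(shape = c(8L, 8L), frames = 60L, seed = 52)
  truth <- model_LN(array(rnorm(25, 0, 0.5), c(1, 5, 5)), "linear")
  reset_state(truth)
  y <- layer_forward(truth, x)
  m <- model_LN(array(0.01 * rnorm(25), c(1, 5, 5)), "linear")
  r <- fit(m, x, y, optimizer_spec(method = "quasi_newton", max_steps = 1, inner = 20))
  expect_lt(r$loss_trace[length(r$loss_trace)], 1e-10 * r$loss_trace[1])
})

test_that("momentum and adaptive methods recover an exponential time constant", {
  ev <- poisson_events(20, 20, 0.001, seed = 53)
  target <- exp_smooth(ev, 0.1)
  m <- sequential_model(e = layer_exp_smooth(0.02))
  r <- fit(m, ev, target, optimizer_spec(method = "adaptive", lr = 0.005,
                                         max_steps = 200))
  expect_lt(abs(get_parameter(m, "e.tau") - 0.1) / 0.1, 0.02)
  m2 <- sequential_model(e = layer_exp_smooth(0.05))
  r2 <- fit(m2, ev, target, optimizer_spec(method = "momentum", lr = 50,
                                           max_steps = 100))
  expect_lt(abs(get_parameter(m2, "e.tau") - 0.1) / 0.1, 0.05)
})

test_that("scan_error_curve is unimodal with one gradient sign change at the truth", {
  ev <- poisson_events(20, 10, 0.001, seed = 54)
  target <- exp_smooth(ev, 0.1)
  grid <- seq(0.04, 0.2, by = 0.02)
  sc <- scan_error_curve(function() sequential_model(e = layer_exp_smooth(0.1)),
                         "e.tau", grid, ev, target)
  expect_true(attr(sc, "unimodal"))
  expect_equal(which.min(sc$loss), which(grid == 0.1))
  # gradient negative below the truth, positive above, (near) zero at it:
  # exactly one sign change, in the cell containing the ground truth
  expect_true(all(sc$gradient[grid < 0.1] < 0))
  expect_true(all(sc$gradient[grid > 0.1] > 0))
  expect_lt(abs(sc$gradient[grid == 0.1]), 1e-10)
  expect_true(attr(sc, "sign_change") %in% which(abs(grid - 0.1) <= 0.0201))
  # scanned gradients agree with finite differences of the scanned error curve
  num <- diff(sc$loss) / diff(sc$value)
  mid <- (sc$gradient[-1] + sc$gradient[-nrow(sc)]) / 2
  expect_gt(stats::cor(num, mid), 0.999)
})

test_that("hessian_pair: symmetry and near-zero coupling of independent gains", {
  # two independent linear gains: stage1 scales channel via kernel weight; use
  # a 2-channel diagonal kernel, each output channel driven by its own gain
  x <- video_tensor(array(rnorm(2 * 20 * 4 * 4), c(1, 2, 20, 4, 4)), 1e-3)
  mkm <- function() {
    k <- array(0, c(2, 2, 1, 1, 1)); k[1, 1, , , ] <- 1.3; k[2, 2, , , ] <- 0.7
    m <- cascade_model(list(cascade_stage(kernel3d(k), "linear")))
    m
  }
  truth <- mkm(); reset_state(truth)
  y <- layer_forward(truth, x)
  # scan the two diagonal weights through a thin wrapper factory
  fac <- function() {
    m <- mkm()
    m
  }
  grad2 <- function(va, vb) {
    m <- fac()
    w <- get_parameter(m, "stage1.linear.weight")
    w[1, 1, 1, 1, 1] <- va; w[2, 2, 1, 1, 1] <- vb
    set_parameter(m, "stage1.linear.weight", w)
    g <- param_gradients(m, x, y)$gradients[[1]]
    c(g[1, 1, 1, 1, 1], g[2, 2, 1, 1, 1])
  }
  h <- 1e-3
  H <- matrix(0, 2, 2)
  H[1, ] <- (grad2(1.3 + h, 0.7) - grad2(1.3 - h, 0.7)) / (2 * h)
  H[2, ] <- (grad2(1.3, 0.7 + h) - grad2(1.3, 0.7 - h)) / (2 * h)
  expect_lt(abs(H[1, 2]), 1e-3 * abs(H[1, 1]))
  expect_lt(abs(H[2, 1]), 1e-3 * abs(H[2, 2]))
  # hessian_pair on the bipolar stage is symmetric
  xb <- checkerboard_flicker(shape = c(6L, 6L), frames = 200L, box_px = 2L,
                             mean = 0, amplitude = 80, hold = 25L, seed = 7)
  fac_b <- function() layer_bipolar(bipolar_params(sigma_A = 1))
  tm <- fac_b(); reset_state(tm)
  yb <- layer_forward(tm, xb)
  hp <- hessian_pair(fac_b, xb, yb, "g_leak", "lambda_bip")
  expect_lt(abs(hp$hessian[1, 2] - hp$hessian[2, 1]), 1e-12)  # symmetrized
  expect_true(all(hp$eigen$values > -1e-8))                  # PSD at the optimum
})

test_that("optimize_stimulus: identical models give a flat objective", {
  cfg <- retina_config(spiking_enabled = FALSE)
  ma <- retina_model(cfg); mb <- retina_model(cfg)
  sfun <- function(s) moving_grating(grating_spec(shape = c(6L, 6L), dt = 0.002,
                                                  frames = 60L, speed = s,
                                                  spatial_freq = 0.1))
  r <- optimize_stimulus(ma, mb, sfun, c(5, 20, 80))
  expect_true(r$flat)
  expect_true(is.na(r$argmax))
})

test_that("fraction_variance_explained behaves as a variance ratio", {
  set.seed(55)
  a <- rnorm(4000)
  expect_equal(fraction_variance_explained(a, a), 1)
  expect_equal(fraction_variance_explained(a, rep(mean(a), 4000)), 0,
               tolerance = 1e-12)
  noise <- rnorm(4000)
  fve <- fraction_variance_explained(a, a + noise)
  expect_lt(abs(fve), 3 / sqrt(4000) * 2 + 0.05)
  expect_error(fraction_variance_explained(rep(1, 10), rnorm(10)), "zero")
})
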