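# the retina cascade: OPL, bipolar gain control, ganglion nonlinearity, LIF

test_that("OPL cancels constant luminance when center and surround balance", {
  p <- opl_params(w_surround = 1)
  lum <- wrap_video(array(0.7, c(400, 9, 9)), 0.001)
  out <- opl_stage(lum, p)
  # after ~10 * max(tau) of settling the output vanishes
  expect_lt(max(abs(out$values[, , 300:400, , ])), 1e-6 * p$lambda_opl * 0.7)
})

test_that("OPL without surround is a low-pass with DC gain lambda_opl", {
  p <- opl_params(w_surround = 0, lambda_opl = 5)
  lum <- wrap_video(array(0.4, c(300, 7, 7)), 0.001)
  out <- opl_stage(lum, p)
  expect_lt(abs(out$values[1, 1, 300, 4, 4] - 5 * 0.4), 1e-4)
  expect_error(opl_stage(video_tensor(array(1, c(1, 2, 5, 4, 4)), 0.001), p),
               "monochrome")
})

test_that("OPL step response matches a dense sampled-kernel oracle", {
  # full-field step: spatial blur is identity, so the oracle is the sampled
  # exponential cascade computed with stats::filter (independent code path)
  p <- opl_params()
  dt <- 0.001; K <- 400L
  step <- c(rep(0, 50), rep(1, K - 50))
  lum <- wrap_video(array(rep(step, each = 1), c(K, 5, 5)), dt)
  out <- opl_stage(lum, p)$values[1, 1, , 3, 3]
  lc <- exp(-dt / p$tau_center); ls <- exp(-dt / p$tau_surround)
  C <- as.numeric(stats::filter((1 - lc) * step, lc, method = "recursive"))
  S <- as.numeric(stats::filter((1 - ls) * C, ls, method = "recursive"))
  oracle <- p$lambda_opl * (C - p$w_surround * S)
  expect_lt(max(abs(out - oracle)), 1e-4)
  # transient overshoot, then decay toward lambda * (1 - w) * step
  expect_gt(max(out), p$lambda_opl * (1 - p$w_surround) * 1.05)
  expect_lt(abs(out[K] - p$lambda_opl * (1 - p$w_surround)), 0.01 * p$lambda_opl)
})

test_that("bipolar stage: linear fixed point and divergence guard", {
  p <- bipolar_params(g_leak = 50, lambda_bip = 0)
  cur <- wrap_video(array(10, c(600, 5, 5)), 0.001)
  v <- bipolar_stage(cur, p)
  expect_lt(abs(v$values[1, 1, 600, 3, 3] - 10 / 50), 1e-4)
  expect_error(bipolar_params(g_leak = 0), "g_leak")
})

test_that("contrast gain control: sublinear gain and phase advance", {
  dt <- 1e-3; tt <- seq(dt, 2, by = dt); f <- 4
  p <- bipolar_params()
  measure <- function(contrast) {
    inp <- wrap_video(array(rep(100 * contrast * sin(2 * pi * f * tt), 9),
                            c(length(tt), 3, 3)), dt)
    tr <- bipolar_stage(inp, p)$values[1, 1, , 2, 2]
    cyc <- tr[(length(tt) - round(1 / f / dt) + 1):length(tt)]
    c(gain = max(cyc) / (100 * contrast), peak = which.max(cyc))
  }
  ladder <- t(vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), measure, numeric(2)))
  expect_true(all(diff(ladder[, "gain"]) <= 0))       # non-increasing gain
  expect_lt(ladder[5, "gain"], ladder[2, "gain"])     # strictly smaller at 0.8
  expect_lt(ladder[5, "peak"], ladder[2, "peak"])     # phase advance
})

test_that("bipolar Euler trajectory converges under dt refinement", {
  p <- bipolar_params()
  f <- 3
  mk <- function(dt) {
    tt <- seq(dt, 0.5, by = dt)
    wrap_video(array(rep(80 * sin(2 * pi * f * tt), 4), c(length(tt), 2, 2)), dt)
  }
  v1 <- bipolar_stage(mk(5e-4), p)$values[1, 1, , 1, 1]
  v2 <- bipolar_stage(mk(5e-5), p)$values[1, 1, , 1, 1]
  amp <- max(abs(v1))
  expect_lt(max(abs(v1 - v2[seq(10, length(v2), by = 10)])) / amp, 1e-2)
})

test_that("pre-spike cascade is linear when lambda_bip = 0", {
  cfg_lin <- function() list(opl = opl_params(), bip = bipolar_params(lambda_bip = 0))
  run <- function(lum) {
    cp <- cfg_lin()
    bipolar_stage(opl_stage(lum, cp$opl), cp$bip)
  }
  a <- small_noise(shape = c(5L, 5L), frames = 40L, seed = 20)
  b <- small_noise(shape = c(5L, 5L), frames = 40L, seed = 21)
  sum_in <- video_tensor(a$values + b$values, a$dt)
  expect_lt(maxabs(run(sum_in), run(a)$values + run(b)$values), 1e-5)
})

test_that("ganglion nonlinearity: threshold values, linear branch, asymptote", {
  p <- ganglion_params(sign = 1, v0 = 0.2, lambda_g = 50, i0 = 10)
  at <- function(u) ganglion_current(video_tensor(array(u, c(1, 1, 1)), 1e-3), p)$values[1]
  expect_equal(at(0.2), 10)
  expect_equal(at(1.2), 10 + 50)
  expect_lt(at(0.2 - 1e6 * 10 / 50), 1e-5 * 10)
  expect_gt(at(-5), 0)  # strictly positive everywhere
  expect_error(ganglion_params(i0 = -1), "i0")
})

test_that("ON/OFF currents are antisymmetric around a luminance step", {
  cfg <- retina_config(spiking_enabled = FALSE)
  K <- 500L
  lum <- array(0.5, c(K, 5, 5)); lum[150:K, , ] <- 0.8  # increment step
  o <- run_retina(wrap_video(lum, cfg$dt), cfg)
  on <- o$i_gang_on$values[1, 1, , 3, 3]; off <- o$i_gang_off$values[1, 1, , 3, 3]
  base_on <- on[149]; base_off <- off[149]
  thr <- function(tr, base) {
    i <- which(tr[150:K] > base + 0.05 * abs(base))[1]
    if (is.na(i)) Inf else i
  }
  expect_lt(thr(on, base_on), thr(off, base_off))
  # decrement step: the OFF current leads instead
  lum2 <- array(0.8, c(K, 5, 5)); lum2[150:K, , ] <- 0.5
  o2 <- run_retina(wrap_video(lum2, cfg$dt), cfg)
  on2 <- o2$i_gang_on$values[1, 1, , 3, 3]; off2 <- o2$i_gang_off$values[1, 1, , 3, 3]
  expect_lt(thr(off2, off2[149]), thr(on2, on2[149]))
})

test_that("LIF: closed-form period, silence at zero drive, seeded determinism", {
  p <- lif_params(g_l = 50, v_thresh = 1, v_reset = 0, tau_refr = 0.003,
                  sigma_noise = 0)
  dt <- 1e-4; I <- 100
  cur <- wrap_video(array(I, c(4000, 1, 1)), dt)
  s <- lif_spikes(cur, p)
  isi <- diff(which(s$spikes$values[1, 1, , 1, 1] == 1)) * dt
  pred <- p$tau_refr + (1 / p$g_l) * log((I - p$g_l * p$v_reset) / (I - p$g_l * p$v_thresh))
  expect_true(all(abs(isi - pred) <= dt + 1e-12))
  # zero drive, no noise: silent
  s0 <- lif_spikes(wrap_video(array(0, c(1000, 1, 1)), dt), p)
  expect_equal(sum(s0$spikes$values), 0)
  # same seed twice: identical rasters
  pn <- lif_params(sigma_noise = 0.5, seed = 7)
  cur2 <- wrap_video(array(45, c(800, 2, 2)), 1e-3)
  r1 <- lif_spikes(cur2, pn)$spikes$values
  r2 <- lif_spikes(cur2, pn)$spikes$values
  expect_identical(r1, r2)
  expect_gt(sum(r1), 0)
})

test_that("run_retina: chirp traces, spiking toggle, chunk/whole rasters", {
  cfg <- retina_config()
  lum <- chirp(chirp_spec(d_pre = 0.2, d_pulse = 0.45, d_freq = 0.6, d_amp = 0.6,
                          d_post = 0.1, shape = c(4L, 4L)))
  o <- run_retina(lum, cfg)
  expect_true(all(is.finite(o$i_opl$values)))
  opl_tr <- o$i_opl$values[1, 1, , 2, 2]
  expect_lt(min(opl_tr), 0)   # crosses zero during the OFF-ON-OFF pulse
  expect_gt(max(opl_tr), 0)
  expect_true(all(o$spikes_on$values %in% c(0, 1)))
  # refractoriness: no two spikes of one unit closer than tau_refr
  st <- which(o$spikes_on$values[1, 1, , 2, 2] == 1)
  if (length(st) > 1) expect_true(all(diff(st) * cfg$dt >= cfg$lif$tau_refr - 1e-12))
  o2 <- run_retina(lum, cfg, chunk_len = 157L)
  expect_identical(o$spikes_on$values, o2$spikes_on$values)
  expect_identical(o$spikes_off$values, o2$spikes_off$values)
  expect_lt(maxabs(o$v_bip, o2$v_bip), 1e-10)
  # spiking disabled: currents only
  cfg2 <- retina_config(spiking_enabled = FALSE)
  o3 <- run_retina(lum, cfg2)
  expect_null(o3$spikes_on)
  expect_false(is.null(o3$i_gang_off))
})

test_that("spike_events and spike_rate are consistent with the raster", {
  cfg <- retina_config()
  lum <- chirp(chirp_spec(d_pre = 0.1, d_pulse = 0.3, d_freq = 0, d_amp = 0,
                          d_post = 0.05, shape = c(3L, 3L)))
  o <- run_retina(lum, cfg)
  ev <- spike_events(o$spikes_on)
  expect_equal(nrow(ev), sum(o$spikes_on$values))
  r <- spike_rate(o$spikes_on, tau = 0.02)
  expect_true(all(r$values >= 0))
})

test_that("VirtualRetina-dialect XML maps onto the configuration", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    '<retina-description-file>',
    ' <retina temporal-step__sec="0.002" pixels-per-degree="2">',
    '  <outer-plexiform-layer>',
    '   <linear-version center-sigma__deg="0.5" surround-sigma__deg="1.5"',
    '     center-tau__sec="0.012" opl-relative-weight="0.8"',
    '     radially-varying-blur="1.0" mystery-attr="3"/>',
    '  </outer-plexiform-layer>',
    '  <contrast-gain-control bipolar-inert-leaks__Hz="40" amplification__Hz="60"',
    '     adaptation-sigma__deg="1" adaptation-tau__sec="0.005"/>',
    '  <ganglion-layer sign="1" value-at-linear-threshold__Hz="50">',
    '   <spiking-channel g-leak__Hz="45" sigma-V="0.2" refr-mean__sec="0.004"/>',
    '  </ganglion-layer>',
    ' </retina>',
    '</retina-description-file>'), xml)
  warns <- character(0)
  cfg <- withCallingHandlers(load_vr_xml(xml), warning = function(w) {
    warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  expect_equal(cfg$dt, 0.002)
  expect_equal(cfg$opl$sigma_center, 1)      # 0.5 deg * 2 px/deg
  expect_equal(cfg$opl$sigma_surround, 3)
  expect_equal(cfg$opl$tau_center, 0.012)
  expect_equal(cfg$opl$w_surround, 0.8)
  expect_equal(cfg$bipolar$g_leak, 40)
  expect_equal(cfg$bipolar$lambda_bip, 60)
  expect_equal(cfg$ganglion_on$i0, 50)
  expect_equal(cfg$ganglion_off$i0, 50)
  expect_equal(cfg$ganglion_off$sign, -1)
  expect_equal(cfg$lif$g_l, 45)
  expect_equal(cfg$lif$tau_refr, 0.004)
  expect_true(any(grepl("radially varying", warns)))
  expect_true(any(grepl("mystery-attr", warns)))
  # minimal document: defaults plus one warning per missing section
  xml2 <- tempfile(fileext = ".xml")
  writeLines("<retina-description-file/>", xml2)
  warns2 <- character(0)
  cfg2 <- withCallingHandlers(load_vr_xml(xml2), warning = function(w) {
    warns2 <<- c(warns2, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  expect_equal(cfg2$dt, retina_config()$dt)
  expect_equal(sum(grepl("missing", warns2)), 4)
  # malformed number
  xml3 <- tempfile(fileext = ".xml")
  writeLines('<retina-description-file><retina temporal-step__sec="abc"/></retina-description-file>', xml3)
  expect_error(suppressWarnings(load_vr_xml(xml3)), "temporal-step__sec")
})

test_that("JSON configuration round of the same fields", {
  js <- tempfile(fileext = ".json")
  writeLines('{"dt": 0.002, "bipolar": {"g_leak": 30}, "spiking_enabled": false}', js)
  cfg <- suppressWarnings(load_retina_json(js))
  expect_equal(cfg$dt, 0.002)
  expect_equal(cfg$bipolar$g_leak, 30)
  expect_false(cfg$spiking_enabled)
})
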