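#' @title Seeded stimulus generators
#' @description Pure functions of (specification, seed) producing
#' [video_tensor] movies: the chirp protocol used to characterize retinal
#' ganglion cell types (an OFF-ON-OFF pulse, a frequency sweep, an amplitude
#' sweep), drifting sinusoidal gratings, random checkerboard flicker, moving
#' bars, Gaussian pixel noise, Poisson event trains, and the noisy-letters
#' image used as a ground-truth spatial receptive field in fitting
#' experiments.
#' @name stimuli
NULL

#' Chirp stimulus specification
#'
#' Defaults: 2 s pre-adaptation, 3 s OFF-ON-OFF pulse, frequency sweep
#' 0.5 -> 8 Hz over 8 s, amplitude sweep at 2 Hz over 8 s, 1 s post, dt 1 ms.
#'
#' @param dt frame duration (s).
#' @param base base luminance.
#' @param amplitude pulse / oscillation amplitude.
#' @param d_pre,d_pulse,d_freq,d_amp,d_post segment durations (s).
#' @param f0,f1 frequency sweep range (Hz), `f1 >= f0 >= 0`.
#' @param a0,a1 amplitude sweep range.
#' @param f_amp fixed frequency of the amplitude sweep (Hz).
#' @param shape spatial size `(x, y)`; the movie is spatially constant.
#' @return list of class `chirp_spec`.
#' @export
chirp_spec <- function(dt = 0.001, base = 0.5, amplitude = 0.5,
                       d_pre = 2, d_pulse = 3, d_freq = 8, d_amp = 8, d_post = 1,
                       f0 = 0.5, f1 = 8, a0 = 0.05, a1 = 0.5, f_amp = 2,
                       shape = c(1L, 1L)) {
  stopifnot(dt > 0, d_pre >= 0, d_pulse >= 0, d_freq >= 0, d_amp >= 0,
            d_post >= 0, f1 >= f0, f0 >= 0)
  structure(as.list(environment()), class = "chirp_spec")
}

#' Generate the chirp stimulus
#'
#' @param spec a [chirp_spec].
#' @return a full-field [video_tensor]; every frame is spatially constant.
#' @export
chirp <- function(spec = chirp_spec()) {
  stopifnot(inherits(spec, "chirp_spec"))
  seg <- function(dur) round(dur / spec$dt)
  n_pre <- seg(spec$d_pre); n_pulse <- seg(spec$d_pulse)
  n_freq <- seg(spec$d_freq); n_amp <- seg(spec$d_amp); n_post <- seg(spec$d_post)
  lum <- rep(spec$base, n_pre)
  # OFF-ON-OFF pulse in thirds
  third <- n_pulse %/% 3L
  lum <- c(lum,
           rep(spec$base - spec$amplitude, third),
           rep(spec$base + spec$amplitude, third),
           rep(spec$base - spec$amplitude, n_pulse - 2L * third))
  # linear frequency sweep: phase = 2*pi*(f0 t + (f1-f0) t^2 / (2 T))
  if (n_freq > 0L) {
    t <- seq_len(n_freq) * spec$dt
    phase <- 2 * pi * (spec$f0 * t + (spec$f1 - spec$f0) * t^2 / (2 * spec$d_freq))
    lum <- c(lum, spec$base + spec$amplitude * sin(phase))
  }
  # amplitude sweep at fixed frequency
  if (n_amp > 0L) {
    t <- seq_len(n_amp) * spec$dt
    a <- spec$a0 + (spec$a1 - spec$a0) * t / spec$d_amp
    lum <- c(lum, spec$base + a * sin(2 * pi * spec$f_amp * t))
  }
  lum <- c(lum, rep(spec$base, n_post))
  K <- length(lum)
  vals <- array(rep(lum, times = prod(spec$shape)), c(K, spec$shape[1L], spec$shape[2L]))
  wrap_video(vals, dt = spec$dt)
}

#' Grating stimulus specification
#'
#' @param shape spatial size `(x, y)` in px.
#' @param dt frame duration (s).
#' @param frames number of frames.
#' @param direction drift direction in degrees.
#' @param speed drift speed in px/s.
#' @param spatial_freq spatial frequency in cycles/px.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param mean mean luminance.
#' @return list of class `grating_spec`.
#' @export
grating_spec <- function(shape = c(20L, 20L), dt = 0.001, frames = 500L,
                         direction = 0, speed = 10, spatial_freq = 0.1,
                         contrast = 0.5, mean = 0.5) {
  stopifnot(contrast >= 0, contrast <= 1, dt > 0, frames >= 1)
  structure(as.list(environment()), class = "grating_spec")
}

#' Generate a drifting sinusoidal grating
#'
#' `L(x,y,t) = mean (1 + contrast sin(2 pi sf (x cos th + y sin th)
#'  - 2 pi sf speed t))`.
#'
#' @param spec a [grating_spec].
#' @return a [video_tensor].
#' @export
moving_grating <- function(spec = grating_spec()) {
  stopifnot(inherits(spec, "grating_spec"))
  th <- spec$direction * pi / 180
  xs <- seq_len(spec$shape[1L]); ys <- seq_len(spec$shape[2L])
  proj <- outer(xs * cos(th), ys * sin(th), "+")       # x cos + y sin
  vals <- array(0, c(spec$frames, spec$shape[1L], spec$shape[2L]))
  for (k in seq_len(spec$frames)) {
    t <- (k - 1L) * spec$dt
    vals[k, , ] <- spec$mean *
      (1 + spec$contrast * sin(2 * pi * spec$spatial_freq * proj -
                               2 * pi * spec$spatial_freq * spec$speed * t))
  }
  wrap_video(vals, dt = spec$dt)
}

#' Random checkerboard flicker
#'
#' Each `box_px`-sized box takes an independent +/-1 value per frame from the
#' seeded stream, scaled to `[mean - amplitude, mean + amplitude]`.  Edge
#' boxes are truncated when `box_px` does not divide the shape.
#'
#' @param shape spatial size `(x, y)`.
#' @param dt frame duration (s).
#' @param frames number of frames.
#' @param box_px box edge length in px.
#' @param mean,amplitude luminance scaling.
#' @param hold frames each random pattern is held before redrawing (stimulus
#'   update interval in units of `dt`).
#' @param seed RNG seed.
#' @return a [video_tensor].
#' @export
checkerboard_flicker <- function(shape = c(16L, 16L), dt = 0.001, frames = 500L,
                                 box_px = 4L, mean = 0.5, amplitude = 0.5,
                                 hold = 1L, seed = 0) {
  nbx <- ceiling(shape[1L] / box_px); nby <- ceiling(shape[2L] / box_px)
  bx <- pmin((seq_len(shape[1L]) - 1L) %/% box_px + 1L, nbx)
  by <- pmin((seq_len(shape[2L]) - 1L) %/% box_px + 1L, nby)
  hold <- max(1L, as.integer(hold))
  ndraw <- ceiling(frames / hold)
  vals <- withr_seed(seed, {
    draws <- array(sample(c(-1, 1), ndraw * nbx * nby, replace = TRUE),
                   c(ndraw, nbx, nby))
    v <- array(0, c(frames, shape[1L], shape[2L]))
    for (k in seq_len(frames)) {
      dk <- (k - 1L) %/% hold + 1L
      v[k, , ] <- mean + amplitude * draws[dk, bx, by]
    }
    v
  })
  wrap_video(vals, dt = dt)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded generators never disturb user randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Moving bright bar
#'
#' A bar of the given width, perpendicular to the motion direction, translates
#' at `speed` px/s across the frame over a dark background.
#'
#' @param shape spatial size `(x, y)`.
#' @param dt frame duration (s).
#' @param frames number of frames.
#' @param width_px bar width in px.
#' @param speed translation speed in px/s.
#' @param direction motion direction in degrees.
#' @param luminance,background bar and background luminance.
#' @return a [video_tensor].
#' @export
moving_bar <- function(shape = c(20L, 20L), dt = 0.001, frames = 100L,
                       width_px = 3, speed = 100, direction = 0,
                       luminance = 1, background = 0) {
  th <- direction * pi / 180
  xs <- seq_len(shape[1L]); ys <- seq_len(shape[2L])
  proj <- outer(xs * cos(th), ys * sin(th), "+")
  p0 <- min(proj) - width_px / 2
  vals <- array(background, c(frames, shape[1L], shape[2L]))
  for (k in seq_len(frames)) {
    ck <- p0 + speed * (k - 1L) * dt
    vals[k, , ][abs(proj - ck) <= width_px / 2] <- luminance
  }
  wrap_video(vals, dt = dt)
}

#' Gaussian pixel noise
#'
#' Independent normal draws per pixel per frame.
#'
#' @param shape spatial size `(x, y)`.
#' @param dt frame duration (s).
#' @param frames number of frames.
#' @param mean mean luminance.
#' @param level standard deviation (>= 0).
#' @param seed RNG seed.
#' @return a [video_tensor].
#' @export
gaussian_noise <- function(shape = c(10L, 10L), dt = 0.001, frames = 500L,
                           mean = 0.5, level = 0.2, seed = 0) {
  if (level < 0) stop("level must be >= 0")
  vals <- withr_seed(seed, {
    array(stats::rnorm(frames * prod(shape), mean, level),
          c(frames, shape[1L], shape[2L]))
  })
  wrap_video(vals, dt = dt)
}

#' Poisson event train on the discrete frame grid
#'
#' Bernoulli thinning: each frame holds an event with probability
#' `rate_hz * dt` (exact on the grid the filters use).  A warning is issued
#' outside the thinning regime `rate * dt > 0.2`.
#'
#' @param rate_hz event rate in Hz.
#' @param duration_s train duration in seconds.
#' @param dt frame duration (s).
#' @param seed RNG seed.
#' @return a single-pixel [video_tensor] of 0/1 values.
#' @export
poisson_events <- function(rate_hz, duration_s, dt = 0.001, seed = 0) {
  p <- rate_hz * dt
  if (p > 0.2) warning("rate * dt = ", p, " is outside the thinning regime")
  K <- round(duration_s / dt)
  ev <- withr_seed(seed, as.numeric(stats::runif(K) < p))
  wrap_video(array(ev, c(K, 1L, 1L)), dt = dt)
}

# 3x5 glyphs for the built-in letter raster
cc_glyphs <- list(
  c = c("111", "100", "100", "100", "111"),
  o = c("111", "101", "101", "101", "111"),
  n = c("101", "111", "111", "101", "101"),
  v = c("101", "101", "101", "101", "010"),
  i = c("111", "010", "010", "010", "111"),
  s = c("111", "100", "111", "001", "111"))

glyph_mat <- function(ch) {
  rows <- cc_glyphs[[ch]]
  t(vapply(rows, function(r) as.numeric(strsplit(r, "")[[1L]]), numeric(3)))
}

# 16x16 binary raster spelling "con" over "vis"
letters_mask <- function() {
  m <- matrix(0, 16L, 16L)
  place <- function(m, word, row0) {
    col <- 3L
    for (ch in strsplit(word, "")[[1L]]) {
      g <- glyph_mat(ch)  # 5 rows x 3 cols
      m[row0:(row0 + 4L), col:(col + 2L)] <- g
      col <- col + 4L
    }
    m
  }
  m <- place(m, "con", 3L)
  place(m, "vis", 10L)
}

#' Noisy-letters ground-truth receptive field
#'
#' The built-in 16 x 16 binary raster spelling "con" / "vis" (or a
#' user-supplied binary mask) plus i.i.d. normal noise: a delicate spatial
#' structure used as ground truth in receptive-field recovery experiments.
#'
#' @param noise_sigma standard deviation of the added noise.
#' @param seed RNG seed for the noise field.
#' @param mask_pattern optional binary matrix replacing the built-in raster.
#' @return a numeric matrix.
#' @export
letters_rf <- function(noise_sigma = 0.1, seed = 0, mask_pattern = NULL) {
  m <- if (is.null(mask_pattern)) letters_mask() else as.matrix(mask_pattern)
  if (noise_sigma > 0) {
    m <- m + withr_seed(seed, matrix(stats::rnorm(length(m), 0, noise_sigma),
                                     nrow(m), ncol(m)))
  }
  m
}
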