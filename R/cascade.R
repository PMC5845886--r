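#' @title LN cascade model family and direction-selective kernels
#' @description Configurable linear-nonlinear cascades: LN, subunit models
#' (LNSN, also written LNLN), and feedback variants (LNSNF, LNFSNF, LNFDSNF)
#' where a stage's own output, exponentially filtered, delayed by at least one
#' frame and gain-weighted, is subtracted from its input.  Also constructs
#' space-time kernels for direction-selective cells: a Gaussian envelope that
#' translates across the receptive field, trailed by a negative Gaussian so
#' that only moving edges excite the cell.
#' @name cascade-models
NULL

#' Describe one cascade stage
#'
#' @param linear a [kernel3d] (dense convolution) or a positive number, read
#'   as the time constant of an exponential temporal filter.
#' @param nonlinearity a [nonlinearity_spec] or kind string.
#' @param feedback optional list with elements `tau` (s, exponential feedback
#'   filter), `delay` (frames, >= 1) and `gain`; the filtered, delayed stage
#'   output is subtracted from the stage input.
#' @return list of class `cascade_stage`.
#' @export
cascade_stage <- function(linear, nonlinearity = "linear", feedback = NULL) {
  if (!is.null(feedback)) {
    stopifnot(is.list(feedback))
    if (is.null(feedback$delay)) feedback$delay <- 1L
    feedback$delay <- as.integer(feedback$delay)
    if (feedback$delay < 1L) stop("feedback delay must be >= 1 frame (causality)")
    if (is.null(feedback$gain)) feedback$gain <- 1
    if (is.null(feedback$tau)) feedback$tau <- 0.01
  }
  structure(list(linear = linear, nonlinearity = nonlinearity, feedback = feedback),
            class = "cascade_stage")
}

stage_channels <- function(linear) {
  if (inherits(linear, "kernel3d")) dim(linear)[1:2] else c(NA_integer_, NA_integer_)
}

#' Build a cascade model from a list of stages
#'
#' @param stages list of [cascade_stage()]s; channel counts must chain
#'   between consecutive convolution stages.
#' @return a composite layer of class `cc_cascade`.
#' @export
cascade_model <- function(stages) {
  stopifnot(length(stages) >= 1L)
  prev_out <- NA_integer_
  children <- list()
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    stopifnot(inherits(st, "cascade_stage"))
    ch <- stage_channels(st$linear)
    if (!is.na(prev_out) && !is.na(ch[2L]) && ch[2L] != prev_out) {
      stop("channel mismatch at stage ", i, ": previous stage emits ", prev_out,
           " channels, this stage expects ", ch[2L])
    }
    if (!is.na(ch[1L])) prev_out <- ch[1L]
    s <- new_layer("cc_stage",
                   init_state = function() list(fb_queue = NULL, fb_pending = NULL))
    s$children <- list(
      linear = if (inherits(st$linear, "kernel3d")) layer_conv3d(st$linear)
               else layer_exp_smooth(st$linear),
      nl = layer_nonlinearity(st$nonlinearity))
    if (!is.null(st$feedback)) {
      fb <- layer_exp_smooth(st$feedback$tau)
      fb$trainable <- character()
      s$children$fb_filter <- fb
      s$params$fb_gain <- st$feedback$gain
      s$fb_delay <- st$feedback$delay
    } else {
      s$fb_delay <- NULL
    }
    children[[paste0("stage", i)]] <- s
  }
  m <- new_layer("cc_cascade")
  m$children <- children
  m
}

#' @export
layer_forward.cc_stage <- function(layer, x, record = FALSE) {
  if (is.null(layer$fb_delay)) {
    y <- layer_forward(layer$children$linear, x, record = record)
    return(layer_forward(layer$children$nl, y, record = record))
  }
  # feedback: process frame by frame so past outputs can modulate the input
  d <- dim(x$values)
  TT <- d[3L]
  gain <- layer$params$fb_gain
  delay <- layer$fb_delay
  queue <- layer$state$fb_queue  # list of the last `delay` filtered outputs
  out <- NULL
  for (k in seq_len(TT)) {
    xk <- x$values[, , k, , , drop = FALSE]
    fb_val <- if (!is.null(queue) && length(queue) >= delay) queue[[1L]] else 0
    xk <- xk - gain * fb_val
    vk <- video_tensor(xk, dt = x$dt, t0 = x$t0 + (k - 1) * x$dt)
    yk <- layer_forward(layer$children$nl,
                        layer_forward(layer$children$linear, vk))
    fk <- layer_forward(layer$children$fb_filter, yk)
    if (is.null(queue)) queue <- list()
    queue[[length(queue) + 1L]] <- fk$values
    if (length(queue) > delay) queue <- queue[-1L]
    if (is.null(out)) {
      dy <- dim(yk$values)
      out <- array(0, c(dy[1:2], TT, dy[4:5]))
    }
    out[, , k, , ] <- yk$values
  }
  layer$state$fb_queue <- queue
  video_tensor(out, dt = x$dt, t0 = x$t0)
}

#' @export
layer_backward.cc_stage <- function(layer, gy) {
  if (!is.null(layer$fb_delay)) {
    stop("gradients through feedback stages are not supported")
  }
  layer_backward(layer$children$linear,
                 layer_backward(layer$children$nl, gy))
}

#' @export
layer_forward.cc_cascade <- function(layer, x, record = FALSE) {
  for (ch in layer$children) x <- layer_forward(ch, x, record = record)
  x
}

#' @export
layer_backward.cc_cascade <- function(layer, gy) {
  for (ch in rev(layer$children)) gy <- layer_backward(ch, gy)
  gy
}

#' Convenience constructors for the LN model family
#'
#' `model_LN` is a single linear-nonlinear stage; `model_LNSN` stacks two
#' (the subunit model, also written LNLN); `model_LNSNF` adds feedback to the
#' second stage, `model_LNFSNF` to both, and `model_LNFDSNF` uses feedback
#' with a configurable delay at both stages.
#'
#' @param kernel,kernel1,kernel2 [kernel3d] stage kernels.
#' @param nl,nl1,nl2 nonlinearity kind strings or [nonlinearity_spec]s.
#' @param fb_tau,fb_gain,fb_delay feedback filter time constant (s), gain and
#'   delay (frames).
#' @return a cascade model layer.
#' @export
model_LN <- function(kernel, nl = "half_wave") {
  cascade_model(list(cascade_stage(kernel3d(kernel), nl)))
}

#' @rdname model_LN
#' @export
model_LNSN <- function(kernel1, kernel2, nl1 = "half_wave", nl2 = "half_wave") {
  cascade_model(list(cascade_stage(kernel3d(kernel1), nl1),
                     cascade_stage(kernel3d(kernel2), nl2)))
}

#' @rdname model_LN
#' @export
model_LNSNF <- function(kernel1, kernel2, nl1 = "half_wave", nl2 = "half_wave",
                        fb_tau = 0.01, fb_gain = 0.5) {
  cascade_model(list(
    cascade_stage(kernel3d(kernel1), nl1),
    cascade_stage(kernel3d(kernel2), nl2,
                  feedback = list(tau = fb_tau, gain = fb_gain, delay = 1L))))
}

#' @rdname model_LN
#' @export
model_LNFSNF <- function(kernel1, kernel2, nl1 = "half_wave", nl2 = "half_wave",
                         fb_tau = 0.01, fb_gain = 0.5) {
  cascade_model(list(
    cascade_stage(kernel3d(kernel1), nl1,
                  feedback = list(tau = fb_tau, gain = fb_gain, delay = 1L)),
    cascade_stage(kernel3d(kernel2), nl2,
                  feedback = list(tau = fb_tau, gain = fb_gain, delay = 1L))))
}

#' @rdname model_LN
#' @export
model_LNFDSNF <- function(kernel1, kernel2, nl1 = "half_wave", nl2 = "half_wave",
                          fb_tau = 0.01, fb_gain = 0.5, fb_delay = 5L) {
  cascade_model(list(
    cascade_stage(kernel3d(kernel1), nl1,
                  feedback = list(tau = fb_tau, gain = fb_gain, delay = fb_delay)),
    cascade_stage(kernel3d(kernel2), nl2,
                  feedback = list(tau = fb_tau, gain = fb_gain, delay = fb_delay))))
}

#' Run a cascade on a video
#' @param video input [video_tensor].
#' @param model a cascade model (state is reset first).
#' @return output [video_tensor].
#' @export
cascade_forward <- function(video, model) {
  reset_state(model)
  layer_forward(model, video)
}

# --- direction-selective kernels ---------------------------------------------

#' Describe a direction-selective space-time kernel
#'
#' @param direction preferred direction in degrees (0 = +x).
#' @param speed envelope translation speed in px/frame.
#' @param sigma Gaussian envelope width in px.
#' @param trail_lag frames between the positive Gaussian and the negative one
#'   trailing it (>= 1); the pairing makes the cell edge-selective.
#' @param duration kernel length in frames.
#' @param extent spatial kernel size in px (square).
#' @return list of class `ds_kernel_spec`.
#' @export
ds_kernel_spec <- function(direction = 0, speed = 1, sigma = 1.5, trail_lag = 2L,
                           duration = 9L, extent = 15L) {
  trail_lag <- as.integer(trail_lag)
  if (trail_lag < 1L) stop("trail_lag must be >= 1")
  if (speed * duration > extent) {
    stop("speed * duration = ", speed * duration,
         " px exceeds the spatial extent (", extent, " px)")
  }
  structure(list(direction = direction, speed = speed, sigma = sigma,
                 trail_lag = trail_lag, duration = as.integer(duration),
                 extent = as.integer(extent)),
            class = "ds_kernel_spec")
}

gauss2d_at <- function(extent, cx, cy, sigma) {
  gx <- exp(-((seq_len(extent) - cx)^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(extent) - cy)^2) / (2 * sigma^2))
  outer(gx, gy)
}

#' Construct a direction-selective 3D kernel
#'
#' Frame `tau` holds a positive Gaussian at
#' `center0 + (tau - 1) * speed * (cos theta, sin theta)` minus a negative
#' Gaussian at the position of lag `tau - trail_lag` (absent while undefined).
#' The kernel is mean-subtracted so its sum is zero: a constant stimulus
#' cannot excite the cell, only edges can.
#'
#' @param spec a [ds_kernel_spec].
#' @return a [kernel3d] of shape `(1, 1, duration, extent, extent)`.
#' @export
make_ds_kernel <- function(spec) {
  stopifnot(inherits(spec, "ds_kernel_spec"))
  th <- spec$direction * pi / 180
  u <- c(cos(th), sin(th))
  mid <- (spec$extent + 1) / 2
  travel <- (spec$duration - 1) * spec$speed
  c0 <- c(mid, mid) - travel / 2 * u
  pos <- function(tau) c0 + (tau - 1) * spec$speed * u
  for (tau in seq_len(spec$duration)) {
    p <- pos(tau)
    if (any(p < 1) || any(p > spec$extent)) {
      stop("the moving envelope leaves the spatial extent at frame ", tau)
    }
  }
  w <- array(0, c(1L, 1L, spec$duration, spec$extent, spec$extent))
  for (tau in seq_len(spec$duration)) {
    p <- pos(tau)
    fr <- gauss2d_at(spec$extent, p[1L], p[2L], spec$sigma)
    lag <- tau - spec$trail_lag
    if (lag >= 1L) {
      q <- pos(lag)
      fr <- fr - gauss2d_at(spec$extent, q[1L], q[2L], spec$sigma)
    }
    w[1L, 1L, tau, , ] <- fr
  }
  w <- w - mean(w)
  kernel3d(w)
}

#' Direction-selective response: rectified filter output pooled over space
#'
#' The absolute value of the convolution response is taken per pixel (so both
#' bright and dark edges drive the cell) and summed over space per frame.
#'
#' @param video a [video_tensor].
#' @param kernel a [kernel3d].
#' @return numeric time series, one value per frame.
#' @export
ds_response <- function(video, kernel) {
  y <- conv3d(video, kernel)
  apply(abs(y$values), 3L, sum)
}

#' Direction tuning curve of a DS kernel
#'
#' Probes the kernel with a drifting stimulus swept over a set of directions
#' at the kernel's own speed and returns the mean rectified response per
#' direction, normalized to a maximum of 1.  The default probe is a smooth
#' sinusoidal grating; a hard-edged moving bar is also available but its
#' pixel-grid aliasing biases responses toward axis-aligned directions.
#'
#' @param spec the [ds_kernel_spec] used to build the kernel.
#' @param directions probe directions in degrees (>= 8 values).
#' @param stimulus `"grating"` or `"bar"`.
#' @param frames probe stimulus duration in frames.
#' @param spatial_freq grating spatial frequency (cycles/px).
#' @param bar_width bar width in px.
#' @param dt frame duration in seconds (scales speed only).
#' @return data.frame with columns `direction` and `response` (max 1).
#' @export
direction_tuning <- function(spec, directions = seq(0, 337.5, by = 22.5),
                             stimulus = c("grating", "bar"),
                             frames = 64L, spatial_freq = 0.08, bar_width = 3,
                             dt = 0.001) {
  if (length(directions) < 8L) stop("need at least 8 probe directions")
  stimulus <- match.arg(stimulus)
  kernel <- make_ds_kernel(spec)
  resp <- vapply(directions, function(th) {
    stim <- if (stimulus == "grating") {
      moving_grating(grating_spec(shape = c(spec$extent, spec$extent), dt = dt,
                                  frames = frames, direction = th,
                                  speed = spec$speed / dt,
                                  spatial_freq = spatial_freq,
                                  contrast = 1, mean = 0.5))
    } else {
      moving_bar(shape = c(spec$extent, spec$extent), dt = dt, frames = frames,
                 width_px = bar_width, speed = spec$speed / dt, direction = th)
    }
    mean(ds_response(stim, kernel))
  }, numeric(1))
  if (max(resp) > 0) resp <- resp / max(resp)
  data.frame(direction = directions, response = resp)
}
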