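#' @title Recursive (IIR) temporal filters
#' @description Per-pixel recursive filtering in time,
#' `Y(k) = sum_{j=0}^{M-1} b_j X(k-j) - sum_{i=1}^{N} a_i Y(k-i)`,
#' with zero initial history (or the layer's state buffer when streaming).
#' The computation runs in temporally correct order; past outputs feed back
#' through the `a` coefficients.  A first-order special case with unit DC
#' gain, the exponential smoother `Y(k) = (1-lambda) X(k) + lambda Y(k-1)`
#' with `lambda = exp(-dt/tau)`, carries an analytic gradient for its time
#' constant `tau`.
#' @name iir-ops
NULL

# (b,c,t,x,y) <-> (t, pixels) matrix
vt_as_mat <- function(vals) {
  d <- dim(vals)
  matrix(aperm(vals, c(3L, 1L, 2L, 4L, 5L)), nrow = d[3L])
}

mat_as_vt <- function(m, d) {
  aperm(array(m, c(d[3L], d[1L], d[2L], d[4L], d[5L])), c(2L, 3L, 1L, 4L, 5L))
}

#' Construct a recursive filter from coefficient vectors
#'
#' @param b input coefficients `b_0 ... b_{M-1}` (length `M >= 1`).
#' @param a feedback coefficients `a_1 ... a_N` applied to past outputs
#'   (length `N >= 0`); `N = 0` gives a finite impulse response.
#' @return an object of class `iir_filter`.
#' @export
iir_filter <- function(b, a = numeric(0)) {
  b <- as.numeric(b); a <- as.numeric(a)
  if (length(b) < 1L || !all(is.finite(b)) || !all(is.finite(a))) {
    stop("iir_filter needs finite coefficients with length(b) >= 1")
  }
  structure(list(b = b, a = a), class = "iir_filter")
}

#' Check stability of a recursive filter
#'
#' @param filt an [iir_filter].
#' @return `TRUE` when every characteristic root lies strictly inside the unit
#'   circle (always `TRUE` for FIR filters).
#' @export
iir_stable <- function(filt) {
  N <- length(filt$a)
  if (N == 0L) return(TRUE)
  roots <- polyroot(rev(c(1, filt$a)))
  all(Mod(roots) < 1)
}

#' Create a recursive temporal filter layer
#'
#' State buffers hold the last `M - 1` inputs and `N` outputs per pixel, so
#' chunked streaming equals one-pass filtering exactly.
#'
#' @param filt an [iir_filter].
#' @return a layer.
#' @export
layer_iir <- function(filt) {
  stopifnot(inherits(filt, "iir_filter"))
  new_layer("cc_iir",
            params = list(b = filt$b, a = filt$a),
            trainable = character(),
            init_state = function() list(x_hist = NULL, y_hist = NULL))
}

#' @export
layer_forward.cc_iir <- function(layer, x, record = FALSE) {
  b <- layer$params$b; a <- layer$params$a
  M <- length(b); N <- length(a)
  d <- dim(x$values)
  TT <- d[3L]
  P <- prod(d[-3L])
  xm <- vt_as_mat(x$values)
  xh <- layer$state$x_hist
  if (M > 1L && is.null(xh)) xh <- matrix(0, M - 1L, P)
  yh <- layer$state$y_hist
  if (N > 0L && is.null(yh)) yh <- matrix(0, N, P)  # row N = most recent
  # FIR part on [history; input]
  xp <- if (M > 1L) rbind(xh, xm) else xm
  z <- matrix(0, TT, P)
  for (j in seq_len(M)) {
    # b_j (1-based) multiplies X(k - (j-1)); padded row index k + M - j
    z <- z + b[j] * xp[(M - j + 1L):(M - j + TT), , drop = FALSE]
  }
  # recursive part
  if (N > 0L) {
    y <- matrix(0, TT, P)
    for (k in seq_len(TT)) {
      acc <- z[k, ]
      for (i in seq_len(N)) {
        yprev <- if (k - i >= 1L) y[k - i, ] else yh[N + (k - i), ]
        acc <- acc - a[i] * yprev
      }
      y[k, ] <- acc
    }
  } else {
    y <- z
  }
  if (M > 1L) layer$state$x_hist <- xp[(TT + 1L):(TT + M - 1L), , drop = FALSE]
  if (N > 0L) {
    ypad <- rbind(yh, y)
    layer$state$y_hist <- ypad[(TT + N - (N - 1L)):(TT + N), , drop = FALSE]
  }
  video_tensor(mat_as_vt(y, d), dt = x$dt, t0 = x$t0)
}

#' Apply a recursive temporal filter to a video (stateless wrapper)
#'
#' @param video a [video_tensor].
#' @param filt an [iir_filter].
#' @return the filtered [video_tensor].
#' @export
iir_temporal <- function(video, filt) {
  layer_forward(layer_iir(filt), video)
}

# --- exponential smoother ----------------------------------------------------

#' Create an exponential low-pass layer with trainable time constant
#'
#' First-order low-pass with unit DC gain:
#' `Y(k) = (1 - lambda) X(k) + lambda Y(k-1)`, `lambda = exp(-dt/tau)`.
#' The `tau` parameter (seconds) carries an analytic reverse-mode gradient.
#'
#' @param tau time constant in seconds, > 0.
#' @return a layer.
#' @export
layer_exp_smooth <- function(tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  new_layer("cc_exp_smooth",
            params = list(tau = tau),
            trainable = "tau",
            init_state = function() list(y_prev = NULL))
}

#' @export
layer_forward.cc_exp_smooth <- function(layer, x, record = FALSE) {
  tau <- layer$params$tau
  if (tau <= 0) stop("tau must be > 0")
  lam <- exp(-x$dt / tau)
  d <- dim(x$values)
  TT <- d[3L]
  xm <- vt_as_mat(x$values)
  yp <- layer$state$y_prev
  if (!is.null(yp) && length(yp) != ncol(xm)) {
    stop("mid-stream shape change: reset_state() before feeding a new geometry")
  }
  if (is.null(yp)) yp <- rep(0, ncol(xm))
  y0 <- yp
  # first-order recursion per column at C speed
  y <- vapply(seq_len(ncol(xm)), function(p) {
    as.numeric(stats::filter((1 - lam) * xm[, p], lam, method = "recursive",
                             init = y0[p]))
  }, numeric(TT))
  dim(y) <- c(TT, ncol(xm))
  layer$state$y_prev <- y[TT, ]
  if (record) layer$cache <- list(x = xm, y = y, y0 = y0, lam = lam, dt = x$dt, d = d)
  video_tensor(mat_as_vt(y, d), dt = x$dt, t0 = x$t0)
}

#' @export
layer_backward.cc_exp_smooth <- function(layer, gy) {
  cc <- layer$cache
  if (is.null(cc)) stop("exp_smooth backward requires a recorded forward pass")
  gym <- vt_as_mat(gy)
  TT <- nrow(gym)
  # adjoint of the recursion is the same filter run in reverse time
  ybar <- vapply(seq_len(ncol(gym)), function(p) {
    rev(as.numeric(stats::filter(rev(gym[, p]), cc$lam, method = "recursive")))
  }, numeric(TT))
  dim(ybar) <- c(TT, ncol(gym))
  yprev <- rbind(cc$y0, cc$y[-TT, , drop = FALSE])
  glam <- sum(ybar * (yprev - cc$x))
  gx <- (1 - cc$lam) * ybar
  tau <- layer$params$tau
  layer$grads$tau <- layer$grads$tau + glam * cc$lam * cc$dt / tau^2
  mat_as_vt(gx, cc$d)
}

#' Exponentially smooth a video in time (stateless wrapper)
#'
#' @param video a [video_tensor].
#' @param tau time constant in seconds, > 0.
#' @return the smoothed [video_tensor] (unit DC gain).
#' @export
exp_smooth <- function(video, tau) {
  layer_forward(layer_exp_smooth(tau), video)
}
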