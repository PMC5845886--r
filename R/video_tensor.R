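#' Five-axis video tensors
#'
#' The universal signal container of the package: a real array with axes
#' `(batch, channel, time, x, y)`, a frame duration `dt` (seconds) and a start
#' time `t0`.  Every filter stage consumes and produces `video_tensor`
#' objects, so a model is a composition of maps on this one type.
#'
#' @param values numeric array; either 5-D `(b, c, t, x, y)` or 3-D
#'   `(t, x, y)` (batch and channel axes of length 1 are prepended).
#' @param dt frame duration in seconds, strictly positive.
#' @param t0 start time in seconds.
#' @return an object of class `video_tensor` with fields `values`, `dt`, `t0`.
#' @examples
#' v <- video_tensor(array(0, c(10, 4, 4)), dt = 0.001)
#' dim(v$values)  # 1 1 10 4 4
#' @export
video_tensor <- function(values, dt, t0 = 0) {
  values <- as.array(values)
  if (length(dim(values)) == 3L) {
    values <- array(values, c(1L, 1L, dim(values)))
  }
  if (length(dim(values)) != 5L) {
    stop("video_tensor values must be a 3-D (t,x,y) or 5-D (b,c,t,x,y) array, got rank ",
         length(dim(values)))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at index (", paste(bad, collapse = ","), ")")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number")
  }
  structure(list(values = values, dt = dt, t0 = t0), class = "video_tensor")
}

#' Wrap a plain (time, x, y) movie as a video tensor
#'
#' Prepends batch and channel axes of length 1; values are unchanged.
#'
#' @param frames 3-D numeric array `(time, x, y)`, all finite.
#' @param dt frame duration in seconds.
#' @param t0 start time in seconds.
#' @return a [video_tensor].
#' @seealso [unwrap_video()] for the inverse.
#' @export
wrap_video <- function(frames, dt, t0 = 0) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L) {
    stop("wrap_video expects a 3-D (time, x, y) array, got rank ", length(dim(frames)))
  }
  video_tensor(frames, dt = dt, t0 = t0)
}

#' Recover the (time, x, y) movie from a single-batch, single-channel tensor
#'
#' @param video a [video_tensor] with batch and channel axes of length 1.
#' @return a 3-D array; `unwrap_video(wrap_video(x, dt))` is `x` bit-identically.
#' @export
unwrap_video <- function(video) {
  stopifnot(inherits(video, "video_tensor"))
  d <- dim(video$values)
  if (d[1L] != 1L || d[2L] != 1L) {
    stop("unwrap_video needs batch and channel axes of length 1, got (",
         d[1L], ",", d[2L], ")")
  }
  array(video$values, d[3:5])
}

#' @export
print.video_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<video_tensor %d batch x %d channel x %d frames x %dx%d px, dt=%g s, t0=%g s>\n",
              d[1], d[2], d[3], d[4], d[5], x$dt, x$t0))
  invisible(x)
}

vt_nframes <- function(video) dim(video$values)[3L]

# slice frames [i1, i2] keeping class and time origin
vt_time_slice <- function(video, i1, i2) {
  video_tensor(video$values[, , i1:i2, , , drop = FALSE], dt = video$dt,
               t0 = video$t0 + (i1 - 1L) * video$dt)
}

# concatenate video tensors along the time axis
vt_time_concat <- function(vts) {
  stopifnot(length(vts) >= 1L)
  d <- dim(vts[[1L]]$values)
  total <- sum(vapply(vts, vt_nframes, integer(1)))
  out <- array(0, c(d[1L], d[2L], total, d[4L], d[5L]))
  at <- 1L
  for (v in vts) {
    n <- vt_nframes(v)
    out[, , at:(at + n - 1L), , ] <- v$values
    at <- at + n
  }
  video_tensor(out, dt = vts[[1L]]$dt, t0 = vts[[1L]]$t0)
}

#' Resample a video tensor in time by linear interpolation
#'
#' The new grid spans the same `[t0, t0 + K*dt]` interval as the input; each
#' pixel trace is linearly interpolated onto it and the `dt` field is updated.
#'
#' @param video a [video_tensor].
#' @param dt_new new frame duration in seconds.
#' @return the resampled [video_tensor].
#' @export
resample_video <- function(video, dt_new) {
  stopifnot(inherits(video, "video_tensor"))
  if (!is.numeric(dt_new) || dt_new <= 0) stop("dt_new must be positive")
  d <- dim(video$values)
  K <- d[3L]
  t_old <- (seq_len(K) - 1L) * video$dt
  span <- (K - 1L) * video$dt
  K_new <- floor(span / dt_new) + 1L
  if (K_new < 2L) {
    stop("dt_new = ", dt_new, " leaves fewer than 2 frames over a span of ",
         span, " s")
  }
  t_new <- (seq_len(K_new) - 1L) * dt_new
  # (K, P) matrix of pixel traces -> interpolate columns at once
  mat <- matrix(aperm(video$values, c(3L, 1L, 2L, 4L, 5L)), nrow = K)
  out <- apply(mat, 2L, function(col) stats::approx(t_old, col, xout = t_new)$y)
  out <- array(out, c(K_new, d[1L], d[2L], d[4L], d[5L]))
  video_tensor(aperm(out, c(2L, 3L, 1L, 4L, 5L)), dt = dt_new, t0 = video$t0)
}
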