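#' @title Dense 3D spatio-temporal convolution
#' @description Arbitrary, non-separable receptive fields as dense weight
#' tensors `(out_channels, in_channels, k_t, k_x, k_y)`.  Temporal handling is
#' causal: output frame `k` draws on input frames `k-k_t+1 ... k`, with zero
#' history before the start of the stream (or the layer's state buffer when
#' streaming).  Spatial handling is same-size zero padding centered on the
#' kernel, ties at even sizes broken toward earlier indices.  Within one
#' output channel the contributions of all input channels are summed.
#' @name conv3d-ops
NULL

#' Construct a 3D convolution kernel
#'
#' @param weights numeric array.  Rank 5 `(out, in, t, x, y)` is taken as-is;
#'   rank 3 `(t, x, y)` and rank 2 `(x, y)` are promoted to single-channel
#'   kernels.
#' @return an object of class `kernel3d` (a 5-D array).
#' @export
kernel3d <- function(weights) {
  weights <- as.array(weights)
  r <- length(dim(weights))
  if (r == 2L) weights <- array(weights, c(1L, 1L, 1L, dim(weights)))
  else if (r == 3L) weights <- array(weights, c(1L, 1L, dim(weights)))
  else if (r != 5L) stop("kernel3d expects a 2-D, 3-D or 5-D array, got rank ", r)
  if (!all(is.finite(weights))) stop("kernel weights must be finite")
  structure(weights, class = "kernel3d")
}

# kernel center index along one spatial axis (ties toward earlier indices)
kcenter <- function(K) (K + 1L) %/% 2L

# out[..., i, ...] = a[..., i - s, ...] with zero fill, along time/x/y of a
# 5-D (b, c, t, x, y) array
shift5 <- function(a, dk = 0L, dx = 0L, dy = 0L) {
  d <- dim(a)
  out <- array(0, d)
  if (abs(dk) >= d[3L] || abs(dx) >= d[4L] || abs(dy) >= d[5L]) return(out)
  ti <- max(1L, 1L + dk):min(d[3L], d[3L] + dk)
  xi <- max(1L, 1L + dx):min(d[4L], d[4L] + dx)
  yi <- max(1L, 1L + dy):min(d[5L], d[5L] + dy)
  out[, , ti, xi, yi] <- a[, , ti - dk, xi - dx, yi - dy, drop = FALSE]
  out
}

# --- BLAS-backed cores on (T, X, Y) slabs ------------------------------------
# The y-axis tap sum is a banded (Y x Y) matrix product; x/time taps become
# slice shifts.  One gemm per (t-tap, x-tap) keeps everything vectorized.

# banded matrix S with S[yo + dv, yo] = wv[v], dv = v - cy
conv_band <- function(wv, Y, cy) {
  S <- matrix(0, Y, Y)
  for (v in seq_along(wv)) {
    if (wv[v] == 0) next
    dv <- v - cy
    yo <- max(1L, 1L - dv):min(Y, Y - dv)
    S[cbind(yo + dv, yo)] <- wv[v]
  }
  S
}

# x-shifted time slab: A[t, x, ] = P[t + j - 1, x + du, ] (zero outside)
conv_slab <- function(P3, j, TT, du) {
  d <- dim(P3)
  A <- array(0, c(TT, d[2L], d[3L]))
  xr <- max(1L, 1L - du):min(d[2L], d[2L] - du)
  if (length(xr)) A[, xr, ] <- P3[j:(j + TT - 1L), xr + du, ]
  A
}

conv_core_fw <- function(P3, w3, TT) {
  dk <- dim(w3)
  X <- dim(P3)[2L]; Y <- dim(P3)[3L]
  cx <- kcenter(dk[2L]); cy <- kcenter(dk[3L])
  out <- matrix(0, TT * X, Y)
  for (j in seq_len(dk[1L])) {
    for (u in seq_len(dk[2L])) {
      wv <- w3[j, u, ]
      if (all(wv == 0)) next
      A <- conv_slab(P3, j, TT, u - cx)
      out <- out + matrix(A, TT * X, Y) %*% conv_band(wv, Y, cy)
    }
  }
  array(out, c(TT, X, Y))
}

conv_core_gw <- function(P3, gy3, kt, kx, ky) {
  TT <- dim(gy3)[1L]; X <- dim(gy3)[2L]; Y <- dim(gy3)[3L]
  cx <- kcenter(kx); cy <- kcenter(ky)
  G <- matrix(gy3, TT * X, Y)
  gw <- array(0, c(kt, kx, ky))
  for (j in seq_len(kt)) {
    for (u in seq_len(kx)) {
      A <- conv_slab(P3, j, TT, u - cx)
      C <- crossprod(matrix(A, TT * X, Y), G)  # C[yi, yo]
      for (v in seq_len(ky)) {
        dv <- v - cy
        yo <- max(1L, 1L - dv):min(Y, Y - dv)
        gw[j, u, v] <- sum(C[cbind(yo + dv, yo)])
      }
    }
  }
  gw
}

conv_core_gx <- function(gy3, w3, kt) {
  dk <- dim(w3)
  TT <- dim(gy3)[1L]; X <- dim(gy3)[2L]; Y <- dim(gy3)[3L]
  cx <- kcenter(dk[2L]); cy <- kcenter(dk[3L])
  gx <- matrix(0, TT * X, Y)
  for (j in seq_len(dk[1L])) {
    for (u in seq_len(dk[2L])) {
      wv <- w3[j, u, ]
      if (all(wv == 0)) next
      # Gt[t, x, ] = gy[t + (kt - j), x - du, ]
      dtk <- kt - j
      du <- u - cx
      Gt <- array(0, c(TT, X, Y))
      tr <- max(1L, 1L - dtk):min(TT, TT - dtk)
      xr <- max(1L, 1L + du):min(X, X + du)
      if (length(tr) && length(xr)) Gt[tr, xr, ] <- gy3[tr + dtk, xr - du, ]
      gx <- gx + matrix(Gt, TT * X, Y) %*% t(conv_band(wv, Y, cy))
    }
  }
  array(gx, c(TT, X, Y))
}

#' Create a 3D convolution layer
#'
#' The layer owns a `weight` parameter (trainable) and a history buffer of the
#' trailing `k_t - 1` input frames so chunked streaming matches one-pass
#' output.
#'
#' @param kernel a [kernel3d] (or array acceptable to `kernel3d()`).
#' @return a convolution layer.
#' @export
layer_conv3d <- function(kernel) {
  kernel <- kernel3d(kernel)
  new_layer("cc_conv3d",
            params = list(weight = unclass(kernel)),
            trainable = "weight",
            init_state = function() list(hist = NULL))
}

#' @export
layer_forward.cc_conv3d <- function(layer, x, record = FALSE) {
  w <- layer$params$weight
  dw <- dim(w)
  OC <- dw[1L]; CI <- dw[2L]; kt <- dw[3L]
  d <- dim(x$values)
  if (d[2L] != CI) {
    stop("channel mismatch: kernel expects ", CI, " input channels, video has ", d[2L])
  }
  TT <- d[3L]
  hist <- layer$state$hist
  if (!is.null(hist) && !identical(dim(hist)[c(1L, 2L, 4L, 5L)], d[c(1L, 2L, 4L, 5L)])) {
    stop("mid-stream shape change: state was built for (",
         paste(dim(hist)[c(1L, 2L, 4L, 5L)], collapse = ","), "), input is (",
         paste(d[c(1L, 2L, 4L, 5L)], collapse = ","), "); reset_state() first")
  }
  if (kt > 1L) {
    if (is.null(hist)) hist <- array(0, c(d[1L], CI, kt - 1L, d[4L], d[5L]))
    P <- array(0, c(d[1L], CI, kt - 1L + TT, d[4L], d[5L]))
    P[, , seq_len(kt - 1L), , ] <- hist
    P[, , kt:(kt - 1L + TT), , ] <- x$values
  } else {
    P <- x$values
  }
  out <- array(0, c(d[1L], OC, TT, d[4L], d[5L]))
  for (b in seq_len(d[1L])) {
    for (co in seq_len(OC)) {
      acc <- NULL
      for (ci in seq_len(CI)) {
        P3 <- array(P[b, ci, , , ], dim(P)[3:5])
        y3 <- conv_core_fw(P3, array(w[co, ci, , , ], dw[3:5]), TT)
        acc <- if (is.null(acc)) y3 else acc + y3
      }
      out[b, co, , , ] <- acc
    }
  }
  if (kt > 1L) {
    layer$state$hist <- P[, , (TT + 1L):(TT + kt - 1L), , , drop = FALSE]
  }
  if (record) layer$cache <- list(P = P, din = d)
  video_tensor(out, dt = x$dt, t0 = x$t0)
}

#' @export
layer_backward.cc_conv3d <- function(layer, gy) {
  if (is.null(layer$cache)) stop("conv3d backward requires a recorded forward pass")
  w <- layer$params$weight
  dw <- dim(w)
  OC <- dw[1L]; CI <- dw[2L]; kt <- dw[3L]
  P <- layer$cache$P
  d <- layer$cache$din
  TT <- d[3L]
  gw <- layer$grads$weight
  gx <- array(0, d)
  for (b in seq_len(d[1L])) {
    for (co in seq_len(OC)) {
      gy3 <- array(gy[b, co, , , ], d[3:5])
      for (ci in seq_len(CI)) {
        P3 <- array(P[b, ci, , , ], dim(P)[3:5])
        gw[co, ci, , , ] <- as.numeric(gw[co, ci, , , ]) +
          as.numeric(conv_core_gw(P3, gy3, kt, dw[4L], dw[5L]))
        gx[b, ci, , , ] <- as.numeric(gx[b, ci, , , ]) +
          as.numeric(conv_core_gx(gy3, array(w[co, ci, , , ], dw[3:5]), kt))
      }
    }
  }
  layer$grads$weight <- gw
  gx
}

#' Convolve a video with a 3D kernel (stateless convenience wrapper)
#'
#' @param video a [video_tensor].
#' @param kernel a [kernel3d] whose `in_channels` equals the video's channel
#'   count.
#' @return the filtered [video_tensor] (same size, `out_channels` channels).
#' @export
conv3d <- function(video, kernel) {
  layer_forward(layer_conv3d(kernel), video)
}
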