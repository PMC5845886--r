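#' @title SoftConv: fixed recursive time base, trainable spatial kernels
#' @description A hybrid filter for slow processes with spatially structured
#' receptive fields: a bank of K *fixed* exponential smoothers with strictly
#' increasing time constants feeds K *trainable* 2D spatial kernels whose
#' outputs are summed.  Only the spatial kernels carry gradients; the time
#' base is never touched by optimizers, giving a smooth temporal profile with
#' decreasing effective spatial resolution at long lags.
#' @name softconv-ops
NULL

#' Create a SoftConv layer
#'
#' @param taus strictly increasing vector of K time constants (seconds).
#' @param spatial_kernels list of K 2D numeric matrices (trainable).
#' @return a composite layer computing
#'   `sum_k conv2d(exp_smooth(x, tau_k), kernel_k)`.
#' @export
layer_softconv <- function(taus, spatial_kernels) {
  taus <- as.numeric(taus)
  K <- length(taus)
  if (K < 1L || any(diff(taus) <= 0) || any(taus <= 0)) {
    stop("taus must be a strictly increasing vector of positive time constants")
  }
  if (!is.list(spatial_kernels) || length(spatial_kernels) != K) {
    stop("need exactly one spatial kernel per tau")
  }
  m <- new_layer("cc_softconv")
  children <- list()
  for (k in seq_len(K)) {
    e <- layer_exp_smooth(taus[k])
    e$trainable <- character()  # time base is fixed by design
    children[[paste0("exp", k)]] <- e
    children[[paste0("conv", k)]] <- layer_conv3d(kernel3d(as.matrix(spatial_kernels[[k]])))
  }
  m$children <- children
  m$K <- K
  m
}

#' @export
layer_forward.cc_softconv <- function(layer, x, record = FALSE) {
  out <- NULL
  for (k in seq_len(layer$K)) {
    s <- layer_forward(layer$children[[paste0("exp", k)]], x, record = record)
    y <- layer_forward(layer$children[[paste0("conv", k)]], s, record = record)
    out <- if (is.null(out)) y$values else out + y$values
  }
  video_tensor(out, dt = x$dt, t0 = x$t0)
}

#' @export
layer_backward.cc_softconv <- function(layer, gy) {
  gx <- NULL
  for (k in seq_len(layer$K)) {
    g <- layer_backward(layer$children[[paste0("conv", k)]], gy)
    g <- layer_backward(layer$children[[paste0("exp", k)]], g)
    gx <- if (is.null(gx)) g else gx + g
  }
  gx
}

#' Apply a SoftConv bank to a video (stateless wrapper)
#'
#' @param video a [video_tensor].
#' @param taus,spatial_kernels see [layer_softconv()].
#' @return the filtered [video_tensor].
#' @export
softconv <- function(video, taus, spatial_kernels) {
  layer_forward(layer_softconv(taus, spatial_kernels), video)
}
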