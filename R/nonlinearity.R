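#' @title Pointwise nonlinearities
#' @description Static nonlinearities applied element-wise: `linear`,
#' `half_wave` (`max(0, v)`), `square`, hard `threshold` (exact 0/1 forward,
#' boxcar surrogate gradient for optimization), `sigmoid` and `tanh` with
#' location/slope parameters.  The hard threshold has zero derivative almost
#' everywhere, so its backward map uses a surrogate: gradient `1/w` inside a
#' window of width `w` around the threshold, zero outside.
#' @name nonlinearity-ops
NULL

NL_KINDS <- c("linear", "half_wave", "square", "threshold", "sigmoid", "tanh")

#' Describe a pointwise nonlinearity
#'
#' @param kind one of `"linear"`, `"half_wave"`, `"square"`, `"threshold"`,
#'   `"sigmoid"`, `"tanh"`.
#' @param theta threshold location (used by `threshold`, `sigmoid`, `tanh`).
#' @param slope slope/scale parameter (`sigmoid`, `tanh`).
#' @param surrogate_width width `w` of the boxcar surrogate gradient of the
#'   hard threshold; `NA` disables the surrogate (backward then errors).
#' @return an object of class `nonlinearity_spec`.
#' @export
nonlinearity_spec <- function(kind, theta = 0, slope = 1, surrogate_width = 1) {
  kind <- match.arg(kind, NL_KINDS)
  structure(list(kind = kind, theta = theta, slope = slope,
                 surrogate_width = surrogate_width),
            class = "nonlinearity_spec")
}

#' Create a pointwise nonlinearity layer
#'
#' `theta` and `slope` are trainable for the parametric kinds (`sigmoid`,
#' `tanh`); the hard threshold trains `theta` through its surrogate gradient.
#'
#' @param spec a [nonlinearity_spec] (or a kind string).
#' @return a layer.
#' @export
layer_nonlinearity <- function(spec) {
  if (is.character(spec)) spec <- nonlinearity_spec(spec)
  stopifnot(inherits(spec, "nonlinearity_spec"))
  trainable <- switch(spec$kind,
                      sigmoid = c("theta", "slope"),
                      tanh = c("theta", "slope"),
                      threshold = "theta",
                      character())
  new_layer("cc_nonlinearity",
            params = list(theta = spec$theta, slope = spec$slope),
            trainable = trainable,
            extra = list(kind = spec$kind, surrogate_width = spec$surrogate_width))
}

nl_eval <- function(kind, v, theta, slope) {
  switch(kind,
         linear = v,
         half_wave = pmax(0, v),
         square = v^2,
         threshold = (v > theta) * 1,
         sigmoid = 1 / (1 + exp(-slope * (v - theta))),
         tanh = tanh(slope * (v - theta)))
}

#' @export
layer_forward.cc_nonlinearity <- function(layer, x, record = FALSE) {
  v <- x$values
  y <- nl_eval(layer$kind, v, layer$params$theta, layer$params$slope)
  dim(y) <- dim(v)
  if (record) layer$cache <- list(v = v)
  video_tensor(y, dt = x$dt, t0 = x$t0)
}

#' @export
layer_backward.cc_nonlinearity <- function(layer, gy) {
  v <- layer$cache$v
  if (is.null(v)) stop("nonlinearity backward requires a recorded forward pass")
  th <- layer$params$theta; sl <- layer$params$slope
  k <- layer$kind
  if (k == "linear") return(gy)
  if (k == "half_wave") return(gy * (v > 0))
  if (k == "square") return(gy * 2 * v)
  if (k == "threshold") {
    w <- layer$surrogate_width
    if (is.na(w) || w <= 0) {
      stop("threshold nonlinearity is non-differentiable and its surrogate gradient is disabled")
    }
    dv <- (abs(v - th) <= w / 2) / w
    layer$grads$theta <- layer$grads$theta - sum(gy * dv)
    return(gy * dv)
  }
  if (k == "sigmoid") {
    s <- 1 / (1 + exp(-sl * (v - th)))
    core <- s * (1 - s)
    layer$grads$theta <- layer$grads$theta - sum(gy * sl * core)
    layer$grads$slope <- layer$grads$slope + sum(gy * (v - th) * core)
    return(gy * sl * core)
  }
  # tanh
  t <- tanh(sl * (v - th))
  core <- 1 - t^2
  layer$grads$theta <- layer$grads$theta - sum(gy * sl * core)
  layer$grads$slope <- layer$grads$slope + sum(gy * (v - th) * core)
  gy * sl * core
}

#' Apply a pointwise nonlinearity to a video (stateless wrapper)
#'
#' @param video a [video_tensor].
#' @param spec a [nonlinearity_spec] or kind string.
#' @return the transformed [video_tensor].
#' @export
apply_nonlinearity <- function(video, spec) {
  layer_forward(layer_nonlinearity(spec), video)
}
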