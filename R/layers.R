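#' @title Model nodes: the layer / parameter / state contract
#'
#' @description Every processing stage is a *layer*: a mutable node holding
#' named `params` (values plus gradient slots), named `state` buffers, and
#' optionally named `children`.  Layers process [video_tensor] input through
#' [layer_forward()]; stateful layers carry history buffers so that chunked
#' streaming ([run_chunked()]) reproduces one-pass processing exactly.
#' Parameters reachable from a root node are collected with unique dotted
#' names ("child.param"), mirroring how module systems in neural-network
#' frameworks collect trainable weights.
#'
#' Layers are environments, so forward passes may update state in place;
#' [reset_state()] restores every buffer to its zero-filled configuration
#' without touching parameters.
#' @name model-nodes
NULL

# Construct a layer environment. init_state() must return the zero state whose
# shapes depend only on the layer configuration.
new_layer <- function(class, params = list(), trainable = character(),
                      init_state = function() list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$params <- lapply(params, function(p) {
    if (is.array(p)) array(as.numeric(p), dim(p)) else as.numeric(p)
  })
  e$grads <- lapply(e$params, function(p) {
    if (is.array(p)) array(0, dim(p)) else 0
  })
  e$trainable <- trainable
  e$init_state <- init_state
  e$state <- init_state()
  e$cache <- NULL
  e$children <- list()
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(class, "cc_layer")
  e
}

#' Run a layer (or model) forward over a video tensor
#'
#' @param layer a layer created by one of the `layer_*` constructors or a
#'   composite model.
#' @param x input [video_tensor].
#' @param record logical; keep the intermediates needed by [layer_backward()].
#' @return the output [video_tensor]; the layer's state buffers advance.
#' @export
layer_forward <- function(layer, x, record = FALSE) UseMethod("layer_forward")

#' Back-propagate a loss gradient through a layer
#'
#' Requires a preceding `layer_forward(..., record = TRUE)`.  Parameter
#' gradients accumulate into the layer's `grads` slots; the return value is
#' the gradient with respect to the layer input (same shape as the input).
#'
#' @param layer a layer.
#' @param gy numeric array, gradient of the scalar loss w.r.t. the output.
#' @return gradient array w.r.t. the input.
#' @export
layer_backward <- function(layer, gy) UseMethod("layer_backward")

#' @export
layer_backward.cc_layer <- function(layer, gy) {
  stop("layer of class '", class(layer)[1L], "' does not support gradients")
}

#' Reset all state buffers of a model to their zero configuration
#'
#' Parameters are untouched; call this whenever the input sequence changes.
#'
#' @param layer a layer or composite model.
#' @return the layer, invisibly.
#' @export
reset_state <- function(layer) UseMethod("reset_state")

#' @export
reset_state.cc_layer <- function(layer) {
  layer$state <- layer$init_state()
  layer$cache <- NULL
  for (ch in layer$children) reset_state(ch)
  invisible(layer)
}

# --- parameter collection ----------------------------------------------------

#' Collect the trainable parameters of a model with dotted names
#'
#' @param layer a layer or composite model.
#' @return named list of numeric values/arrays; names are unique dotted paths.
#' @export
model_parameters <- function(layer) {
  out <- list()
  for (nm in layer$trainable) out[[nm]] <- layer$params[[nm]]
  for (cn in names(layer$children)) {
    sub <- model_parameters(layer$children[[cn]])
    if (length(sub)) {
      names(sub) <- paste(cn, names(sub), sep = ".")
      out <- c(out, sub)
    }
  }
  out
}

# resolve a dotted name to list(layer=, name=)
resolve_param <- function(layer, dotted) {
  parts <- strsplit(dotted, ".", fixed = TRUE)[[1L]]
  node <- layer
  if (length(parts) > 1L) {
    for (p in parts[-length(parts)]) {
      if (is.null(node$children[[p]])) stop("no child '", p, "' in parameter path '", dotted, "'")
      node <- node$children[[p]]
    }
  }
  nm <- parts[length(parts)]
  if (is.null(node$params[[nm]])) stop("no parameter '", dotted, "'")
  list(layer = node, name = nm)
}

#' Read or write one named parameter of a model
#'
#' @param layer a layer or composite model.
#' @param dotted dotted parameter path as produced by [model_parameters()].
#' @param value replacement value (same shape).
#' @return the parameter value (`get_parameter`) or the layer (`set_parameter`).
#' @export
get_parameter <- function(layer, dotted) {
  r <- resolve_param(layer, dotted)
  r$layer$params[[r$name]]
}

#' @rdname get_parameter
#' @export
set_parameter <- function(layer, dotted, value) {
  r <- resolve_param(layer, dotted)
  old <- r$layer$params[[r$name]]
  if (length(old) != length(value)) {
    stop("parameter '", dotted, "' has length ", length(old), ", value has ", length(value))
  }
  r$layer$params[[r$name]] <- if (is.array(old)) array(as.numeric(value), dim(old)) else as.numeric(value)
  invisible(layer)
}

#' Zero every accumulated parameter gradient in a model
#' @param layer a layer or composite model.
#' @return the layer, invisibly.
#' @export
zero_grads <- function(layer) {
  layer$grads <- lapply(layer$params, function(p) if (is.array(p)) array(0, dim(p)) else 0)
  for (ch in layer$children) zero_grads(ch)
  invisible(layer)
}

#' Collect accumulated gradients for the trainable parameters
#' @param layer a layer or composite model.
#' @return named list matching [model_parameters()].
#' @export
model_gradients <- function(layer) {
  out <- list()
  for (nm in layer$trainable) out[[nm]] <- layer$grads[[nm]]
  for (cn in names(layer$children)) {
    sub <- model_gradients(layer$children[[cn]])
    if (length(sub)) {
      names(sub) <- paste(cn, names(sub), sep = ".")
      out <- c(out, sub)
    }
  }
  out
}

# flatten selected parameters to one numeric vector (and back)
get_param_vector <- function(layer, which = NULL) {
  ps <- model_parameters(layer)
  if (!is.null(which)) ps <- ps[which]
  unlist(ps, use.names = FALSE)
}

set_param_vector <- function(layer, theta, which = NULL) {
  ps <- model_parameters(layer)
  if (!is.null(which)) ps <- ps[which]
  at <- 1L
  for (nm in names(ps)) {
    n <- length(ps[[nm]])
    set_parameter(layer, nm, theta[at:(at + n - 1L)])
    at <- at + n
  }
  invisible(layer)
}

get_grad_vector <- function(layer, which = NULL) {
  gs <- model_gradients(layer)
  if (!is.null(which)) gs <- gs[which]
  unlist(gs, use.names = FALSE)
}

# --- sequential container ----------------------------------------------------

#' Compose layers into a sequential model
#'
#' @param ... named layers, applied in order.
#' @return a composite layer of class `cc_sequential`.
#' @export
sequential_model <- function(...) {
  children <- list(...)
  if (is.null(names(children)) || any(names(children) == "")) {
    names(children) <- paste0("stage", seq_along(children))
  }
  m <- new_layer("cc_sequential")
  m$children <- children
  m
}

#' @export
layer_forward.cc_sequential <- function(layer, x, record = FALSE) {
  for (ch in layer$children) x <- layer_forward(ch, x, record = record)
  x
}

#' @export
layer_backward.cc_sequential <- function(layer, gy) {
  for (ch in rev(layer$children)) gy <- layer_backward(ch, gy)
  gy
}

# --- chunked streaming -------------------------------------------------------

#' Process a long video in chunks with state carry-over
#'
#' Splits the input along time into chunks of `chunk_len` frames, feeds them
#' through the model one after another, and concatenates the outputs.  Because
#' every layer owns its history buffers, the result equals one-pass processing
#' (to float tolerance); stochastic layers consume a single random stream so
#' draws are identical at a fixed seed.
#'
#' @param model a layer or composite model whose state is freshly reset or
#'   consistent with the video's history.
#' @param video input [video_tensor].
#' @param chunk_len chunk length in frames (>= 1); larger than the video means
#'   a single chunk.
#' @return the concatenated output [video_tensor].
#' @export
run_chunked <- function(model, video, chunk_len) {
  stopifnot(inherits(video, "video_tensor"))
  chunk_len <- as.integer(chunk_len)
  if (chunk_len < 1L) stop("chunk_len must be >= 1")
  K <- vt_nframes(video)
  outs <- list()
  i <- 1L
  while (i <= K) {
    j <- min(i + chunk_len - 1L, K)
    outs[[length(outs) + 1L]] <- layer_forward(model, vt_time_slice(video, i, j))
    i <- j + 1L
  }
  vt_time_concat(outs)
}
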