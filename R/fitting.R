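#' @title Gradient-based parameter estimation and model diagnostics
#' @description Loss functions, the gradient contract (hand-derived
#' reverse-mode adjoints checked against central finite differences),
#' first-order and quasi-Newton optimizers, error-surface scans for nonlinear
#' parameters, pairwise curvature (Hessian) analysis, and optimization of a
#' stimulus parameter to discriminate two models.
#' @name fitting
NULL

as_values <- function(x) if (inherits(x, "video_tensor")) x$values else as.array(x)

#' Mean squared error between two signals
#'
#' @param a,b [video_tensor]s or arrays of equal shape.
#' @return scalar mean of squared differences over all elements.
#' @export
loss_mse <- function(a, b) {
  av <- as_values(a); bv <- as_values(b)
  if (!identical(dim(av), dim(bv))) {
    stop("shape mismatch: (", paste(dim(av), collapse = ","), ") vs (",
         paste(dim(bv), collapse = ","), ")")
  }
  mean((av - bv)^2)
}

# loss of a model on (x, y) from a clean state
model_loss <- function(model, x, y) {
  reset_state(model)
  loss_mse(layer_forward(model, x), y)
}

#' Gradients of the MSE loss with respect to trainable parameters
#'
#' Runs a recorded forward pass from a clean state and back-propagates the
#' loss through the hand-derived adjoint of every layer.
#'
#' @param model a deterministic model (no spiking layer).
#' @param x input [video_tensor].
#' @param y target [video_tensor] (same shape as the model output).
#' @param params optional character vector restricting to a subset of dotted
#'   parameter names.
#' @return list with `loss`, `gradients` (named list) and `output`.
#' @export
param_gradients <- function(model, x, y, params = NULL) {
  reset_state(model)
  zero_grads(model)
  yhat <- layer_forward(model, x, record = TRUE)
  yv <- as_values(y)
  r <- yhat$values - yv
  n <- length(r)
  layer_backward(model, 2 * r / n)
  g <- model_gradients(model)
  if (!is.null(params)) g <- g[params]
  list(loss = mean(r^2), gradients = g, output = yhat)
}

#' Finite-difference gradients (independent oracle for the gradient contract)
#'
#' Central differences of the MSE loss; the step for each scalar component is
#' `step * max(1, |theta|)`.
#'
#' @inheritParams param_gradients
#' @param step relative step size.
#' @return named list of gradients, shaped like [param_gradients()]'s.
#' @export
param_gradients_fd <- function(model, x, y, params = NULL, step = 1e-4) {
  ps <- model_parameters(model)
  if (!is.null(params)) ps <- ps[params]
  out <- list()
  for (nm in names(ps)) {
    p <- ps[[nm]]
    g <- if (is.array(p)) array(0, dim(p)) else numeric(length(p))
    for (i in seq_along(p)) {
      h <- step * max(1, abs(p[i]))
      pp <- p; pp[i] <- p[i] + h
      set_parameter(model, nm, pp)
      lp <- model_loss(model, x, y)
      pp[i] <- p[i] - h
      set_parameter(model, nm, pp)
      lm <- model_loss(model, x, y)
      g[i] <- (lp - lm) / (2 * h)
    }
    set_parameter(model, nm, p)
    out[[nm]] <- g
  }
  out
}

#' Optimizer specification
#'
#' @param method `"gradient_descent"`, `"momentum"`, `"adaptive"` (Adam) or
#'   `"quasi_newton"` (limited-memory BFGS via `stats::optim`).
#' @param lr learning rate (> 0; ignored by the quasi-Newton method).
#' @param max_steps maximum number of outer steps.  One outer step is one
#'   optimizer update call; for the quasi-Newton method it may perform up to
#'   `inner` internal line-search iterations.
#' @param inner inner-iteration cap for the quasi-Newton method.
#' @param tol stop when the loss drops to or below this value.
#' @param momentum momentum coefficient.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @return list of class `optimizer_spec`.
#' @export
optimizer_spec <- function(method = c("adaptive", "gradient_descent", "momentum",
                                      "quasi_newton"),
                           lr = 0.01, max_steps = 100L, inner = 20L, tol = 0,
                           momentum = 0.9, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  method <- match.arg(method)
  if (lr < 0) stop("learning rate must be >= 0")
  if (max_steps < 1L || inner < 1L) stop("step caps must be >= 1")
  structure(list(method = method, lr = lr, max_steps = as.integer(max_steps),
                 inner = as.integer(inner), tol = tol, momentum = momentum,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "optimizer_spec")
}

#' Fit model parameters to data by gradient-based optimization
#'
#' @param model a deterministic model.
#' @param x input [video_tensor].
#' @param y target [video_tensor].
#' @param opt an [optimizer_spec].
#' @param params optional character vector of dotted parameter names to fit
#'   (default: all trainable parameters).
#' @return object of class `fit_result`: `par_trace` (matrix, one row per
#'   recorded step), `loss_trace`, `grad_norms`, `final_parameters`, `steps`,
#'   `converged`.
#' @export
fit <- function(model, x, y, opt = optimizer_spec(), params = NULL) {
  stopifnot(inherits(opt, "optimizer_spec"))
  if (is.null(params)) params <- names(model_parameters(model))
  theta <- get_param_vector(model, params)
  loss0 <- model_loss(model, x, y)
  par_trace <- list(theta)
  loss_trace <- loss0
  grad_norms <- numeric(0)
  vel <- numeric(length(theta))
  m1 <- numeric(length(theta)); m2 <- numeric(length(theta))
  steps <- 0L
  converged <- loss0 <= opt$tol
  grad_at <- function(th) {
    set_param_vector(model, th, params)
    pg <- param_gradients(model, x, y, params)
    list(loss = pg$loss, g = unlist(pg$gradients, use.names = FALSE))
  }
  for (s in seq_len(opt$max_steps)) {
    if (converged) break
    if (opt$method == "quasi_newton") {
      res <- stats::optim(theta,
                          fn = function(th) { set_param_vector(model, th, params); model_loss(model, x, y) },
                          gr = function(th) grad_at(th)$g,
                          method = "L-BFGS-B",
                          control = list(maxit = opt$inner, factr = 1, pgtol = 0))
      theta <- res$par
      cur <- grad_at(theta)
      g <- cur$g
    } else {
      cur <- grad_at(theta)
      g <- cur$g
      if (opt$method == "gradient_descent") {
        theta <- theta - opt$lr * g
      } else if (opt$method == "momentum") {
        vel <- opt$momentum * vel - opt$lr * g
        theta <- theta + vel
      } else { # adaptive (Adam)
        m1 <- opt$beta1 * m1 + (1 - opt$beta1) * g
        m2 <- opt$beta2 * m2 + (1 - opt$beta2) * g^2
        mh <- m1 / (1 - opt$beta1^s)
        vh <- m2 / (1 - opt$beta2^s)
        theta <- theta - opt$lr * mh / (sqrt(vh) + opt$eps)
      }
      set_param_vector(model, theta, params)
    }
    steps <- s
    loss <- model_loss(model, x, y)
    if (!is.finite(loss) || loss > 1e6 * max(loss0, .Machine$double.xmin)) {
      stop("optimization diverged at step ", s, ": loss = ", loss,
           " (initial ", loss0, "); try a smaller learning rate")
    }
    par_trace[[length(par_trace) + 1L]] <- theta
    loss_trace <- c(loss_trace, loss)
    grad_norms <- c(grad_norms, sqrt(sum(g^2)))
    if (loss <= opt$tol) converged <- TRUE
  }
  set_param_vector(model, theta, params)
  structure(list(par_trace = do.call(rbind, par_trace),
                 loss_trace = loss_trace,
                 grad_norms = grad_norms,
                 final_parameters = model_parameters(model)[params],
                 steps = steps,
                 converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %d steps, loss %.3e -> %.3e%s>\n",
              x$steps, x$loss_trace[1L], x$loss_trace[length(x$loss_trace)],
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Scan the error curve of one parameter around the ground truth
#'
#' All other parameters stay at ground truth; at each grid value the MSE
#' against the target response and the analytic gradient are recorded.
#' The scan reports whether the curve is unimodal and where the gradient
#' changes sign.
#'
#' @param model_factory zero-argument function returning a fresh ground-truth
#'   model.
#' @param param_name dotted name of the scanned (scalar) parameter.
#' @param grid sorted vector of parameter values containing the truth.
#' @param x input [video_tensor].
#' @param target target response ([video_tensor]).
#' @return data.frame `(value, loss, gradient)` with attributes `unimodal`
#'   (logical) and `sign_change` (index of the cell where the gradient flips).
#' @export
scan_error_curve <- function(model_factory, param_name, grid, x, target) {
  if (is.unsorted(grid)) stop("grid must be sorted")
  loss <- numeric(length(grid)); grad <- numeric(length(grid))
  for (i in seq_along(grid)) {
    m <- model_factory()
    set_parameter(m, param_name, grid[i])
    pg <- param_gradients(m, x, target, params = param_name)
    loss[i] <- pg$loss
    grad[i] <- sum(pg$gradients[[param_name]])
  }
  df <- data.frame(value = grid, loss = loss, gradient = grad)
  imin <- which.min(loss)
  unimodal <- all(diff(loss[seq_len(imin)]) <= 0) &&
    all(diff(loss[imin:length(loss)]) >= 0)
  flips <- which(diff(sign(grad)) != 0)
  attr(df, "unimodal") <- unimodal
  attr(df, "sign_change") <- if (length(flips)) flips[1L] else NA_integer_
  df
}

#' Pairwise curvature and gradient flow of two scalar parameters
#'
#' Second derivatives by central finite differences of the analytic first
#' derivatives; the flow field is the negative gradient on a grid around the
#' ground truth.
#'
#' @param model_factory zero-argument function returning a fresh ground-truth
#'   model.
#' @param x input [video_tensor].
#' @param y target response.
#' @param param_a,param_b dotted names of the two scalar parameters.
#' @param rel_h relative step for the outer differences.
#' @param grid_a,grid_b optional grids for the flow field (absolute values).
#' @return list with `hessian` (2x2, symmetrized), `eigen`
#'   (`base::eigen` result) and `flow` (data.frame `a, b, ga, gb, loss`).
#' @export
hessian_pair <- function(model_factory, x, y, param_a, param_b, rel_h = 0.01,
                         grid_a = NULL, grid_b = NULL) {
  names2 <- c(param_a, param_b)
  grad_at <- function(va, vb) {
    m <- model_factory()
    set_parameter(m, param_a, va)
    set_parameter(m, param_b, vb)
    pg <- param_gradients(m, x, y, params = names2)
    c(sum(pg$gradients[[param_a]]), sum(pg$gradients[[param_b]]), pg$loss)
  }
  m0 <- model_factory()
  a0 <- sum(get_parameter(m0, param_a)); b0 <- sum(get_parameter(m0, param_b))
  ha <- rel_h * max(1, abs(a0)); hb <- rel_h * max(1, abs(b0))
  H <- matrix(0, 2L, 2L, dimnames = list(names2, names2))
  gpa <- grad_at(a0 + ha, b0); gma <- grad_at(a0 - ha, b0)
  gpb <- grad_at(a0, b0 + hb); gmb <- grad_at(a0, b0 - hb)
  H[1L, ] <- (gpa[1:2] - gma[1:2]) / (2 * ha)
  H[2L, ] <- (gpb[1:2] - gmb[1:2]) / (2 * hb)
  H <- (H + t(H)) / 2
  flow <- NULL
  if (!is.null(grid_a) && !is.null(grid_b)) {
    flow <- expand.grid(a = grid_a, b = grid_b)
    gg <- t(apply(flow, 1L, function(r) grad_at(r[1L], r[2L])))
    flow$ga <- -gg[, 1L]; flow$gb <- -gg[, 2L]; flow$loss <- gg[, 3L]
  }
  list(hessian = H, eigen = eigen(H, symmetric = TRUE), flow = flow)
}

#' Optimize a scalar stimulus parameter to discriminate two models
#'
#' Evaluates the objective `D(s) = mean |model_a(stim(s)) - model_b(stim(s))|`
#' over a grid of the free parameter, together with its central-difference
#' gradient, and returns the grid argmax and the nearest zero crossing of the
#' gradient.
#'
#' @param model_a,model_b two models sharing input/output shapes; state is
#'   reset before every evaluation.
#' @param stimulus_fun function mapping the scalar parameter to a
#'   [video_tensor].
#' @param grid sorted vector of parameter values.
#' @param rel_h relative step for the gradient.
#' @return list with `curve` (data.frame `s, objective, gradient`), `argmax`,
#'   `zero_crossing` (interpolated gradient root nearest the argmax, `NA` when
#'   none) and `flat` (TRUE when the objective range is < 1e-9).
#' @export
optimize_stimulus <- function(model_a, model_b, stimulus_fun, grid, rel_h = 0.02) {
  D <- function(s) {
    v <- stimulus_fun(s)
    reset_state(model_a); reset_state(model_b)
    mean(abs(layer_forward(model_a, v)$values - layer_forward(model_b, v)$values))
  }
  obj <- vapply(grid, D, numeric(1))
  grad <- vapply(grid, function(s) {
    h <- rel_h * max(abs(s), 1e-6)
    (D(s + h) - D(s - h)) / (2 * h)
  }, numeric(1))
  curve <- data.frame(s = grid, objective = obj, gradient = grad)
  if (diff(range(obj)) < 1e-9) {
    return(list(curve = curve, argmax = NA_real_, zero_crossing = NA_real_,
                flat = TRUE))
  }
  imax <- which.max(obj)
  flips <- which(diff(sign(grad)) != 0)
  zc <- NA_real_
  if (length(flips)) {
    roots <- vapply(flips, function(i) {
      g1 <- grad[i]; g2 <- grad[i + 1L]
      grid[i] + (grid[i + 1L] - grid[i]) * g1 / (g1 - g2)
    }, numeric(1))
    zc <- roots[which.min(abs(roots - grid[imax]))]
  }
  list(curve = curve, argmax = grid[imax], zero_crossing = zc, flat = FALSE)
}

#' Fraction of variance of `a` explained by `b`
#'
#' `1 - var(a - b) / var(a)`: the agreement measure used to compare response
#' traces stage by stage.
#'
#' @param a,b numeric vectors (or [video_tensor]s, flattened) of equal length.
#' @return scalar; 1 for identical traces, about 0 for an unrelated `b`.
#' @export
fraction_variance_explained <- function(a, b) {
  av <- as.numeric(as_values(a)); bv <- as.numeric(as_values(b))
  if (length(av) != length(bv)) stop("traces must have equal length")
  va <- stats::var(av)
  if (!is.finite(va) || va == 0) stop("var(a) is zero: fraction undefined")
  1 - stats::var(av - bv) / va
}
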