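#' @title Retina cascade stages
#' @description The four stages of the retina model: an outer-plexiform-layer
#' (OPL) center-surround filter converting luminance to contrast, a bipolar
#' contrast-gain-control stage (leaky integrator whose leak conductance grows
#' with the local contrast energy, i.e. shunting inhibition), a ganglion-cell
#' static nonlinearity (rectifying, positive, C1), and leaky integrate-and-fire
#' spike generation.
#' @name retina-stages
NULL

# --- OPL ---------------------------------------------------------------------

#' OPL parameters
#' @param sigma_center,sigma_surround spatial scales (px) of center/surround.
#' @param tau_center,tau_surround temporal low-pass constants (s).
#' @param w_surround relative surround weight in `[0, 1]`; 1 cancels constant
#'   luminance exactly at steady state.
#' @param lambda_opl overall gain (output units per luminance unit).
#' @return list of class `opl_params`.
#' @export
opl_params <- function(sigma_center = 1, tau_center = 0.01,
                       sigma_surround = 3, tau_surround = 0.02,
                       w_surround = 0.75, lambda_opl = 20) {
  stopifnot(sigma_center > 0, sigma_surround > 0, tau_center > 0,
            tau_surround > 0, is.finite(lambda_opl))
  structure(list(sigma_center = sigma_center, tau_center = tau_center,
                 sigma_surround = sigma_surround, tau_surround = tau_surround,
                 w_surround = w_surround, lambda_opl = lambda_opl),
            class = "opl_params")
}

#' Create the OPL center-surround layer
#'
#' Center `C = exp_smooth(tau_c) . gauss(sigma_c)` of the luminance; surround
#' `S = exp_smooth(tau_s) . gauss(sigma_s)` of `C`; output
#' `I_OPL = lambda_opl * (C - w_surround * S)`.  Monochrome only.
#'
#' @param p an [opl_params].
#' @return a layer.
#' @export
layer_opl <- function(p) {
  stopifnot(inherits(p, "opl_params"))
  m <- new_layer("cc_opl",
                 params = list(w_surround = p$w_surround, lambda_opl = p$lambda_opl))
  m$children <- list(
    g_c = layer_gaussian2d(p$sigma_center),
    e_c = layer_exp_smooth(p$tau_center),
    g_s = layer_gaussian2d(p$sigma_surround),
    e_s = layer_exp_smooth(p$tau_surround))
  for (ch in m$children) ch$trainable <- character()
  m
}

#' @export
layer_forward.cc_opl <- function(layer, x, record = FALSE) {
  if (dim(x$values)[2L] != 1L) {
    stop("the retina is monochrome: expected 1 channel, got ", dim(x$values)[2L])
  }
  C <- layer_forward(layer$children$e_c,
                     layer_forward(layer$children$g_c, x, record), record)
  S <- layer_forward(layer$children$e_s,
                     layer_forward(layer$children$g_s, C, record), record)
  out <- layer$params$lambda_opl * (C$values - layer$params$w_surround * S$values)
  video_tensor(out, dt = x$dt, t0 = x$t0)
}

#' OPL stage as a stateless function
#' @param luminance single-channel [video_tensor].
#' @param p an [opl_params].
#' @return the contrast signal `I_OPL` as a [video_tensor].
#' @export
opl_stage <- function(luminance, p) layer_forward(layer_opl(p), luminance)

# --- bipolar contrast gain control -------------------------------------------

#' Bipolar gain-control parameters
#' @param g_leak inert leak conductance (1/s), > 0.
#' @param lambda_bip gain-control strength (1/s per unit squared signal), >= 0.
#' @param sigma_A spatial scale (px) of the contrast neighborhood.
#' @param tau_A temporal scale (s) of the contrast neighborhood.
#' @return list of class `bipolar_params`.
#' @export
bipolar_params <- function(g_leak = 50, lambda_bip = 50, sigma_A = 2, tau_A = 0.005) {
  if (g_leak <= 0) stop("g_leak must be > 0 (otherwise the integrator is unbounded)")
  stopifnot(lambda_bip >= 0, sigma_A > 0, tau_A > 0)
  structure(list(g_leak = g_leak, lambda_bip = lambda_bip,
                 sigma_A = sigma_A, tau_A = tau_A),
            class = "bipolar_params")
}

#' Create the bipolar shunting-inhibition layer
#'
#' Explicit-Euler integration per pixel of `dV/dt = I(t) - g(t) V(t)` with
#' `g = g_leak + lambda_bip * A` and `A` a spatio-temporal Gaussian/exponential
#' neighborhood average of `V^2` (the local contrast energy).  `g_leak` and
#' `lambda_bip` are trainable with analytic adjoint gradients.
#'
#' @param p a [bipolar_params].
#' @return a layer.
#' @export
layer_bipolar <- function(p) {
  stopifnot(inherits(p, "bipolar_params"))
  new_layer("cc_bipolar",
            params = list(g_leak = p$g_leak, lambda_bip = p$lambda_bip,
                          sigma_A = p$sigma_A, tau_A = p$tau_A),
            trainable = c("g_leak", "lambda_bip"),
            init_state = function() list(V = NULL, A = NULL))
}

# dense symmetric spatial smoothing of one (b,c,1,x,y) frame
bip_smooth <- function(fr, sigma) {
  if (sigma < 0.05) return(fr)
  dense_gauss_vals(fr, sigma, sigma)
}

#' @export
layer_forward.cc_bipolar <- function(layer, x, record = FALSE) {
  gl <- layer$params$g_leak
  if (gl <= 0) stop("g_leak must be > 0")
  lam <- layer$params$lambda_bip
  sA <- layer$params$sigma_A
  lamA <- exp(-x$dt / layer$params$tau_A)
  d <- dim(x$values)
  TT <- d[3L]
  fr_dim <- c(d[1L], d[2L], 1L, d[4L], d[5L])
  Vprev <- layer$state$V
  if (is.null(Vprev)) Vprev <- array(0, fr_dim)
  Aprev <- layer$state$A
  if (is.null(Aprev)) Aprev <- array(0, fr_dim)
  out <- array(0, d)
  if (record) {
    cacheV <- array(0, c(d[1:2], TT + 1L, d[4:5])); cacheV[, , 1L, , ] <- Vprev
    cacheA <- array(0, d); cacheg <- array(0, d)
  }
  for (k in seq_len(TT)) {
    sk <- bip_smooth(Vprev^2, sA)
    Ak <- lamA * Aprev + (1 - lamA) * sk
    gk <- pmax(gl, gl + lam * Ak)  # lam, A >= 0: the floor never binds
    Ik <- x$values[, , k, , , drop = FALSE]
    Vk <- Vprev + x$dt * (Ik - gk * Vprev)
    out[, , k, , ] <- Vk
    if (record) {
      cacheV[, , k + 1L, , ] <- Vk; cacheA[, , k, , ] <- Ak; cacheg[, , k, , ] <- gk
    }
    Vprev <- Vk; Aprev <- Ak
  }
  layer$state$V <- Vprev
  layer$state$A <- Aprev
  if (record) {
    layer$cache <- list(V = cacheV, A = cacheA, g = cacheg, d = d,
                        dt = x$dt, lamA = lamA, sA = sA)
  }
  video_tensor(out, dt = x$dt, t0 = x$t0)
}

#' @export
layer_backward.cc_bipolar <- function(layer, gy) {
  cc <- layer$cache
  if (is.null(cc)) stop("bipolar backward requires a recorded forward pass")
  d <- cc$d
  TT <- d[3L]
  lam <- layer$params$lambda_bip
  fr_dim <- c(d[1L], d[2L], 1L, d[4L], d[5L])
  vb_next <- array(0, fr_dim)   # dL/dV_{k+1}
  ab_next <- array(0, fr_dim)   # dL/dA_{k+1}
  g_next <- array(0, fr_dim)
  gx <- array(0, d)
  g_gl <- 0; g_lam <- 0
  for (k in rev(seq_len(TT))) {
    gyk <- gy[, , k, , , drop = FALSE]; dim(gyk) <- fr_dim
    Vk <- cc$V[, , k + 1L, , , drop = FALSE]; dim(Vk) <- fr_dim
    Vkm1 <- cc$V[, , k, , , drop = FALSE]; dim(Vkm1) <- fr_dim
    Ak <- cc$A[, , k, , , drop = FALSE]; dim(Ak) <- fr_dim
    gk <- cc$g[, , k, , , drop = FALSE]; dim(gk) <- fr_dim
    # total dL/dV_k: direct output, next Euler step, and the contrast path
    vb <- gyk + vb_next * (1 - cc$dt * g_next) +
      2 * Vk * ((1 - cc$lamA) * bip_smooth(ab_next, cc$sA))
    gb <- -cc$dt * Vkm1 * vb            # dL/dg_k
    g_gl <- g_gl + sum(gb)
    g_lam <- g_lam + sum(gb * Ak)
    ab <- lam * gb + cc$lamA * ab_next  # dL/dA_k
    gx[, , k, , ] <- cc$dt * vb
    vb_next <- vb; ab_next <- ab; g_next <- gk
  }
  layer$grads$g_leak <- layer$grads$g_leak + g_gl
  layer$grads$lambda_bip <- layer$grads$lambda_bip + g_lam
  gx
}

#' Bipolar stage as a stateless function
#' @param i_opl input current [video_tensor] (the OPL output).
#' @param p a [bipolar_params].
#' @return the membrane potential `V_bip` as a [video_tensor].
#' @export
bipolar_stage <- function(i_opl, p) layer_forward(layer_bipolar(p), i_opl)

# --- ganglion static nonlinearity --------------------------------------------

#' Ganglion-cell nonlinearity parameters
#' @param sign `+1` for ON cells, `-1` for OFF cells.
#' @param v0 input threshold of the static nonlinearity.
#' @param lambda_g slope above threshold (current units per input unit), >= 0.
#' @param i0 current at threshold, > 0.
#' @return list of class `ganglion_params`.
#' @export
ganglion_params <- function(sign = 1, v0 = 0, lambda_g = 200, i0 = 60) {
  if (i0 <= 0) stop("i0 must be > 0")
  stopifnot(sign %in% c(-1, 1), lambda_g >= 0)
  structure(list(sign = sign, v0 = v0, lambda_g = lambda_g, i0 = i0),
            class = "ganglion_params")
}

#' Create the ganglion static-nonlinearity layer
#'
#' With `u = sign * v`: linear `i0 + lambda_g (u - v0)` above threshold and
#' the hyperbolic branch `i0^2 / (i0 - lambda_g (u - v0))` below.  The map is
#' continuous, C1 at `v0`, strictly positive and vanishes as `u -> -Inf`
#' (strictly positive synapses rectify the signal).
#'
#' @param p a [ganglion_params].
#' @return a layer with trainable `v0`, `lambda_g`, `i0`.
#' @export
layer_ganglion <- function(p) {
  stopifnot(inherits(p, "ganglion_params"))
  new_layer("cc_ganglion",
            params = list(sign = p$sign, v0 = p$v0,
                          lambda_g = p$lambda_g, i0 = p$i0),
            trainable = c("v0", "lambda_g", "i0"))
}

#' @export
layer_forward.cc_ganglion <- function(layer, x, record = FALSE) {
  pp <- layer$params
  if (pp$i0 <= 0) stop("i0 must be > 0")
  u <- pp$sign * x$values
  z <- u - pp$v0
  hi <- z >= 0
  out <- ifelse(hi, pp$i0 + pp$lambda_g * z, pp$i0^2 / (pp$i0 - pp$lambda_g * z))
  dim(out) <- dim(x$values)
  if (record) layer$cache <- list(u = u)
  video_tensor(out, dt = x$dt, t0 = x$t0)
}

#' @export
layer_backward.cc_ganglion <- function(layer, gy) {
  if (is.null(layer$cache)) stop("ganglion backward requires a recorded forward pass")
  pp <- layer$params
  z <- layer$cache$u - pp$v0
  hi <- z >= 0
  D <- pp$i0 - pp$lambda_g * z
  du <- ifelse(hi, pp$lambda_g, pp$i0^2 * pp$lambda_g / D^2)
  dv0 <- -du
  dlg <- ifelse(hi, z, pp$i0^2 * z / D^2)
  di0 <- ifelse(hi, 1, (2 * pp$i0 * D - pp$i0^2) / D^2)
  layer$grads$v0 <- layer$grads$v0 + sum(gy * dv0)
  layer$grads$lambda_g <- layer$grads$lambda_g + sum(gy * dlg)
  layer$grads$i0 <- layer$grads$i0 + sum(gy * di0)
  gy * du * pp$sign
}

#' Ganglion static nonlinearity as a stateless function
#' @param v_bip bipolar output [video_tensor].
#' @param p a [ganglion_params].
#' @return the ganglion input current as a [video_tensor].
#' @export
ganglion_current <- function(v_bip, p) layer_forward(layer_ganglion(p), v_bip)

# --- leaky integrate-and-fire ------------------------------------------------

#' LIF spike-generation parameters
#' @param g_l membrane leak (1/s).
#' @param v_thresh spike threshold (> `v_reset`).
#' @param v_reset reset potential.
#' @param tau_refr refractory period (s), >= 0.
#' @param sigma_noise membrane noise amplitude per sqrt(second), >= 0.
#' @param seed RNG seed for the layer's private noise stream.
#' @return list of class `lif_params`.
#' @export
lif_params <- function(g_l = 50, v_thresh = 1, v_reset = 0, tau_refr = 0.003,
                       sigma_noise = 0.1, seed = 0) {
  if (v_thresh <= v_reset) stop("v_thresh must exceed v_reset")
  stopifnot(tau_refr >= 0, sigma_noise >= 0)
  structure(list(g_l = g_l, v_thresh = v_thresh, v_reset = v_reset,
                 tau_refr = tau_refr, sigma_noise = sigma_noise, seed = seed),
            class = "lif_params")
}

#' Create a leaky integrate-and-fire layer
#'
#' Euler step `V <- V + dt (I - g_l V) + sigma_noise sqrt(dt) eta` with `eta`
#' standard normal from the layer's private seeded stream; threshold crossing
#' emits a spike, resets `V`, and clamps it at `v_reset` for `tau_refr`.  The
#' noise stream is part of the layer state, so chunked runs draw identical
#' noise to one-pass runs.
#'
#' @param p a [lif_params].
#' @return a layer; forward output is the binary spike raster.  The membrane
#'   trace of the last forward call is kept in `layer$last_membrane`.
#' @export
layer_lif <- function(p) {
  stopifnot(inherits(p, "lif_params"))
  seed <- p$seed
  new_layer("cc_lif",
            params = list(g_l = p$g_l, v_thresh = p$v_thresh, v_reset = p$v_reset,
                          tau_refr = p$tau_refr, sigma_noise = p$sigma_noise),
            init_state = function() {
              rng <- local({
                old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
                set.seed(seed)
                s <- get(".Random.seed", globalenv())
                if (!is.null(old)) assign(".Random.seed", old, globalenv())
                s
              })
              list(V = NULL, refr = NULL, rng = rng)
            },
            extra = list(seed = seed, last_membrane = NULL))
}

#' @export
layer_forward.cc_lif <- function(layer, x, record = FALSE) {
  pp <- layer$params
  d <- dim(x$values)
  TT <- d[3L]
  P <- prod(d[-3L])
  xm <- vt_as_mat(x$values)
  V <- layer$state$V
  if (is.null(V)) V <- rep(pp$v_reset, P)
  refr <- layer$state$refr
  if (is.null(refr)) refr <- rep(0L, P)
  n_refr <- if (pp$tau_refr > 0) as.integer(round(pp$tau_refr / x$dt)) else 0L
  spikes <- matrix(0, TT, P)
  memb <- matrix(0, TT, P)
  # swap in the layer's private RNG stream
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", layer$state$rng, globalenv())
  sqdt <- sqrt(x$dt)
  for (k in seq_len(TT)) {
    eta <- if (pp$sigma_noise > 0) stats::rnorm(P) else 0
    Vn <- V + x$dt * (xm[k, ] - pp$g_l * V) + pp$sigma_noise * sqdt * eta
    inref <- refr > 0L
    Vn[inref] <- pp$v_reset
    refr[inref] <- refr[inref] - 1L
    fire <- !inref & (Vn >= pp$v_thresh)
    spikes[k, fire] <- 1
    Vn[fire] <- pp$v_reset
    refr[fire] <- n_refr
    memb[k, ] <- Vn
    V <- Vn
  }
  layer$state$rng <- get(".Random.seed", globalenv())
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  layer$state$V <- V
  layer$state$refr <- refr
  layer$last_membrane <- video_tensor(mat_as_vt(memb, d), dt = x$dt, t0 = x$t0)
  video_tensor(mat_as_vt(spikes, d), dt = x$dt, t0 = x$t0)
}

#' LIF spike generation as a stateless function
#' @param current input current [video_tensor].
#' @param p a [lif_params].
#' @return list with binary `spikes` and `membrane` [video_tensor]s.
#' @export
lif_spikes <- function(current, p) {
  l <- layer_lif(p)
  s <- layer_forward(l, current)
  list(spikes = s, membrane = l$last_membrane)
}
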