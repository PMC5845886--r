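---
title: "Filter cascades for early vision: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter cascades for early vision: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(convcascade)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic stimuli do
and do not emulate, the numerical choices, and the places where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The data model

All signals are `video_tensor`s: arrays with axes
`(batch, channel, time, x, y)` and a frame duration `dt` in seconds, time on
axis 3 (index 2 when counting from zero). Batches are independent; channels
carry color or cell-type planes. This fixed convention removes all axis
ambiguity from the layer contracts, and mirrors the convention used by
modern tensor frameworks for 3D convolution.

Every processing stage is a *layer* with three kinds of attached data:

- **Parameters** — values an optimizer may change (a convolution kernel, a
  time constant, a leak conductance). Parameters reachable from a composite
  model are collected under unique dotted names
  (`model_parameters()`), e.g. `stage1.linear.weight`.
- **State** — everything that depends on the input history: the trailing
  `k_t − 1` frames for a temporal kernel of length `k_t`, the last `M − 1`
  inputs and `N` outputs of a recursive filter, membrane potentials,
  refractory counters, and the private RNG stream of a stochastic layer.
  `reset_state()` returns every buffer to its zero configuration and never
  touches parameters.
- **Gradients** — one slot per parameter, filled by reverse-mode backward
  passes.

Because each layer owns its history, a long (or unbounded) movie can be fed
in chunks (`run_chunked()`), and the concatenated output equals one-pass
processing to float precision — the spiking layer consumes a single random
stream stored in its state, so even spike rasters are bit-identical under
re-chunking. The computational history is *not* retained across chunk
boundaries: gradients do not flow between chunks. This bounds memory but
means processes much slower than one chunk cannot be fitted through chunked
gradients; no multi-chunk gradient mode is attempted, and fits in this
package always run on one-chunk inputs.

## 2. Linear filters

**Dense 3D convolution** supports arbitrary, non-separable spatio-temporal
receptive fields as `(out_channels, in_channels, k_t, k_x, k_y)` weight
tensors. Temporal handling is causal (output frame `k` sees frames
`k−k_t+1 … k`, zero history before the stream starts); spatial handling is
same-size, zero-padded, kernel-centered, with ties at even kernel sizes
broken toward earlier indices. Internally the y-axis tap sum is a banded
matrix product and x/time taps are slice shifts, so the whole operation runs
on BLAS; a triple-nested-loop oracle in the test suite pins the semantics.

**Recursive temporal filters** implement
`Y(k) = Σ_{j=0}^{M−1} b_j X(k−j) − Σ_{i=1}^{N} a_i Y(k−i)`. The feedback sum
starts at `i = 1`: a printed variant of this recursion that starts the
output sum at `i = 0` would be self-referential, so the standard IIR
convention is adopted (this is flagged, not silently reinterpreted).
Stability is not enforced — `iir_stable()` checks the characteristic roots
on request. The exponential smoother is the `M = N = 1` special case
normalized to unit DC gain, so its time constant `tau` is its only shape
parameter.

**Recursive spatial Gaussians.** A 2D Gaussian blur is separable into two
1D passes; each 1D pass is realized as the sum of a causal and an
anti-causal low-order recursive filter, which costs O(1) per pixel
regardless of σ. The classic construction families fit a fixed-order
rational with published coefficient polynomials; in this implementation the
published third-order polynomial family missed the package's accuracy
contract (max-abs error vs. dense convolution below 1e-3 on a unit impulse
at σ = 2) by an order of magnitude under either published or
variance-matched calibration, so the coefficients are instead *designed
numerically per σ*: the sampled normalized Gaussian is fitted by an
order-6 rational via linear prediction (Prony) for the poles and exact
matching of the leading samples for the numerator, then normalized to DC
gain exactly 1. The fit is accurate to ~1e-4 of the peak or better for any
σ used here, and designs are cached per σ. The accuracy contract is
normative; the approximation family is an implementation detail. Boundaries
replicate edge values, so constant fields pass through unchanged. Below
σ = 0.5 px the code falls back to dense convolution, where any low-order
recursive approximation degrades. Only axis-aligned ellipses are supported —
the recursive decomposition forces x/y separability; tilted Gaussians are a
non-goal.

**SoftConv** targets slow processes with spatially structured receptive
fields: K *fixed* exponential smoothers with strictly increasing time
constants feed K *trainable* 2D spatial kernels whose outputs are summed.
The time base is deliberately excluded from the trainable set (recursive
time constants are the one parameter class the quasi-Newton optimizer
handles poorly; see §5), while the spatial kernels remain cheap linear
parameters.

## 3. The retina cascade

The cascade is OPL → bipolar gain control → ganglion nonlinearity (ON and
OFF in parallel) → LIF spike generation, one model pixel per cell.

**OPL.** Center `C = exp_smooth(τ_c) ∘ gauss(σ_c)` of the luminance;
surround `S = exp_smooth(τ_s) ∘ gauss(σ_s)` applied to `C`; output
`I_OPL = λ_OPL (C − w·S)`. With `w = 1` the steady-state response to
constant luminance is exactly zero — luminance is removed in favor of
contrast. The original reference model adds a partially high-pass temporal
undershoot in the OPL; it is omitted here because the center–surround
difference already removes DC and exact transient parity with the original
simulator is a non-goal (the cascade's *structure*, not its bit-level
output, is the contract).

**Bipolar contrast gain control.** Explicit-Euler integration of
`dV/dt = I_OPL − g(t)·V`, with `g = g_leak + λ_bip · A` and
`A = exp_smooth(τ_A) ∘ gauss(σ_A)` applied to `V²`. The contrast measure is
`V²` rather than `|V|`: smooth, differentiable, and the standard shunting
formulation. Since `λ_bip ≥ 0` and `A ≥ 0`, the floor `g ≥ g_leak` never
binds but is enforced for safety. Rising contrast raises `g`, which both
compresses the amplitude (sublinear gain) and shortens the effective
integration time (phase advance) — the two signatures the acceptance tests
measure on sinusoids at contrasts 0.1 vs 0.8.

**Ganglion static nonlinearity.** The reference model rectifies bipolar
output through strictly positive synapses, but prints no formula; the
adopted form is a design decision. With `u = sign·V` (sign = ±1 for ON/OFF):
linear `i0 + λ_g (u − v0)` above threshold and hyperbolic
`i0² / (i0 − λ_g (u − v0))` below. This map is continuous, C¹ at `v0`,
strictly positive, and decays to zero as `u → −∞` — the qualitative
properties that matter — while staying differentiable for fitting.

**LIF.** Per pixel,
`V ← V + dt (I − g_l V) + σ_noise √dt · η`, `η ~ N(0,1)` from the layer's
private seeded stream; crossing `v_thresh` emits a spike, resets to
`v_reset`, and clamps the potential for `tau_refr`. Noise is drawn every
frame whether or not it is used, so the stream position depends only on the
frame count — this is what makes chunked rasters identical to one-pass
rasters. For constant suprathreshold drive without noise the inter-spike
interval has the closed form
`tau_refr + (1/g_l)·ln((I − g_l v_reset)/(I − g_l v_thresh))`, which the
tests verify to within one Euler step at small `g_l·dt`.

**Default magnitudes.** The source material prints no units for `g_leak`,
`λ_bip`, `i0` or `λ_g`; defaults are chosen once so that, on stimuli with
luminance in [0, 1]: OPL output is O(1–10) (λ_OPL = 20, w = 0.75), bipolar
potentials live in roughly [−1, 1] (g_leak = λ_bip = 50 s⁻¹, σ_A = 2 px,
τ_A = 5 ms), and the ganglion/LIF pair produces a spontaneous rate of a few
tens of Hz with stimulus-modulated firing (i0 = 60, λ_g = 200, g_l = 50 s⁻¹,
v_thresh = 1, tau_refr = 3 ms, σ_noise = 0.1). These are documented
defaults, not fitted values, and were fixed before the acceptance battery
was frozen.

**Integration scheme.** Both the bipolar and LIF stages use explicit Euler
at the video `dt` — the simplest scheme consistent with per-frame streaming.
The configuration warns when `dt` exceeds one fifth of the fastest time
constant, and a refinement test checks that halving-by-ten changes smooth
trajectories by < 1% of amplitude at `dt = 0.5 ms`.

**Configuration files.** A VirtualRetina-dialect XML subset is read through
a mapping table shipped as data (`inst/extdata/vr_xml_mapping.csv`:
node tag + attribute → config field, with degree→pixel scaling via the
document's `pixels-per-degree`), so dialect fixes never touch code.
Unrecognized attributes warn and are ignored; radially-varying-blur
attributes are explicitly ignored (radially varying parameters and
cell-sampling schemes are out of scope — one pixel is one cell). An
equivalent JSON format covers the same fields.

## 4. Stimuli: what the generators emulate

All generators are pure functions of (specification, seed); they restore the
caller's RNG state.

- **Chirp** — the full-field protocol used to characterize ganglion cell
  types: an OFF-ON-OFF pulse, a linear frequency sweep, an amplitude sweep
  at fixed frequency. The published protocol's exact timings are not
  printed anywhere authoritative, so the defaults (2 s pre, 3 s pulse,
  0.5→8 Hz over 8 s, amplitude sweep at 2 Hz over 8 s, dt = 1 ms) mirror
  the protocol's shape and are fully overridable; only the segment
  structure is treated as normative.
- **Moving grating** — `L = mean(1 + c·sin(2π·sf·(x cosθ + y sinθ) −
  2π·sf·speed·t))`.
- **Checkerboard flicker** — independent ±1 boxes per update, with a `hold`
  parameter (update interval in frames) as in real experiments where the
  stimulus updates slower than the monitor refresh. The hold matters: a
  leaky integrator with `1/g ≈ 10 ms` averages out per-millisecond flicker,
  so gain-control experiments use held patterns.
- **Moving bar, Gaussian noise, Poisson event trains** — Poisson events use
  Bernoulli thinning per frame (exact on the discrete grid the filters use,
  unlike inter-arrival sampling), with a warning outside `rate·dt ≤ 0.2`.
- **Letters raster** — a built-in 16×16 binary raster spelling "con"/"vis"
  (tiny 3×5 glyphs, no font dependency) plus seeded noise; the delicate
  ground-truth receptive field for recovery experiments.

None of these emulate photoreceptor adaptation, display gamma, eye
movements, or natural-scene statistics — a green recovery test establishes
that the estimator works on realizable, noise-free (or additive-Gaussian)
synthetic data, not that it is robust to model mismatch on real recordings.

## 5. Fitting: gradients and optimizers

No autodiff library exists in the target environment, so the primary
gradient backend is hand-derived reverse-mode: each differentiable layer
implements a backward pass (convolution: correlation with the cached input
for weights, flipped-kernel convolution for the input; exponential smoother:
reverse-time recursion with an analytic `dλ/dτ` chain; bipolar stage: a full
adjoint of the Euler loop including the `V² → A → g` gain-control path,
with the spatial neighborhood operator being symmetric and hence
self-adjoint; nonlinearities: pointwise derivatives). The published contract
is *agreement between two routes* — analytic vs. central finite differences
at relative error < 1e-4 — never a specific library; `param_gradients()`
and `param_gradients_fd()` implement the two routes independently.

One caveat of the finite-difference route: central differences evaluated
within the step of a half-wave rectifier kink straddle the kink and disagree
with the (correct) one-sided subgradient by construction, so the two-route
comparison for kernel weights is run through smooth nonlinearities at
arbitrary seeds, while the half-wave configuration is pinned by a
closed-form cross-correlation oracle and a fixed, kink-free seed.

The hard threshold nonlinearity has zero derivative almost everywhere; its
forward output is exact 0/1, and optimization uses a boxcar surrogate
gradient of width `w` (default 1.0) around the threshold. Disabling the
surrogate makes backward an explicit error rather than a silent zero.

Optimizers: plain gradient descent, momentum, an Adam-style adaptive method,
and a limited-memory quasi-Newton method (`stats::optim`'s L-BFGS-B). One
**outer step** is one optimizer update call; for the quasi-Newton method an
outer step may perform up to 20 internal line-search iterations. This
definition is normative for all step-count claims. With a white-noise
stimulus the receptive-field problem is extremely well conditioned (the
Hessian is nearly a scaled identity), which is why the quasi-Newton method
reaches loss ratios of ~1e-19 within one to three outer steps in the
acceptance battery. Recursive time constants are the known weak spot for
quasi-Newton (the loss is far from quadratic in τ); the gradient-descent
family recovers τ reliably (Adam, lr 0.005, within 2% in the standing
regression test), and no test asserts the quasi-Newton failure mode itself
since it is not characterized.

`scan_error_curve()` operationalizes "the error function is concave and the
gradient points toward the minimum" as *unimodality plus a single gradient
sign change* on the scanned grid — at a grid point that coincides with the
truth the gradient is exactly zero, which the tests treat as the crossing.

**The g_leak/λ_bip valley.** Bipolar dynamics depend on the parameters only
through `g = g_leak + λ_bip·A`. Around an operating point with contrast
neighborhood average `Ā`, solutions are indistinguishable along
`Δg_leak = −Ā·Δλ_bip`: a low-curvature corridor in the error surface. When
the stimulus is scaled so `Ā ≈ 1` (held checkerboard, amplitude ≈ total g,
which is self-consistent at amplitude 100 for the defaults), this corridor
runs along the (1, −1) diagonal — increasing the inert leak while decreasing
the gain-control strength leaves the response almost unchanged. The
acceptance test computes the 2×2 curvature matrix by central differences of
the analytic gradients and checks that the small-eigenvalue eigenvector lies
within 15° of that trade-off diagonal. (A description of this corridor as
lying "on the line g_leak = λ_bip" is read as naming the two traded-off
parameters, not a +45° direction: with `A ≥ 0` no positive-diagonal
invariance is possible in a shunting model.)

`optimize_stimulus()` treats the stimulus itself as the free parameter:
`D(s) = mean |model_a(stim(s)) − model_b(stim(s))|` over a grid of, e.g.,
grating speeds, with a central-difference gradient in `s` (a scalar stimulus
parameter is outside the layer adjoints, and the two-route contract does not
cover it). For two retina configurations differing in one OPL time constant
the objective is small at extreme speeds — the cascade is bandpass, very
slow and very fast gratings are near-invisible to both models — with an
interior maximum whose gradient zero-crossing the acceptance test locates
within one grid step of the argmax; secondary local maxima from stimulus
periodicity are expected and tolerated.

`fraction_variance_explained(a, b) = 1 − var(a−b)/var(a)` is the per-stage
agreement measure exposed by the `compare` CLI subcommand; it errors on
zero-variance references rather than returning NaN.

## 6. Feedback cascades

The subunit models with feedback (LNSNF, LNFSNF, LNFDSNF) need a wiring
decision that the source material does not make: feedback is implemented as
*subtractive, gain-weighted, exponentially filtered, delayed by ≥ 1 frame,
applied to the stage input, pre-nonlinearity*. This is causal, reduces
exactly to the feedback-free model at gain 0, and matches the "delayed
feedback" naming — but the pre- vs post-nonlinearity placement is a
documented package choice, not an assertion about the original models.
Feedback stages run frame by frame (the delay closes a loop through the
stage) and support streaming state, but not gradients.

## 7. Numerical conventions and degenerate inputs

- Float tolerance for chunked/whole equivalence: 1e-5 max-abs on unit-scale
  signals (single-precision-safe); the implementation typically achieves
  ≤ 1e-10 in double precision.
- Even-sized spatial kernels center toward earlier indices.
- `chunk_len` larger than the video is a single chunk, not an error;
  mid-stream shape changes are rejected with an instruction to reset.
- Non-finite inputs are rejected at tensor construction with the first
  offending index named.
- Resampling is linear interpolation over the same time span; resampling to
  fewer than 2 frames is rejected.
- All stochastic components take explicit seeds; generators and the LIF
  layer restore the caller's RNG state.

## 8. Known limitations

- No parity claim against the original VirtualRetina binaries: the OPL here
  omits the undershoot transient, and no reference traces ship with the
  package, so stage-by-stage variance-explained comparisons are only
  exposed as a harness (`compare`), not asserted against external data.
- Gradients do not cross chunk boundaries or feedback loops.
- Spatial Gaussians are axis-aligned; dense kernels cover tilted cases.
- Explicit Euler limits `dt` (warned); no implicit integrator is provided.
- The CLI reads npy / JSON / XML and writes npy / CSV / JSON; HDF5 and the
  INR format are not implemented in this environment, and image-sequence
  directories are not read (no image codec dependency is available).
- One pixel is one cell: no radially varying parameters, no cell-sampling
  schemes, no color retina.
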