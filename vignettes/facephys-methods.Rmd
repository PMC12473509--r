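---
title: "Methods: multi-task physiological and cognitive state estimation from facial video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task physiological and cognitive state estimation from facial video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Camera-based driver monitoring aims to read three quantities from face video
alone: heart rate (HR, beats/min) and respiration rate (RR, breaths/min),
which are recoverable from subtle pulsatile skin-color changes (remote
photoplethysmography, rPPG), and the driver's cognitive load, a binary label
usually derived from NASA-TLX questionnaires. `facephys` implements one joint
model for all three tasks: a multimodal embedding front end, a bidirectional
selective state-space (Mamba-style) sequence encoder, and three small MLP
prediction heads, trained end to end with a scheduled multi-task objective.
Because the driving corpora this class of model is evaluated on are
access-restricted, the package ships a synthetic physiological-video
generator that reproduces their statistical structure, so every stage is
testable from a clean install.

## Input representation

Video is consumed as fixed-length sliding windows of `L = 300` frames with
stride `s = 30` (at 30 fps: 10-second windows, 1-second hop). Windows shorter
than `L` are discarded, never padded. Each window is decomposed into five
temporally aligned streams:

* **Left eye, right eye, mouth crops** — fixed-size boxes (25x25 for eyes,
  15x35 height-by-width for the mouth) centered per frame on the centroid of a
  configurable landmark index set and clamped inside the frame. Which of the
  106 landmarks define each region is configuration, so the pipeline is
  agnostic to the landmark scheme; defaults match the synthetic generator's
  template.
* **Normalized landmarks** — the `106 x 2` pixel coordinates divided by frame
  width/height and clamped to the unit square.
* **STMap** — the rPPG spatio-temporal map: per frame, the landmark bounding
  box is divided into a 5x5 grid (H = 25 ROIs; standard practice in the STMap
  lineage, configurable), each cell contributing its mean R, G, B; each
  (channel, cell) time series is then min-max normalized over the window.
  Degenerate (constant) series map to 0.5. Row normalization makes the map
  invariant to the raw pulse amplitude, which is why the FFT oracle and the
  learned model both read rate information from *frequency*, not amplitude.

## Embeddings

Each stream is embedded frame-by-frame into a `d`-dimensional feature vector
(default `d = 64`), giving five `L x d` sequences that concatenate to
`F` of width `D = 5 d` with no interpolation:

* Subregion clips pass a fixed temporal-shift module (WTSM) — one channel
  shifted forward one frame, one backward, the rest static, vacated frames
  zero-filled — then two 3x3 convolution + SiLU + 2x2 average-pooling stages
  and a per-frame fully connected map. The shift mixes adjacent-frame
  information into the spatial convolution at zero parameter cost; it can be
  disabled (`wtsm = FALSE`). With 3-channel inputs the shift moves
  `max(1, floor(C / fold_div))` channels per direction.
* Landmarks are treated as a 2-channel 1-D signal over the 106-point axis
  (kernel-3 convolution, batch normalization, SiLU, fully connected). The
  `106 x 2` array has no meaningful 2-D image structure, hence the 1-D view.
  There is deliberately no translation invariance: head position is signal.
* The STMap passes two same-padded 3x3 convolution + batch-norm + SiLU stages
  over the `H x L` image (channels 3 to `stmap_channels` to `d`), then
  adaptive average pooling collapses the ROI axis. Same padding keeps the
  time axis at `L` exactly; the two frames at each end of the window see the
  zero padding and are mildly edge-affected, which matters for none of the
  pooled quantities.

## The sequence encoder

The core of the model is a state-space sequence layer. A continuous linear
system `h'(t) = A h(t) + B x(t)`, `y = C h + D x` is discretized by
zero-order hold: `A_bar = exp(A delta)` and, exactly integrating the held
input, `B_bar = (A_bar - 1)/A * B` (a configuration flag selects the Euler
simplification `delta * B`). `A` is diagonal with entries parameterized as
`-exp(A_log)`, so every eigenvalue is strictly negative and every discrete
transition entry lies in `(0, 1)`: the recurrence is unconditionally stable.
For input-independent parameters the recurrence equals a causal convolution
with kernel `K_t = C A_bar^t B_bar`; the package implements both paths and
tests them against each other, as well as against a dense matrix-exponential
plus quadrature oracle.

The Mamba-style block makes the dynamics input-dependent: pre-RMSNorm, a
linear projection to width `E = 2 D`, a depthwise causal convolution (width
4) with SiLU, then a selective scan in which `delta` (via softplus of a
rank-`ceil(D/16)` projection), `B` and `C` are computed from the current
input; a parallel SiLU gate multiplies the scan output before the output
projection and residual connection. State dimension is `N = 16`, `A_log` is
initialized to `log(1..N)` per channel and the `delta` bias so that initial
step sizes span `[1e-3, 1e-1]` — together these give the initial filter bank
a spread of time constants from a few frames to hundreds, which is what lets
mean-pooled rectified responses encode oscillation frequency.

Two independent stacks of `depth` blocks (default 3, following the observed
1-to-3-layer improvement and beyond-3 plateau) process `F` forward and
time-reversed. The backward stack's output is re-reversed before its linear
map so both directions share the forward time order — mean pooling over a
single time axis requires this alignment, which the formulation leaves
implicit. Per-direction linear maps to `D'' = D` produce
`H_bi = [Z_forward || Z_backward]` of width `2 D''`; temporal mean pooling
and three independent two-layer MLPs (hidden 128, SiLU) emit HR, RR and the
sigmoid cognitive-load probability. The printed head equations list the HR
head twice; the algorithm listing resolves the typo — the third head is RR.

## Objective

* Cognitive load: truncated cross-entropy `-log(max(p_y, eps))` with
  `eps = 0.01` (the floor is described as "a small constant"; 0.01 caps an
  outlier's loss at 4.6 while leaving the `[eps, 1]` regime untouched).
  Below the floor the gradient is exactly zero, which is the point: windows
  whose subjective label disagrees wildly with the model stop dominating the
  gradient.
* HR and RR: smooth L1 (quadratic below unit error, linear above),
  continuous and once-differentiable with slope magnitude at most 1.
* Total: `L_total = L_cog + lambda (L_hr + L_rr)` with
  `t = 2 iter/iter_total`, `lambda = 2 / (1 + exp(-10 t))`. Note
  `lambda(0) = 1`: the printed formula ramps the regression weight from 1
  toward 2, although the surrounding narrative suggests starting near 0. We
  implement the formula verbatim and expose `lambda_start_zero = TRUE` for
  the narrative behavior (`lambda - 1`, ramping 0 to 1).

Training uses Adam (full-scale defaults: lr 1e-5, batch 250, 20 000
iterations), a 6:2:2 subject-wise split (no subject contributes to two
splits), and best-checkpoint selection by validation total loss — the
selection criterion is not specified upstream; validation loss is the
obvious choice. The classification threshold is 0.5. NASA-TLX labeling
follows both corpora's rules: scores below 30 are low load and above 60 high
load with the 30-60 mid-range excluded from classification (retained for
regression), or, for the second corpus, normalized score above 10 together
with a non-driving task means high load.

## The synthetic generator

`synthetic_config()` defines a cohort: baseline HR ~ Normal(70, 7) truncated
to [50, 95] bpm, baseline RR ~ Normal(15, 2) truncated to [10, 22] rpm; high
load adds +8 bpm and +2 rpm (plus unit-s.d. per-window jitter) and raises the
blink rate from 12 to 24 blinks/min (150 ms closures from a Poisson
process). Windows embed the pulse as a sinusoid at the HR frequency whose
amplitude is modulated at the RR frequency (depth 0.25), plus a direct
low-frequency respiratory baseline (0.3 relative amplitude) — so RR is
recoverable both from sidebands and from the baseline band — plus slow
lighting drift, head-motion random walk on the landmarks, and additive
Gaussian sensor noise. Two fidelity levels share one label process: the
tensor level emits the five model inputs directly (cheap; unit tests and
training), the pixel level renders a toy 128x128 face video that exercises
the real crop/normalize/STMap path. The generator is self-verifying: at zero
noise, `build_stmap` + `oracle_rate_from_stmap` recover the embedded HR and
RR within one FFT bin (6 bpm at 30 fps, L = 300).

The load-dependent blink-rate direction is a fixture choice to give the eye
branches class-discriminative signal, not an empirical claim. What passing
tests on this generator show is that the pipeline can extract and fuse the
kinds of signals real data carries — periodic color change, blink events,
label-correlated rates; what they cannot show is robustness to real-world
nuisance (illumination, occlusion, skin-tone-dependent SNR, label noise),
none of which the generator models beyond simple noise and drift.

### A note on the attainable classification accuracy

Under the generator's stated effect sizes the Bayes-optimal per-window
accuracy is itself limited: the three class-discriminative cues are the HR
shift (+8 bpm against a 7 bpm between-subject spread), the RR shift (+2 rpm
against 2 rpm), and the blink count (Poisson means 2 vs 4 per 10 s window).
For an unseen subject these combine to a detectability of roughly d' = 1.9,
i.e. an accuracy ceiling near 0.83 — no classifier, however good, can do
better on held-out subjects without calibrating to the subject's baseline.
The package reports this honestly rather than inflating the generator's
effect sizes; see the decision notes in the test suite.

## Training accelerators

Several standard training aids are package design choices on top of the core
method, all switchable in the configuration:

* **Augmentation.**  Temporal speed resampling of each training window by a
  factor drawn from [0.7, 1.4], with the HR/RR labels rescaled by the same
  factor -- the standard rPPG "frequency augmentation".  It is what forces
  the model to read rates from oscillation frequency rather than subject
  appearance: with only six training subjects and no augmentation the model
  happily memorizes subject identity (training error vanishes, held-out
  error stays at the baseline).  Per-window color jitter on the crops and a
  small landmark translation jitter break the skin-tone and head-position
  shortcuts for the classification task.  Windows are resampled with linear
  interpolation and reflection at the ends; the cognitive label is carried
  unchanged (blink rates scale mildly with speed, acceptable label noise for
  a fixture).
* **Initialization.**  The first STMap-stem channels start as temporal
  derivative, temporal curvature and pass-through filters (the rate
  information of a min-max-normalized oscillation lives in its derivative
  amplitude), analogous to edge-filter initialization of vision stems; block
  output projections are scaled by `1/sqrt(2 depth)` and the head output
  layers start small so initial logits sit near zero -- important under the
  truncated cross-entropy, whose gradient is exactly zero for confidently
  wrong predictions.
* **Optimization.**  AdamW-style decoupled weight decay (1e-4) and an
  optional global gradient-norm clip.

## Desk-scale benchmark sizes

The package's tests and the acceptance script exercise training at sizes a
single CPU handles in minutes, chosen once and fixed: 10 subjects x 20
windows, 10-second windows at 7.5 fps (L = 75, preserving the 6 cycles/min
FFT bin of the 30 fps / L = 300 default), noise s.d. 0.005 ("high SNR"),
model `d = 16`, state dimension 8, depth 3 (depth 1 for the sweep), narrow
stems (c1 = 4, c2 = 8), batch 8, 250-300 Adam steps at lr 1e-3 with z-scored
regression targets (predictions are always reported in physical units; the
z-scoring is a numerical convenience that makes the smooth-L1 knee
meaningful across tasks).  At these sizes the model recovers held-out-subject
HR to a few bpm; respiration is the hardest target because a 10-second
window contains only two to five respiratory cycles.  The full-scale
defaults (d = 64, N = 16, batch 250, lr 1e-5, 20 000 iterations) remain the
package defaults for real-data use and keep the model below the
5.95 M-parameter budget of the reference design (the default configuration
counts ~4.7 M).

## Numerical choices and degenerate inputs

* All arithmetic is double precision. The compiled kernels use a
  Cody-Waite + polynomial `exp` (relative error < 1e-12) in the scan and
  SiLU hot loops; the discretization and oracle paths use `exp` from libm.
* Min-max normalization maps constant STMap rows to 0.5; the FFT oracle
  reports a flat map as `undefined` with confidence 0 rather than a rate.
* Crop boxes are clamped inside the frame (no synthetic padding pixels);
  landmark normalization clamps to [0, 1].
* Batch normalization keeps running statistics (momentum 0.1) used in
  evaluation mode; training mode uses batch statistics with the full
  backward pass through them.
* Undefined metric ratios (empty confusion cells, constant series for
  Pearson) are reported as `NA`, never silently propagated as `NaN`.
* Checkpoints are R serializations of the complete parameter set, BN state
  and configuration; a save/load round trip is bit-exact.
* All randomness derives from one user seed: subject profiles and windows
  from `(seed, subject, window)` mixes, initialization, the subject split
  and minibatch sampling from the training seed. Identical seeds give
  identical loss trajectories.

## Known limitations

* No face detection or landmark estimation: both are upstream concerns, and
  the package consumes their outputs.
* The ROI geometry is an axis-aligned landmark bounding box without skin
  masking or motion compensation; real-data use would benefit from both.
* The sequential scan is exact but not hardware-fused; throughput targets
  desk-scale experiments, not GPU-scale training.
* Whether the temporal-shift module's groups should be learned is not
  decidable from its published description; the fixed shift implemented here
  matches its stated purpose and is switchable.
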