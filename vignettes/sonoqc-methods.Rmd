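---
title: "Quality-gated force adaptation for robotic B-mode ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-gated force adaptation for robotic B-mode ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoqc)
```

sonoqc simulates a robotic ultrasound (US) scanning assistant: a robot holds
the probe, assesses each B-mode frame in real time, and increases the contact
force until the image is judged diagnostically useful. This vignette explains
the models the package implements, the parameters that matter, what the
synthetic phantom does and does not emulate, and the numerical and design
choices that were genuinely open.

## The quality-assessment model

A B-mode frame is an M x N matrix of 8-bit intensities, rows running along
the beam (depth). Three features summarize frame quality:

**Contact (correlation gate).** When the probe is not acoustically coupled to
tissue, the machine images only arc-shaped reverberation artifacts. A
reference frame $I_{nc}$ captured off-tissue therefore acts as a template for
"no useful signal": the Pearson correlation
$\mathrm{corr}(I_k, I_{nc})$ between the current frame and the reference is
high exactly when the probe is not in contact. The binary gate
$c_k = \mathbf{1}[\mathrm{corr}(I_k, I_{nc}) \ge t_{corr}]$ fires (inclusive
boundary) when the frame resembles the no-contact template, and a fired gate
short-circuits classification to "low quality". The default $t_{corr} = 0.7$.
Two points were open and are resolved as follows. First, the gate is binary
by definition even though raw correlation is continuous; the raw value is
recorded alongside the gate for diagnostics. Second, a frame on which the
correlation is undefined (zero intensity variance, e.g. an all-black frame)
is treated as not-in-contact — a blank frame carries no tissue signal — with
the raw correlation recorded as `NA`.

**Compression.** Pressing the probe into tissue deforms it; excessive force
distorts anatomy (and hurts). The compression feature is the depth extent of
supra-threshold pixels relative to frame height: with $U$ and $L$ the largest
and smallest (0-based) row indices holding any pixel $\ge t_{comp}$,
$f_c = (U - L)/M \in [0, 1]$. Row indexing origin does not matter since only
the difference enters. The default $t_{comp} = 20$ lives on the native 8-bit
scale. If no pixel reaches the threshold, $f_c = 0$ with a `no_signal` flag,
and such frames are classified low quality (no tissue is visible).

**Residual noise.** Speckle is multiplicative interference noise intrinsic to
coherent imaging. An adaptive Wiener filter estimates, per pixel, the local
mean $\mu$ and variance $\sigma^2$ over a $P \times Q$ window and shrinks the
pixel toward the local mean:
$$I_f = \mu + \frac{\max(\sigma^2 - \nu^2,\,0)}{\max(\sigma^2,\,\varepsilon)}\,(I - \mu),$$
with $\nu^2$ the global noise variance. The noise feature is the mean plus
standard deviation of the signed residual $I_n = I - I_f$:
$f_n = \bar{I_n} + \sigma_n$. Numerical choices here (all standard adaptive
Wiener filtering practice, exposed for auditability):

- $\nu^2$ is estimated as the mean of all local variances over the frame.
- The gain numerator is clamped at 0 (where $\sigma^2 < \nu^2$ the neighborhood
  is flatter than the noise floor and the pixel is replaced by the local
  mean), and the denominator is guarded with $\varepsilon = 10^{-12}$.
- Borders are reflect-padded (edge row repeated); zero padding would bias
  $\mu$ dark at the borders.
- The default window is $5 \times 5$: small enough to stay local on a 64-row
  frame, large enough to average speckle. It is configurable via
  `feature_config()`.
- The residual mean is taken signed, reading $\bar{I_n}$ literally; on
  near-unbiased filtering residuals the signed mean is close to zero and
  $f_n$ is dominated by $\sigma_n$, which is the behavior a noise estimate
  should have.

The filter kernel is implemented in C++ with accumulation order and precision
matched to an interpreted per-pixel reference computation, so the test suite
can require *bit-identical* agreement with a brute-force oracle rather than
agreement to a tolerance.

## The gated SVM classifier

Only $(f_c, f_n)$ enter the support-vector machine; the correlation feature
acts purely as the gate. Features are standardized to zero mean and unit
variance (statistics learned on the training set and stored in the model),
and a binary SVM with balanced class weights maps them to the verdict
$V_{svm} \in \{0, 1\}$, 1 meaning high quality. Kernel, cost and kernel
width are genuinely unspecified by the method, so the package fixes
documented defaults — RBF kernel, cost 1, $\gamma = 1/2$ (one over the
feature dimension) — records them in the model metadata, and exposes them as
arguments (a linear kernel is one switch away). The training protocol
mirrors the balanced design the method was developed with: 1,000 frames,
500 per class, a seeded uniform 800/200 train/test split
(`split_frame_set()`), and balanced class weighting.

## Force adaptation and the admittance model

The scan loop runs at 30 Hz. Each tick the current frame is classified and
the commanded force updated by
$$F_{k+1} = \min\bigl(F_k + \delta F\,(1 - V_{svm}),\ F_{max}\bigr):$$
low quality increments the force by $\delta F = 0.25$ N, high quality holds
it. The sweep range 1-20 N and the 0.25 N increment come from the database
acquisition protocol; the update rule itself has no ceiling, so the package
clamps at $F_{max} = 20$ N — the largest force the method was ever exercised
at — rather than allowing unbounded growth. Starting at 1 N, 76 increments
reach the ceiling.

The commanded force drives a virtual mass-spring-damper (the admittance
model) that produces the desired probe displacement:
$$H(s) = \frac{X(s)}{F(s)} = \frac{1}{M s^2 + B s + K},$$
with defaults $M = 5.625$ kg and $K = 50$ N/m, and $B$ chosen for a
critically damped z-response, $B = 2\sqrt{MK} = 33.54$ N s/m (to two
decimals). Only the z axis is simulated: the lateral stiffness entries are
zero, so those axes are inert. The inner joint-space force/torque loop
(which runs at 1 kHz on the real robot) is abstracted as ideal: applied
force equals commanded force within a tick.

**Integrator.** Because the admittance model is linear time-invariant and the
force is held constant over each tick, the discrete-time system has an exact
solution: the zero-order-hold discretization
$x_{k+1} = e^{A\Delta t} x_k + A^{-1}(e^{A\Delta t} - I) B_c F_k$. The
package uses it (`Matrix::expm` on the 2x2 state matrix, precomputed once
per simulation), so the simulated trajectory coincides with the closed-form
critically damped response at the tick instants to machine precision. A
first-order fixed-step integrator at the 30 Hz loop rate was rejected
because its discretization error is visible at this step size, as the chunk
below shows; exactness costs nothing here.

```{r integrator-comparison}
M <- 5.625; K <- 50; B <- critical_damping(M, K); F <- 5
dt <- 1 / 30; n <- ceiling(5 / dt); w <- sqrt(K / M)
# semi-implicit Euler
x <- 0; v <- 0; xe <- numeric(n)
for (i in 1:n) { v <- v + dt * (F - B * v - K * x) / M; x <- x + dt * v; xe[i] <- x }
# package (exact ZOH)
st <- scan_state(force = F); xz <- numeric(n)
for (i in 1:n) { st <- admittance_step(st, F, admittance_params(M, K), dt); xz[i] <- st$x }
xa <- (F / K) * (1 - (1 + w * (1:n) * dt) * exp(-w * (1:n) * dt))
c(euler_max_err_pct = 100 * max(abs(xe - xa)) / (F / K),
  zoh_max_err_pct   = 100 * max(abs(xz - xa)) / (F / K))
```

**Convergence.** The method never defines "scan complete"; the package
declares convergence after 10 consecutive high-quality verdicts (a third of
a second at 30 Hz), long enough that a single lucky frame cannot stop the
ramp. Hitting `max_ticks` without convergence returns the trace flagged
`converged = FALSE` rather than raising an error, since a non-converging
scan is a legitimate outcome (e.g. the probe never couples).

## What the synthetic phantom emulates

`virtual_phantom()` generates frames with the statistical structure the
method relies on, so the whole pipeline runs and is testable without
hardware:

- **No-contact frames**: dark background plus bright arcs bending downward at
  the lateral edges (reverberation artifacts), with light additive noise.
  All no-contact renders of one phantom share the deterministic arc pattern,
  so they correlate above 0.99 with the cached reference.
- **Contact frames**: above a contact-threshold force (default 1.5 N, an
  invented value giving the loop a realistic no-contact-to-contact
  transition), a tissue band with multiplicative Rayleigh speckle (unit-mean
  amplitude, then 8-bit quantization — standard B-mode phenomenology)
  replaces the arcs. The band's depth extent follows a monotone saturating
  compression response (default 0.25 to 0.95 of frame height, force constant
  6 N: tissue fills the field and then saturates), and the in-band additive
  noise s.d. and speckle contrast grow linearly with force. The band bottom
  row is stochastically rounded so the *expected* extent varies smoothly
  with force despite row quantization; strict monotonicity of mean features
  is therefore asserted on a 2 N force grid in the tests, with
  non-decrease (within jitter tolerance) on the native 0.25 N grid, because
  at the saturating top of the response the per-0.25 N extent change is
  sub-pixel for any row-quantized image.
- **Labels**: frames rendered at forces inside the quality band (default
  4-9 N) are "high" quality; frames outside — no-contact, under-compressed
  below $F_{lo} - \mathrm{gap}$, over-compressed above
  $F_{hi} + \mathrm{gap}$ (default gap 2 N) — are "low". The gap is the
  separability dial: shrinking it moves the low-quality force regimes
  against the band edges and cannot improve test accuracy. Setting
  `response_contrast = 0` removes all force dependence from the features,
  which is the genuine zero-separation condition: with in-contact-only
  sampling, classifier accuracy falls to chance, which is how the
  class-recovery property is tested.

What it does **not** emulate: acoustic wave propagation, beamforming, scan
conversion, anatomy, attenuation/shadowing, probe orientation, or any
tissue-specific echogenicity — all generator magnitudes (brightness 120,
background 6, arc brightness 110, noise slopes) are package choices stated
in `phantom_config()` defaults. Passing tests therefore demonstrate that the
algorithmic pipeline behaves as specified on data with the assumed
statistical structure; they say nothing about classification accuracy on
real tissue, which depends on the scanner, the anatomy and the rater.

## Evaluation metrics

`ssim()` implements single-scale structural similarity with the reference
defaults (8-bit dynamic range, 11 x 11 Gaussian window with $\sigma = 1.5$,
$K_1 = 0.01$, $K_2 = 0.03$), averaging the local map over fully valid window
positions; `psnr()` is $10\log_{10}(255^2/\mathrm{MSE})$ with an infinite
sentinel for identical frames. `compare_selections()` tabulates both per
scan position between algorithm-selected and human-selected frames. On a
physical phantom such a table quantifies human-algorithm agreement; here the
metrics are validated against brute-force oracles and monotonicity
properties instead, since no physical selections exist in a simulation-only
package.

## Validation problem sizes

The test suite and the acceptance script exercise: oracle equivalence on
twenty 32 x 32 frames times three window sizes; correlation properties on
one hundred seeded 16 x 16 pairs; the full 1,000-frame, 500/500, 800/200
classification protocol averaged over five seeds; fifty seeded closed-loop
scans (plus a rigged always-no-contact phantom); and 5 s step-response
fidelity at 30 Hz. These sizes make the whole suite run in well under a
minute while keeping every protocol-scale quantity at its stated scale.

## Known limitations

- The contact gate depends on the no-contact reference being representative;
  a reference captured with different machine settings would degrade the
  gate before it degrades the SVM.
- $f_c$ is quantized to frame rows; on low-resolution frames the compression
  response is a step function of force.
- The classifier can accept frames slightly outside the nominal quality band:
  with a sampling gap, forces inside the gap are never seen in training and
  the decision boundary falls somewhere within it. The closed-loop
  simulation typically converges just below the band's lower edge for the
  same reason.
- The simulated loop assumes ideal force tracking within a tick; real
  force-control transients at 1 kHz are outside the package's scope.
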