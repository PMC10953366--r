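---
title: "Joint motion-model and image reconstruction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint motion-model and image reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gricsr)
```

## The problem and the model

A Cartesian MRI acquisition measures k-space line by line over minutes.
When the object deforms with respiration, every line sees a different
anatomy, and the naive reconstruction superimposes all of them: blur and
ghosting along the phase-encode direction. gricsr removes this artifact by
reconstructing a single reference image **and** the motion that corrupted
the data, given one extra input that scanners routinely record: a
respiratory-belt trace $s(t)$.

The motion model is deliberately minimal. The displacement of pixel $(x,y)$
at time $t$ is

$$u(x, y, t) = \alpha(x, y)\, s(t),$$

one pair of coefficients per pixel (units: pixels per unit sensor
amplitude). This is the simplest model that captures the dominant,
belt-correlated component of respiratory deformation, and it keeps the
number of motion unknowns at $2 N_x N_y$ rather than one field per time
point. The joint estimate solves

$$\min_{\rho_0, \alpha} \; \|E(u)\,\rho_0 - m\|^2
  + \lambda \|\rho_0\|^2 + \mu \|\nabla \alpha\|^2,$$

where $E(u)$ encodes, per motion state: bilinear backward warp
$W_s$, coil weighting $C_c$, unitary FFT $F$, and phase-encode sampling
$S$. The belt trace is low-pass filtered at 3 Hz (zero-phase, so the trace
stays aligned with the k-space timestamps), its slow drift — typically air
leaks — is removed as a least-squares quadratic in time, and the result is
re-binned into $N_s$ amplitude states. All lines acquired in one state share
one displacement field $u_s = \alpha \cdot s_s$, which is what makes the
operator block-structured and affordable.

### Where the motion information lives

With a fully sampled acquisition the zero-motion operator is unitary: *any*
data can be fit perfectly by some (artifacted) image. What makes the joint
problem identifiable is the coil dimension: $n_c$ coils give $n_c N$
equations for $N$ image unknowns, and motion-corrupted data are *not*
consistent across coils under the wrong motion model. This observation
drives two design choices below (the motion-step over-relaxation and the
coil-map refresh): anything that biases the coil maps directly erodes the
only signal the motion estimation has.

## The solver

Both subproblems are solved by conjugate gradient on their normal
equations:

* **Image step** — $(E^H E + \lambda\nu I)\rho = E^H m$, at most
  `maxit_recon = 10` iterations or relative residual $10^{-3}$.
* **Motion step** — the residual $\epsilon = m - E(u)\rho$ is modeled to
  first order as $L\,\delta\alpha$, where $L$ applies, per state,
  $S F C_c$ to $s_s\,\nabla[W_s\rho]\cdot\delta\alpha$ (the spatial-gradient
  linearization of the warp), regularized by
  $\mu\nu_m\|\nabla(\alpha + \delta\alpha)\|^2$ with forward-difference
  gradients; at most `maxit_motion = 10` CG iterations or relative residual
  $10^{-2}$.

The two steps alternate `n_fixed_point = 4` times per pyramid level,
coarsest level first; at the native resolution only the image step runs.
Coarse levels are central k-space crops (dyadic), where displacements are
sub-pixel and the warp linearization is accurate; the coefficient maps are
upsampled between levels with rescaling by the pixel-size ratio so the
*physical* displacement is preserved. The pyramid depth adapts so the
coarsest level is about 8 pixels (`n_levels = NULL`).

Three solver features are this package's own additions, each motivated by a
measurable failure mode of the plain alternation on the packaged synthetic
study:

1. **Over-relaxation with a safeguard** (`omega_motion = 2`). The
   alternating scheme is strongly damped: after each image re-fit, most of
   the motion-induced residual has been absorbed into the image, so each
   Gauss–Newton step recovers only a fraction of the remaining coefficient
   amplitude. Doubling the increment roughly halves the iterations needed;
   a backtracking safeguard halves the step while the data residual (at the
   current image) grows by more than 10%, which keeps pathological
   configurations stable.
2. **Motion-consistent coil-map refresh** (`mc_coil_refresh =
   "iteration"`). Coil maps estimated from the central calibration lines of
   a motion-corrupted acquisition inherit ghosting. That error flattens the
   objective's sensitivity to the displacement *amplitude*: the recovered
   fields have the right shape but stall at a fraction of the true
   magnitude. `refine_coil_maps()` re-estimates each coil by CG on
   $m_c = S F\,\mathrm{diag}(W_s\hat\rho)\,c$ given the current image and
   motion — the third block of the joint model — pins the magnitude gauge
   by pixelwise RSS normalization (the factorization $c \cdot \rho$ is only
   identifiable up to a smooth field), and smooths magnitude and phase.
   Refinements at coarse levels are propagated to the native maps as
   bandwidth-limited corrections.
3. **Two passes** (`n_passes = 2`). The first coarse-to-fine sweep estimates
   motion against maps that start out biased; the second sweep restarts the
   schedule with the motion-compensated maps and the converged model, which
   removes most of the remaining amplitude bias at ~2x cost.

### Regularization scales

$\lambda = 1$ and $\mu = 0.5$ are meaningful only relative to a data scale.
This package uses unitary FFTs, under which the conventional
unnormalized-DFT settings translate to an internal factor $\nu = 1/(N_x
N_y)$ on $\lambda$. The gradient penalty on $\alpha$ is additionally not
invariant to the data's intensity scale, so the conversion of $\mu$ carries
a genuinely free factor: gricsr uses $\nu_m = 10/(N_x N_y)$
(`nu_motion_scale = 10`), calibrated once on simulations as the weight that
suppresses noise-driven coefficients without flattening smooth fields, and
exposed in the configuration. Coil maps are smoothed by a 2D
second-difference penalized (Whittaker) spline whose penalty is expressed
per mm², so `smoothing_coeff = 1000` yields the same physical smoothing
length (~6 mm) at every pyramid level and pixel size.

## The synthetic test bed

`make_phantom()` builds two half-elliptical bright regions with smooth
internal texture and glandular blobs on a chest-wall band; `make_resp()`
generates an asymmetric raised-cosine breathing waveform (belt extends on
inspiration) with slow phase jitter, optional quadratic drift and white
noise; `make_alpha()` provides three chest-anchored deformation regimes
(vertical, expansion, shear) that vanish smoothly at the chest wall;
`make_coils()` draws RSS-normalized complex Gaussian-lobe sensitivities.
`simulate_acquisition()` groups phase-encode lines into shots, evaluates
the conditioned belt amplitude at each shot time, warps the phantom,
applies coils and a unitary FFT, and stores the shot's lines — optionally
with uniform undersampling plus a fully sampled calibration band, and
optional complex Gaussian noise at a given image-domain SNR.

Two deliberate properties of the simulator define what passing tests do and
do not show:

* The simulator conditions the respiratory trace exactly as the
  reconstruction does and drives the motion with the conditioned signal, so
  the phantom *is* the $s = 0$ reference frame the solver estimates and
  ground-truth RMSE is well defined.
* In `binned` mode the sensor amplitude is quantized to the reconstruction's
  state values: the data then follow the solver's model exactly, which is
  the right setting for measuring solver efficacy (and yields an exact
  consistency oracle between simulator and encoding operator). `continuous`
  mode (the default) keeps the per-shot amplitude, injecting the
  within-state model mismatch of real acquisitions.

What the simulator does **not** emulate: through-plane motion, relaxation
weighting across the echo train, $B_0$/$B_1$ effects, non-rigid deformations
uncorrelated with the belt, and bulk (non-periodic) motion. Passing the
packaged studies therefore demonstrates solver correctness and the expected
direction and rough magnitude of the improvement — not clinical performance.

## The packaged validation study

The reference scene (used by the test suite and `scripts/acceptance.R`) is a
64×64 phantom, 4 coils, vertical-pattern motion scaled to a 5 px peak
displacement over the acquisition, two lines per shot every 4.7 s (about
2.5 minutes of scanning) and $N_s = 6$. Problem sizes were chosen so the
whole study — including the dense-matrix solver oracles at 8–12 px and the
state-count sweep — runs in minutes on a laptop.

The efficacy quantities (ground-truth RMSE ratio, displacement-field
correlation, SI/AES direction) are computed with the simulator's known coil
profiles and a convergent schedule (`n_fixed_point = 6`): coil-map
estimation has its own accuracy tests, and supplying the true profiles
isolates the motion-correction claim. With full self-calibration at 4 broad
coils, the recovered fields still correlate with the truth above 0.9, but
the remaining map error typically limits the RMSE ratio to ~0.5–0.8; the
acceptance script reports that self-calibrated ratio alongside the
known-coil one. Real acquisitions with 18-channel arrays carry considerably
more coil-consistency information than this deliberately hard 4-coil
setting. At a realistic SNR of 30 the noise floor, not residual motion,
dominates full-image RMSE, so the quantitative study is run noiseless;
noise remains a simulator option.

## Numerical choices and edge cases

* Warping is backward (pull) bilinear with zero outside the FOV; the adjoint
  is the transpose of the same sparse matrix, *not* the inverse warp.
* One fixed grid convention everywhere: `[y, x]` arrays, 0-based indices,
  DC at `N/2`, unitary FFTs; pyramid and map resampling align grids at the
  DC pixel, matching how a central k-space crop relates resolutions.
* Equal-width amplitude binning between the 1st and 99th percentiles,
  outliers clamped into the end bins; state values are bin midpoints; at an
  exact midpoint between samples the earlier sample wins the nearest-in-time
  lookup. Binning is by amplitude only (no inhale/exhale split) — the
  alternative is a possible extension, not implemented.
* A constant (degenerate-range) trace collapses to a single state, and a
  single state carries no motion information: the model stays at zero and
  the pipeline reduces exactly to plain regularized parallel-imaging
  reconstruction.
* The zero-phase Butterworth filter uses reflection padding; without it the
  forward–backward pass leaves start-up transients that masquerade as
  respiratory excursions.
* Coil estimation apodizes the calibration band with a Hann taper (no zero
  endpoints), divides by the root-sum-of-squares, and smooths phase through
  the real/imaginary parts of the unit-phase field — no unwrapping. The
  division floor is $10^{-6}$ of the maximum RSS.
* Empty motion states are reported and skipped rather than failing.
* The AES edge detector is Canny with $\sigma = 1$ px and hysteresis at the
  70th/90th gradient percentiles (the cited AES definition fixes the
  formula, not the detector settings; both are configurable). The background
  mask is a k-means stand-in for an unavailable reference procedure: k-means
  on smoothed intensities with deterministic quantile initialization, the
  lowest cluster as background — unless it is not separated (centroid above
  half the maximum), in which case the image is treated as all-foreground —
  followed by morphological closing. `evaluate_pair()` exposes both masked
  and full-FOV metric modes.
* Motion-model reuse across acquisitions (`motion_update = FALSE` with
  `alpha_init`) resamples $\alpha$ bilinearly in physical coordinates; the
  interpolation order is a configurable choice, linear by default.
* One state per shot is assumed (all lines of a shot share a timestamp);
  echo-train orderings that interleave states within a shot are not modeled.

## Known limitations

The model corrects belt-correlated 2D in-plane motion only; hysteresis
between inhale and exhale at equal belt amplitude, through-plane motion and
bulk repositioning are outside the model class. Amplitude recovery depends
on coil-consistency information and degrades gracefully (shape first,
amplitude second) as coils become fewer or smoother. The linear sensor
model, single channel by design, extends conceptually to multiple sensors
(one coefficient pair per channel), which is a documented configuration
path rather than implemented functionality.
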