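---
title: "Multispectral autofluorescence classification of oral lesions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral autofluorescence classification of oral lesions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cancerous and pre-cancerous oral epithelial lesions are hard to tell apart
from benign lesions by visual examination, and widefield autofluorescence
adjuncts that visualize a single emission band have shown poor specificity.
Multispectral autofluorescence endoscopy excites the tissue with a pulsed UV
laser and collects the emission in three bands chosen to separate the
dominant endogenous fluorophores: collagen in the lamina propria
(390 ± 20 nm), NADH (452 ± 22.5 nm) and FAD (> 500 nm) in the epithelium.
Malignant transformation changes this composition in known directions —
collagen-band emission drops (crosslink breakdown, epithelial thickening),
NADH-band emission rises (glycolytic metabolism), and the optical redox
ratio I452/I500 falls.

`oralaf` implements the full analysis chain that turns paired
lesion/contralateral-healthy decay-resolved image cubes into an image-level
cancer/pre-cancer call: preprocessing, per-pixel spectral features, an
L1-regularized linear SVM with embedded feature selection, pixel-level
posterior probability maps, image-level aggregation, constrained-ROC
thresholding, and leave-one-patient-out cross-validation (LOPOCV). Because
no public imaging data accompany the method, the package also ships a
synthetic cohort simulator so that every stage is testable end to end.

## The synthetic cohort simulator

`simulation_config()` describes a cohort of `n_patients`, each contributing
one lesion cube and one contralateral healthy cube. Every pixel trace in
band $\lambda$ is

$$y_\lambda(t) = A_\lambda \, e^{-(t - t_0)/\tau_\lambda} \cdot
\mathbf{1}[t \ge t_0] + \text{offset} + \varepsilon(t),
\qquad \varepsilon(t) \sim \mathcal N(0, \sigma^2),$$

followed by hard clipping at `saturation_level`. Design choices worth
knowing:

* **Single-exponential decays** (default lifetimes 5.0 / 4.0 / 4.5 ns for
  the three bands). The classifier uses only time-integrated intensities,
  so the decay shape is irrelevant to the features; the simplest decay
  model suffices. Time-resolved (lifetime) features are deliberately out of
  scope.
* **Amplitude calibration.** $A_\lambda$ is scaled so that the *discrete
  trapezoidal* integral of the noise-free trace equals
  `amplitude_scale × fraction_λ`. Without this, the band-dependent
  lifetimes would make integrated band fractions deviate from the
  configured composition by the (band-dependent) truncation and quadrature
  error (~1e-4), and the noise-free limit would not recover the class
  composition exactly. With it, recovery is exact to machine precision,
  which the tests exploit.
* **Pre-pulse baseline.** The first `prepulse_samples` (default 16) samples
  carry only offset + noise. This gives the preprocessing a pure-baseline
  region from which to estimate the per-pixel offset and the noise level,
  mirroring the pre-trigger samples of a real gated acquisition.
* **Time axis.** Default 256 samples at 0.1 ns: a 24 ns post-onset window
  that contains ≥ 99% of each exponential's area (validated at
  construction).
* **Class structure.** Each histopathology class (Benign, MoD, HiD, SCC)
  has a mean band-fraction triple; the defaults plant the reported trend
  directions — positive classes have lower $I_{390,n}$, higher $I_{452,n}$
  and lower $I_{452}/I_{500}$ than the benign/healthy composition
  (0.40, 0.33, 0.27 vs 0.28, 0.38, 0.34). Healthy contralateral cubes
  always draw from the benign composition. Two dispersion knobs sit on top:
  per-pixel jitter (`fraction_jitter_sd`, default 0.04) and a per-patient
  random shift (`patient_fraction_sd`, default 0.035). The patient-level
  term matters: without between-patient variability every image of a class
  has the same expected features and cross-validation is degenerate
  (trivially perfect). 0.035 was chosen once as a strong-but-not-degenerate
  effect: class means sit ≈ 3.4 patient-SDs apart on the collagen-band
  fraction.
* **Saturation** is modeled as hard clipping: a configured fraction of
  pixels (default 1%) has its amplitude boosted past the ceiling so the
  saturation mask has something to catch.
* **Noise** is additive Gaussian per time sample (default SD 5 at
  `amplitude_scale` 1000, offset 50); Poisson shot noise is available as an
  option but off by default, since no noise model is prescribed for the
  instrument.

What the simulator does *not* emulate: illumination inhomogeneity across
the endoscopic field, motion blur, the instrument response function,
spatial lesion structure (every pixel of an image shares one composition),
and any realistic relation between histological grade and effect size.
Passing tests on synthetic cohorts therefore demonstrate that the pipeline
recovers *planted* effects under its own assumptions — they are not
estimates of clinical performance, and the package nowhere presents them as
such.

## Preprocessing

`preprocess_sample()` applies five steps, in order, independently to the
lesion and healthy cube; a pixel once masked is never unmasked and keeps
the reason code of the first step that masked it:

1. **Offset subtraction** — per pixel and band, the mean of the leading
   `baseline_samples` pre-pulse samples is subtracted. Per-pixel estimation
   tolerates spatial background structure.
2. **Saturation mask** — a pixel whose maximum amplitude reaches the
   threshold *in any band* is masked: all features need all three bands,
   so one clipped band makes the pixel unusable. No universal detector
   ceiling exists, so the threshold is configuration (absolute units or a
   fraction of the cube maximum); `auto_preprocess_config()` resolves
   `0.9 × (saturation_level − offset_level)` for simulated cohorts, which
   cleanly separates clipped from unclipped pixels.
3. **Spatial smoothing** — a 5×5 averaging filter per time sample. The
   kernel is renormalized over in-image, *unmasked* neighbors, so no
   synthetic values leak in at edges or mask borders; masked pixels keep
   their original trace and contribute nothing.
4. **SNR mask** — SNR is defined here as
   $20 \log_{10}(\text{peak}/\sigma)$ dB per band on the smoothed trace,
   with $\sigma$ the SD of the leading baseline samples; pixels below
   15 dB in any band are masked. The step order implies the filter precedes
   the SNR test. A noise-free pixel ($\sigma = 0$) counts as infinite SNR
   and is kept.
5. **Manual mask** — externally supplied boolean maps (e.g. teeth regions);
   consumed as data, never drawn interactively.

## Spectral features

For each valid pixel, the absolute band intensity is the trapezoidal
integral $I_\lambda = \int y_\lambda(t)\,dt$; the three normalized
intensities $I_{\lambda,n} = I_\lambda / \sum_\lambda I_\lambda$ sum to 1;
and six inter-band ratios complete the nine absolute features. Nine
relative features subtract, per feature, the *median* of the paired healthy
map: $\Delta f(x,y) = f(x,y) - \mu_{f,\text{Healthy}}$ — 18 features in
all, in a fixed canonical order that also serves as the tie-break for
feature ranking. Healthy stacks only ever carry the nine absolute features
(the reference is its own baseline).

Pixels where any band integral is non-positive after offset subtraction
(possible under heavy noise) are masked with a dedicated reason code rather
than producing undefined ratios; every downstream feature needs all three
integrals positive.

## Classification model

Training operates at the pixel level: every valid pixel inherits its
image's biopsy label (a documented label-noise source — there is no
pixel-level ground truth). Features are z-scored on the training pixels
before fitting, since the method compares weight magnitudes across features
and that is only meaningful on commensurate scales. The model is a linear
SVM with L1 penalty and squared-hinge loss,

$$\min_{w, b}\; \|w\|_1 + c \sum_i \max(0,\, 1 - y_i (w^\top x_i + b))^2,
\qquad c = 1,$$

in the sum-form convention of the standard linear-SVM solvers. The solver
is proximal Newton: each iteration builds the second-order model of the
loss over the margin-violating (active) pixel set, solves the resulting
L1-penalized quadratic subproblem by coordinate descent in the small
feature dimension, and safeguards the direction with an Armijo line search
on the true objective; the intercept is an unpenalized extra coordinate.
It stops when the maximal violation of the subgradient optimality (KKT)
conditions falls below `tol` times its zero-solution value, and the tests
verify KKT optimality directly. Two simpler schemes were evaluated first
and discarded: global-stepsize proximal gradient and one-coordinate-at-a-
time descent both zig-zag for thousands of iterations on the strongly
correlated, nearly separable pixel tables this pipeline produces, whereas
the full quadratic model resolves the correlated directions at once.

Embedded feature selection follows the weight-ranking recipe: take
$|w_j| / \sum_k |w_k|$, sort descending (ties broken canonically), retrain
on the top-k features (k = 3, 4, 5 are the evaluated sizes; if fewer than k
weights are nonzero the remainder is filled canonically, with a warning).
The retrained decision values are mapped to posterior probabilities by a
Platt-style sigmoid $p = 1/(1 + e^{A d + B})$ fitted on the training
decision values with regularized targets, which stays finite on separable
data. Any monotone calibrator preserves all downstream rankings; the
logistic choice is the field standard.

## Image-level decision and cross-validation

A lesion's image score is the mean of its posterior map over valid pixels.
The decision threshold is chosen on the *training* ROC curve: among
candidate thresholds (the unique observed training scores plus the
always-feasible reject-all point), restrict to false-positive rate ≤ 30%
and take the one with maximal sensitivity; ties break toward lower FPR,
then larger threshold (the conservative margin). Candidate thresholds
between observed scores cannot enlarge the achievable (sensitivity, FPR)
set under the `score ≥ θ` rule, so enumerating observed scores is exhaustive
— a property test checks agreement with brute-force enumeration.

LOPOCV holds out one patient (one lesion image, with its healthy pair) per
fold; the full-pool fit, ranking, top-k retraining, calibration and
thresholding all see only the remaining patients. A leakage test asserts
that perturbing the held-out image changes neither its fold's model nor its
threshold. Per-image training pixels are capped at 2000 by a seeded uniform
subsample (cap `Inf` reproduces the all-pixels design); one root seed
expands deterministically into per-fold subsampling seeds, making every
report byte-reproducible.

The single-feature baseline runs the identical protocol with
$I_{452,n} + I_{500,n}$ — algebraically $1 - I_{390,n}$ — emulating what a
blue-excitation adjunct like the VELscope visualizes.

## Problem sizes and numerical choices

The package's own validation runs LOPOCV on simulated cohorts of 40
patients with 64×64-pixel images, 256 time samples and a 2000-pixel
training cap — large enough for the planted effects to be comfortably
estimable, small enough to iterate on a laptop; smaller unit-test cohorts
use 16×16 images with 64 samples at 0.5 ns (the window-coverage invariant
fixes the admissible time grids). Tolerances: mask/feature identities at
1e-9; solver convergence at relative KKT residual 1e-6; simulator recovery
checks at 1e-6. Degenerate inputs are handled by explicit rules documented
above (σ = 0 pixels kept; non-positive integrals masked; all-zero weight
vectors fall back to canonical ranking with a warning; empty classes raise
errors rather than returning NaN metrics).

## Known limitations

* Pixel labels inherit the image's central-biopsy label; spatially
  heterogeneous lesions violate this silently in real data.
* The simulator's classes differ only in mean band composition; real
  lesions add texture, illumination and anatomy effects that the pipeline
  has never seen in testing.
* The squared-hinge L1 objective is the standard surrogate when an exact
  hinge+L1 solver is not at hand; coefficients can differ slightly from a
  hinge-loss fit, though selection behavior is equivalent in practice.
* Image scores use only the posterior mean; medians, modes or
  exceedance fractions are deliberately not implemented (kept out of
  scope).
* No registration or illumination correction is performed between lesion
  and healthy images.
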