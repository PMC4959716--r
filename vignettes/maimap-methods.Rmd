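---
title: "Methods: malignancy mapping from multiparametric prostate MRI"
author: "maimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: malignancy mapping from multiparametric prostate MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maimap)
```

This vignette is the package's account of its models, numerical choices and
limits. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Geometry and volume model

A `volume_image` is a 3-D array plus a 4×4 voxel-to-world affine in mm
(right-handed patient frame, 0-based voxel indices). The affine is the single
source of geometry truth; spacing, origin and orientation are derived from
it. Volumes are read and written as NIfTI-1 with data stored as float64
(bit-exact round trip); the NIfTI-1 header keeps the affine in float32, so
geometry round-trips to single precision (~1e-7 relative) — an intrinsic
format limit, asserted in the tests at 1e-5 mm absolute.

## 2. The digital phantom

Every downstream stage is exercised against seeded synthetic studies with
known truth. Design points:

* **Acquisition geometry** follows a 3 T protocol: T2W 0.8 × 0.7 × 3 mm,
  DWI 2.2 × 2.2 × 3 mm at b = 0, 50, 100, 150, 200, 250, 800 s/mm²,
  DCE 1.6 × 1.6 × 1.5 mm sampled every 9.9 s (32 frames by default). Grid
  extents (72 × 72 × 16 T2W voxels) are sized to hold a median-volume
  (~45 cm³) prostate plus margin.
* **Tissue table** (`default_tissue_table()`): one editable row per class.
  Benign peripheral zone uses ADC 1.6e-3 mm²/s and Ktrans 0.05/min; tumour
  classes have ADC decreasing and Ktrans increasing with Gleason grade
  (6–10). These are literature-informed generator configuration, not fitted
  quantities.
* **AIF**: a biexponential population input function (Weinmann-type
  amplitudes 3.99 and 4.78 kg/L, decay 0.144 and 0.0111 /min, 0.1 mmol/kg
  dose) with a 60 s onset; the DCE baseline is the pre-onset frames.
* **Signal texture**: a smooth multiplicative sinusoidal field (amplitude
  0.15, wavelengths 17–23 mm) fixed in anatomy coordinates stands in for
  internal anatomy. It makes registration well conditioned (a plain
  ellipsoid is nearly rotation-invariant) and cancels exactly in the ADC
  log-slope and the DCE enhancement ratio.
* **Noise** is additive Gaussian per modality (σ = 4, 2, 2 a.u. for
  T2W/DWI/DCE against ~100 a.u. baselines, i.e. SNR ≈ 25–50); Rician noise
  is out of scope.
* **Misregistration** is injected by rendering the DWI/DCE content at
  T⁻¹(world), so the registration stage must recover exactly T.
* **Biopsy cores** are ~17 mm segments oriented roughly along +z
  (transperineal approach), 2 targeted per lesion plus a systematic grid,
  16–36 per patient. A Beta(8, 2) effective-length fraction (mean 0.8)
  truncates each core from the entry side; the pathology result is the
  maximum truth grade intersected by the *effective* segment. This
  reproduces the clinically recognized false-negative mechanism of limited
  effective core length.
* **Cohorts** (`cohort_specs()`): exactly `round(n × prevalence)` positive
  patients (a seeded permutation decides which), 1–3 lesions each, grades
  drawn from {6, 7, 7, 8, 9} (median 7), lesion volumes 0.4–2.5 ml, prostate
  volumes ~25–70 cm³. The defaults emulate a 45-patient cohort at 46.7 %
  prevalence.

What the phantom does *not* emulate: zonal anatomy, bias fields,
susceptibility and motion artifacts, Rician noise, grade heterogeneity
within a lesion, and reader-dependent lesion conspicuity. Tests passing on
phantoms therefore demonstrate internal consistency of the pipeline — each
stage inverts the generator's forward model and the statistics reproduce
published tables — not clinical performance. The clean class separation in
the tissue table is also why demonstration cohorts often classify perfectly.

Determinism: every stochastic step takes a seed, runs in a private RNG
stream, and identical spec + seed gives bit-identical volumes, cores, models
and reports.

## 3. Registration

DWI and DCE are registered to the T2W grid with a 9-DoF affine
(translations mm, rotations degrees, scales; applied about the primary
volume centre, rotations composed R_z·R_y·R_x). Choices:

* **Metric**: plug-in mutual information over a 32 × 32 joint histogram
  spanning each sample's 1st–99th percentile range, samples restricted to
  the overlap region (≤ 20 000 primary voxels, deterministic stride).
* **Initialization**: from metadata only — the transform aligning the
  secondary's field-of-view centre and frame orientation onto the primary's.
  For same-frame acquisitions this is ~identity; for equal grids whose
  origins differ by a pure offset it is exactly that offset. Optionally a
  2× downsampled first pass pulls in large offsets.
* **Optimizer**: Polak–Ribière+ conjugate gradient with restart and a
  backtracking line search; gradients by central finite differences
  (h = 0.1 in scaled units); per-parameter scaling 1 mm ≡ 1° ≡ 0.01 scale so
  one step size serves all 9 DoF. Iterates are only accepted if MI
  increases, so the metric is non-decreasing along the accepted path.
* **Stopping**: the run ends when the MI gain stays below 1e-5 nats for
  three consecutive accepted steps, or at 200 iterations. A single-step
  gate proved brittle: conjugate-gradient runs legitimately take small
  interim steps before a larger one, and stopping on the first small gain
  left rotations under-recovered on shallow MI landscapes.

On textured phantoms with injected transforms (|t| ≤ 5 mm, |r| ≤ 5°,
s ∈ [0.95, 1.05]) the acceptance suite requires the median
target-registration error at prostate-surface points to stay below one
primary-grid voxel diagonal (√(0.8² + 0.7² + 3²) ≈ 3.18 mm); typical
recoveries in the tests are a few tenths of a millimetre.

## 4. Parametric maps

* **ADC**: ordinary least squares of ln S on b per voxel; ADC = −slope
  clamped at 0. Voxels with non-positive samples fall back to their positive
  subset (flagged); fewer than two usable samples flags the voxel with
  ADC = 0.
* **Tofts**: the forward convolution uses an exponential-kernel recursion
  that is exact for an AIF that is piecewise linear between frames, making
  the forward model and the fit mutually consistent, with a series guard for
  k_ep·Δt → 0. The fit exploits the model's structure by variable
  projection: for fixed k_ep the model is linear in Ktrans, so a 40-point
  log-spaced k_ep grid (0.02–20 /min) is profiled and the best cell refined
  by golden-section search — vectorized across voxels, deterministic, no
  multi-start needed. Bounds Ktrans ∈ [0, 5] /min, V_e ∈ (0, 1]; solutions
  implying V_e > 1 are re-solved on the V_e = 1 boundary (flagged);
  all-zero curves are flagged with zeros. Noiseless curves are recovered to
  < 1e-4 in both parameters (asserted), and k_ep ≡ Ktrans/V_e holds to 1e-9
  relative by construction.
* **Signal→concentration**: enhancement over the pre-onset baseline divided
  by a configured proportionality constant (default 4.5 per mmol/L). The
  conversion inverts the phantom's signal model exactly; for clinical data
  the constant is a calibration input.
* **T2W normalization**: robust z-score (median, 1.4826 × MAD) over the
  rectangular VOI; invariant to positive affine intensity rescaling by
  construction; a constant VOI is flagged and zeroed.

All maps live on the T2W grid; geometry equality is asserted.

## 5. The MAI model

Feature vectors are fixed to the five computed parameters
(t2w_norm, adc, ktrans, ve, kep), standardized exactly once with constants
stored in the model.

**Architecture.** Gaussian radial-basis activations at grown kernel centres
(one shared width, the median pairwise distance of a training subsample), an
identity projection into predictor space (whose dimension therefore equals
the number of grown kernels, capped at 64), and a linear summation layer.

**Phase 1 — ranking.** The network is trained only to order voxels by
malignancy grade (benign < G6 < … < G10): logistic loss on score differences
over label-ordered pairs (≤ 20 000 pairs per round, seeded subsample),
weights refitted by BFGS after each growth step. Growth is error-feedback:
the next kernel centre is placed at the training sample contributing the
largest ranking loss (skipping near-duplicates). Growth stops when the
held-out ranking error (20 % split) has not improved for 5 rounds; the
best-validating model is kept.

**Phase 2 — Gleason congruence.** With phase-1 weights frozen, class-median
raw scores are mapped to anchors by isotonic (pool-adjacent-violators)
regression — the monotone map minimizing squared anchor distance — giving
strictly increasing piecewise-linear calibration nodes. The anchor policy is
linear: grade g ↦ 0.6 + 0.1·(g − 6) (so Gleason 6 sits exactly at the 0.6
decision level and Gleason 10 at 1.0), benign at 0.3. Outside the outer
nodes the map clamps, and all MAI values lie in [0, 1].

Two practical consequences, both asserted in tests:

* The calibration can only anchor grades present in training. A cohort
  slice without Gleason-6 lesions yields a model whose G6 response
  interpolates between the benign and G7 nodes (≈ 0.5); congruence checks
  therefore train on cohorts containing every grade of interest.
* Training must see everything the VOI contains at prediction time. The VOI
  is rectangular, so periprostatic tissue is included under the non-cancer
  label; a model trained only on intra-prostatic voxels scores
  out-of-distribution background near the raw-score origin, which calibrates
  uncomfortably close to the 0.6 threshold.

Models serialize as versioned JSON at 17 significant digits (bit-exact round
trip, asserted). No trained weights ship with the package; the training
procedure plus seeds reproduce any fixture model.

## 6. Core profiles, lesions, patients

* **Core profiles**: the MAI map is sampled along each core's effective
  segment every 0.5 mm; each station averages the axis point and 4 radial
  offsets at 1 mm radius (radius 0 gives pure line sampling for sensitivity
  analysis). Features are the profile max and mean; a histogram over fixed
  edges 0, 0.05, …, 1 is attached.
* **Decision rule**: positive iff max ≥ 0.6 AND mean ≥ threshold. All
  threshold comparisons use ≥ uniformly.
* **Lesions**: 26-connected components of voxels with MAI ≥ 0.6; clinically
  relevant iff component mean MAI ≥ 0.6 and volume ≥ 0.5 ml (both
  configurable). The labelled component volume also attributes cores to
  lesions (a core belongs to a lesion if any sample station falls in its
  component).
* **Patient scoring**: a sampled predicted lesion is confirmed when at least
  one of its cores is positive in pathology (Gleason ≥ 6) *and* in the MAI
  analysis; unsampled lesions are excluded. Patient = TP if any lesion is
  confirmed; TN if no (sampled) lesions and no pathology-positive cores; FN
  if no (sampled) lesions but pathology-positive cores; FP otherwise. The
  rule is total — the test suite enumerates the evidence combinations.

## 7. Statistics

Wilson score intervals use z fixed at 1.96 (not the exact 97.5 % quantile):
this is what reproduces conventionally printed 95 % interval decimals; the
generic-z path is cross-checked against `prop.test(correct = FALSE)`. The
Youden interval sums the *unrounded* Wilson bounds of sensitivity and
specificity (lower = L_sens + L_spec − 100, upper likewise) — not a standard
interval, but the reproduction policy for published tables that pair Youden
indices with per-proportion Wilson intervals; a table assembled from
already-rounded percentages can disagree in the final printed digit, which
is why one published lower bound prints 30.62 where the unrounded
computation gives 30.61. ROC points are (1 − spec, sens) with (0,0) and
(1,1) appended, sorted by false-positive rate, integrated by trapezoid
(cross-checked against shoelace polygon area). Percentages are rounded
half-up to two decimals, at reporting only.

## 8. Problem sizes and runtime choices

The shipped configurations are desk-scale by design: the default study is
72 × 72 × 16 T2W voxels with 7 DWI volumes and 32 DCE frames (one study
simulates in ~0.5 s; its maps fit in ~5 s on one core), cohort checks use 30
patients, registration recovery uses 20 phantoms at ≤ 80 CG iterations and
10 000 metric samples, and the demonstration cohort (`fixture_config()`)
runs 6 reduced-grid patients end to end in ~20 s. These sizes were chosen so
the whole validation suite completes in minutes while leaving every
algorithmic path exercised; all of them scale up by configuration only.

## 9. Known limitations

* Affine-only registration; no deformable model, no multi-resolution pyramid
  beyond the optional 2× first pass.
* The standard Tofts model (no plasma-volume term, no T1/B1 correction); the
  signal→concentration constant is configuration, not estimated.
* The phantom's simplifications listed in §2; in particular, phantom-perfect
  separation must not be read as expected clinical accuracy.
* The Youden interval construction is a reproduction policy (§7), not a
  recommended inferential procedure; no AUC confidence interval is provided.
* Kernel width is a single shared bandwidth; per-kernel widths are stored in
  the model schema but the trainer does not currently adapt them.
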