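---
title: "Collateral maps from dynamic angiography: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collateral maps from dynamic angiography: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science inside `collateralmap`: the models
and rules each stage implements, the tunable parameters and their
defaults, what the digital phantom does and does not emulate, and the
numerical choices made where the underlying clinical methodology left
the design open.

## The collateral map

Cerebral ischemia with a proximal arterial occlusion produces a
spectrum of tissue states governed by collateral flow.  A dynamic
contrast-enhanced MR angiography acquisition samples the passage of a
contrast bolus through the brain every `frame_interval_s` seconds.  The
collateral map condenses this 4D signal into five phase images aligned
to the patient's own hemodynamics rather than to fixed times, so that
delayed collateral filling of the ischemic MCA territory becomes
directly visible: tissue that only enhances in the early or late venous
phase is perfused late, via collaterals.

### Phase segmentation

Two reference curves drive the segmentation: the arterial curve from an
ROI on the contralateral (normal-side) MCA and the venous curve from
the superior sagittal sinus.  `detect_bolus()` estimates, per curve:

* baseline: median of the initial 10% of frames (at least 3);
* robust noise: `1.4826 * MAD` of those baseline frames;
* peak: the global maximum (a peak elevation below 5 times the noise
  raises a "no bolus detected" error);
* arrival: first time the intensity exceeds baseline plus
  `arrival_fraction` (default 0.1) of the peak elevation;
* half- and late-decay: first post-peak times at 50% and 10% of the
  peak elevation, truncation-flagged when the curve stays elevated
  through the end of the acquisition.

`segment_phases()` then defines arterial `[arrival_a, peak_a)`,
capillary `[peak_a, peak_v)`, early venous `[peak_v, halfdecay_v)`,
late venous `[halfdecay_v, latedecay_v)` and delay
`[latedecay_v, end)`.  The clinical programs that inspired this
pipeline delegate their exact boundary criteria to in-house software;
the peak/50%/10% landmark rules used here are this package's explicit,
config-exposed operationalisation and are not claimed to replicate any
in-house implementation bit for bit.  Windows are half-open and
contiguous, so they partition the post-arrival time axis; when a
computed boundary would leave a window without a single frame, the
window is widened by one frame and a warning is emitted, which keeps
every phase image well defined even for truncated venous curves.

Curves are not smoothed by default — the default path is exactly
reproducible from the voxel data.  ROI means over O(100) voxels already
suppress voxel noise by an order of magnitude.

### Phase images and hypoperfusion masks

`build_phase_maps()` subtracts the per-voxel mean of the pre-arrival
frames (the subtraction baseline) and takes the voxelwise temporal
maximum over the frames inside each window, clipping negatives to
zero.  The maximum, not the mean, is used because collateral perfusion
shows up as a *transient* enhancement somewhere inside the window.

The clinical delineation of "less perfusion than the contralateral
hemisphere" was a visual, manual judgement.  `detect_hypoperfusion()`
replaces it with a deterministic surrogate: an ipsilateral MCA voxel is
hypoperfused in a phase when its intensity is below
`threshold_fraction` (default 0.5) times the intensity of its mirror
voxel across the mid-sagittal plane.  Two regularisations keep the
surrogate stable:

* connected components smaller than `min_cluster_voxels` (default 27,
  a 3×3×3 neighbourhood) are removed from the capillary mask;
* later phases keep only capillary-mask voxels that satisfy the
  criterion in *every* intervening phase — the persisting-region rule.
  This construction makes the nesting
  `delay ⊆ late venous ⊆ early venous ⊆ capillary` a structural
  invariant rather than an empirical observation, and volumes (voxel
  count × voxel volume, reported in mL) non-increasing across phases.

The 0.5 threshold is a surrogate choice, not a claim of equivalence
with expert painting; both it and the cluster size are config-exposed.
Mirroring is a plain axis flip: the phantom is built mirror-symmetric,
and registration of real, asymmetric anatomy is out of scope.

### Grading

`count_delayed_regions()` counts a region as delayed in a phase when at
least `region_fraction_threshold` (default 0.5, boundary inclusive) of
its voxels are hypoperfused.  `collateral_score()` maps the count
triple (capillary, early venous, late venous) to the 0–5 score;
"more than half of the territory" means more than 4 of the 8 regions,
and "no or small" delay means at most `small_max_regions` (default 0)
delayed regions, with sub-threshold voxels permitted.  Clauses are
evaluated top-down and the first match wins; the overlap between the
score-3 clause ("> ½ capillary and no-or-small early venous") and the
score-2 clause is resolved in favour of score 3 by that order.  The
delay phase does not enter scoring: score 0 keys on the late venous
count.  An exhaustive enumeration of all 165 nesting-valid count
triples is tested against an independent clause-by-clause transcription
of the grading table, along with monotonicity (worsening any count
never raises the score).

### Lesion metrics

The lesion growth ratio is follow-up over baseline DWI lesion volume;
growth is a ratio ≥ 1.2 (boundary inclusive), the margin absorbing
vasogenic edema.  The Tmax/DWI ratio thresholds the Tmax map strictly
above 6 s.  `match_phase()` operationalises "the phase with the
hypoperfused lesion most approximate to the DWI lesion" as maximal Dice
overlap, with ties broken toward the later (smaller, nested) phase and
an `undetermined` result when the best Dice falls below `min_dice`
(default 0.2) or no hypoperfused lesion exists — the typical situation
of good-collateral patients with small lesions.  Dice was chosen over
volume difference because it rewards spatial coincidence, not just
size; 0.2 guards against spurious matches between unrelated small
masks.  Collateral ratios fall back to 1.0 when a phase is undetermined
or a denominator volume is zero, consistent with the absence of growth
in such patients.  Predictors are dichotomised at the same 1.2
threshold as the outcome by default; the clinical sources do not state
their dichotomisation rule, so the threshold is exposed.

## The digital perfusion phantom

`generate_phantom()` builds a 4D series with known truth.  Defaults
(chosen once, as the package's study conditions):

| parameter | default | meaning |
|---|---|---|
| `grid_shape` | 64×64×32 | voxels; first axis is left–right |
| `voxel_size_mm` | 1.8×1.8×4 | typical DCE-MRA resolution |
| `n_frames`, `frame_interval_s` | 60, 1 s | one-minute acquisition |
| `arterial_arrival_s` | 8 s | bolus onset, contralateral side |
| `bolus_shape` | α = 3, β = 3, amplitude 100 | gamma-variate; peak 9 s after onset |
| `venous_lag_s` | 4 s | venous peak − arterial peak |
| `region_delay_s` | 0 × 8 | collateral filling delay per MCA region |
| `noise_sd` | 5 | i.i.d. Gaussian signal noise (SNR 20) |

The gamma-variate
`amplitude · ((t−t0)/αβ)^α · exp(α(1 − (t−t0)/αβ))` is the standard
first-pass bolus model; α and β were set so that the arterial curve has
decayed to only ~25% of peak at the start of the late venous window,
keeping the mirrored-comparison reference well above the noise floor in
every scored phase at SNR ≥ 10.  The venous curve is the same shape
shifted by the venous lag; each ipsilateral MCA region is shifted by
its collateral delay.  `delays_for_counts()` inverts the noiseless
detection rule to place delays midway between phase-boundary delay
thresholds, so a requested delayed-region count profile (and hence an
intended score) is realised with maximal noise margin.
`phantom_config_for_score()` wraps canonical profiles for each score.

The ground-truth record contains two boundary sets: the continuous-time
landmark solution of the analytic curves, and the frame-quantized
boundaries obtained by running the landmark detector on the noiseless
frame-sampled curves.  Noiseless recovery is tested against the former
(within one frame); noisy recovery is tested against the latter,
because threshold-crossing jitter under noise is bounded by one frame
relative to the quantized reference but not relative to the continuous
crossing time when that falls just before a frame.

What the phantom does *not* emulate: MR physics (T1/T2*, coil
profiles, inflow saturation), motion, partial-volume effects, spatially
correlated noise, anatomical asymmetry, and real lesion shapes (lesions
are unions of atlas regions or centred sub-region boxes).  Passing the
phantom suite therefore demonstrates the correctness and noise
robustness of the *algorithms*, not clinical performance on patient
data.

`generate_cohort()` emulates the patient-level statistics instead: the
default grade mix is 16 good / 29 intermediate / 7 poor per 52
patients; good-grade patients carry pCR = 1 (their lesions do not
grow), intermediate/poor pCRs are log-normal around medians 2.8 / 3.1;
the growth ratio is `pCR · (1 + ε)` with `ε ~ N(0, 0.08)`; the aCR adds
15% relative noise to the pCR; and the Tmax/DWI ratio multiplies the
growth ratio by a ×3 log-normal-noised positive bias, mimicking the
systematic penumbra overestimation of fixed-threshold perfusion
imaging.  These noise levels were fixed once as plausible for the
respective measurement chains; the cohort reproduces the *structure* of
the clinical findings (near-perfect pCR concordance, degraded Tmax/DWI
concordance, complete separation of growth by grade), not any
particular patient sample.

## Evaluation statistics

* **Diagnostic performance** uses exact Clopper–Pearson intervals by
  default (Wilson available).  The choice matters: the printed interval
  endpoints of the clinical performance table are reproduced exactly by
  the beta-quantile bounds on the reconstructed integer counts.
  `metrics_from_rates()` recovers those counts from rates printed to
  one decimal place by rounding against the group sizes.
* **Lin's CCC** uses population (1/n) moments, with the Fisher-z
  asymptotic variance for its interval.  CCC differences use a paired
  case-resampling bootstrap (B = 2000 by default) with a
  bias-corrected and accelerated interval; the BCa machinery is
  computed in-package from the bootstrap replicates because degenerate
  resamples (zero variance) must be dropped and counted rather than
  crash the interval.  Significance is read as the interval excluding
  zero.
* **Firth logistic regression** maximises the Jeffreys-penalized
  likelihood by Newton steps on the hat-corrected score with
  step-halving.  It is validated against the add-½ closed form on 2×2
  tables and an independent optimizer, and converges to the MLE as
  counts scale.  Wald p-values are reported (penalized-likelihood-ratio
  tests are not implemented).  This estimator is what makes the
  growth-on-grade model identifiable: with no growth events among good
  collaterals the ML odds ratios diverge, while the penalized estimates
  are finite and match the published values to printed precision.
* **McNemar** is applied to paired correct/incorrect indicators, with
  the exact binomial path below 25 discordant pairs.  **DeLong**
  AUC comparison is delegated to `pROC` and cross-checked against an
  O(n²) Mann–Whitney oracle in the tests.  **Weighted kappa** supports
  linear and quadratic weights.

## Problem sizes and runtimes

The validation suite evaluates 100 seeded phantoms at 48×48×24 voxels
(score recovery ≥ 95% required, boundary agreement within one frame,
pCR within 10% of the true volume ratio), the exhaustive 165-profile
grading oracle, and BCa bootstraps at B = 2000 on n = 200 vectors;
the full suite runs in about a minute on one CPU, the acceptance
script in about half a minute.  The 64×64×32 default grid costs about
1.7 s per phantom end to end.

## Known limitations

* The hypoperfusion surrogate is calibrated on the symmetric phantom;
  on real data the 0.5 mirror threshold would need evaluation against
  expert delineation, and mirroring would need registration.
* The delay-phase mask is computed but unreliable at low SNR because
  the contralateral reference has largely washed out by then; it is
  never used in scoring.
* Bolus recirculation, venous sinus anatomy and tissue enhancement are
  not modelled; the venous curve is a shifted arterial curve.
* Firth p-values are Wald-based; profile-penalized-likelihood
  intervals are not provided.
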