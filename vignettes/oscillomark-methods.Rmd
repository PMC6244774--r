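---
title: "Methods: oscillatory brain activity as a glioma progression biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillatory brain activity as a glioma progression biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillomark)
```

## The scientific question

Preclinical work has shown that neuronal activity promotes diffuse glioma
growth, with the post-synaptic adhesion protein neuroligin-3 (NLGN3) —
secreted in an activity-dependent manner — as a key mediator. oscillomark
implements the clinical counterpart of that hypothesis as a reproducible
pipeline: if neuronal activity feeds tumor growth, then patients with
*lower* macroscopically measured brain activity should show *lower* NLGN3
expression in resected tumor tissue and *longer* progression-free survival
(PFS).

Brain activity is operationalised as broadband (0.5–48 Hz) oscillatory
power of source-reconstructed MEG signals in 78 cortical atlas regions.
Three per-patient summaries are formed:

* **peritumor activity** — mean power over the regions overlapping the
  twice-dilated tumor mask,
* **global activity** — mean power over all 78 regions,
* **non-tumor activity** — mean power over the complement of the peritumor
  set.

By construction these satisfy, for `R` regions of which `k` are peritumor,

```
R * global = k * peritumor + (R - k) * nontumor
```

exactly; `compute_oba()` enforces this identity and the test suite checks
it on every synthetic patient. Raw means are converted to z-scores against
the patient cohort (`zscore_cohort()`, sample SD with divisor n − 1), so
all downstream statistics are scale-free; an external reference
distribution (e.g. healthy controls) can be used instead via
`zscore_reference()`.

Beamforming, artifact handling and the projection of the atlas onto
individual anatomy are upstream of this package: its inputs are per-region
signals (or band powers) plus a labeled atlas volume and a binary tumor
mask on a common voxel grid.

## Pipeline stages and their parameters

### Band power

`band_power()` uses a Welch estimate: 4-s segments, 50 % overlap, Hann
taper, demeaned per segment, one-sided PSD integrated over the band. The
segment length trades frequency resolution (0.25 Hz at 4 s, comfortably
below the 0.5 Hz band edge) against variance; 4-s Hann segments with 50 %
overlap are conventional for eyes-closed resting-state recordings. Any
consistent PSD estimator preserves the analysis because every activity
measure is z-scored afterwards; the estimator only needs to be monotone in
true band power. Unit tests pin the two calibration points that matter: a
unit sinusoid inside the band integrates to amplitude²/2 = 0.5, and white
noise over the full Nyquist range integrates to its variance (Parseval),
both within 5 %.

### Mask dilation and the peritumor set

The tumor mask is dilated with a 3×3×3 box structuring element
(26-neighborhood plus centre), the default dilation kernel of the FSL
toolbox, applied twice (`dilate_mask(mask, 2)`). A region enters the
peritumor set if at least one of its voxels lies in the dilated mask
(`peritumor_regions()`, `min_voxels = 1`); the minimal reading of
"overlapping", with a configurable threshold for stricter definitions. The
peritumor average deliberately *includes* regions inside the tumor core —
the peritumor measure is "tumor and surrounding tissue", not an annulus —
matching how the original analysis illustrated the measure. Both
operations have brute-force oracles in the tests (neighborhood-union
dilation; per-voxel overlap scan).

All volumes are voxel-indexed on a shared grid; no world-coordinate
transforms are performed (registration is out of scope). NIfTI I/O is
available through `read_volume()`/`write_volume()` (RNifti).

### Rank statistics

NLGN3 expression is an ordered three-tier immunohistochemistry score
(low / moderate / high), so activity–expression association uses rank
tests, implemented from their definitions:

* `kruskal_wallis()` — midranks, tie correction
  `1 − Σ(t³−t)/(N³−N)`, chi-square reference with k − 1 df.
* `mann_whitney_u()` — reports `min(U₁, U₂)` (the convention of mainstream
  clinical statistics software, and the scale on which the reference
  results are printed). For pooled samples of ≤ 25 without ties the
  two-sided p is **exact**: the null distribution of U is enumerated by
  the standard counting recurrence, and the one-tail probability
  `P(U ≤ u)` is doubled (capped at 1). This matters at the cohort's group
  sizes: for n = (3, 6), `P(U ≤ 1) = 2/84`, giving p = 4/84 ≈ 0.048,
  which a normal approximation misses. Larger or tied samples use the
  tie-corrected normal approximation, and the `method` field records which
  path was taken.

A pooled-variance two-sample t test (`two_sample_t()`) covers the
patients-versus-controls comparison of global activity; it is exercised on
synthetic data only, since no control measurements ship with the package.

### Cox proportional hazards

`cox_fit()` maximises the Cox partial likelihood directly:

* **Ties**: Breslow (default) or Efron denominators. Breslow is the
  default because it is the default of the statistical software the
  reference analysis used, and the packaged cohort contains tied event
  times (two progressions at 54 weeks). Both methods agree exactly on
  untied data, which the tests verify.
* **Optimisation**: safeguarded Newton–Raphson — analytic gradient and
  Hessian, step-halving on any partial-likelihood decrease, at most 50
  iterations, convergence when the gradient norm falls below 1e-8.
* **Inference**: Wald — `se` from the inverse observed information,
  95 % CI `exp(coef ± 1.96·se)`, two-sided normal p-values; again the
  convention of the reference software.
* **Degenerate inputs**: constant covariates and collinear covariate
  pairs are errors. A monotone partial likelihood (perfect separation)
  cannot be caught by the gradient criterion alone, because the gradient
  vanishes as the coefficient diverges; `cox_fit()` therefore flags
  non-convergence when any |coefficient| × covariate-SD exceeds 15 — a
  log hazard ratio beyond e¹⁵ per SD is divergence, not estimation.
* **Missing covariates** are dropped listwise per model and counted in
  `n_dropped`, mirroring the varying N of the confounder models.

`km_estimate()` is the product-limit estimator; the reported median is the
first time at which survival reaches 0.5 or below, undefined (NA) when the
curve never does. `median_split()` dichotomises at the sample median with
values *at* the median assigned to the low group (the documented tie
rule). The cohort's summary "median PFS" is the median of observed event
times with censored follow-up excluded (`median_event_time()`); this
definition reproduces the reference value of 87 weeks exactly, whereas a
Kaplan–Meier median would not.

### Covariate encodings

`encode_covariates()` reproduces the confounder codings of the reference
analysis; where a direction was ambiguous it was fixed by refitting the
bivariate models and matching the printed hazard ratios. The indicators
are: age ≤ 40, KPS ≤ 80, WHO grade II (grade II is the *indicated* level),
male sex; histology is ordinal (oligodendroglioma 1, oligoastrocytoma 2,
astrocytoma/GBM 3); IDH1 is an indicator of *wildtype*; adjuvant treatment
is ordinal in the order radiotherapy+chemotherapy, radiotherapy, none. The
2016 WHO molecular grouping (1 IDH-mutant codeleted, 2 IDH-mutant
non-codeleted, 3 IDH-wildtype) applies the cohort's retrospective rule —
an IDH1-mutant astrocytoma without 1p/19q assessment is non-codeleted —
and marks records whose annotations are contradictory under that scheme
(IDH-wildtype yet codeleted) as unclassifiable; with that rule the
bivariate molecular model reproduces the reference estimates.

### Validation machinery

* `leave_one_out()` refits the univariate model n times, one patient
  excluded per refit, and reports the range of Wald p-values. Any
  non-convergent refit is an error naming the excluded patient.
* `permutation_null()` shuffles the predictor across patients B times
  (default 1000) with (time, event) pairs kept together — censoring is
  never decoupled from its follow-up time — and compares the observed
  Wald p to the permuted ones with the add-one estimator
  `(1 + #{p_perm ≤ p_obs})/(B + 1)`, which is valid and never exactly
  zero. The shuffle seed is mandatory and recorded in the result. Under an
  exchangeable null the empirical p is uniform on its support, a property
  the acceptance suite checks with a Kolmogorov–Smirnov test.

## The synthetic-cohort generator

`generate_cohort()` produces complete cohorts with the statistical
structure the analysis assumes, so every stage is testable without any
recordings:

* **Atlas**: an ellipsoidal foreground on a 32³ grid partitioned into 78
  contiguous parcels by multi-source breadth-first region growing from
  random seeds — every parcel nonempty, 6-connected, volumes summing to
  the foreground.
* **Tumor masks**: random ellipsoids (semi-axes 2–5 voxels) centred on
  foreground voxels; placements overlapping no region are resampled.
* **Signals**: per region, pink (1/f) noise plus a 10 Hz alpha
  oscillation, both scaled by the region's activity amplitude, so band
  power grows as amplitude². An alpha-peak-plus-1/f spectrum is the
  minimal resting-state-like choice; any spectrum with controllable
  broadband power would serve.
* **Survival**: Weibull proportional hazards with log-hazard
  `log_hr_per_sd × z`; the default effect size is ln 2.10 per SD of
  global activity, the reference cohort's estimate. The default shape 1
  reduces to an exponential baseline; other shapes let tests probe the
  fit under baseline misspecification (proportional hazards holds either
  way). Censoring emulates an administrative cutoff as an independent
  uniform horizon `C ~ U(0, u)`, with `u` calibrated by root-finding on
  the drawn event times so the expected censored fraction equals
  `censor_rate` (default 0.29, the packaged cohort's 7/24).
* **NLGN3 tiers**: `cut(z + noise, thresholds)` with default thresholds at
  the 12/21 and 18/21 quantiles of the latent scale (standard-normal
  quantiles scaled by `sqrt(1 + noise_sd²)`), giving expected tier
  prevalences 12/6/3 out of 21 — the packaged cohort's prevalences. Noise
  SD defaults to 0.5, a moderate misclassification level reflecting that
  semi-quantitative immunohistochemistry scoring is an imperfect readout
  of activity.
* Identical config and seed give a bit-identical cohort; `generate_cohort()`
  seeds the R RNG once and all generators consume that stream.

Survival is driven by the cohort z-score of each patient's *realised*
global power, so the full pipeline is parameter-consistent: regressing the
generated outcome on the measured activity z recovers `log_hr_per_sd`
without attenuation in the fast (analytic power) path, and with only
PSD-estimation noise in the signal path.

What the generator does **not** emulate: sensor-level MEG physics, head
geometry and forward/inverse modelling, spatially correlated power between
neighbouring regions, informative censoring, and the clinical covariate
structure (the synthetic covariates are drawn independently of survival).
Passing tests on synthetic cohorts therefore demonstrate the correctness
of the computational pipeline under its stated model, not the clinical
validity of the biomarker.

## Problem sizes used by the test and acceptance suites

The simulation-based properties run at sizes chosen to keep Monte-Carlo
error well below the tested margins on a single CPU:

* Wald CI coverage: 1000 cohorts of n = 200 at the default effect size;
  the 93–97 % band is ±3 binomial SEs around 0.95.
* Hazard-ratio recovery: 200 cohorts of n = 500 at log-HR ln 2.10 with
  full follow-up (`censor_rate = 0`), requiring HR ∈ [1.9, 2.3] in ≥ 90 %
  of cohorts. Full follow-up is the clean engine-recovery setting: all 500
  events contribute, and the band then sits ≈ 1.9 estimated SEs from the
  truth on each side.
* Exact-U enumeration is compared against brute-force labelings for every
  group-size pair with pooled n ≤ 12 (the largest instance enumerates
  C(12,6) = 924 labelings).
* Permutation-null uniformity: 150 null cohorts of n = 24 with B = 99
  shuffles each.

## Known limitations

* The Cox engine fits fixed covariates only — no time-varying effects,
  stratification, frailty or proportionality diagnostics, which the
  target analysis does not use.
* Exact Mann–Whitney inference switches to the normal approximation in
  the presence of any tie, even in small samples where a
  midrank-permutation exact test would be feasible.
* The peritumor pathway assumes atlas and mask share a voxel grid;
  registration, resampling and anatomical atlas projection are out of
  scope.
* Reference-based z-scoring is implemented and tested on synthetic
  controls only; no healthy-control measurements are distributed with the
  package.
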