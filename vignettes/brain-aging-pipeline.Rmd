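---
title: "Linking biological brain aging to cognitive and motor performance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking biological brain aging to cognitive and motor performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Several MRI-derived markers summarize how "old" a brain looks relative to
its owner's chronological age: morphometry-based **relative brain age**, the
cerebral small vessel disease burden captured by **white matter
hyperintensity (WMH) load**, and the global white-matter microstructure
marker **PSMD** (peak width of skeletonized mean diffusivity). In
population-imaging cohorts these markers co-vary with each other, with
vascular risk factors, and with cognitive and motor performance. This
package implements the full analytic chain for studying that triangle:
marker computation, multivariate imaging–behavior association via partial
least squares correlation (PLS-C), and bootstrap mediation of vascular-risk
effects through the imaging pattern — together with a synthetic cohort
generator so every stage is testable without access to restricted cohort
data.

```{r, eval = FALSE}
library(brainagelink)
bundle <- run_full_analysis(run_config(
  synthetic = synthetic_config(n_subjects = 5000),
  n_perm = 500, n_boot = 500, seed = 1))
print(bundle)
```

## Relative brain age

Brain age estimation predicts chronological age from regional cortical
thickness and subcortical volumes with ordinary least squares, separately
per sex, with out-of-fold predictions from a seeded 5-fold cross-validation
(`fit_predict_age()`). The naive gap `predicted − chronological` is
negatively correlated with age (regression dilution), so a second stage
(`relative_brain_age()`) regresses predicted age on chronological age per
stratum and subtracts the fitted *expected age*:

relative brain age = predicted age − expected age.

Because the expected-age line is fit on the pooled out-of-fold predictions
of the same sample it corrects, the result has exactly zero mean and zero
correlation with age within each stratum — the property the two-stage
construction exists to guarantee, asserted to 1e−8 in the tests. We chose
the pooled (not per-fold) second stage because only the pooled fit gives
this orthogonality exactly; the alternative is available by running the
stage on any subset externally.

Collinear morphometry fails loudly naming the offending columns; a minimal
ridge (`1e−8 ×` mean diagonal) is available behind `ridge = TRUE` for
degenerate synthetic fixtures only.

## WMH load and PSMD

`compute_wmh_load()` forms `load% = 100 · WMH volume / ICV` and returns its
natural log. Zero-WMH subjects are floored at `ε = 1e−3 %` before the log
(configurable, flagged in output); the log base only rescales loadings and
never changes inference. `compute_psmd()` is the p95 − p5 range of the
skeleton MD values under linear-interpolation percentiles (R type 7, the
numpy default) — declared explicitly because the peak width differs across
percentile conventions. It is order-invariant and positively
affine-equivariant, and requires ≥ 20 values because extreme percentiles of
smaller samples are unstable.

Both absolute markers have *gap variants* (`marker_gap()`): the identical
two-stage pipeline run with the single marker as the sole feature, yielding
WMH brain age and microstructural brain age for the sensitivity analysis in
which deviations from age norms replace absolute values.

## Clinical harmonization

Timed scores where larger means worse (Trail Making Test, reaction time,
timed up-and-go) are transformed with `−log(raw)` before z-scoring; the
direction-then-log order is a declared choice — any monotone composition
gives the same ranks, and `−log` keeps the scale interpretable as log-time.
Tests are z-scored within the analysis sample (after exclusions, per
cohort) and averaged into domain scores over available tests per subject.
Grip strength is the left/right mean divided by squared height (kg/m²).
Education enters as a single ordinal covariate. Two editable domain-map
presets ship (a UKB-style and an HCHS-style battery); the assignment of
tests to domains is configuration, not package ground truth.

## PLS correlation

`fit_pls()` centers and unit-scales both blocks (so cross-covariance and
cross-correlation coincide and loadings are comparable across native
scales) and decomposes `R = X'Y/(n−1)` by SVD. Per latent variable (LV):
covariance explained `s² / Σ s²`, subject scores `XU` and `YV`, and a
deterministic sign convention — the relative-brain-age loading is oriented
positive, so "more brain aging ↔ negative clinical loadings" reads
directly.

Significance: `permutation_test()` shuffles rows of the imaging block only
and compares same-index singular values, with the add-one estimator
`p = (1 + #{s_perm ≥ s_emp}) / (1 + n_perm)` and FDR adjustment across LVs.
A Procrustes-rotated variant sits behind `rotate = TRUE`; the unrotated
same-index comparison is the default as the simplest defensible scheme.
Stability: `bootstrap_stability()` resamples subjects with replacement,
aligns each replicate to the original by per-component sign flip (full
Procrustes behind a flag — unaligned replicates would corrupt the SEs), and
reports bootstrap ratios (loading / bootstrap SE, |BSR| > 1.96 as the
stability flag) for imaging variables and percentile 95% CIs for clinical
variables. Replicates with a constant resampled column are redrawn and
counted.

The covariates (age, sex, education) travel inside the clinical block as
*check columns*: the imaging block is residualized against them
(`residualize()`), so their loadings should be null — their bootstrap CIs
covering 0 is asserted in the tests as the deconfounding check.
`crossval_score_correlation()` reports the mean out-of-fold LV1 Spearman
correlation over a seeded 10-fold partition, each fold's projection using
training-set centering, scaling and loadings.

## Mediation

`mediate()` fits three OLS models on z-scored inputs — `m ~ x + cov`
(path a), `y ~ x + m + cov` (b and c′), `y ~ x + cov` (c) — so all paths
are standardized and the decomposition `c = c′ + ab` holds exactly on the
sample (asserted to 1e−8 on every run). The indirect effect `ab` gets a
percentile bootstrap 95% CI and the two-sided p-value
`2·min(P(ab* ≤ 0), P(ab* ≥ 0))` clipped to `[2/n_boot, 1]`; percentile
(not BCa) is the default because nothing more specific is stated by the
procedure this mirrors. The proportion mediated `ab/c` is reported only
when `|c| > 10·SE(c)`, otherwise flagged unstable. `run_mediation_suite()`
runs all nine vascular risk factors, FDR-corrects *within each effect
family* (all a's together, all b's, …) — chosen over joint correction
because the families answer different questions — and classifies: `full`
when a, b and ab are significant and c′ is not; `partial` when c′ remains
significant but attenuated (|c′| < |c|); `none` otherwise.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` states one world and keeps it fixed:

* **Marginals** match the emulated population table: age ~ N(63.7, 7.6)
  truncated to [45, 80]; systolic BP 138.6 ± 18.6 mmHg; the other risk
  factors at their table moments, log-normal for the skewed pack years and
  triglycerides; education ordinal 1–6 with mean 4.5.
* **One latent dimension.** The brain-aging deviation δ (years,
  `delta_sd = 3`) collects standardized risk contributions
  `a_k` — 0.8/0.8/0.5/0.8/1.0/1.0 years per SD for systolic BP, diastolic
  BP, triglycerides, glucose, waist-hip ratio and pack years, 0 for the
  three cholesterol fractions as a planted negative control — and drives
  all three imaging markers through biological age `age + δ`: 84
  morphometric features with region-wise linear decline, log WMH load with
  slope 0.04/yr, PSMD with slope 3e−6 mm²/s/yr around 2.29e−4. MD voxel
  samples are drawn so their p95 − p5 equals the PSMD target in expectation.
* **Behavior.** A single latent η = −b·z(δ) + Σ c′_k·z(risk) −
  s_age·z(age) + noise (b = 0.35, s_age = 0.3) drives every test with
  loading 0.7, mapped to native scales — timed tests through the log-normal
  inverse of the invert-log transform, grip in kg with sex-specific base
  and height.

Path magnitudes are our declaration of a "clearly recoverable but not
trivial" regime at n ≈ 5,000; they were set once from the design (before
running the acceptance suite) and are not tuned to test outcomes. The
generator deliberately omits: risk-factor cross-correlations (an optional
hook exists, none are reported to emulate), scanner/site effects, test
reliabilities, non-linear aging, missingness, and any spatial structure in
the MD values. A green recovery test therefore establishes that the
pipeline recovers the stated linear single-latent world — not that real
cohort effect sizes would be recovered, and the real-data headline numbers
are intentionally *not* numeric targets anywhere in the package.

## Numerical choices

* Percentiles: type 7 everywhere (declared; PSMD depends on it).
* Exclusion masks use single-pass full-sample mean/SD — note that at
  sample size n no point can exceed `(n−1)/√n` SDs, so small toy samples
  cannot trip a 3-SD rule by construction.
* Permutations pre-standardize both blocks once: row shuffles leave column
  statistics unchanged, so this is the naive scheme, only faster.
* Add-one permutation p-values avoid zero; bootstrap ab p-values clip at
  `2/n_boot`.
* Seeds: one master seed derives independent per-stage seeds
  (`stage_seed()`), so changing `n_perm` never changes the simulated data
  or fold assignments; all seeded functions restore the caller's RNG
  state.
* Degenerate inputs: zero-variance vectors error in `mediate()` and
  `fit_pls()` (naming the column); zero-SD exclusion vectors keep all
  subjects with a warning; zero WMH volumes are floored and flagged.

## Known limitations

Cross-sectional, associative mediation only — no causal identification,
no multiple or serial mediators. OLS is the only brain-age learner, as in
the procedure this implements. No sparse or regularized PLS and at most
`min(p, q)` components. The CLI orchestrates files but does not attempt
figure parity; outputs are the tabular equivalents of the usual LV-summary,
loading and path plots.
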