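---
title: "Methods: cerebellar functional gradients and outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebellar functional gradients and outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbgrad)
```

## Overview

`cbgrad` studies how the functional organization of the neonatal cerebellum
relates to social–emotional outcome scores measured in toddlerhood. The
pipeline has five statistical stages — volume censoring, voxel-wise
functional connectivity, group-PCA functional gradients, covariate-adjusted
association under FDR control, and leakage-safe cross-validated prediction
with permutation inference — plus a synthetic-cohort generator that plants
a known ground truth so each stage can be tested end to end. This vignette
documents the model, the tunable parameters, the numerical choices, and the
limits of what the synthetic validation can show.

## The data model behind the generator

One subject's preprocessed BOLD matrix (voxels × time) is simulated as

$$X_s = M\,\mathrm{diag}(w_s)\,Z_s + \sigma E_s,$$

where

* $M$ (voxels × L) holds **fixed spatial source maps** shared by all
  subjects. Each of the $L$ latent sources concentrates on two of the eight
  lobar ROIs (chosen round-robin) over a diffuse background
  (`map_background_sd = 0.15`), and columns are scaled to unit RMS so the
  BOLD noise SD is interpretable as a signal-to-noise ratio.
* $w_s$ are **per-subject source strengths**: geometric base amplitudes
  `source_decay^(l-1)` (default ratio 0.55) times log-normal multipliers
  (`strength_sdlog = 0.35`). The decaying amplitudes reproduce the steeply
  decreasing eigenspectrum seen in empirical connectivity cohorts, where the
  first component dominates (tens of percent) and later components each
  carry a few percent. This decay also makes individual sources
  identifiable: with equal amplitudes, principal components of the group
  matrix mix the sources and no single coefficient vector tracks a single
  planted strength.
* $Z_s$ (L × time) are unit-variance Gaussian temporal sources regenerated
  per subject; $E_s$ is white noise with `noise_sd = 1`.

Functional connectivity therefore varies across subjects through
$\mathrm{corr}$-normalizing $M\,\mathrm{diag}(w_s^2)\,M^\top + \sigma^2 I$,
and the subject-to-subject variation in FC is driven entirely by $w_s$ —
the quantity the gradient coefficients should recover.

**Outcomes.** Four domain t-scores (Externalizing, Internalizing,
Dysregulation, Competence; mean 50, SD 10). The coupled domain (default
Externalizing) is generated as
$50 + 10\,(r\,z_s + \sqrt{1-r^2}\,e_s)$ with $z_s$ the standardized planted
strength column and $r =$ `coupling_r` (default 0.42), so the population
correlation between the planted strength and the coupled score equals $r$.
The three "problem" domains share pairwise-0.3 correlated noise while
Competence is independent, mirroring the inter-domain structure reported
for this instrument. The distributional form of the outcome noise is an
assumption — the instrument's true item-level noise process is not
specified anywhere — and is deliberately the simplest choice (Gaussian).

**Covariates and volumes.** PMA at scan is truncated normal
(42.00 ± 1.91 weeks on 38.57–47.43), birthweight 3303 ± 432 g on
2280–4184 g, sex Bernoulli(0.5). Each ROI volume is
`intercept + slope × PMA + noise`, with lobar intercepts summing to
~26 cm³ at 40 weeks and slopes of 4.5%/week (the neonatal cerebellum
roughly doubles between 37 and 44 weeks); the noise SD is solved in closed
form, $\sigma = \beta\,\mathrm{sd}(\mathrm{PMA})\sqrt{1/r^2-1}$, so the
population volume–PMA correlation equals `volume_target_r` (default 0.74,
the midpoint of the reported 0.65–0.81 range, which implies ~55% variance
explained).

**Motion.** Six parameters per volume: baseline jitter
(`motion_jitter_mm = 0.005` per translation parameter, matched in arc
length for rotations) plus step displacements of `motion_spike_mm = 0.5`
injected at Bernoulli(`motion_spike_rate = 0.05`) volumes, each producing
one high-FD frame.

What the generator does **not** emulate: hemodynamic response shape,
spatial autocorrelation of noise, scanner artifacts, distance-dependent
motion artifacts, or age-/sex-norming of raw questionnaire items. Passing
tests on synthetic cohorts therefore demonstrate the *statistical
machinery* — recovery, calibration, leakage safety — not robustness to
these real-data phenomena.

## Quality control

Framewise displacement is the Power-style sum of absolute backward
differences of the six parameters, rotations converted to arc length on a
sphere of radius `sphere_radius_mm = 50` (configurable; a standard
convention for small heads). The first volume's FD is defined as 0. A
volume is censored iff FD > 0.2 mm (strictly) or more than 10% of voxels
are intensity outliers; a voxel is an outlier at volume $t$ when it
deviates from its temporal median by more than `k_mad = 3.5` robust SDs
(MAD × 1.4826). Zero-MAD voxels carry no outlier information and are
excluded from the denominator. A scan passes QC iff it retains at least
120 volumes, so 119 is excluded and 120 retained. Censored volumes'
neighbors are *not* additionally censored, and censored series are
concatenated (not segment-wise) before correlation; both are documented
choices where the protocol is silent.

## Gradients: PCA of the group connectome

The group matrix (connections × subjects) is centered per connection
across subjects, with **no variance scaling** — centering-only matches the
rank statement that S subjects admit at most S−1 nonzero-variance
components. The eigendecomposition is computed on the S×S Gram matrix of
the centered data, which is mathematically identical to decomposing the
C×C connection covariance but feasible at C = 52,650. Numerical choices:

* **Sign convention:** each component is flipped so its largest-|loading|
  entry is positive. PCA signs are otherwise arbitrary; determinism is
  needed for tests and reports.
* **K = 10** components by default (configurable); the choice is heuristic,
  motivated by the top components jointly explaining about half the
  variance in the data this design emulates.
* **Degenerate input** (all subjects identical) raises an error rather
  than returning zero-variance components.
* **Localization:** the top `floor(0.05 C)` connections by |loading| —
  positive and negative pooled by magnitude, with the sign reported — are
  mapped to their two incident voxels; ties at the threshold break by lower
  linear (row-major upper-triangle) index. Any fixed linearization order is
  valid, but the same order must be used for analysis and localization, so
  it is fixed and documented in `upper_index_map()`.

Held-out subjects are projected with the *training* connection means, never
their own; projecting the training set reproduces the training coefficients
exactly. This is the property that makes within-fold PCA leakage-safe.

## Association and multiple testing

Each (feature, domain) cell fits
`score ~ feature + sex + PMA + birthweight` by OLS on complete cases
(two-sided t on n−5 df). FDR correction is Benjamini–Hochberg applied
**within each domain across features** (m = 10 for ten gradient features,
m = 8 for eight volumes). This scope is inferred rather than stated in the
emulated protocol: multiplying the published uncorrected p-values 0.032 and
0.015 by 10 reproduces the published adjusted values 0.32 and 0.15 exactly,
while pooling across domains does not. The scope is configurable
(`fdr_scope`).

## Prediction and permutation inference

Per repeat, subjects are partitioned into `n_folds = 10` folds by a seeded
shuffle followed by contiguous near-equal blocks. For functional features
the gradient basis is refit on training columns only; combined features
concatenate volumes and gradient coefficients, each column standardized on
training statistics. Non-imaging covariates are deliberately excluded from
the predictor set. Performance per repeat is the Pearson correlation of
**pooled** out-of-fold predictions with actual scores, Fisher-z
transformed; pooling is used because per-fold correlations on ~6 subjects
are unstable.

The permutation test shuffles scores and reruns a full CV cycle per
shuffle. Two implementation decisions matter:

* **Fixed fold partition, features computed once.** The fold partition and
  the within-fold feature construction are drawn once from the seed and
  shared by the observed and null runs. Since the basis construction never
  sees scores, this is *exactly* equivalent to recomputing it per
  permutation, and it is what makes 5,000 permutations tractable.
* **Add-one p-value:** $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})
  /(1 + B)$, one-sided (higher performance more extreme), avoiding p = 0.

By default the observed statistic is the repeat-averaged mean z
(`observed_stat = "mean_z"`); setting `"single_z"` compares a single cycle
computed on the same partition as the nulls, which makes observed and null
statistics exactly exchangeable under the null hypothesis.

A property worth knowing: pooled out-of-fold correlations carry a small
**negative bias** under the null (each fold's predictions embed the
training mean, which anti-correlates with the held-out scores), so the
permutation null mean z sits around −0.1 to −0.2 rather than 0. The
observed statistic carries the same bias, so the permutation p-value
remains calibrated — the package's tests verify a type-I error rate close
to the nominal 5% — but the null mean itself should not be read as a
performance baseline.

## Problem sizes used in validation

The test-suite and acceptance computations run the full study geometry
(325 voxels, 52,650 connections, 72 subjects) for the deterministic
identities, and a reduced geometry — 120 voxels (7,140 connections),
150 volumes, 60–72 subjects — for the stochastic suites: gradient recovery
over 50 seeds, permutation calibration over 200 replicates of 199
shuffles, and power over 20 seeds of 500 shuffles. These sizes were chosen
so the Monte-Carlo error of each check is small relative to its acceptance
band while the whole suite remains comfortably runnable on a laptop core;
the reduced geometry preserves the ratios that matter (connections ≫
subjects, sources ≪ voxels).

## Known limitations

* Gradient estimation is plain PCA; diffusion-map embeddings and Procrustes
  alignment across cohorts are out of scope.
* FC is within-cerebellum only; cerebro-cerebellar connectivity is not
  modeled.
* The prediction stage is deliberately unregularized OLS; with many more
  components than the default 10 it will overfit small folds.
* Real-data ingestion expects already-preprocessed series; no slice-timing,
  registration, filtering or nuisance regression is performed here.
* The synthetic generator's noise and coupling forms are assumptions (see
  above); conclusions about real data require real data.
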