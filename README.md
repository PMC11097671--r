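# cbgrad

Functional gradients of the neonatal cerebellum and their association with
toddler social–emotional outcomes.

## The scientific problem

The cerebellum matures rapidly around birth, and early cerebellar injury is
associated with later social–emotional difficulties. In typically developing
newborns, the question is whether the *functional organization* of the
cerebellum — not just its volume — carries information about social–emotional
development measured a year and a half later. `cbgrad` implements the full
analysis pipeline for this question as a tested, reusable R package:

1. **QC / volume censoring.** From six rigid-body motion parameters, the
   framewise displacement FD(t) = Σ|Δp(t)| (rotations converted to arc length
   on a 50 mm sphere) flags volumes with FD > 0.2 mm; volumes with > 10% of
   voxels deviating from the voxel median by more than 3.5 robust SD (MAD)
   are flagged as intensity outliers; scans retaining fewer than 120 clean
   volumes (4 min at TR = 2 s) are excluded.
2. **Connectome.** Per subject, voxel-to-voxel Pearson functional
   connectivity over retained volumes; the upper triangle of the V×V matrix
   (C = V(V−1)/2 connections; 52,650 for V = 325) is vectorized row-major and
   the cohort is assembled into a C×S group matrix.
3. **Functional gradients (FGR).** PCA of the group matrix after
   per-connection centering: orthonormal loadings in connection space (C×K,
   K = 10 by default) and per-subject coefficients (K×S). With S subjects at
   most S−1 components have nonzero variance. The strongest ±5% loadings of
   a component are localized to ROI clusters.
4. **Association.** Per (feature, domain): ordinary least squares
   `score ~ feature + sex + PMA + birthweight`, two-sided t test on n−5
   degrees of freedom, Benjamini–Hochberg FDR within each domain.
5. **Prediction.** Repeated 10-fold cross-validated linear regression of
   each domain score on functional and/or anatomical features, with the
   gradient basis re-estimated inside each training fold (leakage-safe);
   performance is the Fisher z = atanh(r) of pooled out-of-fold predictions
   against actual scores, tested against a score-shuffling permutation null.

Because the underlying cohort data are not deposited, the package ships a
synthetic-cohort generator with *planted ground truth*: BOLD signal
`X = M diag(w_s) Z_s + σE` with fixed spatial source maps M, per-subject
source strengths w_s, one strength column linearly coupled to one outcome
domain (target r = 0.42), t-score outcomes (mean 50, SD 10), PMA-dependent
ROI volume growth, and motion traces with spikes. Every stage of the
pipeline is validated against this known truth.

## Worked example

```r
library(cbgrad)

cfg <- cohort_config(n_subjects = 60, n_voxels = 60, n_volumes = 120,
                     coupling_r = 0.6, seed = 42)
coh <- generate_cohort(cfg)

# QC + connectome: censor volumes, drop failing scans, build the group matrix
res <- cohort_group_matrix(coh, min_volumes = 90)
dim(res$group)
#> [1] 1770   60

# Functional gradients
model <- fit_group_pca(res$group, k = 10)
model
#> <gradient_model> 10 components over 1770 connections x 60 subjects
#>   variance explained (top 10): 61.5%

# Which gradient tracks the planted source?
cors <- cor(t(model$coefficients), coh$truth$subject_strengths[, 3])
which.max(abs(cors)); round(max(abs(cors)), 3)
#> [1] 3
#> [1] 0.893

# Covariate-adjusted association with the coupled domain
dat <- cbind(coh$subjects, as.data.frame(t(model$coefficients)))
tab <- association_table(dat, sprintf("FGR%d", 1:10))
as.data.frame(tab[tab$feature == "FGR3" & tab$domain == "Externalizing", ])
#>   feature        domain estimate t_stat    p_unc  n    p_fdr
#> 3    FGR3 Externalizing     4.68   4.39 5.18e-05 60 0.000518

# Leakage-safe prediction with permutation inference
pcfg <- prediction_config(n_folds = 10, n_repeats = 20, n_permutations = 199,
                          feature_set = "functional", seed = 42)
fit <- cv_predict(coh$subjects, "Externalizing", pcfg, group = res$group)
perm <- permutation_test(fit$mean_z, coh$subjects, "Externalizing", pcfg,
                         group = res$group)
fit; perm
#> <prediction_result> Externalizing ~ functional features
#>   20 repeats of 10-fold CV: mean z = 0.457 (SE 0.010)
#> <permutation_result> Externalizing ~ functional features
#>   observed z = 0.457 vs 199 shuffles: p = 0.005
```

The gradient model recovers the planted connectivity source (|r| = 0.89
between a top-10 coefficient vector and the planted strengths), the
association stage flags the coupled (gradient, domain) pair after FDR
correction (p_fdr ≈ 5×10⁻⁴), and held-out prediction of the coupled domain
beats all 199 score shuffles (p = 0.005).

A one-shot end-to-end run (simulate → qc → connectome → gradients →
associate → predict → report) is available as `run_pipeline()`, or from the
shell via `Rscript inst/cli/cbgrad.R --subjects 60 --voxels 60 --seed 42`.

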