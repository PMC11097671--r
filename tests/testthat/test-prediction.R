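pred_cohort <- function(seed = 1, n = 30, coupling_r = 0.42) {
  cfg <- cohort_config(n_subjects = n, n_voxels = 40, n_volumes = 60,
                       n_latent = 4, coupled_source_index = 2,
                       coupling_r = coupling_r, seed = seed)
  coh <- generate_cohort(cfg)
  res <- cohort_group_matrix(coh, min_volumes = 30)
  list(cohort = coh, group = res$group)
}

test_that("Fisher z is atanh with domain checks", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.42), 0.4477, tolerance = 5e-5)  # closed form, 4 dp
  expect_equal(fisher_z(-0.3), -fisher_z(0.3), tolerance = 1e-12)
  expect_error(fisher_z(1), "within")
  expect_error(fisher_z(-1.2), "within")
})

test_that("folds partition the cohort with near-equal sizes every repeat", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(15:61, 1)
    k <- sample(2:10, 1)
    folds <- cbgrad:::make_folds(n, k)
    expect_length(folds, k)
    expect_setequal(unlist(folds), seq_len(n))
    sizes <- lengths(folds)
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(cbgrad:::make_folds(5, 10), "n_folds")
})

test_that("a noiseless function of a recoverable gradient is predicted almost perfectly", {
  pc <- pred_cohort(seed = 72)
  full <- fit_group_pca(pc$group, k = 4)
  subj <- pc$cohort$subjects
  subj$target <- as.numeric(full$coefficients[1, ]) +
    rnorm(ncol(pc$group), sd = 1e-3 * sd(full$coefficients[1, ]))
  cfg <- prediction_config(n_folds = 5, n_repeats = 3, feature_set = "functional",
                           k_components = 4, seed = 1)
  fit <- cv_predict(subj, "target", cfg, group = pc$group)
  expect_true(all(fit$r > 0.95))
})

test_that("pure-noise outcomes give near-zero mean pooled correlation", {
  set.seed(73)
  rs <- replicate(200, {
    n <- 40
    subj <- data.frame(y = rnorm(n))
    vols <- matrix(rnorm(n * 8), n, 8)
    cfg <- prediction_config(n_folds = 5, n_repeats = 1,
                             feature_set = "anatomical",
                             seed = sample.int(1e6, 1))
    cv_predict(subj, "y", cfg, volumes = vols)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("each subject is predicted exactly once per repeat and z = atanh(r)", {
  pc <- pred_cohort(seed = 74)
  subj <- pc$cohort$subjects
  cfg <- prediction_config(n_folds = 6, n_repeats = 4,
                           feature_set = "functional", k_components = 3,
                           seed = 4)
  fit <- cv_predict(subj, "Externalizing", cfg, group = pc$group)
  expect_false(anyNA(fit$predictions))
  expect_identical(dim(fit$predictions), c(30L, 4L))
  expect_equal(fit$z, atanh(fit$r), tolerance = 1e-12)
  expect_equal(fit$mean_z, mean(fit$z), tolerance = 1e-12)
})

test_that("prediction is deterministic under a fixed seed", {
  pc <- pred_cohort(seed = 75)
  subj <- pc$cohort$subjects
  cfg <- prediction_config(n_folds = 5, n_repeats = 2,
                           feature_set = "functional", k_components = 3,
                           seed = 7)
  f1 <- cv_predict(subj, "Externalizing", cfg, group = pc$group)
  f2 <- cv_predict(subj, "Externalizing", cfg, group = pc$group)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$z, f2$z)

  p1 <- permutation_test(f1$mean_z, subj, "Externalizing",
                         prediction_config(n_folds = 5, n_repeats = 1,
                                           n_permutations = 30,
                                           feature_set = "functional",
                                           k_components = 3, seed = 7),
                         group = pc$group)
  p2 <- permutation_test(f1$mean_z, subj, "Externalizing",
                         prediction_config(n_folds = 5, n_repeats = 1,
                                           n_permutations = 30,
                                           feature_set = "functional",
                                           k_components = 3, seed = 7),
                         group = pc$group)
  expect_identical(p1$null, p2$null)
  expect_identical(p1$p_perm, p2$p_perm)
})

test_that("altering held-out scores leaves every training-derived quantity bit-identical", {
  pc <- pred_cohort(seed = 76)
  n <- ncol(pc$group)
  set.seed(5)
  folds <- cbgrad:::make_folds(n, 5)
  test_idx <- folds[[1]]
  train_idx <- setdiff(seq_len(n), test_idx)

  ft1 <- cbgrad:::fold_features("functional", pc$group, NULL,
                                train_idx, test_idx, 3)
  # corrupt the held-out columns entirely: the training fit must not notice
  g2 <- pc$group
  g2[, test_idx] <- 1e6
  ft2 <- cbgrad:::fold_features("functional", g2, NULL,
                                train_idx, test_idx, 3)
  expect_identical(ft1$model$loadings, ft2$model$loadings)
  expect_identical(ft1$model$connection_means, ft2$model$connection_means)
  expect_identical(ft1$model$coefficients, ft2$model$coefficients)
  expect_identical(ft1$train, ft2$train)

  # corrupt held-out scores: per-fold regression weights unchanged
  y <- pc$cohort$subjects$Externalizing
  y2 <- y
  y2[test_idx] <- y2[test_idx] + 100
  b1 <- lm.fit(cbind(1, ft1$train), y[train_idx])$coefficients
  b2 <- lm.fit(cbind(1, ft1$train), y2[train_idx])$coefficients
  expect_identical(b1, b2)
})

test_that("permutation p-values follow the add-one rule at the extremes", {
  set.seed(77)
  n <- 24
  subj <- data.frame(y = rnorm(n))
  vols <- matrix(rnorm(n * 4), n, 4)
  cfg <- prediction_config(n_folds = 4, n_repeats = 1, n_permutations = 999,
                           feature_set = "anatomical", seed = 3)
  hi <- permutation_test(10, subj, "y", cfg, volumes = vols)   # beats all nulls
  expect_equal(hi$p_perm, 1 / 1000)
  lo <- permutation_test(-Inf, subj, "y", cfg, volumes = vols) # worse than all
  expect_equal(lo$p_perm, 1)
  expect_warning(
    permutation_test(0, subj, "y",
                     prediction_config(n_folds = 4, n_repeats = 1,
                                       n_permutations = 10,
                                       feature_set = "anatomical", seed = 3),
                     volumes = vols),
    "20 permutations")
})

test_that("the permutation null is centered near zero", {
  pc <- pred_cohort(seed = 78, n = 60)
  subj <- pc$cohort$subjects
  cfg <- prediction_config(n_folds = 10, n_repeats = 1, n_permutations = 150,
                           feature_set = "functional", k_components = 3,
                           seed = 9)
  perm <- permutation_test(NULL, subj, "Externalizing", cfg, group = pc$group)
  # Pooled out-of-fold correlations carry a small negative bias under the
  # null (fold-wise training means anti-correlate with held-out scores);
  # the observed statistic shares it, so calibration is unaffected.
  expect_lt(mean(perm$null), 0.05)
  expect_gt(mean(perm$null), -0.3)
})

test_that("feature-set comparison produces the 4 x 3 grid and ranks planted signals", {
  pc <- pred_cohort(seed = 79, n = 40, coupling_r = 0.8)
  subj <- pc$cohort$subjects
  vols <- pc$cohort$volumes
  cfg <- prediction_config(n_folds = 5, n_repeats = 2, n_permutations = 25,
                           feature_set = "functional", k_components = 3,
                           seed = 2)
  grid <- compare_feature_sets(subj, pc$group, vols,
                               domains = c("Externalizing", "Competence"),
                               config = cfg)
  expect_identical(nrow(grid), 6L)   # 2 domains x 3 feature sets
  expect_setequal(unique(grid$feature_set),
                  c("functional", "anatomical", "combined"))

  # outcome coupled to a gradient source: functional features beat anatomical
  fz <- grid$mean_z[grid$domain == "Externalizing" &
                    grid$feature_set == "functional"]
  az <- grid$mean_z[grid$domain == "Externalizing" &
                    grid$feature_set == "anatomical"]
  expect_gt(fz, az)

  # outcome coupled to one ROI volume's residual: anatomical features win
  set.seed(80)
  subj2 <- subj
  subj2$VolScore <- as.numeric(scale(vols$Central_L)) * 10 + 50 +
    rnorm(nrow(subj), sd = 2)
  g2 <- compare_feature_sets(subj2, pc$group, vols, domains = "VolScore",
                             config = cfg)
  expect_gt(g2$mean_z[g2$feature_set == "anatomical"],
            g2$mean_z[g2$feature_set == "functional"])
})
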