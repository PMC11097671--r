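test_that("cohort generation is bit-reproducible given a seed", {
  cfg <- tiny_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$bold[[3]]$data, b$bold[[3]]$data)
  expect_identical(unclass(a$motion[[5]]), unclass(b$motion[[5]]))
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$truth$subject_strengths, b$truth$subject_strengths)

  c <- generate_cohort(tiny_config(seed = 12))
  expect_false(identical(a$subjects, c$subjects))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_volumes = 3), "n_volumes")
  expect_error(cohort_config(coupling_r = 1), "coupling_r")
  expect_error(cohort_config(coupling_r = -0.1), "coupling_r")
  expect_error(cohort_config(n_voxels = 2, n_latent = 5), "n_latent")
  expect_error(cohort_config(coupled_source_index = 9), "coupled_source_index")
  expect_error(cohort_config(roi_labels = c("a", "b")), "roi_labels")
})

test_that("outcome t-scores have mean near 50 and SD near 10", {
  # moments pooled over a batch of seeds (single-cohort means at n = 72 have
  # SE ~ 1.2, so per-seed bounds would mostly measure sampling noise)
  moments <- sapply(1:6, function(seed) {
    coh <- generate_cohort(score_config(seed = seed))
    sc <- as.matrix(coh$subjects[, c("Externalizing", "Internalizing",
                                     "Dysregulation", "Competence")])
    c(colMeans(sc), apply(sc, 2, sd))
  })
  expect_true(all(abs(rowMeans(moments)[1:4] - 50) < 1.5))
  expect_true(all(abs(rowMeans(moments)[5:8] - 10) < 1.5))
})

test_that("covariates respect the stated demographic bounds", {
  coh <- generate_cohort(score_config(seed = 2))
  expect_true(all(coh$subjects$pma_weeks >= 38.57 &
                  coh$subjects$pma_weeks <= 47.43))
  expect_true(all(coh$subjects$birthweight_g >= 2280 &
                  coh$subjects$birthweight_g <= 4184))
  expect_true(all(coh$subjects$sex %in% c(0, 1)))
})

test_that("null coupling leaves planted strengths uncorrelated with scores", {
  rs <- vapply(1:50, function(seed) {
    coh <- generate_cohort(score_config(seed = seed, coupling_r = 0))
    cor(coh$truth$subject_strengths[, 2], coh$subjects$Externalizing)
  }, numeric(1))
  # centered at zero with spread no wider than the null sampling error
  # (SE ~ 1/sqrt(n-3) ~ 0.12 at n = 72)
  expect_lt(abs(mean(rs)), 0.05)
  expect_lt(sd(rs), 0.2)
  expect_gt(mean(abs(rs) < 0.15), 0.6)
})

test_that("planted coupling matches its target on average (Monte-Carlo oracle)", {
  # Independent oracle: the mixing formula itself, simulated directly.
  set.seed(99)
  oracle <- replicate(200, {
    z <- as.numeric(scale(rlnorm(72, 0, 0.35)))
    y <- 0.42 * z + sqrt(1 - 0.42^2) * rnorm(72)
    cor(z, y)
  })
  expect_lt(abs(mean(oracle) - 0.42), 0.05)

  gen <- vapply(1:200, function(seed) {
    coh <- generate_cohort(score_config(seed = seed))
    cor(coh$truth$subject_strengths[, 2], coh$subjects$Externalizing)
  }, numeric(1))
  expect_lt(abs(mean(gen) - 0.42), 0.05)
  # generator and oracle agree on the sampling distribution's spread
  expect_lt(abs(sd(gen) - sd(oracle)), 0.05)
})

test_that("uncoupled problem domains are positively inter-correlated, Competence near zero", {
  rs <- sapply(1:30, function(seed) {
    coh <- generate_cohort(score_config(seed = seed, coupling_r = 0.42))
    r <- cor(as.matrix(coh$subjects[, c("Externalizing", "Internalizing",
                                        "Dysregulation", "Competence")]))
    c(ei = r[1, 2], ed = r[1, 3], id = r[2, 3],
      comp = max(abs(r[4, 1:3])))
  })
  expect_true(all(rowMeans(rs)[c("ei", "ed", "id")] > 0.15))
  expect_lt(mean(rs["comp", ]), 0.35)
})

test_that("BOLD follows the planted low-rank model (closed-form covariance oracle)", {
  cfg <- cohort_config(n_subjects = 4, n_voxels = 20, n_volumes = 4000,
                       n_latent = 2, coupled_source_index = 1,
                       noise_sd = 0.8, seed = 5)
  coh <- generate_cohort(cfg)
  M <- coh$truth$spatial_maps
  w <- coh$truth$subject_strengths[1, ]
  # closed form: cov = M diag(w^2) M' + sigma^2 I, correlation-normalized
  Sig <- M %*% diag(w^2) %*% t(M) + 0.8^2 * diag(20)
  Rpop <- cov2cor(Sig)
  Remp <- fc_matrix(coh$bold[[1]])
  expect_lt(max(abs(Remp - Rpop)), 0.08)

  # doubling all strengths leaves the noiseless FC unchanged (scale invariance)
  cfg0 <- cohort_config(n_subjects = 4, n_voxels = 20, n_volumes = 200,
                        n_latent = 2, coupled_source_index = 1,
                        noise_sd = 0, seed = 5)
  coh0 <- generate_cohort(cfg0)
  truth2 <- coh0$truth
  truth2$subject_strengths <- 2 * truth2$subject_strengths
  b1 <- generate_bold(coh0$truth, 2, cfg0)
  b2 <- generate_bold(truth2, 2, cfg0)
  expect_equal(fc_matrix(b1), fc_matrix(b2), tolerance = 1e-12)
})

test_that("rank-1 noiseless signal gives |FC| = 1 everywhere", {
  cfg <- cohort_config(n_subjects = 3, n_voxels = 10, n_volumes = 50,
                       n_latent = 1, coupled_source_index = 1,
                       noise_sd = 0, seed = 8)
  coh <- generate_cohort(cfg)
  fc <- fc_matrix(coh$bold[[1]])
  expect_equal(abs(fc), matrix(1, 10, 10), tolerance = 1e-10)
})

test_that("subject FC matrices differ across subjects", {
  coh <- generate_cohort(tiny_config(seed = 4))
  f1 <- fc_matrix(coh$bold[[1]])
  f2 <- fc_matrix(coh$bold[[2]])
  expect_gt(norm(f1 - f2, "F"), 0)
})

test_that("generate_bold rejects unidentifiable source counts", {
  cfg <- tiny_config()
  coh <- generate_cohort(cfg)
  bad <- cfg
  bad$n_volumes <- cfg$n_latent
  expect_error(generate_bold(coh$truth, 1, bad), "unidentifiable")
  expect_error(generate_bold(coh$truth, 99, cfg), "subject_index")
})

test_that("motion traces: clean traces give zero FD, spikes censor binomially", {
  cfg <- tiny_config()
  clean <- generate_motion_trace(cfg, 1, spike_rate = 0, jitter_mm = 0)
  expect_equal(framewise_displacement(clean), rep(0, cfg$n_volumes))

  cfg200 <- cohort_config(n_subjects = 3, n_voxels = 10, n_volumes = 200,
                          seed = 1)
  counts <- vapply(1:20, function(s) {
    tr <- generate_motion_trace(cfg200, s, spike_rate = 0.5, spike_mm = 0.5)
    fd <- framewise_displacement(tr)
    sum(censor_volumes(fd, 0)$keep == FALSE)
  }, numeric(1))
  # binomial oracle: 199 eligible volumes at rate 0.5
  expected <- 199 * 0.5
  sdev <- sqrt(199 * 0.25)
  expect_true(all(abs(counts - expected) < 3 * sdev))

  expect_error(generate_motion_trace(cfg, 1, spike_mm = -1), "spike_mm")
  expect_error(generate_motion_trace(cfg, 1, spike_rate = 2), "spike_rate")
})

test_that("a scan engineered to retain 119 volumes is excluded downstream", {
  cfg <- cohort_config(n_subjects = 2, n_voxels = 10, n_volumes = 200, seed = 3)
  tr <- generate_motion_trace(cfg, 1, spike_rate = 0, jitter_mm = 0)
  m <- unclass(tr)
  m[2:200, 1] <- 0.3 * pmin(2:200, 82)   # ramp: FD = 0.3 on volumes 2..82
  fd <- framewise_displacement(m)
  mask <- censor_volumes(fd, 0)
  expect_identical(mask$retained, 119L)
  expect_false(scan_passes_qc(mask))
})

test_that("ROI volumes track PMA at the calibrated correlation", {
  # closed-form identity: population r^2 at target_r = 0.7388 is 54.58%
  expect_equal(100 * 0.7388^2, 54.58, tolerance = 0.01)

  cfg <- score_config(seed = 1)
  big <- data.frame(subject_id = sprintf("s%d", 1:4000),
                    pma_weeks = with_seed_pma(4000, cfg))
  vols <- generate_volumes(big, NULL, target_r = 0.7388, config = cfg)
  r2 <- sapply(setdiff(names(vols), "subject_id"),
               function(cl) cor(vols[[cl]], big$pma_weeks)^2)
  expect_lt(abs(mean(100 * r2) - 54.58), 3)

  # per-ROI sample r stays in the reported band for most seeds at n = 81
  frac_in_band <- vapply(1:15, function(seed) {
    cfg81 <- cohort_config(n_subjects = 81, n_voxels = 12, n_volumes = 20,
                           n_latent = 2, coupled_source_index = 1,
                           seed = seed)
    coh <- generate_cohort(cfg81)
    g <- volume_growth(coh$volumes, coh$subjects$pma_weeks)
    mean(g$r >= 0.60 & g$r <= 0.85)
  }, numeric(1))
  expect_gt(mean(frac_in_band), 0.85)
})

test_that("volume generation validates inputs", {
  cfg <- tiny_config()
  coh <- generate_cohort(cfg)
  expect_error(generate_volumes(coh$subjects, coh$truth, target_r = 0,
                                config = cfg), "target_r")
  expect_error(generate_volumes(coh$subjects[1:2, ], coh$truth,
                                target_r = 0.7, config = cfg), "3 subjects")
  expect_true(all(as.matrix(coh$volumes[, -1]) > 0))
})
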