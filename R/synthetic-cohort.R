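## Synthetic cohort generator: BOLD matrices with low-rank latent structure,
## motion traces, covariates, ROI volumes and outcome t-scores, all tied to a
## known ground truth so every downstream stage can be validated.

# Assign voxels to the 8 ROIs in contiguous, near-equal blocks.
cb_voxel_rois <- function(n_voxels, roi_labels) {
  idx <- sort(rep_len(seq_along(roi_labels), n_voxels))
  factor(roi_labels[idx], levels = roi_labels)
}

# Spatial source maps: each latent source concentrates on two ROIs (chosen
# round-robin) over a diffuse background; columns scaled to unit RMS so
# `noise_sd` is interpretable as a signal-to-noise ratio.
cb_spatial_maps <- function(config) {
  V <- config$n_voxels
  L <- config$n_latent
  rois <- cb_voxel_rois(V, config$roi_labels)
  maps <- matrix(stats::rnorm(V * L, sd = config$map_background_sd), V, L)
  for (l in seq_len(L)) {
    focus <- config$roi_labels[(2 * (l - 1) + 0:1) %% 8 + 1]
    on_focus <- rois %in% focus
    maps[on_focus, l] <- stats::rnorm(sum(on_focus))
  }
  rms <- sqrt(colMeans(maps^2))
  if (any(rms == 0)) cb_stop("degenerate spatial map (zero column)")
  sweep(maps, 2, rms, "/")
}

# Per-subject source strengths: geometric base amplitudes (steeply decaying,
# as in empirical FC eigenspectra) times log-normal multipliers around 1.
cb_subject_strengths <- function(config) {
  n <- config$n_subjects
  L <- config$n_latent
  amp <- config$source_decay^(0:(L - 1))
  mult <- matrix(stats::rlnorm(n * L, meanlog = 0,
                               sdlog = config$strength_sdlog), n, L)
  sweep(mult, 2, amp, "*")
}

# Outcome t-scores. The coupled domain is 50 + 10 * (r * z_strength +
# sqrt(1 - r^2) * e), where z_strength is the sample-standardized planted
# strength column and e is the domain's unit-variance noise, so the population
# correlation with the planted strengths equals coupling_r. The three problem
# domains share pairwise-0.3 correlated noise; Competence noise is independent.
cb_domain_scores <- function(strengths, config) {
  n <- config$n_subjects
  domains <- itsea_domains()
  sigma <- diag(4)
  prob <- which(domains != "Competence")
  sigma[prob, prob] <- 0.3
  diag(sigma) <- 1
  noise <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = sigma)
  colnames(noise) <- domains

  s <- strengths[, config$coupled_source_index]
  z <- as.numeric(scale(s))
  r <- config$coupling_r
  latent <- noise
  latent[, config$coupled_domain] <-
    r * z + sqrt(1 - r^2) * noise[, config$coupled_domain]
  scores <- 50 + 10 * latent
  list(scores = scores, true_linear = latent[, config$coupled_domain])
}

#' Generate a complete synthetic study cohort
#'
#' Draws a full synthetic dataset emulating a neonatal resting-state study:
#' per-subject BOLD matrices whose functional connectivity varies along
#' low-rank latent sources, six-parameter motion traces with spikes,
#' demographic covariates, PMA-dependent ROI volumes, and four outcome
#' t-score domains, one of which is linearly coupled to a planted latent
#' source. The returned ground truth makes every downstream stage testable.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cb_cohort` with elements:
#'   \describe{
#'     \item{subjects}{data.frame of subject id, sex (0/1), PMA (weeks),
#'       birthweight (g), and the four domain t-scores.}
#'     \item{bold}{list of `bold_series`, one per subject.}
#'     \item{motion}{list of `motion_trace`, one per subject.}
#'     \item{volumes}{data.frame of subject id plus 8 ROI volumes (cm^3).}
#'     \item{truth}{ground truth: `spatial_maps` (voxel x latent),
#'       `subject_strengths` (subject x latent), `true_scores_linear`,
#'       `volume_slopes`, and the voxel ROI labels.}
#'   }
#' @examples
#' cfg <- cohort_config(n_subjects = 8, n_voxels = 24, n_volumes = 30, seed = 7)
#' coh <- generate_cohort(cfg)
#' dim(coh$bold[[1]]$data)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    cb_stop("'config' must be a cohort_config object")
  }
  n <- config$n_subjects

  covariates_scores <- with_local_seed(cb_derive_seed(config$seed, 1L), {
    maps <- cb_spatial_maps(config)
    strengths <- cb_subject_strengths(config)
    sex <- stats::rbinom(n, 1L, 0.5)
    pma <- rtruncnorm(n, config$pma_mean, config$pma_sd,
                      config$pma_range[1], config$pma_range[2])
    bw <- rtruncnorm(n, config$birthweight_mean, config$birthweight_sd,
                     config$birthweight_range[1], config$birthweight_range[2])
    sc <- cb_domain_scores(strengths, config)
    list(maps = maps, strengths = strengths, sex = sex, pma = pma, bw = bw,
         scores = sc$scores, true_linear = sc$true_linear)
  })

  ids <- sprintf("sub-%03d", seq_len(n))
  subjects <- data.frame(
    subject_id = ids,
    sex = covariates_scores$sex,
    pma_weeks = covariates_scores$pma,
    birthweight_g = covariates_scores$bw,
    stringsAsFactors = FALSE
  )
  subjects <- cbind(subjects, as.data.frame(covariates_scores$scores))

  truth <- list(
    spatial_maps = covariates_scores$maps,
    subject_strengths = covariates_scores$strengths,
    true_scores_linear = covariates_scores$true_linear,
    voxel_rois = cb_voxel_rois(config$n_voxels, config$roi_labels),
    volume_slopes = NULL
  )

  bold <- lapply(seq_len(n), function(s) generate_bold(truth, s, config))
  motion <- lapply(seq_len(n), function(s) generate_motion_trace(config, s))

  vols <- generate_volumes(subjects, truth, config$volume_target_r, config)
  truth$volume_slopes <- attr(vols, "slopes")

  structure(list(subjects = subjects, bold = bold, motion = motion,
                 volumes = vols, truth = truth, config = config),
            class = "cb_cohort")
}

#' Generate one subject's BOLD matrix
#'
#' Builds the voxels-by-time signal `X = M diag(w_s) Z_s + noise_sd * E`,
#' where `M` holds the fixed spatial source maps, `w_s` the subject's source
#' strengths, and `Z_s` per-subject unit-variance temporal sources regenerated
#' from the seed. Emulates data after standard preprocessing (detrending,
#' filtering, nuisance regression).
#'
#' @param truth Ground-truth list from [generate_cohort()] (needs
#'   `spatial_maps`, `subject_strengths`, `voxel_rois`).
#' @param subject_index 1-based subject index.
#' @param config The [cohort_config()] used to generate `truth`.
#' @return A `bold_series`: list with `data` (voxels x time matrix),
#'   `voxel_ids`, and `roi` (voxel ROI labels).
#' @export
generate_bold <- function(truth, subject_index, config) {
  n <- nrow(truth$subject_strengths)
  subject_index <- cb_check_count(subject_index, "subject_index")
  if (subject_index > n) {
    cb_stop("'subject_index' (%d) exceeds the cohort size (%d)",
            subject_index, n)
  }
  if (config$n_volumes <= config$n_latent) {
    cb_stop("'n_volumes' (%d) must exceed 'n_latent' (%d): sources unidentifiable",
            config$n_volumes, config$n_latent)
  }
  V <- config$n_voxels
  Tt <- config$n_volumes
  L <- config$n_latent
  w <- truth$subject_strengths[subject_index, ]
  X <- with_local_seed(cb_derive_seed(config$seed, 2L, subject_index), {
    Z <- matrix(stats::rnorm(L * Tt), L, Tt)
    noise <- if (config$noise_sd > 0) {
      config$noise_sd * matrix(stats::rnorm(V * Tt), V, Tt)
    } else 0
    truth$spatial_maps %*% (w * Z) + noise
  })
  structure(list(
    data = X,
    voxel_ids = seq_len(V),
    roi = truth$voxel_rois
  ), class = "bold_series")
}

#' Generate a six-parameter motion trace
#'
#' Produces per-volume rigid-body motion parameters (3 translations in mm,
#' 3 rotations in radians) consisting of small baseline jitter plus step
#' displacements ("spikes") of about `spike_mm` injected at Bernoulli
#' `spike_rate` volumes, yielding one high-displacement frame per spike.
#'
#' @param config A [cohort_config()].
#' @param subject_index 1-based subject index (seeds the trace).
#' @param spike_rate Per-volume spike probability.
#' @param spike_mm Spike displacement in mm (must be non-negative).
#' @param jitter_mm Baseline jitter SD per parameter in mm.
#' @return A `motion_trace`: volumes x 6 matrix with columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
generate_motion_trace <- function(config, subject_index,
                                  spike_rate = config$motion_spike_rate,
                                  spike_mm = config$motion_spike_mm,
                                  jitter_mm = config$motion_jitter_mm) {
  subject_index <- cb_check_count(subject_index, "subject_index")
  spike_rate <- cb_check_number(spike_rate, "spike_rate", lower = 0, upper = 1)
  if (!is.numeric(spike_mm) || length(spike_mm) != 1L || spike_mm < 0) {
    cb_stop("'spike_mm' must be a single non-negative number")
  }
  Tt <- config$n_volumes
  trace <- with_local_seed(cb_derive_seed(config$seed, 3L, subject_index), {
    m <- matrix(0, Tt, 6)
    if (jitter_mm > 0) {
      m[, 1:3] <- stats::rnorm(Tt * 3, sd = jitter_mm)
      # rotational jitter in radians, matched in arc length on a 50 mm sphere
      m[, 4:6] <- stats::rnorm(Tt * 3, sd = jitter_mm / 50)
    }
    if (spike_rate > 0 && spike_mm > 0 && Tt >= 2) {
      spikes <- which(stats::runif(Tt - 1) < spike_rate) + 1L
      for (k in spikes) {
        step <- sample(c(-1, 1), 1L) * spike_mm
        m[k:Tt, 1] <- m[k:Tt, 1] + step
      }
    }
    m
  })
  colnames(trace) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
  structure(trace, class = c("motion_trace", class(trace)))
}

#' Generate PMA-dependent ROI volumes
#'
#' Each ROI volume follows `intercept + slope * PMA + noise`, with the noise
#' SD solved in closed form so the population volume-PMA correlation equals
#' `target_r` (using the population SD of the truncated-normal PMA
#' distribution): `sd_noise = slope * sd_pma * sqrt(1 / r^2 - 1)`.
#'
#' @param records Subject data.frame with columns `subject_id`, `pma_weeks`.
#' @param truth Ground-truth list (used only for reproducible seeding info);
#'   may be `NULL`.
#' @param target_r Target volume-PMA correlation, in (0, 1).
#' @param config A [cohort_config()].
#' @return data.frame of `subject_id` plus one column per ROI (cm^3), with the
#'   per-ROI growth slopes attached as attribute `"slopes"`.
#' @export
generate_volumes <- function(records, truth, target_r = config$volume_target_r,
                             config) {
  target_r <- cb_check_number(target_r, "target_r", lower = 0, upper = 1,
                              lower_open = TRUE, upper_open = TRUE)
  pma <- records$pma_weeks
  if (is.null(pma) || length(pma) < 3L) {
    cb_stop("'records' must contain at least 3 subjects with 'pma_weeks'")
  }
  sd_pma <- truncnorm_sd(config$pma_mean, config$pma_sd,
                         config$pma_range[1], config$pma_range[2])
  if (!is.finite(sd_pma) || sd_pma <= 0) {
    cb_stop("degenerate PMA variance: cannot calibrate volume noise")
  }
  # Lobar volumes (cm^3) at 40 weeks PMA, summing to ~ 26 cm^3, growing
  # ~4.5% per week (neonatal cerebellum roughly doubles from 37 to 44 weeks).
  base <- c(Anterior_L = 2.6, Anterior_R = 2.6, Central_L = 8.3,
            Central_R = 8.3, Posterior_L = 0.55, Posterior_R = 0.55,
            Vermis_Central = 2.6, Vermis_Posterior = 0.45)
  names(base) <- config$roi_labels
  slopes <- 0.045 * base
  sd_noise <- slopes * sd_pma * sqrt(1 / target_r^2 - 1)

  n <- length(pma)
  vols <- with_local_seed(cb_derive_seed(config$seed, 4L), {
    sapply(seq_along(base), function(i) {
      base[i] + slopes[i] * (pma - 40) +
        if (sd_noise[i] > 0) stats::rnorm(n, sd = sd_noise[i]) else 0
    })
  })
  vols <- matrix(vols, nrow = n)
  vols[vols <= 0] <- min(base) * 0.05   # volumes are strictly positive
  colnames(vols) <- config$roi_labels
  out <- data.frame(subject_id = records$subject_id, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vols))
  attr(out, "slopes") <- slopes
  out
}

#' @export
print.cb_cohort <- function(x, ...) {
  cat("<cb_cohort>\n")
  cat(sprintf("  %d subjects, %d voxels, %d volumes\n",
              nrow(x$subjects), x$config$n_voxels, x$config$n_volumes))
  cat(sprintf("  coupled source %d -> %s (target r = %.2f)\n",
              x$config$coupled_source_index, x$config$coupled_domain,
              x$config$coupling_r))
  invisible(x)
}
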