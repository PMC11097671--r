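#' Default cerebellar ROI labels
#'
#' The eight lobar regions used throughout the pipeline: left/right anterior
#' lobe, left/right central lobe, left/right posterior lobe, and the central
#' and posterior vermis.
#'
#' @return Character vector of length 8.
#' @export
cb_roi_labels <- function() {
  c("Anterior_L", "Anterior_R", "Central_L", "Central_R",
    "Posterior_L", "Posterior_R", "Vermis_Central", "Vermis_Posterior")
}

itsea_domains <- function() {
  c("Externalizing", "Internalizing", "Dysregulation", "Competence")
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort size,
#' voxel grid, scan length, the latent connectivity sources that drive
#' between-subject variation in functional connectivity, and the strength of
#' the planted coupling between one latent source and one outcome domain.
#'
#' Defaults mirror the emulated study: 72 subjects with usable fMRI, 325
#' cerebellar voxels in 8 ROIs, 200 volumes at TR = 2 s, outcome t-scores
#' (mean 50, SD 10), postmenstrual age 42.00 +/- 1.91 weeks truncated to
#' 38.57-47.43, birthweight 3303 +/- 432 g, and a planted source-outcome
#' correlation of 0.42.
#'
#' @param n_subjects Number of subjects.
#' @param n_voxels Number of cerebellar voxels.
#' @param n_volumes BOLD volumes per scan (after initial-volume removal).
#' @param tr_seconds Repetition time in seconds.
#' @param n_latent Number of latent connectivity sources.
#' @param coupled_source_index 1-based index of the latent source coupled to
#'   the outcome.
#' @param coupled_domain Outcome domain receiving the planted coupling.
#' @param coupling_r Target population correlation between the planted
#'   per-subject source strength and the coupled domain score; in `[0, 1)`.
#' @param noise_sd Standard deviation of additive voxel noise in the BOLD
#'   signal, on the scale of a unit-RMS source map.
#' @param strength_sdlog Log-scale SD of the log-normal per-subject source
#'   strength multipliers.
#' @param source_decay Geometric decay ratio of successive latent source base
#'   amplitudes; values below 1 give the steeply decreasing connectivity
#'   eigenspectrum seen in real cohorts.
#' @param map_background_sd SD of the diffuse (non-focal) spatial map weights.
#' @param pma_mean,pma_sd,pma_range Postmenstrual age at scan (weeks):
#'   truncated-normal moments and bounds.
#' @param birthweight_mean,birthweight_sd,birthweight_range Birthweight (g).
#' @param volume_target_r Target population correlation between each ROI
#'   volume and PMA.
#' @param motion_spike_rate Per-volume probability of a motion spike.
#' @param motion_spike_mm Displacement of a motion spike in mm.
#' @param motion_jitter_mm SD of baseline motion jitter per parameter in mm.
#' @param roi_labels Character vector of 8 ROI names.
#' @param seed Integer RNG seed; generation is bit-reproducible given the seed.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 72,
                          n_voxels = 325,
                          n_volumes = 200,
                          tr_seconds = 2.0,
                          n_latent = 6,
                          coupled_source_index = 3,
                          coupled_domain = "Externalizing",
                          coupling_r = 0.42,
                          noise_sd = 1.0,
                          strength_sdlog = 0.35,
                          source_decay = 0.55,
                          map_background_sd = 0.15,
                          pma_mean = 42.00,
                          pma_sd = 1.91,
                          pma_range = c(38.57, 47.43),
                          birthweight_mean = 3303,
                          birthweight_sd = 432,
                          birthweight_range = c(2280, 4184),
                          volume_target_r = 0.74,
                          motion_spike_rate = 0.05,
                          motion_spike_mm = 0.5,
                          motion_jitter_mm = 0.005,
                          roi_labels = cb_roi_labels(),
                          seed = 1L) {
  n_subjects <- cb_check_count(n_subjects, "n_subjects", min = 2L)
  n_voxels <- cb_check_count(n_voxels, "n_voxels", min = 2L)
  n_volumes <- cb_check_count(n_volumes, "n_volumes", min = 5L)
  tr_seconds <- cb_check_number(tr_seconds, "tr_seconds", lower = 0,
                                lower_open = TRUE)
  n_latent <- cb_check_count(n_latent, "n_latent", min = 1L)
  if (n_voxels < n_latent) {
    cb_stop("'n_voxels' (%d) must be >= 'n_latent' (%d)", n_voxels, n_latent)
  }
  coupled_source_index <- cb_check_count(coupled_source_index,
                                         "coupled_source_index")
  if (coupled_source_index > n_latent) {
    cb_stop("'coupled_source_index' (%d) exceeds 'n_latent' (%d)",
            coupled_source_index, n_latent)
  }
  if (!is.character(coupled_domain) || length(coupled_domain) != 1L ||
      !coupled_domain %in% itsea_domains()) {
    cb_stop("'coupled_domain' must be one of: %s",
            paste(itsea_domains(), collapse = ", "))
  }
  coupling_r <- cb_check_number(coupling_r, "coupling_r", lower = 0, upper = 1,
                                upper_open = TRUE)
  noise_sd <- cb_check_number(noise_sd, "noise_sd", lower = 0)
  strength_sdlog <- cb_check_number(strength_sdlog, "strength_sdlog", lower = 0)
  source_decay <- cb_check_number(source_decay, "source_decay", lower = 0,
                                  upper = 1, lower_open = TRUE)
  map_background_sd <- cb_check_number(map_background_sd, "map_background_sd",
                                       lower = 0)
  pma_sd <- cb_check_number(pma_sd, "pma_sd", lower = 0, lower_open = TRUE)
  volume_target_r <- cb_check_number(volume_target_r, "volume_target_r",
                                     lower = 0, upper = 1, lower_open = TRUE,
                                     upper_open = TRUE)
  motion_spike_rate <- cb_check_number(motion_spike_rate, "motion_spike_rate",
                                       lower = 0, upper = 1)
  motion_spike_mm <- cb_check_number(motion_spike_mm, "motion_spike_mm",
                                     lower = 0)
  motion_jitter_mm <- cb_check_number(motion_jitter_mm, "motion_jitter_mm",
                                      lower = 0)
  if (!is.character(roi_labels) || length(roi_labels) != 8L ||
      anyDuplicated(roi_labels)) {
    cb_stop("'roi_labels' must be 8 distinct ROI names")
  }
  if (length(pma_range) != 2L || pma_range[1] >= pma_range[2]) {
    cb_stop("'pma_range' must be an increasing pair of bounds")
  }
  if (length(birthweight_range) != 2L ||
      birthweight_range[1] >= birthweight_range[2]) {
    cb_stop("'birthweight_range' must be an increasing pair of bounds")
  }
  seed <- cb_check_count(seed, "seed", min = 0L)

  structure(list(
    n_subjects = n_subjects, n_voxels = n_voxels, n_volumes = n_volumes,
    tr_seconds = tr_seconds, n_latent = n_latent,
    coupled_source_index = coupled_source_index,
    coupled_domain = coupled_domain, coupling_r = coupling_r,
    noise_sd = noise_sd, strength_sdlog = strength_sdlog,
    source_decay = source_decay, map_background_sd = map_background_sd,
    pma_mean = pma_mean, pma_sd = pma_sd, pma_range = as.numeric(pma_range),
    birthweight_mean = birthweight_mean, birthweight_sd = birthweight_sd,
    birthweight_range = as.numeric(birthweight_range),
    volume_target_r = volume_target_r,
    motion_spike_rate = motion_spike_rate, motion_spike_mm = motion_spike_mm,
    motion_jitter_mm = motion_jitter_mm,
    roi_labels = roi_labels, seed = seed
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects, %d voxels in 8 ROIs, %d volumes @ TR %.1f s\n",
              x$n_subjects, x$n_voxels, x$n_volumes, x$tr_seconds))
  cat(sprintf("  %d latent sources; source %d coupled to %s at r = %.2f\n",
              x$n_latent, x$coupled_source_index, x$coupled_domain,
              x$coupling_r))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
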