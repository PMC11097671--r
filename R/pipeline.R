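## End-to-end orchestration: simulate -> qc -> connectome -> gradients ->
## associate -> predict -> report, with seeded reproducibility, CSV/TSV/JSON
## outputs and a checksum manifest.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] for the simulate stage.
#' @param prediction A [prediction_config()] for the predict stage.
#' @param out_dir Output directory (created if absent).
#' @param stages Character vector of stages to run, in fixed order from
#'   `simulate` to `report`.
#' @param fd_thresh,frac_thresh,min_volumes,k_mad QC thresholds.
#' @param k Number of gradient components.
#' @param cluster_quantile Top-loading selection fraction for localization.
#' @param write_bold Whether to write per-subject BOLD TSV and motion files
#'   (large; off by default).
#' @param seed Master seed, propagated to every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            prediction = prediction_config(),
                            out_dir = tempfile("cbgrad_run_"),
                            stages = c("simulate", "qc", "connectome",
                                       "gradients", "associate", "predict",
                                       "report"),
                            fd_thresh = 0.2, frac_thresh = 0.10,
                            min_volumes = 120, k_mad = 3.5,
                            k = 10, cluster_quantile = 0.05,
                            write_bold = FALSE,
                            seed = 1L) {
  all_stages <- c("simulate", "qc", "connectome", "gradients", "associate",
                  "predict", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) cb_stop("unknown stage(s): %s", paste(bad, collapse = ", "))
  seed <- cb_check_count(seed, "seed", min = 0L)
  cohort$seed <- seed
  prediction$seed <- seed
  structure(list(cohort = cohort, prediction = prediction,
                 out_dir = out_dir,
                 stages = all_stages[all_stages %in% stages],
                 fd_thresh = fd_thresh, frac_thresh = frac_thresh,
                 min_volumes = min_volumes, k_mad = k_mad,
                 k = k, cluster_quantile = cluster_quantile,
                 write_bold = write_bold, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort: generation,
#' motion/intensity QC, per-subject connectomes and the group matrix,
#' gradient estimation and localization, covariate-adjusted association
#' tables with BH-FDR, cross-validated prediction with a permutation test,
#' and a text report. Every stage draws its randomness from the master seed,
#' so re-running with an identical configuration reproduces identical
#' outputs and checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of stage artifacts plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    cb_stop("'config' must be a pipeline_config object")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list(config = config)
  t0 <- Sys.time()
  timing <- list()
  for (stage in config$stages) {
    ts <- Sys.time()
    art <- tryCatch(
      switch(stage,
        simulate = stage_simulate(art, config),
        qc = stage_qc(art, config),
        connectome = stage_connectome(art, config),
        gradients = stage_gradients(art, config),
        associate = stage_associate(art, config),
        predict = stage_predict(art, config),
        report = stage_report(art, config)
      ),
      error = function(e) {
        cb_stop("stage '%s' failed: %s", stage, conditionMessage(e))
      })
    timing[[stage]] <- as.numeric(difftime(Sys.time(), ts, units = "secs"))
  }
  art$manifest <- write_manifest(config, timing, t0)
  invisible(art)
}

stage_simulate <- function(art, config) {
  cohort <- generate_cohort(config$cohort)
  utils::write.csv(cohort$subjects,
                   file.path(config$out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$volumes,
                   file.path(config$out_dir, "volumes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    subject_strengths = cohort$truth$subject_strengths,
    true_scores_linear = cohort$truth$true_scores_linear,
    volume_slopes = as.list(cohort$truth$volume_slopes),
    voxel_rois = as.character(cohort$truth$voxel_rois)
  ), file.path(config$out_dir, "truth.json"), digits = NA)
  if (config$write_bold) {
    for (s in seq_len(nrow(cohort$subjects))) {
      id <- cohort$subjects$subject_id[s]
      utils::write.table(cohort$bold[[s]]$data,
                         file.path(config$out_dir, sprintf("bold_%s.tsv", id)),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      utils::write.table(unclass(cohort$motion[[s]]),
                         file.path(config$out_dir, sprintf("motion_%s.par", id)),
                         sep = " ", row.names = FALSE, col.names = FALSE)
    }
  }
  art$cohort <- cohort
  art
}

stage_qc <- function(art, config) {
  if (is.null(art$cohort)) cb_stop("qc: no cohort (run 'simulate' first)")
  cohort <- art$cohort
  n <- nrow(cohort$subjects)
  masks <- vector("list", n)
  qc <- data.frame(subject_id = cohort$subjects$subject_id,
                   retained = NA_integer_, passes = NA)
  for (s in seq_len(n)) {
    fd <- framewise_displacement(cohort$motion[[s]])
    of <- outlier_fraction(cohort$bold[[s]], k_mad = config$k_mad)
    masks[[s]] <- censor_volumes(fd, of, config$fd_thresh, config$frac_thresh)
    qc$retained[s] <- masks[[s]]$retained
    qc$passes[s] <- scan_passes_qc(masks[[s]], config$min_volumes)
  }
  jsonlite::write_json(list(
    n_scans = n, n_passed = sum(qc$passes),
    n_excluded = sum(!qc$passes), min_volumes = config$min_volumes,
    subjects = qc
  ), file.path(config$out_dir, "qc_report.json"), auto_unbox = TRUE,
     digits = NA)
  art$masks <- masks
  art$qc <- qc
  art
}

stage_connectome <- function(art, config) {
  if (is.null(art$qc)) cb_stop("connectome: no QC results (run 'qc' first)")
  cohort <- art$cohort
  keep <- which(art$qc$passes)
  if (!length(keep)) cb_stop("connectome: no scan passed QC")
  vectors <- lapply(keep, function(s) {
    vectorize_upper(fc_matrix(cohort$bold[[s]], art$masks[[s]]))
  })
  art$group <- assemble_group_matrix(vectors,
                                     cohort$subjects$subject_id[keep])
  art$analysis_subjects <- cohort$subjects[keep, , drop = FALSE]
  jsonlite::write_json(list(
    n_connections = nrow(art$group), n_subjects = ncol(art$group),
    n_voxels = attr(art$group, "n_voxels"),
    subject_ids = colnames(art$group)
  ), file.path(config$out_dir, "group_matrix.json"), auto_unbox = TRUE)
  art
}

stage_gradients <- function(art, config) {
  if (is.null(art$group)) cb_stop("gradients: no group matrix")
  art$model <- fit_group_pca(art$group, k = config$k)
  coefs <- t(art$model$coefficients)
  utils::write.table(
    data.frame(subject_id = rownames(coefs), coefs, check.names = FALSE),
    file.path(config$out_dir, "gradient_coefficients.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    k = art$model$k,
    variance_fraction = art$model$variance_fraction[seq_len(art$model$k)],
    cumulative_variance = variance_explained(art$model)
  ), file.path(config$out_dir, "gradient_variance.json"), digits = NA,
     auto_unbox = TRUE)
  art
}

stage_associate <- function(art, config) {
  if (is.null(art$model)) cb_stop("associate: no gradient model")
  subj <- art$analysis_subjects
  coefs <- t(art$model$coefficients)
  dat <- cbind(subj, as.data.frame(coefs))
  gradient_features <- colnames(coefs)
  art$assoc_gradients <- association_table(dat, gradient_features)

  vol <- art$cohort$volumes
  vol_dat <- merge(art$cohort$subjects, vol, by = "subject_id")
  art$assoc_volumes <- association_table(vol_dat,
                                         setdiff(names(vol), "subject_id"))
  art$growth <- volume_growth(vol, art$cohort$subjects$pma_weeks)
  art$domain_cor <- domain_intercorrelation(
    art$cohort$subjects[, itsea_domains()])
  utils::write.table(art$assoc_gradients,
                     file.path(config$out_dir, "associations_gradients.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(art$assoc_volumes,
                     file.path(config$out_dir, "associations_volumes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(art$growth,
                     file.path(config$out_dir, "volume_growth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  art
}

stage_predict <- function(art, config) {
  if (is.null(art$group)) cb_stop("predict: no group matrix")
  subj <- art$analysis_subjects
  vol <- art$cohort$volumes
  vol <- vol[match(subj$subject_id, vol$subject_id), , drop = FALSE]
  domain <- config$cohort$coupled_domain
  fit <- cv_predict(subj, domain, config$prediction, art$group, vol)
  perm <- permutation_test(fit$mean_z, subj, domain, config$prediction,
                           art$group, vol)
  art$prediction <- fit
  art$permutation <- perm
  jsonlite::write_json(list(
    domain = domain, feature_set = fit$feature_set,
    mean_z = fit$mean_z, se_z = fit$se_z, p_perm = perm$p_perm,
    null_mean = mean(perm$null), null_sd = stats::sd(perm$null)
  ), file.path(config$out_dir, "prediction.json"), auto_unbox = TRUE,
     digits = NA)
  utils::write.table(
    data.frame(subject_id = subj$subject_id,
               actual = subj[[domain]],
               predicted_mean = rowMeans(fit$predictions)),
    file.path(config$out_dir, "predictions.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  art
}

stage_report <- function(art, config) {
  lines <- render_report(art)
  writeLines(lines, file.path(config$out_dir, "report.txt"))
  art$report <- lines
  art
}

#' Render a human-readable run summary
#'
#' Summarizes whatever artifacts are present (QC exclusions, gradient
#' variance, feature-by-domain association grids, prediction performance);
#' missing stages are listed as absent rather than failing.
#'
#' @param art Artifact list from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(art) {
  lines <- c("cbgrad run report", strrep("=", 17), "")
  if (!is.null(art$qc)) {
    lines <- c(lines, sprintf("QC: %d/%d scans passed (min %d retained volumes)",
                              sum(art$qc$passes), nrow(art$qc),
                              art$config$min_volumes), "")
  } else lines <- c(lines, "QC: absent", "")
  if (!is.null(art$model)) {
    lines <- c(lines,
               sprintf("Gradients: top %d components explain %.1f%% of variance",
                       art$model$k, 100 * variance_explained(art$model)), "")
  } else lines <- c(lines, "Gradients: absent", "")
  for (nm in c("assoc_gradients", "assoc_volumes")) {
    if (!is.null(art[[nm]])) {
      tab <- art[[nm]]
      lines <- c(lines, sprintf("%s associations (t, p_unc, p_fdr):",
                                if (nm == "assoc_gradients") "Gradient"
                                else "Volume"))
      lines <- c(lines, utils::capture.output(print(
        format_assoc_grid(tab), row.names = FALSE)), "")
    } else {
      lines <- c(lines, sprintf("%s: absent",
                                if (nm == "assoc_gradients")
                                  "Gradient associations"
                                else "Volume associations"), "")
    }
  }
  if (!is.null(art$prediction)) {
    lines <- c(lines, sprintf(
      "Prediction (%s, %s features): mean z = %.3f (SE %.3f), permutation p = %.4g",
      art$prediction$domain, art$prediction$feature_set,
      art$prediction$mean_z, art$prediction$se_z, art$permutation$p_perm))
  } else lines <- c(lines, "Prediction: absent (placeholder)")
  lines
}

format_assoc_grid <- function(tab) {
  wide <- stats::reshape(
    data.frame(feature = tab$feature, domain = tab$domain,
               cell = sprintf("%.2f (%.3f/%.3f)", tab$t_stat, tab$p_unc,
                              tab$p_fdr)),
    idvar = "feature", timevar = "domain", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  wide
}

write_manifest <- function(config, timing, t0) {
  files <- sort(list.files(config$out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  sums <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(sums) <- files
  manifest <- list(
    package = "cbgrad",
    version = as.character(utils::packageVersion("cbgrad")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stages = config$stages,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    stage_seconds = timing,
    checksums = sums
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Default 28-to-8 lobule grouping table
#'
#' Maps the 28 fine cerebellar atlas regions (10 lobules per hemisphere plus
#' 8 vermal segments) onto the 8 lobar ROIs: lobules I-IV and V to the
#' anterior lobes, VI through IX (including Crus I/II) to the central lobes,
#' X to the posterior lobes, vermal VI-IX to the central vermis and vermal X
#' to the posterior vermis. The table is plain data and can be edited before
#' passing it to [reduce_atlas_labels()].
#'
#' @return data.frame with columns `fine`, `group`.
#' @export
default_atlas_grouping <- function() {
  lob <- c("I_IV", "V", "VI", "CrusI", "CrusII", "VIIb", "VIIIa", "VIIIb",
           "IX", "X")
  grp <- c("Anterior", "Anterior", rep("Central", 7), "Posterior")
  fine <- c(paste0("Left_", lob), paste0("Right_", lob),
            paste0("Vermis_", lob[3:10]))
  group <- c(paste0(grp, "_L"), paste0(grp, "_R"),
             ifelse(lob[3:10] == "X", "Vermis_Posterior", "Vermis_Central"))
  data.frame(fine = fine, group = group, stringsAsFactors = FALSE)
}

#' Reduce fine atlas labels to the 8 lobar ROIs
#'
#' Maps every voxel's fine atlas label to its lobar group; voxel counts are
#' conserved and an unmapped label is an error naming the label.
#'
#' @param fine_labels Character vector of per-voxel fine labels.
#' @param grouping data.frame with columns `fine`, `group` (default
#'   [default_atlas_grouping()]).
#' @return Character vector of per-voxel group labels.
#' @export
reduce_atlas_labels <- function(fine_labels, grouping = default_atlas_grouping()) {
  fine_labels <- as.character(fine_labels)
  if (!all(c("fine", "group") %in% names(grouping))) {
    cb_stop("'grouping' needs columns 'fine' and 'group'")
  }
  idx <- match(fine_labels, grouping$fine)
  if (anyNA(idx)) {
    cb_stop("unmapped atlas label(s): %s",
            paste(unique(fine_labels[is.na(idx)]), collapse = ", "))
  }
  grouping$group[idx]
}
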