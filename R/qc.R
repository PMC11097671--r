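## Volume censoring and scan-level quality control: framewise displacement
## from six rigid-body parameters, intensity-outlier fractions, the combined
## censoring rule (FD > 0.2 mm or > 10% outlier voxels), and the minimum
## retained-volume criterion (scans with < 120 motion-free volumes excluded).

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute volume-to-volume
#' differences of the six parameters, with the three rotations (radians)
#' converted to arc length on a sphere of radius `sphere_radius_mm`. The first
#' volume's displacement is defined as 0.
#'
#' @param trace A `motion_trace` or a volumes x 6 numeric matrix
#'   (translations in mm, rotations in radians).
#' @param sphere_radius_mm Radius used to convert rotations to mm.
#' @return Numeric vector of per-volume displacement (mm).
#' @export
framewise_displacement <- function(trace, sphere_radius_mm = 50) {
  m <- unclass(trace)
  if (!is.matrix(m) || ncol(m) != 6L) {
    cb_stop("'trace' must be a volumes x 6 matrix of motion parameters")
  }
  if (nrow(m) < 2L) cb_stop("'trace' must contain at least 2 volumes")
  if (!all(is.finite(m))) cb_stop("'trace' contains non-finite entries")
  sphere_radius_mm <- cb_check_number(sphere_radius_mm, "sphere_radius_mm",
                                      lower = 0, lower_open = TRUE)
  scaled <- m
  scaled[, 4:6] <- scaled[, 4:6] * sphere_radius_mm
  c(0, rowSums(abs(diff(scaled))))
}

#' Per-volume fraction of intensity-outlier voxels
#'
#' A voxel is an outlier at a given volume when its value deviates from the
#' voxel's temporal median by more than `k_mad` robust standard deviations
#' (median absolute deviation scaled by 1.4826). Voxels with zero MAD carry
#' no outlier information and are excluded from the denominator.
#'
#' @param bold A `bold_series` or a voxels x time numeric matrix.
#' @param k_mad Outlier threshold in MAD-based robust SD units.
#' @return Numeric vector (length = volumes) of outlier fractions in `[0, 1]`.
#' @export
outlier_fraction <- function(bold, k_mad = 3.5) {
  X <- if (inherits(bold, "bold_series")) bold$data else bold
  if (!is.matrix(X) || ncol(X) < 2L) {
    cb_stop("'bold' must be a voxels x time matrix with >= 2 volumes")
  }
  k_mad <- cb_check_number(k_mad, "k_mad", lower = 0, lower_open = TRUE)
  med <- apply(X, 1, stats::median)
  madv <- apply(X, 1, stats::mad)
  valid <- madv > 0
  if (!any(valid)) {
    cb_stop("all voxel rows have zero variance: outlier fractions undefined")
  }
  dev <- abs(X[valid, , drop = FALSE] - med[valid])
  out <- dev > k_mad * madv[valid]
  colMeans(out)
}

#' Censor volumes by motion and intensity-outlier thresholds
#'
#' A volume is censored iff its framewise displacement strictly exceeds
#' `fd_thresh` (default 0.2 mm) or its outlier-voxel fraction strictly
#' exceeds `frac_thresh` (default 0.10).
#'
#' @param fd Per-volume framewise displacement (mm).
#' @param outfrac Per-volume outlier fraction, or a single value recycled
#'   across volumes.
#' @param fd_thresh Motion threshold in mm.
#' @param frac_thresh Outlier-fraction threshold.
#' @return A `censor_mask`: list with `keep` (logical per volume), `retained`
#'   (count), and `reasons` (per censored volume: "motion", "outlier", or
#'   "motion+outlier").
#' @export
censor_volumes <- function(fd, outfrac, fd_thresh = 0.2, frac_thresh = 0.10) {
  if (length(outfrac) == 1L) outfrac <- rep(outfrac, length(fd))
  if (length(fd) != length(outfrac)) {
    cb_stop("'fd' (%d) and 'outfrac' (%d) lengths differ",
            length(fd), length(outfrac))
  }
  if (!all(is.finite(fd)) || !all(is.finite(outfrac))) {
    cb_stop("'fd' and 'outfrac' must be finite")
  }
  motion <- fd > fd_thresh
  outlier <- outfrac > frac_thresh
  keep <- !(motion | outlier)
  reasons <- character(length(fd))
  reasons[motion & !outlier] <- "motion"
  reasons[!motion & outlier] <- "outlier"
  reasons[motion & outlier] <- "motion+outlier"
  structure(list(keep = keep, retained = sum(keep),
                 reasons = reasons[!keep],
                 fd_thresh = fd_thresh, frac_thresh = frac_thresh),
            class = "censor_mask")
}

#' Scan-level quality-control decision
#'
#' A scan passes QC iff it retains at least `min_volumes` motion-free volumes;
#' with the default threshold of 120 volumes (4 minutes at TR = 2 s), a scan
#' retaining 119 volumes is excluded and one retaining 120 is kept.
#'
#' @param mask A [censor_volumes()] mask.
#' @param min_volumes Minimum retained-volume count.
#' @return `TRUE` if the scan passes, else `FALSE`.
#' @export
scan_passes_qc <- function(mask, min_volumes = 120) {
  if (!inherits(mask, "censor_mask")) {
    cb_stop("'mask' must be a censor_mask object")
  }
  mask$retained >= min_volumes
}

#' Read a six-column motion parameter file
#'
#' Whitespace-delimited text, one row per volume: three translations (mm)
#' then three rotations (radians).
#'
#' @param path File path.
#' @return A `motion_trace` matrix.
#' @export
read_motion_par <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) cb_stop("motion file '%s' must have 6 columns", path)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  structure(m, class = c("motion_trace", class(m)))
}

#' Write a censor mask and QC report
#'
#' Writes the keep flags as single-column 0/1 text and a JSON QC report with
#' the retained count, pass flag, and censoring reasons.
#'
#' @param mask A [censor_volumes()] mask.
#' @param mask_path Path for the 0/1 text mask.
#' @param report_path Path for the JSON report.
#' @param min_volumes Threshold forwarded to [scan_passes_qc()].
#' @return Invisibly, the report list.
#' @export
write_qc_report <- function(mask, mask_path, report_path, min_volumes = 120) {
  writeLines(as.character(as.integer(mask$keep)), mask_path)
  report <- list(
    n_volumes = length(mask$keep),
    retained = mask$retained,
    passes_qc = scan_passes_qc(mask, min_volumes),
    min_volumes = min_volumes,
    reasons = table_to_list(mask$reasons)
  )
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

table_to_list <- function(x) {
  if (length(x) == 0L) return(list())
  as.list(table(x))
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("<censor_mask> %d/%d volumes retained\n",
              x$retained, length(x$keep)))
  invisible(x)
}
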