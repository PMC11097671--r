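## Voxel-wise functional connectivity: per-subject Pearson correlation over
## retained volumes, row-major upper-triangle vectorization, and assembly of
## the group connections x subjects matrix (52650 x 72 at full size).

#' Voxel-to-voxel functional connectivity matrix
#'
#' Pearson correlation between every pair of voxel time series, computed over
#' the retained (non-censored) volumes only.
#'
#' @param bold A `bold_series` or a voxels x time numeric matrix.
#' @param mask Optional [censor_volumes()] mask; `NULL` keeps all volumes.
#' @return Symmetric voxels x voxels correlation matrix with unit diagonal.
#' @export
fc_matrix <- function(bold, mask = NULL) {
  X <- if (inherits(bold, "bold_series")) bold$data else bold
  ids <- if (inherits(bold, "bold_series")) bold$voxel_ids else seq_len(nrow(X))
  if (!is.matrix(X)) cb_stop("'bold' must be a voxels x time matrix")
  if (!is.null(mask)) {
    if (!inherits(mask, "censor_mask")) {
      cb_stop("'mask' must be a censor_mask object")
    }
    if (length(mask$keep) != ncol(X)) {
      cb_stop("mask length (%d) does not match volume count (%d)",
              length(mask$keep), ncol(X))
    }
    X <- X[, mask$keep, drop = FALSE]
  }
  if (ncol(X) < 3L) {
    cb_stop("too few retained volumes (%d): need at least 3", ncol(X))
  }
  v <- apply(X, 1, stats::var)
  if (any(v == 0)) {
    cb_stop("zero-variance retained series for voxel(s): %s",
            paste(ids[v == 0], collapse = ", "))
  }
  r <- stats::cor(t(X))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Row-major upper-triangle index map
#'
#' Linearization order of voxel pairs: `(1,2), (1,3), ..., (1,V), (2,3), ...`,
#' i.e. the upper triangle excluding the diagonal read row by row.
#'
#' @param n_voxels Number of voxels V.
#' @return data.frame with columns `pos`, `i`, `j` (1-based voxel indices).
#' @export
upper_index_map <- function(n_voxels) {
  V <- cb_check_count(n_voxels, "n_voxels", min = 2L)
  i <- rep.int(seq_len(V - 1), times = (V - 1):1)
  j <- i + sequence((V - 1):1)
  data.frame(pos = seq_along(i), i = i, j = j)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Returns the `V(V-1)/2` off-diagonal upper-triangle values in row-major
#' order (see [upper_index_map()]); for V = 325 the length is 52650.
#'
#' @param fc Square symmetric matrix.
#' @return A `connectome_vector`: numeric vector with attribute `n_voxels`.
#' @seealso [devectorize_upper()]
#' @export
vectorize_upper <- function(fc) {
  if (!is.matrix(fc) || nrow(fc) != ncol(fc)) {
    cb_stop("'fc' must be a square matrix")
  }
  if (max(abs(fc - t(fc))) > 1e-8) cb_stop("'fc' must be symmetric")
  # t(fc)[lower.tri] walks the upper triangle of fc in row-major order
  v <- t(fc)[lower.tri(fc)]
  structure(v, n_voxels = nrow(fc), class = "connectome_vector")
}

#' Rebuild a connectivity matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()] for correlation matrices (unit diagonal).
#'
#' @param vec A `connectome_vector` or numeric vector of length `V(V-1)/2`.
#' @param diag_value Value placed on the diagonal.
#' @return Symmetric V x V matrix.
#' @export
devectorize_upper <- function(vec, diag_value = 1) {
  C <- length(vec)
  V <- (1 + sqrt(1 + 8 * C)) / 2
  if (V != round(V)) cb_stop("length %d is not V(V-1)/2 for integer V", C)
  V <- as.integer(V)
  m <- matrix(0, V, V)
  tm <- t(m)
  tm[lower.tri(tm)] <- as.numeric(vec)
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Assemble the group connections-by-subjects matrix
#'
#' Binds subject connectome vectors into a C x S matrix (connections x
#' subjects), preserving subject order.
#'
#' @param vectors List of [vectorize_upper()] outputs, one per subject.
#' @param subject_ids Optional character vector of subject identifiers.
#' @return A `group_matrix`: C x S numeric matrix with subject ids as column
#'   names and attribute `n_voxels`.
#' @export
assemble_group_matrix <- function(vectors, subject_ids = NULL) {
  if (!length(vectors)) cb_stop("'vectors' is empty")
  lens <- vapply(vectors, length, integer(1))
  if (length(unique(lens)) != 1L) {
    cb_stop("connectome vectors differ in length: %s",
            paste(unique(lens), collapse = ", "))
  }
  nv <- unique(vapply(vectors, function(v) {
    nv <- attr(v, "n_voxels")
    if (is.null(nv)) (1 + sqrt(1 + 8 * length(v))) / 2 else as.numeric(nv)
  }, numeric(1)))
  if (length(nv) != 1L) cb_stop("connectome vectors use different index maps")
  if (is.null(subject_ids)) {
    subject_ids <- names(vectors)
    if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_along(vectors))
  }
  if (length(subject_ids) != length(vectors)) {
    cb_stop("'subject_ids' length (%d) != number of vectors (%d)",
            length(subject_ids), length(vectors))
  }
  g <- vapply(vectors, as.numeric, numeric(lens[1]))
  g <- matrix(g, nrow = lens[1], dimnames = list(NULL, subject_ids))
  structure(g, n_voxels = as.integer(nv), class = c("group_matrix", "matrix"))
}

#' Per-subject connectomes for a whole cohort
#'
#' Convenience wrapper: censors each subject's volumes from its motion trace
#' and signal, drops scans failing QC, computes FC on retained volumes and
#' assembles the group matrix.
#'
#' @param cohort A [generate_cohort()] result (or an equivalent list with
#'   `bold`, `motion`, `subjects`).
#' @param fd_thresh,frac_thresh,min_volumes QC thresholds (see
#'   [censor_volumes()] and [scan_passes_qc()]).
#' @param k_mad Outlier threshold for [outlier_fraction()].
#' @return List: `group` (a `group_matrix` over passing subjects), `qc`
#'   (data.frame of subject id, retained count, pass flag).
#' @export
cohort_group_matrix <- function(cohort, fd_thresh = 0.2, frac_thresh = 0.10,
                                min_volumes = 120, k_mad = 3.5) {
  n <- nrow(cohort$subjects)
  qc <- data.frame(subject_id = cohort$subjects$subject_id,
                   retained = NA_integer_, passes = NA)
  vectors <- vector("list", n)
  for (s in seq_len(n)) {
    fd <- framewise_displacement(cohort$motion[[s]])
    of <- outlier_fraction(cohort$bold[[s]], k_mad = k_mad)
    mask <- censor_volumes(fd, of, fd_thresh, frac_thresh)
    qc$retained[s] <- mask$retained
    qc$passes[s] <- scan_passes_qc(mask, min_volumes)
    if (qc$passes[s]) {
      vectors[[s]] <- vectorize_upper(fc_matrix(cohort$bold[[s]], mask))
    }
  }
  keep <- which(qc$passes)
  if (!length(keep)) cb_stop("no scan passed QC")
  group <- assemble_group_matrix(vectors[keep],
                                 cohort$subjects$subject_id[keep])
  list(group = group, qc = qc)
}

#' @export
print.connectome_vector <- function(x, ...) {
  cat(sprintf("<connectome_vector> %d connections (%d voxels)\n",
              length(x), attr(x, "n_voxels")))
  invisible(x)
}
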