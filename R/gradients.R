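## Functional gradients: PCA of the group connections x subjects matrix.
## Loadings live on voxel-pair connections (C x K), coefficients index
## subjects (K x S). Computed via eigendecomposition of the S x S Gram matrix
## of the per-connection-centered data, which is mathematically identical to
## the eigendecomposition of the C x C covariance but feasible at C = 52650.

#' Fit the group-level gradient model
#'
#' Centers each connection across subjects (no variance scaling), then
#' extracts the top `k` principal components. Component loadings are
#' orthonormal in connection space; per-subject coefficients are the
#' projections of the centered profiles onto the loadings. With S subjects at
#' most S - 1 components have nonzero variance. Each component's sign is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param group A `group_matrix` or C x S numeric matrix
#'   (connections x subjects).
#' @param k Number of components to retain (default 10); must be <= S - 1.
#' @return A `gradient_model`: list with `connection_means` (length C),
#'   `loadings` (C x k, orthonormal columns), `variance_fraction` (per
#'   component, all S - 1 possible components), `coefficients` (k x S),
#'   `k`, `n_subjects`, `n_voxels`.
#' @export
fit_group_pca <- function(group, k = 10) {
  X <- unclass(group)
  if (!is.matrix(X) || !is.numeric(X)) cb_stop("'group' must be a numeric matrix")
  S <- ncol(X)
  if (S < 2L) cb_stop("need at least 2 subjects, got %d", S)
  k <- cb_check_count(k, "k")
  if (k > S - 1L) cb_stop("'k' (%d) must be <= S - 1 = %d", k, S - 1L)

  mu <- rowMeans(X)
  Xc <- X - mu
  gram <- crossprod(Xc)                      # S x S
  e <- eigen(gram, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  total <- sum(lambda)
  if (total <= max(1e-12, 1e-12 * nrow(X))) {
    cb_stop("degenerate group matrix: no between-subject variance")
  }
  if (lambda[k] <= 1e-10 * total) {
    cb_stop("fewer than %d components with nonzero variance", k)
  }
  varfrac <- lambda / total

  loadings <- Xc %*% e$vectors[, seq_len(k), drop = FALSE]
  loadings <- sweep(loadings, 2, sqrt(lambda[seq_len(k)]), "/")
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    m <- which.max(abs(loadings[, j]))
    if (loadings[m, j] < 0) loadings[, j] <- -loadings[, j]
  }
  coefficients <- crossprod(loadings, Xc)    # k x S
  rownames(coefficients) <- colnames(loadings) <-
    sprintf("FGR%d", seq_len(k))
  colnames(coefficients) <- colnames(X)

  nv <- attr(group, "n_voxels")
  structure(list(
    connection_means = mu,
    loadings = loadings,
    variance_fraction = varfrac,
    coefficients = coefficients,
    k = k, n_subjects = S,
    n_voxels = if (is.null(nv)) NA_integer_ else nv
  ), class = "gradient_model")
}

#' Project subjects onto a fitted gradient model
#'
#' Centers new connectome profiles with the model's stored connection means
#' (never the new data's own means, so held-out subjects leak no information
#' into the basis) and projects them onto the loadings. Projecting the
#' training set reproduces the model's own coefficients exactly.
#'
#' @param model A [fit_group_pca()] model.
#' @param group_new C x S' matrix of connectome profiles.
#' @return k x S' coefficient matrix.
#' @export
project_subjects <- function(model, group_new) {
  X <- unclass(group_new)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (nrow(X) != length(model$connection_means)) {
    cb_stop("connection dimension (%d) does not match the model (%d)",
            nrow(X), length(model$connection_means))
  }
  crossprod(model$loadings, X - model$connection_means)
}

#' Cumulative variance explained
#'
#' Fraction of total between-subject variance captured by the first `k`
#' components.
#'
#' @param model A [fit_group_pca()] model.
#' @param k Number of leading components.
#' @return Single fraction in `[0, 1]`.
#' @export
variance_explained <- function(model, k = model$k) {
  k <- cb_check_count(k, "k")
  if (k > length(model$variance_fraction)) {
    cb_stop("'k' (%d) exceeds available components (%d)",
            k, length(model$variance_fraction))
  }
  sum(model$variance_fraction[seq_len(k)])
}

#' Localize a component's strongest connections to ROI clusters
#'
#' Selects the `floor(quantile * C)` connections with the largest absolute
#' loading on one component (positive and negative pooled by magnitude; ties
#' at the threshold broken by lower linear index), maps each selected
#' connection to its two voxels, and aggregates per-voxel incidence and a
#' ranked ROI summary.
#'
#' @param model A [fit_group_pca()] model.
#' @param component 1-based component index.
#' @param quantile Fraction of connections to select (default 0.05, i.e. the
#'   top 5% strongest; 2632 of 52650 connections at full size).
#' @param labels Voxel ROI labels (factor or character, one per voxel).
#' @return A `cluster_report`: list with `selected` (data.frame: pos, voxel_i,
#'   voxel_j, loading, sign), `incidence` (named per-voxel counts; sums to
#'   twice the selected count), and `roi_ranking` (data.frame: roi, incidence,
#'   sorted decreasing).
#' @export
top_loading_clusters <- function(model, component, quantile = 0.05, labels) {
  component <- cb_check_count(component, "component")
  if (component > model$k) {
    cb_stop("'component' (%d) exceeds fitted components (%d)",
            component, model$k)
  }
  quantile <- cb_check_number(quantile, "quantile", lower = 0, upper = 1,
                              lower_open = TRUE)
  l <- model$loadings[, component]
  C <- length(l)
  V <- as.integer((1 + sqrt(1 + 8 * C)) / 2)
  labels <- as.character(labels)
  if (length(labels) != V) {
    cb_stop("'labels' must cover all %d voxels (got %d)", V, length(labels))
  }
  n_sel <- floor(quantile * C)
  if (n_sel < 1L) cb_stop("'quantile' selects no connection")
  ord <- order(-abs(l), seq_len(C))
  sel <- sort(ord[seq_len(n_sel)])
  map <- upper_index_map(V)
  selected <- data.frame(
    pos = sel,
    voxel_i = map$i[sel],
    voxel_j = map$j[sel],
    loading = l[sel],
    sign = ifelse(l[sel] >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  incidence <- tabulate(c(selected$voxel_i, selected$voxel_j), nbins = V)
  names(incidence) <- seq_len(V)
  roi_tot <- tapply(incidence, labels, sum)
  roi_ranking <- data.frame(
    roi = names(roi_tot),
    incidence = as.integer(roi_tot),
    stringsAsFactors = FALSE
  )
  roi_ranking <- roi_ranking[order(-roi_ranking$incidence, roi_ranking$roi), ]
  rownames(roi_ranking) <- NULL
  structure(list(selected = selected, incidence = incidence,
                 roi_ranking = roi_ranking, component = component,
                 quantile = quantile),
            class = "cluster_report")
}

#' @export
print.gradient_model <- function(x, ...) {
  cat(sprintf("<gradient_model> %d components over %d connections x %d subjects\n",
              x$k, nrow(x$loadings), x$n_subjects))
  cat(sprintf("  variance explained (top %d): %.1f%%\n", x$k,
              100 * variance_explained(x)))
  invisible(x)
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> component %d, top %.1f%%: %d connections\n",
              x$component, 100 * x$quantile, nrow(x$selected)))
  print(utils::head(x$roi_ranking, 4))
  invisible(x)
}
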