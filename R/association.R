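## Covariate-adjusted association of outcome domain scores with cerebellar
## features (ROI volumes, gradient coefficients): ordinary least squares with
## sex, PMA and birthweight as covariates, Benjamini-Hochberg FDR correction,
## ROI volume growth versus PMA, and inter-domain score correlations.

cb_covariates <- function() c("sex", "pma_weeks", "birthweight_g")

#' Covariate-adjusted linear model for one (feature, domain) pair
#'
#' Fits `score ~ feature + sex + pma_weeks + birthweight_g` by ordinary least
#' squares on complete cases and reports the feature coefficient's
#' t statistic and two-sided p-value (t distribution on n - 5 degrees of
#' freedom: intercept + feature + 3 covariates).
#'
#' @param data data.frame containing the outcome, feature and covariate
#'   columns.
#' @param feature Feature column name.
#' @param outcome Outcome column name.
#' @param covariates Covariate column names (default sex, PMA, birthweight).
#' @return List: `feature`, `outcome`, `estimate`, `t_stat`, `p_unc`, `n`,
#'   `df`.
#' @export
fit_feature_model <- function(data, feature, outcome,
                              covariates = cb_covariates()) {
  cols <- c(outcome, feature, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    cb_stop("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]),
            cols, drop = FALSE]
  n <- nrow(d)
  p_params <- length(covariates) + 2L   # intercept + feature + covariates
  if (n <= p_params) {
    cb_stop("too few complete cases (n = %d) for %d model parameters",
            n, p_params)
  }
  fml <- stats::reformulate(c(feature, covariates), response = outcome)
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    cb_stop("rank-deficient design for feature '%s'", feature)
  }
  sm <- summary(fit)$coefficients
  list(feature = feature, outcome = outcome,
       estimate = sm[feature, "Estimate"],
       t_stat = sm[feature, "t value"],
       p_unc = sm[feature, "Pr(>|t|)"],
       n = n, df = fit$df.residual)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: for ascending p-values, the adjusted value at rank
#' i is `min over j >= i of p_(j) * m / j`, capped at 1 and returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || !length(p_values)) {
    cb_stop("'p_values' must be a non-empty numeric vector")
  }
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    cb_stop("'p_values' must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Feature-by-domain association table
#'
#' One covariate-adjusted model per (feature, domain) pair, with BH-FDR
#' applied within the chosen scope: per domain across features (default,
#' m = number of features), globally across all cells, or per feature across
#' domains.
#'
#' @param data Subject data.frame with outcome, feature and covariate columns.
#' @param features Character vector of feature column names.
#' @param domains Character vector of outcome column names (default the four
#'   ITSEA domains).
#' @param fdr_scope `"domain"`, `"global"`, or `"feature"`.
#' @param covariates Covariate column names.
#' @return An `association_table` data.frame: feature, domain, estimate,
#'   t_stat, p_unc, p_fdr, n.
#' @export
association_table <- function(data, features, domains = itsea_domains(),
                              fdr_scope = c("domain", "global", "feature"),
                              covariates = cb_covariates()) {
  fdr_scope <- match.arg(fdr_scope)
  res <- do.call(rbind, lapply(domains, function(dom) {
    do.call(rbind, lapply(features, function(f) {
      r <- fit_feature_model(data, f, dom, covariates)
      data.frame(feature = f, domain = dom, estimate = r$estimate,
                 t_stat = r$t_stat, p_unc = r$p_unc, n = r$n,
                 stringsAsFactors = FALSE)
    }))
  }))
  res$p_fdr <- switch(fdr_scope,
    domain = stats::ave(res$p_unc, res$domain, FUN = bh_fdr),
    feature = stats::ave(res$p_unc, res$feature, FUN = bh_fdr),
    global = bh_fdr(res$p_unc)
  )
  class(res) <- c("association_table", "data.frame")
  attr(res, "fdr_scope") <- fdr_scope
  res
}

#' ROI volume growth with postmenstrual age
#'
#' Per-ROI Pearson correlation between volume and PMA at scan, with percent
#' variance explained (100 r^2) and BH-FDR across the ROIs.
#'
#' @param volumes ROI volume data.frame ([generate_volumes()] layout) or a
#'   subjects x ROI numeric matrix.
#' @param pma Per-subject PMA in weeks.
#' @return data.frame: roi, r, r_squared_pct, p_unc, p_fdr.
#' @export
volume_growth <- function(volumes, pma) {
  v <- volumes
  if (is.data.frame(v)) v <- v[, setdiff(names(v), "subject_id"), drop = FALSE]
  v <- as.matrix(v)
  if (nrow(v) != length(pma)) {
    cb_stop("'volumes' rows (%d) must match 'pma' length (%d)",
            nrow(v), length(pma))
  }
  if (nrow(v) < 3L) cb_stop("need at least 3 subjects")
  if (stats::var(pma) == 0) cb_stop("degenerate PMA variance")
  zv <- apply(v, 2, stats::var) == 0
  if (any(zv)) {
    cb_stop("zero-variance volume column(s): %s",
            paste(colnames(v)[zv], collapse = ", "))
  }
  tests <- lapply(seq_len(ncol(v)), function(i) {
    stats::cor.test(v[, i], pma)
  })
  r <- vapply(tests, function(t) unname(t$estimate), numeric(1))
  p <- vapply(tests, function(t) t$p.value, numeric(1))
  data.frame(
    roi = colnames(v),
    r = r,
    r_squared_pct = 100 * r^2,
    p_unc = p,
    p_fdr = bh_fdr(p),
    stringsAsFactors = FALSE
  )
}

#' Correlations among the four outcome domains
#'
#' Pairwise Pearson correlations between domain scores with two-sided
#' p-values.
#'
#' @param scores data.frame or matrix with one column per domain.
#' @return List: `r` (symmetric correlation matrix, unit diagonal) and `p`
#'   (p-value matrix, NA on the diagonal).
#' @export
domain_intercorrelation <- function(scores) {
  m <- as.matrix(scores)
  if (nrow(m) < 3L) cb_stop("need at least 3 subjects")
  cv <- apply(m, 2, stats::var)
  if (any(cv == 0)) {
    cb_stop("constant domain column(s): %s",
            paste(colnames(m)[cv == 0], collapse = ", "))
  }
  k <- ncol(m)
  r <- stats::cor(m)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p[i, j] <- p[j, i] <- stats::cor.test(m[, i], m[, j])$p.value
    }
  }
  list(r = r, p = p)
}

#' @export
print.association_table <- function(x, digits = 3, ...) {
  cat(sprintf("<association_table> %d features x %d domains (FDR scope: %s)\n",
              length(unique(x$feature)), length(unique(x$domain)),
              attr(x, "fdr_scope")))
  wide <- stats::reshape(
    data.frame(feature = x$feature, domain = x$domain,
               cell = sprintf("%.2f (%.3f)", x$t_stat, x$p_unc)),
    idvar = "feature", timevar = "domain", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
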