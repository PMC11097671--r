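## Leakage-safe cross-validated outcome prediction. For functional features
## the gradient basis is re-estimated on each training fold only and held-out
## subjects are projected with the training connection means, so no held-out
## information reaches the model. Performance per repeat is the Pearson
## correlation between pooled out-of-fold predictions and actual scores,
## Fisher-z transformed; inference uses a score-shuffling permutation test.

#' Configuration for cross-validated prediction
#'
#' @param n_folds Number of CV folds (default 10).
#' @param n_repeats Number of repeated CV cycles for the observed performance
#'   (default 100).
#' @param n_permutations Number of score shuffles for the null distribution
#'   (default 5000).
#' @param feature_set `"functional"` (within-fold gradient coefficients),
#'   `"anatomical"` (8 ROI volumes), or `"combined"` (both, each column
#'   standardized on training statistics).
#' @param k_components Gradient components used as functional features.
#' @param observed_stat `"mean_z"` compares the repeat-averaged Fisher z to
#'   the null; `"single_z"` compares a single CV cycle's z.
#' @param seed Integer RNG seed.
#' @return An object of class `prediction_config`.
#' @export
prediction_config <- function(n_folds = 10, n_repeats = 100,
                              n_permutations = 5000,
                              feature_set = c("functional", "anatomical",
                                              "combined"),
                              k_components = 10,
                              observed_stat = c("mean_z", "single_z"),
                              seed = 1L) {
  structure(list(
    n_folds = cb_check_count(n_folds, "n_folds", min = 2L),
    n_repeats = cb_check_count(n_repeats, "n_repeats", min = 1L),
    n_permutations = cb_check_count(n_permutations, "n_permutations", min = 1L),
    feature_set = match.arg(feature_set),
    k_components = cb_check_count(k_components, "k_components", min = 1L),
    observed_stat = match.arg(observed_stat),
    seed = cb_check_count(seed, "seed", min = 0L)
  ), class = "prediction_config")
}

#' Fisher's z transform of a correlation
#'
#' `z = atanh(r)`; variance-stabilizing, odd in `r`.
#'
#' @param r Correlation in (-1, 1).
#' @return Fisher z value.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    cb_stop("'r' must lie strictly within (-1, 1); perfect correlations give an infinite z")
  }
  atanh(r)
}

# Random partition of n subjects into k near-equal folds: seeded shuffle,
# then contiguous blocks. Returns a list of test-index vectors.
make_folds <- function(n, k) {
  if (k > n) cb_stop("'n_folds' (%d) exceeds the number of subjects (%d)", k, n)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  split(perm, rep(seq_len(k), times = sizes))
}

# Training and held-out feature matrices for one fold. Scores never enter.
fold_features <- function(feature_set, group, volumes, train, test,
                          k_components) {
  if (feature_set %in% c("functional", "combined")) {
    if (is.null(group)) cb_stop("functional features require a group matrix")
    model <- fit_group_pca(unclass(group)[, train, drop = FALSE],
                           k = k_components)
    f_tr <- t(model$coefficients)
    f_te <- t(project_subjects(model, unclass(group)[, test, drop = FALSE]))
  }
  if (feature_set %in% c("anatomical", "combined")) {
    if (is.null(volumes)) cb_stop("anatomical features require ROI volumes")
    a_tr <- volumes[train, , drop = FALSE]
    a_te <- volumes[test, , drop = FALSE]
  }
  out <- switch(feature_set,
    functional = list(train = f_tr, test = f_te),
    anatomical = list(train = a_tr, test = a_te),
    combined = {
      Xtr <- cbind(a_tr, f_tr)
      Xte <- cbind(a_te, f_te)
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
           test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
    })
  if (feature_set %in% c("functional", "combined")) out$model <- model
  out
}

# One full CV cycle over a given fold partition: OLS per fold, pooled
# out-of-fold predictions. `features` may be precomputed per fold (list of
# fold_features outputs) to avoid refitting the unsupervised basis when only
# the scores change (as in the permutation test).
cv_cycle <- function(y, folds, feature_set, group, volumes, k_components,
                     features = NULL) {
  n <- length(y)
  pred <- rep(NA_real_, n)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    ft <- if (is.null(features)) {
      fold_features(feature_set, group, volumes, train, test, k_components)
    } else features[[f]]
    Xtr <- cbind(1, as.matrix(ft$train))
    if (nrow(Xtr) < 2L * ncol(Xtr)) {
      cb_stop("fold %d has %d training subjects for %d predictors: need >= 2 per predictor",
              f, nrow(Xtr), ncol(Xtr))
    }
    beta <- stats::lm.fit(Xtr, y[train])$coefficients
    beta[is.na(beta)] <- 0
    pred[test] <- cbind(1, as.matrix(ft$test)) %*% beta
  }
  pred
}

cycle_performance <- function(pred, y) {
  r <- stats::cor(pred, y)
  if (!is.finite(r)) cb_stop("undefined prediction correlation (constant predictions)")
  if (abs(r) >= 1) {
    cb_stop("perfect prediction correlation (|r| = 1): Fisher z is infinite; add noise or reduce features")
  }
  r
}

#' Cross-validated prediction of a domain score
#'
#' Repeated 10-fold cross-validation: per repeat, subjects are randomly
#' partitioned; for functional features the gradient model is fit on the
#' training columns only and held-out subjects are projected with training
#' means; an ordinary least-squares model maps features to scores; pooled
#' out-of-fold predictions are correlated with actual scores and Fisher-z
#' transformed. Non-imaging covariates are deliberately excluded from the
#' predictor set.
#'
#' @param subjects Subject data.frame containing the `domain` column.
#' @param domain Outcome column name.
#' @param config A [prediction_config()].
#' @param group C x S group connectome matrix (required for functional or
#'   combined features); columns must align with `subjects` rows.
#' @param volumes Subjects x 8 matrix or [generate_volumes()] data.frame
#'   (required for anatomical or combined features).
#' @return A `prediction_result`: list with `predictions` (subjects x
#'   repeats), `r` and `z` per repeat, `mean_z`, `se_z`, `domain`,
#'   `feature_set`, `config`.
#' @export
cv_predict <- function(subjects, domain, config = prediction_config(),
                       group = NULL, volumes = NULL) {
  y <- subjects[[domain]]
  if (is.null(y)) cb_stop("missing outcome column '%s'", domain)
  if (anyNA(y)) cb_stop("'%s' contains missing scores; subset to complete cases first", domain)
  n <- length(y)
  if (config$n_folds > n) {
    cb_stop("'n_folds' (%d) exceeds the number of subjects (%d)",
            config$n_folds, n)
  }
  volumes <- prep_volumes(volumes)
  if (!is.null(group) && ncol(group) != n) {
    cb_stop("group matrix has %d columns but %d subjects", ncol(group), n)
  }
  if (!is.null(volumes) && nrow(volumes) != n) {
    cb_stop("volume table has %d rows but %d subjects", nrow(volumes), n)
  }

  preds <- matrix(NA_real_, n, config$n_repeats)
  r <- numeric(config$n_repeats)
  with_local_seed(cb_derive_seed(config$seed, 10L), {
    for (rep_i in seq_len(config$n_repeats)) {
      folds <- make_folds(n, config$n_folds)
      preds[, rep_i] <- cv_cycle(y, folds, config$feature_set, group, volumes,
                                 config$k_components)
      r[rep_i] <- cycle_performance(preds[, rep_i], y)
    }
  })
  z <- fisher_z(r)
  structure(list(
    predictions = preds, r = r, z = z,
    mean_z = mean(z),
    se_z = if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else NA_real_,
    domain = domain, feature_set = config$feature_set, config = config
  ), class = "prediction_result")
}

prep_volumes <- function(volumes) {
  if (is.null(volumes)) return(NULL)
  if (is.data.frame(volumes)) {
    volumes <- volumes[, setdiff(names(volumes), "subject_id"), drop = FALSE]
  }
  as.matrix(volumes)
}

#' Permutation test of prediction performance
#'
#' Generates a null distribution by shuffling the outcome scores and rerunning
#' a full cross-validation cycle per shuffle on a fixed fold partition. The
#' fold partition and the (unsupervised, score-free) within-fold feature
#' construction are computed once and shared by the observed and null runs;
#' shuffling scores cannot change them. The p-value uses the add-one rule:
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`, one-sided with
#' higher performance more extreme.
#'
#' @param observed Observed performance (Fisher z), e.g. `mean_z` from
#'   [cv_predict()]; if `NULL`, it is computed from the same fixed partition
#'   according to `config$observed_stat`.
#' @param subjects,domain,config,group,volumes As in [cv_predict()].
#' @return A `permutation_result`: list with `null` (length
#'   `n_permutations`), `observed`, and `p_perm`.
#' @export
permutation_test <- function(observed = NULL, subjects, domain,
                             config = prediction_config(),
                             group = NULL, volumes = NULL) {
  if (config$n_permutations < 20L) {
    warning("fewer than 20 permutations: the null distribution will be coarse",
            call. = FALSE)
  }
  y <- subjects[[domain]]
  if (is.null(y)) cb_stop("missing outcome column '%s'", domain)
  n <- length(y)
  volumes <- prep_volumes(volumes)

  res <- with_local_seed(cb_derive_seed(config$seed, 11L), {
    folds <- make_folds(n, config$n_folds)
    features <- lapply(seq_along(folds), function(f) {
      fold_features(config$feature_set, group, volumes,
                    setdiff(seq_len(n), folds[[f]]), folds[[f]],
                    config$k_components)
    })
    obs <- observed
    if (is.null(obs)) {
      if (config$observed_stat == "mean_z") {
        obs <- cv_predict(subjects, domain, config, group, volumes)$mean_z
      } else {
        obs <- fisher_z(cycle_performance(
          cv_cycle(y, folds, config$feature_set, group, volumes,
                   config$k_components, features), y))
      }
    }
    null <- numeric(config$n_permutations)
    for (b in seq_len(config$n_permutations)) {
      yp <- y[sample.int(n)]
      pred <- cv_cycle(yp, folds, config$feature_set, group, volumes,
                       config$k_components, features)
      null[b] <- fisher_z(cycle_performance(pred, yp))
    }
    list(null = null, observed = obs)
  })
  p <- (1 + sum(res$null >= res$observed)) / (1 + config$n_permutations)
  structure(list(null = res$null, observed = res$observed, p_perm = p,
                 domain = domain, feature_set = config$feature_set),
            class = "permutation_result")
}

#' Compare functional, anatomical and combined feature sets
#'
#' Runs [cv_predict()] and [permutation_test()] for every (domain, feature
#' set) combination, mirroring a 4 x 3 performance grid.
#'
#' @param subjects Subject data.frame with the domain columns.
#' @param group C x S group connectome matrix.
#' @param volumes ROI volume table.
#' @param domains Outcome column names (default the four ITSEA domains).
#' @param config A [prediction_config()]; its `feature_set` field is
#'   overridden per cell.
#' @return data.frame: domain, feature_set, mean_z, se_z, p_perm.
#' @export
compare_feature_sets <- function(subjects, group, volumes,
                                 domains = itsea_domains(),
                                 config = prediction_config()) {
  sets <- c("functional", "anatomical", "combined")
  grid <- expand.grid(domain = domains, feature_set = sets,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$feature_set <- grid$feature_set[i]
    fit <- cv_predict(subjects, grid$domain[i], cfg, group, volumes)
    perm <- permutation_test(fit$mean_z, subjects, grid$domain[i], cfg,
                             group, volumes)
    data.frame(domain = grid$domain[i], feature_set = grid$feature_set[i],
               mean_z = fit$mean_z, se_z = fit$se_z, p_perm = perm$p_perm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s ~ %s features\n", x$domain,
              x$feature_set))
  cat(sprintf("  %d repeats of %d-fold CV: mean z = %.3f (SE %.3f)\n",
              length(x$z), x$config$n_folds, x$mean_z, x$se_z))
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s ~ %s features\n", x$domain,
              x$feature_set))
  cat(sprintf("  observed z = %.3f vs %d shuffles: p = %.4g\n",
              x$observed, length(x$null), x$p_perm))
  invisible(x)
}
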