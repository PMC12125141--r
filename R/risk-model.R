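# L2-penalised logistic PSH-risk model with class weighting, stratified
# five-fold cross-validation and a regularisation-strength grid.
#
# "Strength" C follows the inverse-penalty convention: the fit minimises
#   sum_i s_i * logloss_i + ||beta||^2 / (2C)
# with an unpenalised intercept, so larger C means a weaker penalty. The
# standard grid is {2N, N, 1, 1/N, 1/(2N)} with N the number of
# instances. The fit is a damped Newton iteration written directly so the
# objective and weighting conventions are exact; an independent optimiser
# serves as the oracle in the test suite.

#' Model/evaluation configuration
#'
#' @param n_instances Cohort size N used to span the default strength
#'   grid `{2N, N, 1, 1/N, 1/(2N)}`.
#' @param strengths Regularisation strengths C (inverse penalty weights).
#' @param weightings Class-weighting settings explored.
#' @param k_folds Number of stratified CV folds.
#' @param standardize Z-score features within training folds.
#' @param seed Seed for the fold assignment.
#' @return A `model_config` list.
#' @export
model_config <- function(n_instances = 41L,
                         strengths = c(2 * n_instances, n_instances, 1,
                                       1 / n_instances, 1 / (2 * n_instances)),
                         weightings = c("balanced", "unbalanced"),
                         k_folds = 5L, standardize = TRUE, seed = 1L) {
  stopifnot(all(strengths > 0), k_folds >= 2L,
            all(weightings %in% c("balanced", "unbalanced")))
  structure(list(strengths = strengths, weightings = weightings,
                 k_folds = k_folds, standardize = standardize, seed = seed),
            class = "model_config")
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members to the folds
#' in rotation, so per-fold class counts differ by at most one and the
#' fold class proportions match the cohort's within rounding.
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  if (any(table(labels) < k)) {
    stop("every class must have at least k = ", k, " members")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

class_weights <- function(y, weighting) {
  if (weighting == "balanced") {
    n <- length(y)
    w <- n / (2 * table(factor(y, levels = 0:1)))
    as.numeric(w[as.character(y)])
  } else {
    rep(1, length(y))
  }
}

#' Fit an L2-penalised logistic regression
#'
#' Minimises the weighted negative log-likelihood plus `||beta||^2 / (2C)`
#' (intercept unpenalised) by damped Newton iteration. With `"balanced"`
#' weighting each instance is weighted by `n / (2 * n_class)`, so both
#' classes contribute equally to the loss. Standardisation parameters
#' (mean, sd) are learned from the supplied (training) data and stored
#' for prediction. Zero-variance columns are dropped from the
#' optimisation with a warning and reported with coefficient 0.
#'
#' @param X Numeric matrix (no missing values).
#' @param y Binary labels (0/1).
#' @param strength Regularisation strength C (inverse penalty).
#' @param weighting `"balanced"` or `"unbalanced"`.
#' @param standardize Z-score columns before fitting.
#' @param max_iter,tol Newton iteration controls.
#' @return A `psh_logit` model: `coef` (on the fitting scale),
#'   `intercept`, `center`, `scale`, `dropped`, plus the call settings.
#' @export
fit_logistic <- function(X, y, strength, weighting = "unbalanced",
                         standardize = TRUE, max_iter = 200L, tol = 1e-10) {
  X <- as.matrix(X)
  stopifnot(!anyNA(X), length(unique(y)) == 2L, strength > 0)
  weighting <- match.arg(weighting, c("balanced", "unbalanced"))
  p_all <- ncol(X)
  feature_names <- colnames(X) %||% paste0("x", seq_len(p_all))

  center <- rep(0, p_all); scale <- rep(1, p_all)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale < 1e-12] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  }
  keep <- apply(X, 2L, function(col) stats::sd(col) > 1e-12)
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(feature_names[!keep], collapse = ", "))
  }
  Xk <- X[, keep, drop = FALSE]
  w <- class_weights(y, weighting)
  p <- ncol(Xk)
  Z <- cbind(1, Xk)
  beta <- rep(0, p + 1L)
  pen <- c(0, rep(1 / strength, p))  # intercept unpenalised

  objective <- function(b) {
    eta <- drop(Z %*% b)
    # numerically stable weighted log-loss
    ll <- sum(w * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta))
    ll + sum(pen * b^2) / 2
  }
  obj <- objective(beta)
  for (iter in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Z, w * (mu - y))) + pen * beta
    if (max(abs(grad)) < tol) break
    Wd <- w * mu * (1 - mu)
    H <- crossprod(Z, Z * Wd) + diag(pen, p + 1L)
    step <- solve(H + diag(1e-12, p + 1L), grad)
    # damping: halve the step until the objective decreases
    lr <- 1
    repeat {
      cand <- beta - lr * step
      cand_obj <- objective(cand)
      if (cand_obj <= obj + 1e-14 || lr < 1e-8) break
      lr <- lr / 2
    }
    if (abs(obj - cand_obj) < tol * (abs(obj) + 1)) {
      beta <- cand; obj <- cand_obj; break
    }
    beta <- cand; obj <- cand_obj
  }
  coef_full <- rep(0, p_all)
  coef_full[keep] <- beta[-1L]
  structure(list(coef = stats::setNames(coef_full, feature_names),
                 intercept = beta[1L], center = center, scale = scale,
                 dropped = feature_names[!keep], strength = strength,
                 weighting = weighting, standardize = standardize,
                 objective = obj, iterations = iter),
            class = "psh_logit")
}

#' @export
print.psh_logit <- function(x, ...) {
  cat(sprintf("<psh_logit> C = %g, %s weighting, %d features (%d dropped)\n",
              x$strength, x$weighting, length(x$coef), length(x$dropped)))
  invisible(x)
}

#' Predicted PSH-risk probability
#'
#' @param object A `psh_logit` model.
#' @param newdata Numeric matrix on the raw (unstandardised) scale.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.psh_logit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  stats::plogis(object$intercept + drop(X %*% object$coef))
}

roc_auc <- function(y, score) {
  if (length(unique(y)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

impute_train_median <- function(train, valid) {
  med <- apply(train, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0  # all-missing training column
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(train), valid = fill(valid), medians = med)
}

#' Grid-searched stratified cross-validation
#'
#' For every (strength, weighting) configuration, runs stratified k-fold
#' CV with fold-local median imputation and standardisation (statistics
#' learned on training folds only, so no information leaks into
#' validation) and records per-fold validation AUC and accuracy
#' (probability threshold 0.5). The best configuration is the one with
#' the highest mean AUC; ties resolve to the smaller strength, then to
#' balanced weighting.
#'
#' @param features A `feature_matrix` (or list with `x`, `y`).
#' @param config A `model_config`.
#' @return A `cv_report`: `grid` (per-configuration mean/sd AUC and ACC),
#'   `best` (chosen strength/weighting and its metrics), `folds` (fold
#'   assignment), and `fold_fits` for the best configuration (per-fold
#'   model, validation indices, AUC, ACC).
#' @export
grid_search_cv <- function(features, config = model_config(length(features$y))) {
  X <- features$x; y <- features$y
  folds <- stratified_folds(y, k = config$k_folds, seed = config$seed)
  grid <- expand.grid(strength = config$strengths,
                      weighting = config$weightings,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  run_config <- function(strength, weighting, keep_fits = FALSE) {
    aucs <- accs <- rep(NA_real_, config$k_folds)
    fits <- vector("list", config$k_folds)
    for (f in seq_len(config$k_folds)) {
      tr <- folds != f; va <- !tr
      imp <- impute_train_median(X[tr, , drop = FALSE],
                                 X[va, , drop = FALSE])
      fit <- suppressWarnings(
        fit_logistic(imp$train, y[tr], strength = strength,
                     weighting = weighting,
                     standardize = config$standardize))
      prob <- predict(fit, imp$valid)
      aucs[f] <- roc_auc(y[va], prob)
      accs[f] <- mean((prob >= 0.5) == (y[va] == 1L))
      if (keep_fits) {
        fits[[f]] <- list(model = fit, valid_idx = which(va),
                          valid_prob = prob, valid_x = imp$valid,
                          auc = aucs[f], acc = accs[f])
      }
    }
    list(aucs = aucs, accs = accs, fits = fits)
  }

  res <- lapply(seq_len(nrow(grid)), function(i) {
    run_config(grid$strength[i], grid$weighting[i])
  })
  grid$auc_mean <- vapply(res, function(r) mean(r$aucs, na.rm = TRUE), 0)
  grid$auc_sd <- vapply(res, function(r) stats::sd(r$aucs, na.rm = TRUE), 0)
  grid$acc_mean <- vapply(res, function(r) mean(r$accs, na.rm = TRUE), 0)
  grid$acc_sd <- vapply(res, function(r) stats::sd(r$accs, na.rm = TRUE), 0)

  ord <- order(-grid$auc_mean, grid$strength,
               match(grid$weighting, c("balanced", "unbalanced")))
  best_row <- grid[ord[1L], ]
  best <- run_config(best_row$strength, best_row$weighting, keep_fits = TRUE)

  structure(list(grid = grid, best = best_row, folds = folds,
                 fold_fits = best$fits,
                 feature_names = colnames(X),
                 level = features$level, metric = features$metric,
                 window_hours = features$window_hours,
                 config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  b <- x$best
  cat(sprintf("<cv_report> level %s: best C = %g (%s), AUC %.2f +/- %.2f, ACC %.2f +/- %.2f\n",
              x$level %||% "?", b$strength, b$weighting,
              b$auc_mean, b$auc_sd, b$acc_mean, b$acc_sd))
  invisible(x)
}

#' Best-configuration summaries across the metric x window grid
#'
#' Enumerates the 3 variability metrics x 4 window lengths, builds the
#' level-III feature set for each, runs [grid_search_cv()], and reports
#' the best AUC/ACC per configuration plus a best-metric-per-window
#' summary table.
#'
#' @param metadata,records,config As in [build_feature_set()] /
#'   [grid_search_cv()].
#' @param metrics,windows Grid to enumerate.
#' @param min_valid Completeness gate for [transient_features()].
#' @return List with `grid` (12 rows: window_h, metric, auc_mean, auc_sd,
#'   acc_mean, acc_sd, strength, weighting) and `best_per_window`.
#' @export
metric_window_summary <- function(metadata, records,
                                  config = model_config(nrow(metadata)),
                                  metrics = c("ZCR", "STD", "MEAN"),
                                  windows = c(3, 6, 12, 24),
                                  min_valid = 0.9) {
  rows <- list()
  for (w in windows) {
    tf <- do.call(rbind, lapply(records, transient_features,
                                window_hours = w, min_valid = min_valid))
    for (m in metrics) {
      fm <- build_feature_set("III", metadata, records, tf,
                              metric = m, window_hours = w)
      cv <- grid_search_cv(fm, config)
      rows[[length(rows) + 1L]] <- data.frame(
        window_h = w, metric = m,
        auc_mean = cv$best$auc_mean, auc_sd = cv$best$auc_sd,
        acc_mean = cv$best$acc_mean, acc_sd = cv$best$acc_sd,
        strength = cv$best$strength, weighting = cv$best$weighting,
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  best_per_window <- do.call(rbind, lapply(split(grid, grid$window_h),
                                           function(g) g[which.max(g$auc_mean), ]))
  rownames(best_per_window) <- NULL
  list(grid = grid, best_per_window = best_per_window)
}
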