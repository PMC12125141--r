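# Feature importance: absolute regression coefficients and exact additive
# attributions for the linear model, aggregated across CV folds, min-max
# normalised, and reduced to a temporal significance profile over the
# transient-feature time bins.

#' Absolute-coefficient importance per fold
#'
#' @param cv_report A `cv_report` from [grid_search_cv()].
#' @return Matrix folds x features of `|coefficient|` (on the
#'   standardised fitting scale; dropped features contribute 0).
#' @export
coefficient_importance <- function(cv_report) {
  out <- t(vapply(cv_report$fold_fits,
                  function(f) abs(f$model$coef),
                  numeric(length(cv_report$feature_names))))
  colnames(out) <- cv_report$feature_names
  out
}

#' Exact additive attribution for a linear model
#'
#' For a fitted logistic model the attribution of feature `j` for
#' instance `i` is `coef_j * (z_ij - z_bj)` on the linear-predictor
#' scale, where `z` is the model's standardised representation and `b`
#' the background (by default the training means, i.e. the model's
#' centring point). The attributions plus the base value (the linear
#' predictor at the background) reconstruct every linear predictor
#' exactly -- the closed-form Shapley decomposition for an additive
#' model.
#'
#' @param model A `psh_logit`.
#' @param X_validation Numeric matrix on the raw scale (imputed).
#' @param background Raw-scale background row; defaults to the model's
#'   training means.
#' @return List with `attributions` (instances x features) and
#'   `base_value`.
#' @export
additive_attribution <- function(model, X_validation,
                                 background = model$center) {
  X <- as.matrix(X_validation)
  if (length(background) != ncol(X)) {
    stop("background length does not match the feature count")
  }
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  zb <- (background - model$center) / model$scale
  attributions <- sweep(Z, 2L, zb) %*% diag(model$coef, ncol(Z))
  colnames(attributions) <- names(model$coef)
  base <- model$intercept + sum(model$coef * zb)
  list(attributions = attributions, base_value = base)
}

#' Aggregate per-fold importances and min-max normalise
#'
#' Sums absolute values across folds (and, for attributions, across
#' validation instances) per feature, then rescales the aggregate to
#' `[0, 1]` by min-max normalisation. A degenerate aggregate (all values
#' equal) yields zeros with a warning.
#'
#' @param values Matrix with features in columns: folds x features of
#'   `|coefficients|`, or stacked validation attributions.
#' @return Named numeric vector of normalised importances in `[0, 1]`.
#' @export
aggregate_normalize <- function(values) {
  raw <- colSums(abs(as.matrix(values)))
  rng <- range(raw)
  if (diff(rng) < 1e-15) {
    warning("degenerate importance aggregate: all values equal")
    return(stats::setNames(rep(0, length(raw)), names(raw)))
  }
  (raw - rng[1L]) / diff(rng)
}

#' Aggregated, normalised importance profile for a CV report
#'
#' `method = "coefficient"` aggregates `|coefficients|` across folds;
#' `method = "attribution"` aggregates `|additive attribution|` across
#' every validation instance of every fold (background = each fold's
#' training means). Both are min-max normalised over all features.
#'
#' @param cv_report A `cv_report` with retained fold fits.
#' @param method `"coefficient"` or `"attribution"`.
#' @return Named numeric vector in `[0, 1]`, one entry per feature.
#' @export
importance_profile <- function(cv_report,
                               method = c("coefficient", "attribution")) {
  method <- match.arg(method)
  values <- if (method == "coefficient") {
    coefficient_importance(cv_report)
  } else {
    do.call(rbind, lapply(cv_report$fold_fits, function(f) {
      additive_attribution(f$model, f$valid_x)$attributions
    }))
  }
  aggregate_normalize(values)
}

#' Temporal significance profile over transient-feature bins
#'
#' Restricts a normalised importance vector to the transient features of
#' one metric/window configuration, aggregates per time bin as the mean
#' of the six pairs' normalised importances, min-max rescales the bin
#' profile to `[0, 1]`, and marks as influential the bins strictly
#' exceeding the threshold defined by the mean of the (rescaled) bin
#' values. With all bins equal the profile is degenerate and no bin is
#' influential.
#'
#' @param importance Named importance vector from [importance_profile()].
#' @param window_hours Bin length in hours (names encode the bins).
#' @param metric Metric whose columns to use (default: inferred from the
#'   names).
#' @return Data frame `bin_index, bin_start_h, importance, influential`
#'   with attribute `"threshold"`.
#' @export
temporal_profile <- function(importance, window_hours, metric = NULL) {
  nm <- names(importance)
  pat <- "^(zcr|std|mean)_([a-z]+)_([a-z]+)_b([0-9]+)$"
  sel <- grepl(pat, nm)
  if (!is.null(metric)) {
    sel <- sel & startsWith(nm, tolower(metric))
  }
  if (!any(sel)) stop("no transient-feature columns in the importance vector")
  bins <- as.integer(sub(pat, "\\4", nm[sel]))
  agg <- tapply(importance[sel], bins, mean)
  bin_index <- as.integer(names(agg))
  rng <- range(agg)
  scaled <- if (diff(rng) < 1e-15) rep(0, length(agg)) else
    (agg - rng[1L]) / diff(rng)
  threshold <- mean(scaled)
  out <- data.frame(bin_index = bin_index,
                    bin_start_h = bin_index * window_hours,
                    importance = as.numeric(scaled),
                    influential = as.numeric(scaled) > threshold)
  out <- out[order(out$bin_index), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Pair-level aggregated importance of transient features
#'
#' Sums the normalised importance of a pair's bins, ranking the six
#' ANS x hemodynamics pairs by their overall contribution.
#'
#' @param importance Named importance vector from [importance_profile()].
#' @return Data frame `pair, importance`, sorted decreasing.
#' @export
pair_importance <- function(importance) {
  nm <- names(importance)
  pat <- "^(zcr|std|mean)_([a-z]+)_([a-z]+)_b([0-9]+)$"
  sel <- grepl(pat, nm)
  if (!any(sel)) stop("no transient-feature columns in the importance vector")
  pair <- paste(sub(pat, "\\2", nm[sel]), sub(pat, "\\3", nm[sel]), sep = "-")
  agg <- tapply(importance[sel], pair, sum)
  out <- data.frame(pair = names(agg), importance = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
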