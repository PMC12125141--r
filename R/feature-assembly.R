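# Nested feature sets (clinical metadata; + 72-h neuromonitoring means;
# + one transient variability metric) and the stratified group comparison
# table.

METADATA_FEATURES <- c("age", "sex_male", "gcs_sum", "iss",
                       "trauma_isolated", "hb", "wbc",
                       "ct_sdh", "ct_edh", "ct_tich", "ct_edema",
                       "ct_dai", "ct_tsah")

#' 72-h channel means of a trend record
#'
#' Gaps are first filled with [interpolate_gaps()]; the mean of each
#' channel is then taken over its defined samples.
#'
#' @param record A `trend_record`.
#' @return Named numeric vector `mean_abp, mean_hr, mean_brs, mean_icp,
#'   mean_prx`.
#' @export
trend_means <- function(record) {
  out <- vapply(record$channels, function(s) {
    mean(interpolate_gaps(s)$values, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, paste0("mean_", names(out)))
}

#' Build a nested feature matrix
#'
#' Level I: the 13 clinical-metadata covariates (flags coded 0/1).
#' Level II: level I plus the five 72-h neuromonitoring channel means.
#' Level III: level II plus, for each of the six ANS x hemodynamics pairs
#' and each time bin, the value of one variability metric (MEAN, STD or
#' ZCR) of the rolling correlation at one window length. Transient column
#' names encode metric, pair and bin (`zcr_hr_icp_b00`, ...). Column
#' order is deterministic and the level-III matrix restricted to level-II
#' columns equals the level-II matrix.
#'
#' Missing transient values (bins with too few defined correlations) are
#' kept as `NA` here; imputation happens fold-locally at model time.
#'
#' @param level `"I"`, `"II"` or `"III"`.
#' @param metadata Data frame from [gen_metadata()] (or the same layout).
#' @param records Named list of `trend_record`s (levels II/III).
#' @param transients Data frame from [transient_features()] rows for all
#'   patients (level III).
#' @param metric One of `"ZCR", "STD", "MEAN"` (level III).
#' @param window_hours Window length in hours (level III).
#' @return A `feature_matrix`: list with `x` (numeric matrix), `y`
#'   (labels), `patient_id`, `level`, `metric`, `window_hours`.
#' @export
build_feature_set <- function(level = c("I", "II", "III"), metadata,
                              records = NULL, transients = NULL,
                              metric = NULL, window_hours = NULL) {
  level <- match.arg(level)
  x <- as.matrix(metadata[, METADATA_FEATURES])
  rownames(x) <- metadata$patient_id

  if (level %in% c("II", "III")) {
    if (is.null(records)) stop("level ", level, " requires `records`")
    tm <- t(vapply(metadata$patient_id, function(id) {
      if (is.null(records[[id]])) stop("no trend record for ", id)
      trend_means(records[[id]])
    }, numeric(5)))
    x <- cbind(x, tm)
  }

  if (level == "III") {
    if (is.null(transients)) stop("level III requires `transients`")
    if (is.null(metric) || is.null(window_hours)) {
      stop("level III requires exactly one `metric` and one `window_hours`")
    }
    metric <- match.arg(metric, c("ZCR", "STD", "MEAN"))
    tf <- transients[transients$metric == metric &
                       transients$window_h == window_hours, ]
    if (nrow(tf) == 0L) {
      stop("no transient features for metric ", metric, " at ",
           window_hours, " h")
    }
    pairs <- paste(signal_pairs()$ans, signal_pairs()$hemo, sep = "-")
    bins <- sort(unique(tf$bin_index))
    grid <- expand.grid(bin = bins, pair = pairs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- function(id, pair, bin) paste(id, pair, bin, sep = "|")
    lut <- stats::setNames(tf$value, key(tf$patient_id, tf$pair, tf$bin_index))
    tf_mat <- matrix(NA_real_, nrow = nrow(metadata), ncol = nrow(grid),
                     dimnames = list(metadata$patient_id,
                                     sprintf("%s_%s_b%02d", tolower(metric),
                                             gsub("-", "_", grid$pair),
                                             grid$bin)))
    for (j in seq_len(nrow(grid))) {
      tf_mat[, j] <- unname(lut[key(metadata$patient_id, grid$pair[j],
                                    grid$bin[j])])
    }
    x <- cbind(x, tf_mat)
  }

  structure(list(x = x, y = metadata$psh_risk,
                 patient_id = metadata$patient_id, level = level,
                 metric = metric, window_hours = window_hours),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> level %s: %d patients x %d features (%d positive)\n",
              x$level, nrow(x$x), ncol(x$x), sum(x$y)))
  invisible(x)
}

#' Group comparison table (cohort characteristics by PSH risk)
#'
#' Numeric variables are summarised as median (IQR) per group and
#' compared with the two-sided Mann-Whitney U test; binary flags as
#' count (%) with Fisher's exact test.
#'
#' @param metadata Metadata data frame including `psh_risk`.
#' @param trend_mean_table Optional data frame of per-patient channel
#'   means (columns `mean_*`) to append, row order matching `metadata`.
#' @param alpha Significance level used for the `significant` flag.
#' @return Data frame with one row per variable: group summaries,
#'   `p_value`, `test`, `significant`.
#' @export
compare_groups <- function(metadata, trend_mean_table = NULL, alpha = 0.05) {
  y <- metadata$psh_risk
  if (length(unique(y)) < 2L) stop("both groups must be non-empty")
  vars <- metadata[, setdiff(names(metadata), c("patient_id", "psh_risk")),
                   drop = FALSE]
  if (!is.null(trend_mean_table)) vars <- cbind(vars, trend_mean_table)

  summarise <- function(v, grp) {
    v <- v[grp]
    if (all(v %in% c(0, 1, NA))) {
      sprintf("%d (%.0f%%)", sum(v, na.rm = TRUE),
              100 * mean(v, na.rm = TRUE))
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
      sprintf("%.1f (%.1f-%.1f)", q[2L], q[1L], q[3L])
    }
  }
  rows <- lapply(names(vars), function(nm) {
    v <- vars[[nm]]
    binary <- all(v %in% c(0, 1, NA))
    p <- if (binary) {
      stats::fisher.test(table(factor(v, levels = 0:1),
                               factor(y, levels = 0:1)))$p.value
    } else {
      # exact null distribution when sample sizes permit and no ties
      suppressWarnings(stats::wilcox.test(v ~ y)$p.value)
    }
    data.frame(variable = nm,
               at_risk = summarise(v, y == 1L),
               not_at_risk = summarise(v, y == 0L),
               p_value = p,
               test = if (binary) "fisher" else "mann-whitney",
               significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
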