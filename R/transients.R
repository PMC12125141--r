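# Rolling-window Pearson correlation between ANS and cerebral-hemodynamic
# trend channels, and the MEAN / STD / ZCR variability metrics extracted
# from the correlation track in consecutive time bins.

ANS_CHANNELS <- c("hr", "abp", "brs")
HEMO_CHANNELS <- c("icp", "prx")

#' All ANS x hemodynamics channel pairs
#'
#' The six analysed signal pairs: each autonomic metric (HR, ABP, BRS)
#' against each cerebral-hemodynamics metric (ICP, PRx).
#'
#' @return Data frame with columns `ans` and `hemo` (six rows).
#' @export
signal_pairs <- function() {
  expand.grid(ans = ANS_CHANNELS, hemo = HEMO_CHANNELS,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Rolling Pearson correlation of two trend channels
#'
#' Computes the correlation over a sliding window of `window_hours`,
#' advanced one 60-s sample at a time, using pairwise-complete samples.
#' A window's value is labelled by its start time and is missing when the
#' complete fraction falls below `min_valid` or either channel has zero
#' variance within the window.
#'
#' The sliding sums are accumulated on mean-centred data so that the
#' single-pass formula stays numerically benign for physiological
#' magnitudes.
#'
#' @param x,y `uniform_series` on a shared grid.
#' @param window_hours Window length in hours (3, 6, 12 or 24 in the
#'   standard configuration).
#' @param min_valid Minimum fraction of pairwise-complete samples per
#'   window.
#' @return A `correlation_track`: list with `pair`, `window_hours`,
#'   `times` (window start, seconds) and `corr` (with `NA` for gated
#'   windows).
#' @export
rolling_correlation <- function(x, y, window_hours, min_valid = 0.9) {
  if (!isTRUE(all.equal(x$dt, y$dt)) ||
      !isTRUE(all.equal(x$start_time, y$start_time)) ||
      length(x$values) != length(y$values)) {
    stop("rolling_correlation: x and y must share the sampling grid")
  }
  n <- length(x$values)
  w <- as.integer(round(window_hours * 3600 / x$dt))
  if (w < 2L || w > n) stop("window of ", window_hours,
                            " h does not fit the record")
  ok <- !is.na(x$values) & !is.na(y$values)
  xv <- ifelse(ok, x$values, 0)
  yv <- ifelse(ok, y$values, 0)
  xv[ok] <- xv[ok] - mean(xv[ok])
  yv[ok] <- yv[ok] - mean(yv[ok])

  roll <- function(v) {
    cs <- cumsum(v)
    cs[w:n] - c(0, cs[seq_len(n - w)])
  }
  nv <- roll(as.numeric(ok))
  sx <- roll(xv);      sy <- roll(yv)
  sxx <- roll(xv^2);   syy <- roll(yv^2);   sxy <- roll(xv * yv)

  num <- sxy - sx * sy / nv
  varx <- sxx - sx^2 / nv
  vary <- syy - sy^2 / nv
  eps <- 1e-12
  defined <- nv >= min_valid * w & varx > eps & vary > eps
  corr <- rep(NA_real_, length(num))
  corr[defined] <- pmin(1, pmax(-1, num[defined] /
                                  sqrt(varx[defined] * vary[defined])))
  structure(list(pair = c(x$name, y$name), window_hours = window_hours,
                 dt = x$dt,
                 times = x$start_time + (seq_len(n - w + 1L) - 1L) * x$dt,
                 corr = corr),
            class = "correlation_track")
}

#' @export
print.correlation_track <- function(x, ...) {
  cat(sprintf("<correlation_track> %s-%s, %g-h window: %d values (%.1f%% defined)\n",
              x$pair[1L], x$pair[2L], x$window_hours, length(x$corr),
              100 * mean(!is.na(x$corr))))
  invisible(x)
}

#' Zero-crossing rate of a correlation sequence
#'
#' ZCR = (1 / (N - 1)) * sum_n |sgn(corr[n]) - sgn(corr[n-1])|, evaluated
#' literally with sgn(0) = 0 over the defined (non-missing) values in
#' order. A full sign flip contributes 2, a transition through an exact
#' zero contributes 1, so the value lies in [0, 2]. Quantifies how
#' frequently the correlation changes sign.
#'
#' @param corr Numeric vector of correlation values; `NA`s are dropped
#'   before evaluation.
#' @return ZCR in `[0, 2]`, or `NA` when fewer than 2 defined values
#'   remain.
#' @export
zcr <- function(corr) {
  v <- corr[!is.na(corr)]
  if (length(v) < 2L) return(NA_real_)
  sum(abs(diff(sign(v)))) / (length(v) - 1L)
}

#' MEAN / STD / ZCR variability metrics per time bin
#'
#' Divides the record's time axis into consecutive non-overlapping bins of
#' length `window_hours` (anchored at time zero, `ceil(total_hours / W)`
#' bins) and computes, over the defined correlation values whose window
#' start falls in each bin, the mean (MEAN), sample standard deviation
#' (STD) and zero-crossing rate (ZCR). A bin with fewer than 2 defined
#' values yields missing metrics. Because correlation windows must lie
#' fully inside the record, the last bin is computed from the few windows
#' starting in it (typically one) and is therefore missing by this rule.
#'
#' @param track A `correlation_track`.
#' @param total_hours Length of the binned axis in hours (72 for the
#'   standard record).
#' @return Data frame with columns `pair`, `window_h`, `metric`,
#'   `bin_index` (0-based), `bin_start_h`, `value`.
#' @export
variability_metrics <- function(track, total_hours = 72) {
  w <- track$window_hours
  n_bins <- ceiling(total_hours / w)
  bin_of <- pmin(floor(track$times / 3600 / w), n_bins - 1L)
  out <- vector("list", n_bins)
  for (b in seq_len(n_bins) - 1L) {
    v <- track$corr[bin_of == b & !is.na(track$corr)]
    vals <- if (length(v) >= 2L) {
      c(MEAN = mean(v), STD = stats::sd(v), ZCR = zcr(v))
    } else {
      c(MEAN = NA_real_, STD = NA_real_, ZCR = NA_real_)
    }
    out[[b + 1L]] <- data.frame(
      pair = paste(track$pair, collapse = "-"),
      window_h = w, metric = names(vals), bin_index = b,
      bin_start_h = b * w, value = unname(vals),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Variability metrics for all six pairs of a trend record
#'
#' Runs [rolling_correlation()] and [variability_metrics()] for every
#' ANS x hemodynamics pair of a (QC-passed, gap-interpolated) record.
#'
#' @param record A `trend_record`.
#' @param window_hours Correlation window / bin length in hours.
#' @param min_valid Completeness gate passed to [rolling_correlation()].
#' @param interpolate Apply [interpolate_gaps()] to each channel first.
#' @return Data frame as [variability_metrics()] with a `patient_id`
#'   column prepended.
#' @export
transient_features <- function(record, window_hours, min_valid = 0.9,
                               interpolate = TRUE) {
  chans <- record$channels
  if (interpolate) chans <- lapply(chans, interpolate_gaps)
  total_hours <- record_hours(record)
  pairs <- signal_pairs()
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    track <- rolling_correlation(chans[[pairs$ans[i]]],
                                 chans[[pairs$hemo[i]]],
                                 window_hours, min_valid = min_valid)
    variability_metrics(track, total_hours = total_hours)
  })
  res <- do.call(rbind, res)
  cbind(patient_id = record$patient_id, res, stringsAsFactors = FALSE)
}
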