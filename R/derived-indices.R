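# Waveform-level estimators: spectral heart rate, beat detection,
# baroreflex sensitivity by the time-domain cross-correlation method, the
# pressure reactivity index, and 60-s trend averaging.

#' Raw 200-Hz ABP/ICP waveform record
#'
#' @param patient_id Identifier.
#' @param abp,icp `uniform_series` on a shared grid (typically 200 Hz).
#' @return A `waveform_record`.
#' @export
waveform_record <- function(patient_id, abp, icp) {
  stopifnot(inherits(abp, "uniform_series"), inherits(icp, "uniform_series"),
            isTRUE(all.equal(abp$dt, icp$dt)),
            length(abp$values) == length(icp$values))
  structure(list(patient_id = patient_id, abp = abp, icp = icp),
            class = "waveform_record")
}

#' Spectral heart-rate estimate from an ABP segment
#'
#' The heart rate is taken as 60 times the frequency of the largest
#' magnitude-spectrum peak of the linearly detrended segment within the
#' cardiac band (default 0.67-2.33 Hz, i.e. 40-140 bpm). The estimate is
#' missing when the in-band peak does not rise above a noise floor,
#' defined as `floor_ratio` times the largest non-DC spectral magnitude of
#' the whole segment, or when the segment is shorter than `min_duration`.
#'
#' Invariant to constant offsets and to amplitude scaling of the input.
#'
#' @param abp_segment A `uniform_series` (waveform scale).
#' @param band Search band in Hz.
#' @param min_duration Minimum segment length in seconds.
#' @param floor_ratio In-band peak acceptance threshold relative to the
#'   global spectral peak.
#' @return Heart rate in bpm, or `NA` when no credible cardiac peak.
#' @export
estimate_hr_fft <- function(abp_segment, band = c(0.67, 2.33),
                            min_duration = 30, floor_ratio = 0.25) {
  v <- abp_segment$values
  n <- length(v)
  if (n * abp_segment$dt < min_duration || anyNA(v)) return(NA_real_)
  t <- seq_len(n)
  v <- stats::residuals(stats::lm.fit(cbind(1, t), v))  # linear detrend
  mag <- Mod(stats::fft(v))[seq_len(floor(n / 2) + 1L)]
  freq <- (seq_along(mag) - 1L) / (n * abp_segment$dt)
  in_band <- freq >= band[1L] & freq <= band[2L]
  non_dc <- freq > 0
  if (!any(in_band) || max(mag[non_dc]) == 0) return(NA_real_)
  peak <- max(mag[in_band])
  if (peak < floor_ratio * max(mag[non_dc])) return(NA_real_)
  60 * freq[in_band][which.max(mag[in_band])]
}

#' Detect cardiac beats in an ABP waveform
#'
#' The slow baseline (respiratory, Mayer and B-waves) is removed with a
#' centred moving average (default 1 s) and local maxima of the residual
#' pulsatile component are accepted when they exceed `min_prominence`
#' times its 95th percentile, with a refractory period (default 0.25 s)
#' between beats. Each accepted peak defines a beat; the raw signal value
#' at the peak is the systolic pressure (SBP) and consecutive peak times
#' give the interbeat interval (IBI, ms). A flat signal yields an empty
#' beat series.
#'
#' @param abp A `uniform_series` waveform.
#' @param refractory_s Minimum beat spacing in seconds.
#' @param min_prominence Acceptance threshold as a fraction of the
#'   detrended signal's 95th percentile.
#' @param baseline_s Moving-average window for baseline removal, seconds.
#' @return A `beat_series`: data frame with `beat_times` (s), `sbp` (mmHg)
#'   and `ibi` (ms; `NA` for the first beat).
#' @export
detect_beats <- function(abp, refractory_s = 0.25, min_prominence = 0.5,
                         baseline_s = 1) {
  v <- abp$values
  empty <- data.frame(beat_times = numeric(0), sbp = numeric(0),
                      ibi = numeric(0))
  class(empty) <- c("beat_series", "data.frame")
  width <- max(3L, round(baseline_s / abp$dt))
  if (width %% 2L == 0L) width <- width + 1L
  baseline <- stats::filter(v, rep(1 / width, width), sides = 2)
  baseline[is.na(baseline)] <- mean(v)
  d <- v - as.numeric(baseline)
  amp <- stats::quantile(d, 0.95, names = FALSE, na.rm = TRUE)
  if (!is.finite(amp) || amp < 1e-8) return(empty)
  pk <- pracma::findpeaks(d,
                          minpeakheight = min_prominence * amp,
                          minpeakdistance = max(1L, round(refractory_s / abp$dt)))
  if (is.null(pk)) return(empty)
  idx <- sort(pk[, 2L])
  times <- abp$start_time + (idx - 1L) * abp$dt
  out <- data.frame(beat_times = times, sbp = v[idx],
                    ibi = c(NA_real_, diff(times) * 1000))
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Baroreflex sensitivity by the cross-correlation method
#'
#' SBP and IBI beat series are resampled onto a 1-s grid; within each
#' non-overlapping 10-s segment, the correlation between IBI and SBP
#' delayed by each integer lag in `lags` (default 0-5 s) is computed. At
#' the lag maximising the correlation -- required to be positive, since
#' baroreflex coupling drives IBI up with systolic pressure -- the
#' regression slope of IBI on the lagged SBP is taken as the segment's
#' BRS. Segment estimates are averaged into the returned value. Segments
#' with zero variance or a non-positive best correlation are missing.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @param segment_s Segment length in seconds.
#' @param lags Integer lags searched, in seconds.
#' @param min_corr Optional significance gate on the best correlation
#'   (disabled by default; set e.g. 0.6 to require a clear match).
#' @return Mean BRS in ms/mmHg with a `"segments"` attribute (data frame
#'   of per-segment `lag`, `corr`, `slope`), or `NA` when no segment
#'   qualifies.
#' @export
estimate_brs_xcorr <- function(beats, segment_s = 10, lags = 0:5,
                               min_corr = 0) {
  if (nrow(beats) < 3L ||
      diff(range(beats$beat_times)) < segment_s) return(NA_real_)
  t0 <- ceiling(beats$beat_times[1L])
  t1 <- floor(beats$beat_times[nrow(beats)])
  if (t1 - t0 < segment_s) return(NA_real_)
  grid <- seq(t0, t1, by = 1)
  sbp <- stats::approx(beats$beat_times, beats$sbp, xout = grid)$y
  keep <- !is.na(beats$ibi)
  ibi <- stats::approx(beats$beat_times[keep], beats$ibi[keep],
                       xout = grid, rule = 2)$y
  offset <- max(lags)  # so every lag is evaluable in every segment
  n_seg <- floor((length(grid) - offset) / segment_s)
  if (n_seg < 1L) return(NA_real_)
  segs <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    idx <- offset + (((s - 1L) * segment_s + 1L):(s * segment_s))
    best <- list(corr = -Inf, lag = NA_integer_, slope = NA_real_)
    for (lag in lags) {
      src <- idx - lag
      if (src[1L] < 1L) next
      xs <- sbp[src]; ys <- ibi[idx]
      if (stats::sd(xs) < 1e-10 || stats::sd(ys) < 1e-10) next
      r <- stats::cor(xs, ys)
      if (r > best$corr) {
        best <- list(corr = r, lag = lag,
                     slope = stats::cov(xs, ys) / stats::var(xs))
      }
    }
    segs[[s]] <- if (is.finite(best$corr) && best$corr > min_corr) {
      data.frame(segment = s, lag = best$lag, corr = best$corr,
                 slope = best$slope)
    } else NULL
  }
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0L) return(NA_real_)
  structure(mean(segs$slope), segments = segs)
}

#' Pressure reactivity index (PRx)
#'
#' The Pearson correlation between slow-wave oscillations of ABP and ICP:
#' both channels are reduced to consecutive 10-s means, and PRx at each
#' 10-s update is the correlation of the 30 most recent means (a 5-min
#' moving window). Values where either channel has zero variance within
#' the window are missing. Positive PRx indicates impaired cerebrovascular
#' pressure reactivity.
#'
#' @param abp,icp Co-registered `uniform_series` waveforms.
#' @param pre_avg_s Pre-averaging bin in seconds.
#' @param n_means Number of consecutive means correlated per update.
#' @return A `uniform_series` named `"prx"` with `dt = pre_avg_s`, one
#'   value per update, labelled by the start of the 5-min window.
#' @export
compute_prx <- function(abp, icp, pre_avg_s = 10, n_means = 30L) {
  stopifnot(isTRUE(all.equal(abp$dt, icp$dt)),
            length(abp$values) == length(icp$values))
  per_bin <- round(pre_avg_s / abp$dt)
  n_bins <- floor(length(abp$values) / per_bin)
  if (n_bins < n_means) stop("record shorter than one PRx window")
  bin_mean <- function(v) {
    colMeans(matrix(v[seq_len(n_bins * per_bin)], nrow = per_bin))
  }
  a <- bin_mean(abp$values)
  b <- bin_mean(icp$values)
  prx <- rep(NA_real_, n_bins - n_means + 1L)
  for (i in seq_along(prx)) {
    idx <- i:(i + n_means - 1L)
    if (stats::sd(a[idx]) > 1e-10 && stats::sd(b[idx]) > 1e-10) {
      prx[i] <- stats::cor(a[idx], b[idx])
    }
  }
  uniform_series(prx, dt = pre_avg_s, start_time = abp$start_time,
                 name = "prx", units = "")
}

#' Non-overlapping 60-s trend averaging
#'
#' Reduces a series to consecutive window means. A bin whose source
#' samples are more than 50% missing is missing; otherwise the mean of
#' the observed samples is used.
#'
#' @param series A `uniform_series` whose `dt` divides the window.
#' @param window_s Averaging window in seconds.
#' @return A `uniform_series` on the window grid.
#' @export
trend_average <- function(series, window_s = 60) {
  per_bin <- window_s / series$dt
  if (abs(per_bin - round(per_bin)) > 1e-9) {
    stop("dt must divide the averaging window")
  }
  per_bin <- as.integer(round(per_bin))
  n_bins <- floor(length(series$values) / per_bin)
  m <- matrix(series$values[seq_len(n_bins * per_bin)], nrow = per_bin)
  miss <- colMeans(is.na(m))
  out <- colMeans(m, na.rm = TRUE)
  out[miss > 0.5] <- NA_real_
  out[is.nan(out)] <- NA_real_
  uniform_series(out, dt = window_s, start_time = series$start_time,
                 name = series$name, units = series$units)
}

#' Derive the 60-s trend channels from a waveform record
#'
#' Produces the five trend channels from raw ABP/ICP: ABP and ICP are
#' 60-s means of the waveforms; HR is [estimate_hr_fft()] per 60-s
#' segment; BRS is [estimate_brs_xcorr()] on the beats of each 60-s
#' segment; PRx is [compute_prx()] reduced to the 60-s grid by
#' [trend_average()].
#'
#' @param wf A `waveform_record`.
#' @param ... Passed to the estimators (`band`, `lags`, ...).
#' @return A `trend_record` covering the full 60-s bins of the waveform.
#' @export
derive_trend_record <- function(wf, ...) {
  dt <- wf$abp$dt
  per_min <- as.integer(round(60 / dt))
  n_bins <- floor(length(wf$abp$values) / per_min)
  if (n_bins < 1L) stop("waveform shorter than one 60-s bin")
  hr <- brs <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1L) * per_min + 1L):(b * per_min)
    seg <- uniform_series(wf$abp$values[idx], dt = dt,
                          start_time = wf$abp$start_time + (b - 1L) * 60,
                          name = "abp", units = "mmHg")
    hr[b] <- estimate_hr_fft(seg, ...)
    brs_b <- estimate_brs_xcorr(detect_beats(seg))
    brs[b] <- as.numeric(brs_b)
  }
  prx_10s <- compute_prx(wf$abp, wf$icp)
  prx_60 <- trend_average(prx_10s, 60)
  nv <- function(v, name, units) {
    uniform_series(v[seq_len(n_bins)], dt = 60,
                   start_time = wf$abp$start_time, name = name, units = units)
  }
  pad <- function(v) c(v, rep(NA_real_, max(0L, n_bins - length(v))))
  trend_record(wf$patient_id, list(
    abp = trend_average(wf$abp, 60),
    hr = nv(hr, "hr", "bpm"),
    brs = nv(brs, "brs", "ms/mmHg"),
    icp = trend_average(wf$icp, 60),
    prx = nv(pad(prx_60$values), "prx", "")))
}
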