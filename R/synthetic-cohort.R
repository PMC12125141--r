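# Synthetic multimodal-neuromonitoring cohort: raw ABP/ICP waveform
# segments for estimator validation, 60-s trend records with a
# controllable group difference in the sign-switch rate of ANS-
# hemodynamics coupling, clinical metadata matched to published cohort
# distributions, and gap injection for QC fixtures.
#
# All generator choices are stand-ins with the statistical structure the
# analysis assumes; they are not reconstructions of any patient data.

derive_seed <- function(seed, stage, index = 0L) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729 + index) %% 2147483629)
}

# Band-limited random oscillation: sum of k random sinusoids with
# frequencies in `band`, rescaled to standard deviation `sd`.
band_limited_wave <- function(t, band, sd = 1, k = 8L) {
  if (sd <= 0) return(rep(0, length(t)))
  f <- stats::runif(k, band[1L], band[2L])
  ph <- stats::runif(k, 0, 2 * pi)
  amp <- stats::runif(k, 0.3, 1)
  w <- colSums(amp * sin(outer(2 * pi * f, t) + ph))
  w <- w - mean(w)
  s <- stats::sd(w)
  if (s < 1e-12) return(rep(0, length(t)))
  w * sd / s
}

#' Parameters of the synthetic ABP/ICP waveform generator
#'
#' @param duration Segment length in seconds.
#' @param sampling_rate Hz (default 200).
#' @param mean_abp Mean arterial pressure, mmHg.
#' @param pulse_freq Cardiac fundamental, Hz.
#' @param pulse_amp Pulse pressure excursion above the mean, mmHg.
#' @param resp_freq,resp_amp Respiratory oscillation (Hz, mmHg).
#' @param mayer_freq,mayer_amp Mayer-wave oscillation (~0.1 Hz, mmHg).
#' @param slow_band,slow_amp Band-limited slow (B-) waves: frequency
#'   interval in Hz and standard deviation in mmHg.
#' @param brs_gain Baroreflex gain, ms/mmHg: slope of IBI on systolic
#'   pressure.
#' @param brs_delay Baroreflex response delay in seconds (0-5).
#' @param icp_mean Mean ICP, mmHg.
#' @param icp_slow_coupling In [-1, 1]; determines the sign and strength
#'   of the shared slow component between ABP and ICP (hence the sign of
#'   PRx).
#' @param icp_slow_amp,icp_pulse_amp ICP slow-wave and pulsatile
#'   amplitudes, mmHg.
#' @param noise_sd Additive white measurement noise, mmHg.
#' @param seed RNG seed.
#' @return A `waveform_params` list.
#' @export
waveform_params <- function(duration = 600, sampling_rate = 200,
                            mean_abp = 84, pulse_freq = 1.3, pulse_amp = 20,
                            resp_freq = 0.25, resp_amp = 2,
                            mayer_freq = 0.1, mayer_amp = 2,
                            slow_band = c(0.005, 0.05), slow_amp = 3,
                            brs_gain = 6, brs_delay = 1,
                            icp_mean = 11, icp_slow_coupling = 0.5,
                            icp_slow_amp = 2, icp_pulse_amp = 1.5,
                            noise_sd = 0.5, seed = 1L) {
  stopifnot(duration > 0, sampling_rate > 0,
            sampling_rate > 2 * pulse_freq,
            brs_delay >= 0, brs_delay <= 5,
            icp_slow_coupling >= -1, icp_slow_coupling <= 1)
  structure(as.list(environment()), class = "waveform_params")
}

#' Generate a synthetic ABP/ICP waveform segment
#'
#' ABP is a baseline (mean + respiratory + Mayer + band-limited slow
#' waves) plus a pulsatile component rendered as harmonics of the beat
#' phase, plus white noise. Beat timing is generated sequentially so that
#' each interbeat interval responds to the systolic envelope `brs_delay`
#' seconds earlier with slope `brs_gain` (ms/mmHg). ICP shares the slow
#' component scaled by `icp_slow_coupling` (mixed with an independent
#' slow wave so the coupling coefficient is the slow-wave correlation),
#' plus its own pulsatility and noise.
#'
#' The record carries the ground-truth beat times, IBI sequence, systolic
#' envelope and parameters in attribute `"truth"` for recovery tests.
#'
#' @param params A `waveform_params` object.
#' @return A `waveform_record` with attribute `"truth"`.
#' @export
gen_waveform <- function(params) {
  stopifnot(inherits(params, "waveform_params"))
  p <- params
  set.seed(p$seed)
  dt <- 1 / p$sampling_rate
  t <- seq(0, p$duration - dt, by = dt)

  slow_shared <- band_limited_wave(t, p$slow_band, p$slow_amp)
  slow_indep <- band_limited_wave(t, p$slow_band, p$slow_amp)
  baseline <- p$mean_abp +
    p$resp_amp * sin(2 * pi * p$resp_freq * t) +
    p$mayer_amp * sin(2 * pi * p$mayer_freq * t) +
    slow_shared
  # Systolic envelope: pressure at the beat peaks.
  sbp_env <- baseline + p$pulse_amp
  env_at <- stats::approxfun(t, sbp_env, rule = 2)

  # Sequential beat generation: the interbeat interval ending at beat
  # k+1 responds to the systolic envelope brs_delay seconds before that
  # beat (IBI is conventionally time-stamped at the closing beat).
  base_ibi <- 1000 / p$pulse_freq
  ref_sbp <- p$mean_abp + p$pulse_amp
  beat_times <- numeric(ceiling(p$duration * p$pulse_freq * 2) + 2L)
  ibis <- numeric(length(beat_times))
  beat_times[1L] <- 0
  ibis[1L] <- NA_real_
  k <- 1L
  while (beat_times[k] < p$duration) {
    ibi <- base_ibi + p$brs_gain *
      (env_at(max(beat_times[k] + base_ibi / 1000 - p$brs_delay, 0)) -
         ref_sbp)
    ibi <- max(ibi, 250)  # physiological floor, 240 bpm
    k <- k + 1L
    beat_times[k] <- beat_times[k - 1L] + ibi / 1000
    ibis[k] <- ibi
  }
  beat_times <- beat_times[seq_len(k)]
  ibis <- ibis[seq_len(k)]

  # Beat phase in [0, 1) and a pulse shape peaking at phase 0 with zero
  # mean over the cycle.
  beat_idx <- findInterval(t, beat_times)
  beat_idx[beat_idx < 1L] <- 1L
  beat_idx[beat_idx >= length(beat_times)] <- length(beat_times) - 1L
  phase <- (t - beat_times[beat_idx]) /
    (beat_times[beat_idx + 1L] - beat_times[beat_idx])
  pulse_shape <- 0.6 * cos(2 * pi * phase) + 0.25 * cos(4 * pi * phase) +
    0.15 * cos(6 * pi * phase)

  abp <- baseline + p$pulse_amp * pulse_shape +
    stats::rnorm(length(t), 0, p$noise_sd)

  cpl <- p$icp_slow_coupling
  icp_slow <- (cpl * slow_shared + sqrt(1 - cpl^2) * slow_indep) *
    (p$icp_slow_amp / max(p$slow_amp, 1e-12))
  icp <- p$icp_mean + icp_slow + p$icp_pulse_amp * pulse_shape +
    stats::rnorm(length(t), 0, p$noise_sd)

  rec <- waveform_record(
    patient_id = sprintf("wf_seed%d", p$seed),
    abp = uniform_series(abp, dt = dt, name = "abp", units = "mmHg"),
    icp = uniform_series(icp, dt = dt, name = "icp", units = "mmHg"))
  attr(rec, "truth") <- list(params = p, beat_times = beat_times,
                             ibi = ibis, sbp_env = sbp_env,
                             slow_shared = slow_shared, time = t)
  rec
}

#' Parameters of the synthetic trend-level cohort
#'
#' Defaults emulate a 41-patient severe-TBI cohort with 14 patients at
#' risk of PSH. Channel baselines follow the published cohort medians
#' (ABP 84 mmHg, HR 78 bpm, BRS 6.8 ms/mmHg, ICP 11 mmHg, PRx 0.05);
#' between-patient spreads are set from the printed interquartile ranges.
#' Minute-scale within-patient fluctuation is AR(1) noise. The HR-ICP
#' and HR-PRx pairs carry a latent two-state (+/- magnitude) coupling
#' whose sign switches as a hardcore renewal process (refractory gap plus
#' an exponential): rate `lambda_base` switches/hour for everyone, with
#' an additional early unstable phase at rate `lambda_at_risk_early` over
#' hours `early_start`-`early_end` for the at-risk group only. The phase
#' is positioned so the induced sign changes of the 3-h rolling
#' correlation fall in the first 3-h feature bin, injecting the group
#' difference in correlation-sign instability that the risk model is
#' designed to reward.
#'
#' @param n_patients Cohort size (default 41).
#' @param n_at_risk Patients labelled at risk of PSH (default 14).
#' @param duration_hours Record length (default 72).
#' @param channel_baselines Data frame `channel, location, between_sd,
#'   within_sd` for the five trend channels.
#' @param coupling_pairs Data frame `ans, hemo, magnitude, lambda_base,
#'   lambda_at_risk_early, early_start, early_end, refractory_h` (rates
#'   in switches/hour, phase bounds in hours).
#' @param ar1_phi Lag-1 autocorrelation of the minute-scale fluctuation.
#' @param missing_spec Default gap specification applied by
#'   [inject_gaps()] when simulating records: `list(frac=, mean_len=)`.
#' @param seed RNG seed fanned out to per-patient streams.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 41L, n_at_risk = 14L,
                          duration_hours = 72,
                          channel_baselines = default_channel_baselines(),
                          coupling_pairs = default_coupling_pairs(),
                          ar1_phi = 0.6,
                          missing_spec = list(frac = 0.02, mean_len = 3),
                          seed = 1L) {
  stopifnot(n_at_risk <= n_patients, n_at_risk >= 0,
            all(coupling_pairs$lambda_base >= 0),
            all(coupling_pairs$lambda_at_risk_early >= 0))
  structure(as.list(environment()), class = "cohort_params")
}

#' @rdname cohort_params
#' @export
default_channel_baselines <- function() {
  data.frame(
    channel = c("abp", "hr", "brs", "icp", "prx"),
    location = c(84, 78, 6.8, 11, 0.05),
    between_sd = c(5.9, 11.9, 3.0, 5.2, 0.13),
    within_sd = c(5, 4, 1.5, 2, 0.15),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_params
#' @export
default_coupling_pairs <- function() {
  pairs <- signal_pairs()
  key <- paste(pairs$ans, pairs$hemo, sep = "-")
  # HR carries the switching coupling; the remaining pairs have stable
  # weak coupling (slow-wave transmission, strongest for ABP-ICP).
  pairs$magnitude <- c(`hr-icp` = 0.7, `abp-icp` = 0.45, `brs-icp` = 0.4,
                       `hr-prx` = 0.7, `abp-prx` = 0.4,
                       `brs-prx` = 0.4)[key]
  switching <- pairs$ans == "hr"
  pairs$lambda_base <- ifelse(switching, 0.02, 0)
  pairs$lambda_at_risk_early <- ifelse(switching, 3, 0)
  pairs$early_start <- 1.5
  pairs$early_end <- 4.5
  pairs$refractory_h <- 1.6
  pairs
}

# Hardcore-renewal switch times: consecutive sign reversals are separated
# by a refractory gap plus an exponential with the configured rate, so
# reversals are resolvable at the correlation-window scale (a pure Poisson
# process yields switch pairs that cancel inside the sliding window). The
# at-risk elevation runs over [early_start, early_end] so its induced
# zero crossings of the W-long rolling correlation land in the first
# feature bin of window starts.
switch_times <- function(duration_h, lambda_base, lambda_early,
                         early_start = 1.5, early_end = 4.5,
                         refractory_h = 0.75) {
  draw <- function(rate, from, to) {
    if (rate <= 0 || to <= from) return(numeric(0))
    times <- numeric(0)
    t <- from
    repeat {
      t <- t + refractory_h + stats::rexp(1L, rate)
      if (t >= to) break
      times <- c(times, t)
    }
    times
  }
  base <- draw(lambda_base, 0, duration_h)
  early <- if (lambda_early > lambda_base) {
    draw(lambda_early, max(early_start - refractory_h, 0),
         min(early_end, duration_h))
  } else numeric(0)
  sort(c(base, early))
}

ar1_noise <- function(n, phi) {
  as.numeric(stats::arima.sim(list(ar = phi), n = n,
                              sd = sqrt(1 - phi^2)))
}

#' Generate one patient's 60-s trend record
#'
#' Each channel is a patient-specific baseline plus AR(1) minute-scale
#' fluctuation. For every configured coupling pair the hemodynamic
#' channel's fluctuation is a mixture `sigma(t) * rho * e_ans +
#' sqrt(1 - rho^2) * eta`, where `sigma(t)` is the latent +/-1 coupling
#' sign switching at the group's Poisson rate, so the short-horizon
#' correlation of the pair tracks the latent sign. Ground-truth switch
#' times are stored in attribute `"truth"`.
#'
#' @param cohort A `cohort_params` object.
#' @param patient_index 1-based patient index (`<= n_patients`).
#' @param group `"at_risk"` or `"not_at_risk"`; by default patients
#'   `1..n_at_risk` are at risk.
#' @return A `trend_record` (fully observed; see [inject_gaps()]).
#' @export
gen_trend_record <- function(cohort, patient_index,
                             group = if (patient_index <= cohort$n_at_risk)
                               "at_risk" else "not_at_risk") {
  stopifnot(inherits(cohort, "cohort_params"),
            patient_index >= 1L, patient_index <= cohort$n_patients)
  group <- match.arg(group, c("at_risk", "not_at_risk"))
  set.seed(derive_seed(cohort$seed, 1L, patient_index))
  n <- as.integer(round(cohort$duration_hours * 60))
  cb <- cohort$channel_baselines

  baselines <- stats::setNames(
    stats::rnorm(nrow(cb), cb$location, cb$between_sd), cb$channel)
  baselines["brs"] <- max(baselines["brs"], 0.5)
  baselines["icp"] <- max(baselines["icp"], 1)
  baselines["prx"] <- min(max(baselines["prx"], -0.9), 0.9)

  e <- lapply(stats::setNames(cb$channel, cb$channel),
              function(ch) ar1_noise(n, cohort$ar1_phi))
  truth <- list(group = group, baselines = baselines, switches = list())

  time_h <- (seq_len(n) - 1L) / 60
  cp <- cohort$coupling_pairs
  # Each hemodynamic channel is composed from all its configured ANS
  # couplings plus an independent residual; requires sum(rho^2) <= 1.
  for (hemo in unique(cp$hemo)) {
    rows <- which(cp$hemo == hemo & cp$magnitude > 0)
    if (length(rows) == 0L) next
    total_var <- sum(cp$magnitude[rows]^2)
    if (total_var > 1) stop("sum of squared coupling magnitudes for ",
                            hemo, " exceeds 1")
    mix <- sqrt(1 - total_var) * ar1_noise(n, cohort$ar1_phi)
    for (i in rows) {
      rho <- cp$magnitude[i]
      lam_early <- if (group == "at_risk") cp$lambda_at_risk_early[i] else
        cp$lambda_base[i]
      sw <- switch_times(cohort$duration_hours, cp$lambda_base[i],
                         lam_early, cp$early_start[i], cp$early_end[i],
                         cp$refractory_h[i])
      sign0 <- sample(c(-1, 1), 1L)
      sigma <- sign0 * (-1)^findInterval(time_h, sw)
      mix <- mix + sigma * rho * e[[cp$ans[i]]]
      truth$switches[[paste(cp$ans[i], hemo, sep = "-")]] <-
        list(times_h = sw, sign0 = sign0, rho = rho)
    }
    e[[hemo]] <- mix
  }

  channels <- lapply(stats::setNames(cb$channel, cb$channel), function(ch) {
    w <- cb$within_sd[cb$channel == ch]
    v <- baselines[[ch]] + w * e[[ch]]
    if (ch == "prx") v <- pmin(pmax(v, -1), 1)
    if (ch %in% c("brs", "icp", "hr", "abp")) v <- pmax(v, 0.1)
    uniform_series(v, dt = 60, name = ch, units = TREND_UNITS[[ch]])
  })
  rec <- trend_record(sprintf("P%03d", patient_index), channels)
  attr(rec, "truth") <- truth
  rec
}

#' Generate clinical metadata for the cohort
#'
#' One row per patient. Numeric covariates are drawn from location/scale
#' families matched to published group medians and IQRs: log-normal for
#' the skewed WBC, age and ISS; normal for Hb; discrete uniform over the
#' printed IQR for the GCS sum score. Binary flags are Bernoulli at the
#' published group rates. WBC is group-dependent (at-risk median 20.3 vs
#' 14.2 * 10^3/ul), the cohort's one clearly separated admission marker.
#'
#' @param cohort A `cohort_params` object.
#' @return Data frame with columns `patient_id, psh_risk, age, sex_male,
#'   gcs_sum, iss, trauma_isolated, hb, wbc` and the six CT flags
#'   `ct_sdh, ct_edh, ct_tich, ct_edema, ct_dai, ct_tsah`.
#' @export
gen_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_params"))
  set.seed(derive_seed(cohort$seed, 2L))
  n <- cohort$n_patients
  risk <- as.integer(seq_len(n) <= cohort$n_at_risk)

  # log-normal matched to median m and IQR (q25, q75):
  # mu = log(m), sigma = log(q75 / q25) / (2 * qnorm(0.75))
  lsig <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))
  draw_ln <- function(m1, s1, m0, s0) {
    ifelse(risk == 1L, stats::rlnorm(n, log(m1), s1),
           stats::rlnorm(n, log(m0), s0))
  }
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    psh_risk = risk,
    age = round(draw_ln(33, lsig(28, 40), 38, lsig(28, 52))),
    sex_male = stats::rbinom(n, 1L, ifelse(risk == 1L, 1 - 0.357, 1 - 0.185)),
    gcs_sum = sample(4:8, n, replace = TRUE),
    iss = round(draw_ln(24, lsig(20, 34), 25, lsig(18, 41))),
    trauma_isolated = stats::rbinom(n, 1L, 0.39),
    hb = stats::rnorm(n, ifelse(risk == 1L, 13.2, 13.1),
                      ifelse(risk == 1L, 2.30, 2.74)),
    wbc = draw_ln(20.3, lsig(15.8, 21.9), 14.2, lsig(10.1, 17.4)),
    ct_sdh = stats::rbinom(n, 1L, ifelse(risk == 1L, 0.57, 0.41)),
    ct_edh = stats::rbinom(n, 1L, ifelse(risk == 1L, 0.01, 0.07)),
    ct_tich = stats::rbinom(n, 1L, ifelse(risk == 1L, 0.07, 0.30)),
    ct_edema = stats::rbinom(n, 1L, ifelse(risk == 1L, 0.71, 0.67)),
    ct_dai = stats::rbinom(n, 1L, ifelse(risk == 1L, 0.79, 0.81)),
    ct_tsah = stats::rbinom(n, 1L, ifelse(risk == 1L, 0.43, 0.59)),
    stringsAsFactors = FALSE)
}

#' Inject missing-data gaps into a trend record
#'
#' Either an explicit gap table (`missing_spec$gaps`: data frame
#' `channel, start, length` in samples) or a random specification
#' (`missing_spec$frac`: overall missing fraction per channel;
#' `missing_spec$mean_len`: geometric mean gap length in samples) is
#' applied. The realised per-channel missing fraction and maximum run
#' length are recorded in attribute `"gap_summary"`.
#'
#' @param record A `trend_record`.
#' @param missing_spec Gap specification (see above); `NULL` or
#'   `frac = 0` leaves the record unchanged.
#' @param seed RNG seed for random gap placement.
#' @return The record with the selected samples set to missing.
#' @export
inject_gaps <- function(record, missing_spec, seed = 1L) {
  if (is.null(missing_spec) ||
      (is.null(missing_spec$gaps) && (missing_spec$frac %||% 0) == 0)) {
    return(record)
  }
  n <- length(record$channels[[1L]]$values)
  if (!is.null(missing_spec$frac) && missing_spec$frac > 1) {
    stop("requested missing fraction exceeds 1")
  }
  set.seed(seed)
  if (!is.null(missing_spec$gaps)) {
    g <- missing_spec$gaps
    for (i in seq_len(nrow(g))) {
      idx <- g$start[i]:min(g$start[i] + g$length[i] - 1L, n)
      record$channels[[g$channel[i]]]$values[idx] <- NA_real_
    }
  } else {
    target <- missing_spec$frac * n
    mean_len <- missing_spec$mean_len %||% 3
    for (ch in names(record$channels)) {
      miss <- rep(FALSE, n)
      while (sum(miss) < target) {
        len <- 1L + stats::rgeom(1L, 1 / mean_len)
        start <- sample.int(n - len + 1L, 1L)
        miss[start:(start + len - 1L)] <- TRUE
      }
      record$channels[[ch]]$values[miss] <- NA_real_
    }
  }
  summ <- lapply(record$channels, function(s) {
    na <- is.na(s$values)
    r <- rle(na)
    list(missing_frac = mean(na),
         max_run = if (any(na)) max(r$lengths[r$values]) else 0L)
  })
  attr(record, "gap_summary") <- summ
  record
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the full synthetic cohort
#'
#' Generates metadata and one trend record per patient (gap injection per
#' `cohort$missing_spec`), with patients `1..n_at_risk` labelled at risk.
#'
#' @param cohort A `cohort_params` object.
#' @param inject_missing Apply [inject_gaps()] with the cohort's
#'   `missing_spec`.
#' @return List with `metadata` (data frame) and `records` (list of
#'   `trend_record`s named by patient id).
#' @export
simulate_cohort <- function(cohort, inject_missing = TRUE) {
  metadata <- gen_metadata(cohort)
  records <- lapply(seq_len(cohort$n_patients), function(i) {
    rec <- gen_trend_record(cohort, i)
    if (inject_missing) {
      rec <- inject_gaps(rec, cohort$missing_spec,
                         seed = derive_seed(cohort$seed, 3L, i))
    }
    rec
  })
  names(records) <- metadata$patient_id
  list(metadata = metadata, records = records)
}
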