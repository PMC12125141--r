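test_that("waveform generator rejects invalid parameters", {
  expect_error(waveform_params(duration = -5))
  expect_error(waveform_params(sampling_rate = 2, pulse_freq = 1.3))
  expect_error(waveform_params(icp_slow_coupling = 2))
})

test_that("a pure pulse tone has its spectral peak at the pulse frequency", {
  wp <- waveform_params(duration = 60, pulse_freq = 1.3, noise_sd = 0,
                        brs_gain = 0, resp_amp = 0, mayer_amp = 0,
                        slow_amp = 0, seed = 1)
  v <- gen_waveform(wp)$abp$values
  mag <- Mod(fft(v - mean(v)))[seq_len(length(v) / 2)]
  freq <- (seq_along(mag) - 1) / 60
  inb <- freq >= 0.67 & freq <= 2.33
  expect_equal(freq[inb][which.max(mag[inb])], 1.3, tolerance = 1 / 60)
})

test_that("full slow-wave coupling makes 10-s ABP/ICP means correlate +1", {
  wp <- waveform_params(duration = 300, icp_slow_coupling = 1, noise_sd = 0,
                        pulse_amp = 0, resp_amp = 0, mayer_amp = 0,
                        slow_amp = 3, icp_slow_amp = 3, brs_gain = 0, seed = 2)
  wf <- gen_waveform(wp)
  m10 <- function(v) colMeans(matrix(v, nrow = 2000))
  expect_equal(cor(m10(wf$abp$values), m10(wf$icp$values)), 1,
               tolerance = 1e-9)
})

test_that("ground-truth IBI regresses on the lagged envelope with slope brs_gain", {
  wp <- waveform_params(duration = 300, pulse_freq = 1.2, brs_gain = 6,
                        brs_delay = 1, noise_sd = 0, mayer_amp = 3,
                        resp_amp = 1, slow_amp = 2, seed = 3)
  wf <- gen_waveform(wp)
  tr <- attr(wf, "truth")
  env <- approxfun(tr$time, tr$sbp_env, rule = 2)
  k <- which(!is.na(tr$ibi) & tr$beat_times < 300)
  lagged_sbp <- env(tr$beat_times[k] - 1)
  fit <- lm(tr$ibi[k] ~ lagged_sbp)
  expect_equal(unname(coef(fit)[2]), 6, tolerance = 0.05)
})

test_that("trend generator is seed-deterministic and seed-sensitive", {
  cp <- small_cohort(3)
  a <- gen_trend_record(cp, 1)
  b <- gen_trend_record(cp, 1)
  expect_identical(a$channels$hr$values, b$channels$hr$values)
  c2 <- gen_trend_record(small_cohort(4), 1)
  expect_false(identical(a$channels$hr$values, c2$channels$hr$values))
})

test_that("generated records reproduce their configured baselines", {
  cp <- small_cohort(6)
  cb <- default_channel_baselines()
  devs <- sapply(1:10, function(i) {
    rec <- gen_trend_record(cp, i)
    vapply(cb$channel, function(ch) {
      mean(rec$channels[[ch]]$values) -
        attr(rec, "truth")$baselines[[ch]]
    }, numeric(1))
  })
  # within-record mean error is bounded by the AR(1) fluctuation scale
  expect_true(all(abs(rowMeans(devs)) < cb$within_sd / 2))
})

test_that("a never-switching positive coupling yields ZCR zero", {
  cp0 <- default_coupling_pairs()
  cp0$lambda_base[] <- 0
  cp0$lambda_at_risk_early[] <- 0
  cp <- cohort_params(n_patients = 4, n_at_risk = 2, coupling_pairs = cp0,
                      seed = 8)
  rec <- gen_trend_record(cp, 1)
  sw <- attr(rec, "truth")$switches
  expect_true(all(vapply(sw, function(s) length(s$times_h), integer(1)) == 0))
  hr <- interpolate_gaps(rec$channels$hr)
  icp <- interpolate_gaps(rec$channels$icp)
  track <- rolling_correlation(hr, icp, 3)
  sgn <- attr(rec, "truth")$switches[["hr-icp"]]$sign0
  expect_true(all(sign(track$corr) == sgn, na.rm = TRUE))
  expect_equal(zcr(track$corr), 0)
})

test_that("an uncoupled pair's rolling correlation is centred on zero", {
  cp0 <- default_coupling_pairs()
  cp0$magnitude[] <- 0
  cp <- cohort_params(n_patients = 2, n_at_risk = 1, coupling_pairs = cp0,
                      seed = 9)
  means <- sapply(1:8, function(i) {
    cp$seed <- 100 + i
    rec <- gen_trend_record(cp, 2)
    mean(rolling_correlation(rec$channels$hr, rec$channels$icp, 3)$corr,
         na.rm = TRUE)
  })
  # standard error of the mean across independent records
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
})

test_that("cohort-mean bin-0 ZCR is higher in the at-risk group", {
  ord <- sapply(1:6, function(s) {
    cp <- cohort_params(n_patients = 10, n_at_risk = 5, seed = 500 + s)
    z <- sapply(1:10, function(i) {
      tf <- transient_features(gen_trend_record(cp, i), 3)
      mean(tf$value[tf$metric == "ZCR" & tf$bin_index == 0 &
                      tf$pair %in% c("hr-icp", "hr-prx")], na.rm = TRUE)
    })
    mean(z[1:5]) > mean(z[6:10])
  })
  expect_true(all(ord))
})

test_that("estimated ZCR increases with the switch rate", {
  lambdas <- c(0, 0.3, 1, 3)
  mean_zcr <- sapply(lambdas, function(lam) {
    cp0 <- default_coupling_pairs()
    cp0$lambda_base[cp0$ans == "hr"] <- lam
    cp0$lambda_at_risk_early[] <- 0
    mean(sapply(1:6, function(s) {
      cp <- cohort_params(n_patients = 1, n_at_risk = 0,
                          coupling_pairs = cp0, seed = 900 + s)
      rec <- gen_trend_record(cp, 1)
      track <- rolling_correlation(rec$channels$hr, rec$channels$icp, 3)
      zcr(track$corr)
    }))
  })
  expect_equal(cor(mean_zcr, lambdas, method = "spearman"), 1)
})

test_that("metadata distributions match the configured cohort profile", {
  cp <- cohort_params(n_patients = 4000, n_at_risk = 1400, seed = 10)
  md <- gen_metadata(cp)
  expect_equal(median(md$wbc[md$psh_risk == 1]), 20.3, tolerance = 0.1)
  expect_equal(median(md$wbc[md$psh_risk == 0]), 14.2, tolerance = 0.1)
  expect_equal(1 - mean(md$sex_male), 0.24, tolerance = 0.1)
  expect_true(all(md$gcs_sum >= 3 & md$gcs_sum <= 15))

  none <- gen_metadata(cohort_params(n_patients = 20, n_at_risk = 0,
                                     seed = 11))
  expect_true(all(none$psh_risk == 0))
})

test_that("gap injection honours explicit specs and records a summary", {
  rec <- constant_record(n = 400)
  spec <- list(gaps = data.frame(channel = "hr",
                                 start = c(10, 100, 300), length = 5))
  out <- inject_gaps(rec, spec)
  gs <- attr(out, "gap_summary")
  expect_equal(gs$hr$max_run, 5)
  expect_equal(sum(is.na(out$channels$hr$values)), 15)
  # eligible for interpolation: QC passes
  expect_true(qc_passed(qc_record(out, required_hours = 0)))

  unchanged <- inject_gaps(rec, NULL)
  expect_identical(unchanged$channels$hr$values, rec$channels$hr$values)
  expect_error(inject_gaps(rec, list(frac = 1.5)), "fraction")
})

test_that("heavy missingness injected as one run fails QC downstream", {
  rec <- constant_record(n = 400)
  spec <- list(gaps = data.frame(channel = "icp", start = 1, length = 60))
  out <- inject_gaps(rec, spec)  # 15% of samples in one run
  expect_false(qc_passed(qc_record(out, required_hours = 0)))
})

test_that("random gap placement differs across seeds but not within one", {
  rec <- constant_record(n = 1000)
  spec <- list(frac = 0.05, mean_len = 3)
  a <- inject_gaps(rec, spec, seed = 1)
  b <- inject_gaps(rec, spec, seed = 1)
  c2 <- inject_gaps(rec, spec, seed = 2)
  expect_identical(is.na(a$channels$hr$values), is.na(b$channels$hr$values))
  expect_false(identical(is.na(a$channels$hr$values),
                         is.na(c2$channels$hr$values)))
})
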