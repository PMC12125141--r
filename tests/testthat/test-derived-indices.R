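tone <- function(freq, duration = 60, fs = 200, amp = 10, offset = 84) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  uniform_series(offset + amp * sin(2 * pi * freq * t), dt = 1 / fs,
                 name = "abp", units = "mmHg")
}

test_that("spectral HR finds the cardiac peak and respects the band", {
  expect_equal(estimate_hr_fft(tone(1.3)), 78, tolerance = 1e-6)
  expect_true(is.na(estimate_hr_fft(tone(0.25))))     # respiratory only
  expect_true(is.na(estimate_hr_fft(tone(1.3, duration = 20))))  # too short
})

test_that("HR picks the fundamental of a harmonic pulse train", {
  t <- seq(0, 60 - 1 / 200, by = 1 / 200)
  v <- 84 + 10 * sin(2 * pi * 1 * t) + 6 * sin(2 * pi * 2 * t) +
    3 * sin(2 * pi * 3 * t)
  s <- uniform_series(v, dt = 1 / 200, name = "abp")
  expect_equal(estimate_hr_fft(s), 60, tolerance = 1e-6)
  # independent oracle: direct spectrum argmax inside the band
  mag <- Mod(fft(v - mean(v)))[seq_len(length(v) / 2)]
  freq <- (seq_along(mag) - 1) / 60
  inb <- freq >= 0.67 & freq <= 2.33
  expect_equal(estimate_hr_fft(s), 60 * freq[inb][which.max(mag[inb])])
})

test_that("HR is invariant to offset and amplitude scaling", {
  base <- estimate_hr_fft(tone(1.7))
  expect_equal(estimate_hr_fft(tone(1.7, amp = 50, offset = 200)), base)
})

test_that("beat detection finds one beat per cycle and rejects flat input", {
  wp <- waveform_params(duration = 60, pulse_freq = 1, noise_sd = 0,
                        brs_gain = 0, resp_amp = 0, mayer_amp = 0,
                        slow_amp = 0, seed = 1)
  b <- detect_beats(gen_waveform(wp)$abp)
  expect_true(abs(nrow(b) - 60) <= 1)
  expect_equal(mean(b$ibi, na.rm = TRUE), 1000, tolerance = 0.01)

  flat <- uniform_series(rep(90, 2000), dt = 1 / 200, name = "abp")
  expect_equal(nrow(detect_beats(flat)), 0)
})

test_that("beat count matches the generator's ground truth", {
  wp <- waveform_params(duration = 120, pulse_freq = 1.2, brs_gain = 6,
                        brs_delay = 2, noise_sd = 0, seed = 3)
  wf <- gen_waveform(wp)
  truth <- attr(wf, "truth")
  n_true <- sum(truth$beat_times < 120)
  expect_true(abs(nrow(detect_beats(wf$abp)) - n_true) <= 2)
})

test_that("BRS recovers a constructed linear SBP-IBI relation at lag 1", {
  # IBI[k] = 800 + 6 * (SBP[k-1] - 120) on a 1-s beat grid
  set.seed(9)
  n <- 60
  sbp <- 120 + 5 * sin(2 * pi * 0.1 * (0:n)) + rnorm(n + 1, 0, 0.3)
  ibi <- c(NA, 800 + 6 * (sbp[1:n] - 120))
  beats <- data.frame(beat_times = 0:n, sbp = sbp, ibi = ibi)
  class(beats) <- c("beat_series", "data.frame")
  est <- estimate_brs_xcorr(beats)
  segs <- attr(est, "segments")
  # independent oracle: direct least squares at the true lag
  fitted <- coef(lm(ibi[-1] ~ sbp[1:n]))[2]
  expect_equal(as.numeric(est), as.numeric(fitted), tolerance = 0.05)
  expect_equal(as.numeric(est), 6, tolerance = 0.1)
  lag_mode <- as.integer(names(sort(table(segs$lag), decreasing = TRUE))[1])
  expect_equal(lag_mode, 1L)
})

test_that("BRS is missing for zero-variance segments", {
  beats <- data.frame(beat_times = 0:30, sbp = rep(120, 31),
                      ibi = c(NA, rep(800, 30)))
  class(beats) <- c("beat_series", "data.frame")
  expect_true(is.na(estimate_brs_xcorr(beats)))
})

test_that("BRS recovers gain 12 at delay 3 within 10% on clean waveforms", {
  ests <- vapply(1:10, function(s) {
    wp <- waveform_params(duration = 180, pulse_freq = 1.2, brs_gain = 12,
                          brs_delay = 3, noise_sd = 0, mayer_amp = 3,
                          resp_amp = 1, slow_amp = 2, seed = s)
    as.numeric(estimate_brs_xcorr(detect_beats(gen_waveform(wp)$abp)))
  }, numeric(1))
  expect_lt(abs(median(ests) - 12) / 12, 0.1)
})

test_that("PRx hits +/-1 for perfectly coupled slow waves", {
  for (cpl in c(1, -1)) {
    wp <- waveform_params(duration = 900, icp_slow_coupling = cpl,
                          noise_sd = 0, pulse_amp = 0, resp_amp = 0,
                          mayer_amp = 0, slow_amp = 3, brs_gain = 0,
                          seed = 4)
    wf <- gen_waveform(wp)
    prx <- compute_prx(wf$abp, wf$icp)
    expect_true(all(abs(prx$values - cpl) < 1e-8, na.rm = TRUE))
  }
})

test_that("PRx is bounded, affine-invariant and sign-flips under negation", {
  set.seed(5)
  a <- uniform_series(rnorm(12000, 84, 3), dt = 1 / 10, name = "abp")
  b <- uniform_series(rnorm(12000, 11, 2), dt = 1 / 10, name = "icp")
  p0 <- compute_prx(a, b)
  expect_true(all(abs(p0$values) <= 1, na.rm = TRUE))

  a2 <- a; a2$values <- 3 * a$values + 10
  expect_equal(compute_prx(a2, b)$values, p0$values, tolerance = 1e-9)
  a3 <- a; a3$values <- -2 * a$values
  expect_equal(compute_prx(a3, b)$values, -p0$values, tolerance = 1e-9)
})

test_that("trend averaging honours the 50% missing rule", {
  s <- uniform_series(rep(7, 300), dt = 1, name = "x")
  expect_true(all(trend_average(s)$values == 7))

  alt <- uniform_series(rep(c(0, 2), 60), dt = 1, name = "x")
  expect_equal(trend_average(alt)$values, c(1, 1))

  v <- rep(1, 120)
  v[1:36] <- NA                     # bin 1: 60% missing
  v[61:80] <- NA                    # bin 2: 33% missing
  out <- trend_average(uniform_series(v, dt = 1, name = "x"))$values
  expect_true(is.na(out[1]))
  expect_equal(out[2], 1)
})

test_that("waveform-to-trend derivation reproduces configured parameters", {
  wp <- waveform_params(duration = 600, pulse_freq = 1.3,
                        icp_slow_coupling = 1, noise_sd = 0, seed = 6)
  tr <- derive_trend_record(gen_waveform(wp))
  expect_equal(length(tr$channels$abp$values), 10)
  expect_equal(mean(tr$channels$hr$values, na.rm = TRUE), 78, tolerance = 0.5)
  expect_equal(mean(tr$channels$abp$values), 84, tolerance = 1)
  expect_equal(mean(tr$channels$icp$values), 11, tolerance = 1)
  expect_gt(mean(tr$channels$prx$values, na.rm = TRUE), 0.8)
})
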