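test_that("rolling correlation reproduces exact values on affine pairs", {
  set.seed(1)
  x <- trend_series(rnorm(600, 84, 5), name = "abp")
  y_same <- x; y_same$name <- "icp"
  expect_true(all(abs(rolling_correlation(x, y_same, 3)$corr - 1) < 1e-9))

  y_neg <- x
  y_neg$values <- -2 * x$values + 7
  y_neg$name <- "icp"
  expect_true(all(abs(rolling_correlation(x, y_neg, 3)$corr + 1) < 1e-9))
})

test_that("rolling correlation equals the naive per-window oracle", {
  # the full-scale oracle sweep lives in the acceptance suite; this is a
  # focused version including the 5-sample worked example
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(1, 2, 2, 5, 4)
  xs <- uniform_series(x5, dt = 60, name = "a")
  ys <- uniform_series(y5, dt = 60, name = "b")
  track <- rolling_correlation(xs, ys, window_hours = 3 / 60)  # 3 samples
  expect_equal(track$corr, naive_rolling_cor(x5, y5, 3), tolerance = 1e-12)

  set.seed(2)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    w <- sample(5:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- rolling_correlation(uniform_series(a, 60, name = "a"),
                               uniform_series(b, 60, name = "b"),
                               window_hours = w / 60)$corr
    expect_equal(got, naive_rolling_cor(a, b, w), tolerance = 1e-12)
  }
})

test_that("rolling correlation gates on completeness and variance", {
  set.seed(3)
  a <- rnorm(300); b <- rnorm(300)
  a[50:75] <- NA  # 26 of 180 samples missing in early windows (> 10%)
  t <- rolling_correlation(trend_series(a), trend_series(b, name = "y"), 3)
  expect_true(is.na(t$corr[1]))
  expect_false(anyNA(t$corr[100:121]))

  const <- trend_series(rep(5, 300))
  t2 <- rolling_correlation(const, trend_series(rnorm(300), name = "y"), 3)
  expect_true(all(is.na(t2$corr)))

  bad <- trend_series(rnorm(300), start_time = 60)
  expect_error(rolling_correlation(trend_series(rnorm(300)), bad, 3),
               "grid")
})

test_that("zcr evaluates the sign-change rate literally", {
  expect_equal(zcr(c(0.5, -0.2, -0.1, 0.3)), 4 / 3)
  expect_equal(zcr(rep(0.7, 50)), 0)
  expect_equal(zcr(c(-1, -2, -0.5)), 0)
  expect_equal(zcr(rep(c(1, -1), 20)), 2)
  expect_equal(zcr(c(0.5, NA, -0.2)), 2)   # missing values drop out
  expect_true(is.na(zcr(c(NA, 0.3))))      # fewer than 2 defined values
  expect_equal(zcr(c(1, 0, -1)), 1)        # sgn(0) = 0 contributes 1 + 1 over 2
})

test_that("zcr matches the brute-force counter on random sequences", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(2:100, 1)
    v <- sample(c(rnorm(n), 0, 0), n)
    expect_equal(zcr(v), brute_zcr(v), tolerance = 1e-12)
  }
})

test_that("variability metrics bin a constant track correctly", {
  x <- trend_series(rep(1, 4320))
  track <- list(pair = c("hr", "icp"), window_hours = 3, dt = 60,
                times = (seq_len(4141) - 1) * 60,
                corr = rep(0.5, 4141))
  class(track) <- "correlation_track"
  vm <- variability_metrics(track)
  expect_equal(nrow(vm), 24 * 3)
  full <- vm[vm$bin_index < 23, ]
  expect_true(all(full$value[full$metric == "MEAN"] == 0.5))
  expect_true(all(full$value[full$metric == "STD"] == 0))
  expect_true(all(full$value[full$metric == "ZCR"] == 0))
  # last bin holds a single window start, so its metrics are missing
  expect_true(all(is.na(vm$value[vm$bin_index == 23])))
})

test_that("within-bin metrics match direct formula evaluation", {
  vals <- c(0.4, -0.4, 0.4)
  track <- list(pair = c("hr", "icp"), window_hours = 3, dt = 60,
                times = c(0, 60, 120),
                corr = vals)
  class(track) <- "correlation_track"
  vm <- variability_metrics(track, total_hours = 3)
  expect_equal(vm$value[vm$metric == "MEAN"], mean(vals))
  expect_equal(vm$value[vm$metric == "STD"], sd(vals))
  expect_equal(vm$value[vm$metric == "ZCR"], brute_zcr(vals))
})

test_that("transient features cover 6 pairs x 3 metrics x ceil(72/W) bins", {
  rec <- gen_trend_record(small_cohort(5), 1)
  for (w in c(3, 24)) {
    tf <- transient_features(rec, w)
    expect_equal(nrow(tf), 6 * 3 * ceiling(72 / w))
    expect_setequal(unique(tf$pair),
                    paste(signal_pairs()$ans, signal_pairs()$hemo, sep = "-"))
  }
  tf <- transient_features(rec, 3)
  ok <- !is.na(tf$value)
  expect_true(all(tf$value[ok & tf$metric == "ZCR"] >= 0))
  expect_true(all(tf$value[ok & tf$metric == "ZCR"] <= 2))
  expect_true(all(abs(tf$value[ok & tf$metric == "MEAN"]) <= 1))
  expect_true(all(tf$value[ok & tf$metric == "STD"] >= 0))
})
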