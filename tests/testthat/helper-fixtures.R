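# Shared fixtures built in code.

# shorthand for a 60-s trend series
trend_series <- function(values, name = "x", start_time = 0) {
  uniform_series(values, dt = 60, start_time = start_time, name = name)
}

# fully observed trend record with constant channels
constant_record <- function(n = 4320, values = c(abp = 84, hr = 78,
                                                 brs = 6.8, icp = 11,
                                                 prx = 0.05)) {
  chans <- lapply(names(values), function(ch) {
    trend_series(rep(values[[ch]], n), name = ch)
  })
  names(chans) <- names(values)
  trend_record("TEST", chans)
}

# small cohort sized so stratified 5-fold CV is possible (>= 5 per class)
small_cohort <- function(seed = 1L, n = 16L, n_at_risk = 6L) {
  cohort_params(n_patients = n, n_at_risk = n_at_risk, seed = seed)
}

# naive per-window Pearson correlation, the independent oracle for
# rolling_correlation
naive_rolling_cor <- function(x, y, w) {
  n <- length(x)
  vapply(seq_len(n - w + 1L), function(s) {
    stats::cor(x[s:(s + w - 1L)], y[s:(s + w - 1L)])
  }, numeric(1))
}

# brute-force sign-change counter, the independent oracle for zcr()
brute_zcr <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  total <- 0
  for (i in 2:length(v)) {
    total <- total + abs(sign(v[i]) - sign(v[i - 1L]))
  }
  total / (length(v) - 1L)
}
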