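# Uniform time-series container, trend CSV dialect, gap interpolation and
# record-level quality control.

TREND_CHANNELS <- c("abp", "hr", "brs", "icp", "prx")
TREND_CSV_COLUMNS <- c("timestamp_s", "abp_mmhg", "hr_bpm",
                       "brs_ms_per_mmhg", "icp_mmhg", "prx")
TREND_UNITS <- c(abp = "mmHg", hr = "bpm", brs = "ms/mmHg",
                 icp = "mmHg", prx = "")

#' Regularly sampled series with explicit missingness
#'
#' The uniform container used by every pipeline stage. Samples are labelled
#' by interval start (0-based, half-open): sample `i` covers
#' `[start_time + (i-1) * dt, start_time + i * dt)` seconds. Missing values
#' are `NA` and are never silently dropped.
#'
#' @param values Numeric vector, `NA` marking missing samples.
#' @param dt Seconds per sample (> 0).
#' @param start_time Seconds from monitoring start of the first sample.
#' @param name Channel label.
#' @param units Unit string (e.g. `"mmHg"`).
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, dt, start_time = 0, name = "", units = "") {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            length(values) > 0L)
  structure(list(values = as.numeric(values), dt = dt,
                 start_time = start_time, name = name, units = units),
            class = "uniform_series")
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %s [%s]: %d samples, dt = %g s, %.1f%% missing\n",
              x$name, x$units, length(x$values), x$dt,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Sample times of a uniform series
#'
#' @param x A `uniform_series`.
#' @return Numeric vector of interval-start times in seconds.
#' @export
series_times <- function(x) {
  x$start_time + (seq_along(x$values) - 1L) * x$dt
}

#' Multichannel 60-s trend record
#'
#' Bundles the five trend channels (ABP, HR, BRS, ICP, PRx) on a shared
#' 60-s grid for one patient. All channels must agree in start time, dt
#' and length.
#'
#' @param patient_id Patient identifier (string).
#' @param channels Named list of five `uniform_series` with names
#'   `abp, hr, brs, icp, prx`.
#' @return An object of class `trend_record`.
#' @export
trend_record <- function(patient_id, channels) {
  stopifnot(setequal(names(channels), TREND_CHANNELS))
  channels <- channels[TREND_CHANNELS]
  ref <- channels[[1L]]
  for (ch in channels) {
    stopifnot(inherits(ch, "uniform_series"),
              isTRUE(all.equal(ch$dt, ref$dt)),
              isTRUE(all.equal(ch$start_time, ref$start_time)),
              length(ch$values) == length(ref$values))
  }
  structure(list(patient_id = patient_id, channels = channels),
            class = "trend_record")
}

#' @export
print.trend_record <- function(x, ...) {
  n <- length(x$channels[[1L]]$values)
  cat(sprintf("<trend_record> %s: %d samples x %d channels (%.1f h at %g s)\n",
              x$patient_id, n, length(x$channels),
              n * x$channels[[1L]]$dt / 3600, x$channels[[1L]]$dt))
  invisible(x)
}

#' Duration of a trend record in hours
#' @param record A `trend_record`.
#' @return Hours covered by the record.
#' @export
record_hours <- function(record) {
  ch <- record$channels[[1L]]
  length(ch$values) * ch$dt / 3600
}

#' Write a trend record to CSV
#'
#' Columns `timestamp_s, abp_mmhg, hr_bpm, brs_ms_per_mmhg, icp_mmhg, prx`;
#' missing samples are written as empty cells. The round trip through
#' [read_trend_csv()] is lossless including the missingness mask.
#'
#' @param record A `trend_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trend_csv <- function(record, path) {
  df <- data.frame(timestamp_s = series_times(record$channels$abp))
  for (i in seq_along(TREND_CHANNELS)) {
    df[[TREND_CSV_COLUMNS[i + 1L]]] <- record$channels[[TREND_CHANNELS[i]]]$values
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trend record from CSV
#'
#' Enforces the documented dialect: exact header, strictly increasing
#' timestamps on a regular grid. Empty cells become `NA`, never zero.
#'
#' @param path CSV file path.
#' @param patient_id Identifier to attach; defaults to the file base name.
#' @return A `trend_record`.
#' @export
read_trend_csv <- function(path, patient_id = NULL) {
  if (is.null(patient_id)) {
    patient_id <- sub("\\.csv$", "", basename(path))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), TREND_CSV_COLUMNS)) {
    stop("malformed trend CSV header in ", path, ": expected columns ",
         paste(TREND_CSV_COLUMNS, collapse = ", "))
  }
  ts <- df$timestamp_s
  if (nrow(df) < 2L) stop("trend CSV ", path, " has fewer than 2 rows")
  dts <- diff(ts)
  bad <- which(abs(dts - dts[1L]) > 1e-6 | dts <= 0)
  if (length(bad) > 0L) {
    stop("irregular or non-monotone timestamp grid in ", path,
         " at row ", bad[1L] + 1L)
  }
  channels <- list()
  for (i in seq_along(TREND_CHANNELS)) {
    ch <- TREND_CHANNELS[i]
    channels[[ch]] <- uniform_series(df[[TREND_CSV_COLUMNS[i + 1L]]],
                                     dt = dts[1L], start_time = ts[1L],
                                     name = ch, units = TREND_UNITS[[ch]])
  }
  trend_record(patient_id, channels)
}

#' Linearly interpolate short missing runs
#'
#' Runs of up to `max_run` consecutive missing samples that have observed
#' values on both sides are filled by linear interpolation. Longer runs and
#' runs touching either boundary (no anchor on one side) are left missing.
#' Observed values are never altered, and the operation is idempotent.
#'
#' On the 60-s trend grid the default of 10 samples corresponds to 10
#' minutes of data.
#'
#' @param series A `uniform_series`.
#' @param max_run Longest missing run (in samples) eligible for filling.
#' @return The series with eligible gaps filled.
#' @export
interpolate_gaps <- function(series, max_run = 10L) {
  v <- series$values
  na <- is.na(v)
  if (!any(na) || all(na)) return(series)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    len <- r$lengths[k]
    s <- starts[k]; e <- ends[k]
    if (len > max_run || s == 1L || e == length(v)) next
    left <- v[s - 1L]; right <- v[e + 1L]
    v[s:e] <- left + (right - left) * seq_len(len) / (len + 1)
  }
  series$values <- v
  series
}

#' Quality control of a trend record
#'
#' A record passes when, after [interpolate_gaps()] with the `max_run`
#' rule, every channel retains at most `max_missing_frac` missing samples
#' and the record covers at least `required_hours`. The decision does not
#' depend on channel order or on the time-axis origin.
#'
#' @param record A `trend_record` on the 60-s grid.
#' @param max_missing_frac Tolerated residual missing fraction per channel.
#' @param required_hours Minimum record duration in hours.
#' @param max_run Interpolation run-length rule, in samples.
#' @return A `qc_report`: data frame with one row per channel
#'   (`missing_frac`, `max_missing_run`, `channel_ok`) plus attributes
#'   `patient_id`, `passed` and `failed_channels`.
#' @export
qc_record <- function(record, max_missing_frac = 0.10, required_hours = 72,
                      max_run = 10L) {
  rows <- lapply(TREND_CHANNELS, function(ch) {
    filled <- interpolate_gaps(record$channels[[ch]], max_run = max_run)
    na <- is.na(filled$values)
    runs <- if (any(na)) {
      r <- rle(na); max(r$lengths[r$values])
    } else 0L
    data.frame(channel = ch, missing_frac = mean(na),
               max_missing_run = runs,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$channel_ok <- report$missing_frac <= max_missing_frac
  long_enough <- record_hours(record) >= required_hours
  passed <- all(report$channel_ok) && long_enough
  structure(report,
            patient_id = record$patient_id,
            passed = passed,
            long_enough = long_enough,
            failed_channels = report$channel[!report$channel_ok],
            class = c("qc_report", "data.frame"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s\n", attr(x, "patient_id"),
              if (attr(x, "passed")) "PASSED" else "FAILED"))
  print.data.frame(x, ...)
  invisible(x)
}

#' Did a record pass quality control?
#' @param report A `qc_report`.
#' @return Logical flag.
#' @export
qc_passed <- function(report) isTRUE(attr(report, "passed"))
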