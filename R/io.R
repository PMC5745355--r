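#' Read an accelerometer trace from CSV
#'
#' Expects a comma-separated file with a header row and columns
#' `t,x,y,z`: epoch seconds (fractional part allowed) and acceleration in
#' m/s^2. Timestamps must be nondecreasing. The trace is treated as
#' nominally uniform at `fs_expected`; recording gaps larger than
#' `gap_mult` sample periods are reported as warnings with their spans,
#' never resampled (dropped transmission data is an exclusion problem,
#' not something to interpolate over).
#'
#' @param path Path to a CSV file.
#' @param fs_expected Nominal sampling frequency in Hz.
#' @param gap_mult Multiple of the sample period above which a timestamp
#'   step is reported as a gap.
#' @return An [accel_trace].
#' @export
read_accel_csv <- function(path, fs_expected = 20, gap_mult = 2) {
  df <- suppressWarnings(readr::read_csv(path,
    col_types = readr::cols(
      t = readr::col_double(), x = readr::col_double(),
      y = readr::col_double(), z = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    # problems() reports file lines; data rows start after the header
    abort(sprintf(
      "parse error in %s: row %s (%s)",
      path, paste(pmax(probs$row - 1, 1), collapse = ", "), probs$expected[1]
    ))
  }
  if (nrow(df) == 0) abort(sprintf("empty trace file: %s", path))
  if (!all(c("t", "x", "y", "z") %in% names(df))) {
    abort("trace file must have columns t,x,y,z")
  }
  if (is.unsorted(df$t)) abort("timestamps must be nondecreasing")
  dt <- diff(df$t)
  gap_at <- which(dt > gap_mult / fs_expected)
  if (length(gap_at) > 0) {
    warn(sprintf(
      "%d recording gap(s) exceeding %g sample periods: %s",
      length(gap_at), gap_mult,
      paste(sprintf("%.2f s after row %d", dt[gap_at], gap_at), collapse = "; ")
    ))
  }
  tr <- accel_trace(df$x, df$y, df$z, fs = fs_expected, t0 = df$t[1])
  tr
}

#' Write an accelerometer trace to CSV
#'
#' Inverse of [read_accel_csv()]; sample values round-trip bit-exactly.
#'
#' @param trace An [accel_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[, c("t", "x", "y", "z")], path,
    progress = FALSE)
  invisible(path)
}

#' Read a self-report smoking log from CSV
#'
#' Expects columns `start,end,puff_count,first_of_pack`: epoch-second
#' session bounds, the participant's approximate puff count, and whether
#' the cigarette was the first from a new pack. Any cell may be empty;
#' empty cells become `NA`. A row must carry at least one of `start`,
#' `end` (rows with neither are dropped with a warning) and satisfy
#' `start < end` when both are present (violations are an error naming
#' the rows).
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per retained log entry, in file order.
#' @export
read_smoking_log <- function(path) {
  df <- suppressWarnings(readr::read_csv(path,
    col_types = readr::cols(
      start = readr::col_double(), end = readr::col_double(),
      puff_count = readr::col_integer(), first_of_pack = readr::col_logical()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "parse error in %s: row %s",
      path, paste(unique(pmax(probs$row - 1, 1)), collapse = ", ")
    ))
  }
  bad_order <- which(!is.na(df$start) & !is.na(df$end) & df$start >= df$end)
  if (length(bad_order) > 0) {
    abort(sprintf(
      "log rows with start >= end: %s", paste(bad_order, collapse = ", ")
    ))
  }
  both_missing <- which(is.na(df$start) & is.na(df$end))
  if (length(both_missing) > 0) {
    warn(sprintf(
      "dropping %d log row(s) with neither start nor end: %s",
      length(both_missing), paste(both_missing, collapse = ", ")
    ))
    df <- df[-both_missing, ]
  }
  df
}

#' Write a self-report smoking log to CSV
#'
#' @param log Tibble with columns `start,end,puff_count,first_of_pack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smoking_log <- function(log, path) {
  readr::write_csv(
    as_tibble(log)[, c("start", "end", "puff_count", "first_of_pack")],
    path, na = "", progress = FALSE
  )
  invisible(path)
}
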