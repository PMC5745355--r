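#' Zero-phase low-pass filter an accelerometer trace
#'
#' Smooths each axis independently with a 4th-order Butterworth low-pass
#' applied forward and backward (zero phase shift), removing the
#' high-frequency content of walking, shaking and sensor jitter while
#' preserving the slow (< ~1 Hz) arm-raise morphology of hand-to-mouth
#' gestures. The DC component (gravity) is preserved. Edge transients are
#' suppressed by odd-reflection padding before filtering.
#'
#' @param trace An [accel_trace].
#' @param cutoff_hz Cutoff frequency in Hz; must lie in (0, fs/2).
#' @param order Butterworth order.
#' @return A filtered [accel_trace] with identical length and timing.
#' @export
#' @examples
#' tr <- accel_trace(rnorm(200), rnorm(200), 9.81 + rnorm(200))
#' sm <- lowpass(tr, cutoff_hz = 5)
lowpass <- function(trace, cutoff_hz = 5, order = 4) {
  fs <- trace_fs(trace)
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1 ||
      cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort(sprintf("cutoff_hz must lie strictly between 0 and fs/2 = %g", fs / 2))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  out <- trace
  for (ax in c("x", "y", "z")) {
    out[[ax]] <- filtfilt_padded(bf, trace[[ax]])
  }
  new_accel_trace(as_tibble(out), fs = fs, t0 = attr(trace, "t0"))
}

# forward-backward IIR filtering with odd (point-reflected) end padding
# long enough for the startup transient to settle, so constant and slowly
# varying signals pass without edge artefacts
filtfilt_padded <- function(bf, v) {
  n <- length(v)
  if (n == 0) return(v)
  p <- min(n - 1, 30 * max(length(bf$b), length(bf$a)))
  if (p < 1) return(v)
  head_pad <- 2 * v[1] - v[(p + 1):2]
  tail_pad <- 2 * v[n] - v[(n - 1):(n - p)]
  padded <- c(head_pad, v, tail_pad)
  filtered <- signal::filtfilt(bf, padded)
  filtered[(p + 1):(p + n)]
}

#' Cut a trace into fixed-length rolling windows
#'
#' Slices the trace into windows of `window_s` seconds advanced by
#' `stride` samples; each window is flattened axis-major into a feature
#' vector (all x samples, then all y, then all z) — 300 features for a
#' 5-second window at 20 Hz, the input unit of the gesture classifier.
#'
#' @param trace An [accel_trace].
#' @param window_s Window length in seconds.
#' @param stride Stride between window starts, in samples.
#' @return A tibble with columns `start_index` (1-based sample index of
#'   the window start) and `features` (a numeric matrix column, one row
#'   per window). A trace shorter than one window yields zero rows.
#' @export
gesture_windows <- function(trace, window_s = 5, stride = 1) {
  fs <- trace_fs(trace)
  w <- as.integer(round(window_s * fs))
  if (w < 1) abort("window_s * fs must be at least 1 sample")
  if (stride < 1) abort("stride must be a positive sample count")
  n <- nrow(trace)
  if (n < w) {
    return(tibble(
      start_index = integer(0),
      features = matrix(numeric(0), nrow = 0, ncol = 3 * w)
    ))
  }
  starts <- seq.int(1L, n - w + 1L, by = as.integer(stride))
  feats <- window_matrix(trace$x, trace$y, trace$z, starts, w)
  tibble(start_index = starts, features = feats)
}

# rows are windows: [x_1..x_w, y_1..y_w, z_1..z_w]
window_matrix <- function(x, y, z, starts, w) {
  idx <- outer(starts, 0:(w - 1L), `+`)
  cbind(
    matrix(x[idx], nrow = length(starts)),
    matrix(y[idx], nrow = length(starts)),
    matrix(z[idx], nrow = length(starts))
  )
}
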