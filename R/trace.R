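#' Build a triaxial accelerometer trace
#'
#' An `accel_trace` is a tibble with columns `t` (epoch seconds), `x`, `y`,
#' `z` (acceleration in m/s^2) that carries its nominal sampling frequency
#' as an attribute. Sample `i` (1-based) occurs at `t0 + (i - 1) / fs`; the
#' series is treated as uniformly sampled at `fs`.
#'
#' @param x,y,z Equal-length numeric vectors of acceleration in m/s^2.
#'   With the watch face up, gravity appears as `z` close to +9.81.
#' @param fs Sampling frequency in Hz (nominal 20).
#' @param t0 Epoch seconds of the first sample.
#' @return A tibble of class `accel_trace` with columns `t, x, y, z` and
#'   attributes `fs` and `t0`.
#' @export
#' @examples
#' tr <- accel_trace(x = rnorm(100), y = rnorm(100), z = 9.81 + rnorm(100))
#' trace_fs(tr)
#' trace_duration(tr)
accel_trace <- function(x, y, z, fs = 20, t0 = 0) {
  if (length(x) != length(y) || length(y) != length(z)) {
    abort("x, y and z must have identical length")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("fs must be a single positive number")
  }
  n <- length(x)
  out <- tibble(
    t = t0 + (seq_len(n) - 1) / fs,
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
  new_accel_trace(out, fs = fs, t0 = t0)
}

new_accel_trace <- function(df, fs, t0) {
  structure(df,
    fs = fs, t0 = t0,
    class = c("accel_trace", class(tibble())))
}

#' @rdname accel_trace
#' @param trace An `accel_trace`.
#' @export
trace_fs <- function(trace) attr(trace, "fs")

#' @rdname accel_trace
#' @export
trace_duration <- function(trace) nrow(trace) / trace_fs(trace)

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf(
    "# accel_trace: %d samples at %g Hz (%.1f s)\n",
    nrow(x), trace_fs(x), trace_duration(x)
  ))
  NextMethod()
}

#' Plot an accelerometer trace
#'
#' Draws the three acceleration axes over time, optionally shading
#' detected or ground-truth smoking sessions.
#'
#' @param object An [accel_trace].
#' @param sessions Optional tibble with `start_s`, `end_s` columns
#'   (seconds from trace start) to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accel_trace <- function(object, sessions = NULL, ...) {
  t0 <- attr(object, "t0") %||% object$t[1]
  df <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(object), t = .data$t - t0),
    c("x", "y", "z"),
    names_to = "axis", values_to = "accel"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$accel, colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "acceleration (m/s²)", colour = NULL)
  if (!is.null(sessions) && nrow(sessions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(sessions),
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40",
      inherit.aes = FALSE
    )
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
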