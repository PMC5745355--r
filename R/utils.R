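sigmoid <- function(x) 1 / (1 + exp(-x))

# cubic smoothstep ramp on [0, 1]; flat derivative at both ends
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Truncated whole-percent rate
#'
#' Converts a fraction to a whole percent by truncation (floor), the
#' convention used when reporting session-level true-positive and
#' self-report accuracy rates (e.g. 100/121 prints as 82, not 83).
#'
#' @param x Fraction in \[0, 1\].
#' @return Integer percent.
#' @export
#' @examples
#' pct_trunc(100 / 121) # 82
pct_trunc <- function(x) {
  as.integer(floor(100 * x + 1e-9))
}

#' Half-up rounding to a fixed number of decimals
#'
#' Ordinary commercial rounding (0.5 always rounds away from zero),
#' used for one-decimal false-positive percentages.
#'
#' @param x Numeric vector.
#' @param digits Decimal places kept.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# seed handling: run body under a local RNG seeded with `seed` when given,
# otherwise use (and advance) the caller's RNG stream
with_seed_or_rng <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
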