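# Internal numeric helpers shared across modules.

#' Full linear convolution via padded FFTs
#'
#' Equivalent to the coefficient sequence of the polynomial product of
#' `x` and `y`; length `length(x) + length(y) - 1`.
#'
#' @param x,y numeric vectors.
#' @return numeric vector.
#' @keywords internal
#' @noRd
conv_full <- function(x, y) {
  n <- length(x) + length(y) - 1L
  m <- stats::nextn(n, c(2L, 3L, 5L))
  fx <- stats::fft(c(x, numeric(m - length(x))))
  fy <- stats::fft(c(y, numeric(m - length(y))))
  Re(stats::fft(fx * fy, inverse = TRUE))[seq_len(n)] / m
}

# Wrap angles (radians) into (-pi, pi].
wrap_pi <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  w[w <= -pi] <- pi  # exact -pi maps to pi
  w
}

# Wrap minutes-of-day into [0, 1440).
wrap_mod <- function(minutes) minutes %% 1440

#' Circular mean of clock times
#'
#' Minutes-of-day live on a 1440-min circle; the arithmetic mean of
#' e.g. 23:50 and 00:10 should be midnight, not noon.
#'
#' @param minutes numeric vector of minutes-of-day.
#' @return circular mean in [0, 1440).
#' @keywords internal
#' @noRd
circular_mean_min <- function(minutes) {
  theta <- minutes / 1440 * 2 * pi
  m <- atan2(mean(sin(theta)), mean(cos(theta)))
  wrap_mod(m / (2 * pi) * 1440)
}

# Signed minimal deviation of minutes-of-day from a reference clock time,
# in (-720, 720].
circular_dev_min <- function(minutes, ref) {
  d <- (minutes - ref) %% 1440
  d[d > 720] <- d[d > 720] - 1440
  d
}

#' Dispersion of clock times about their circular mean
#'
#' Sample SD (n - 1 denominator) of the signed minimal deviations from
#' the circular mean. A linear fallback (`circular = FALSE`) is provided
#' for sensitivity analyses against a naive SD.
#'
#' @keywords internal
#' @noRd
circular_sd_min <- function(minutes, circular = TRUE) {
  if (length(minutes) < 2L) return(NA_real_)
  if (!circular) return(stats::sd(minutes))
  mu <- circular_mean_min(minutes)
  stats::sd(circular_dev_min(minutes, mu))
}

#' Derive a per-unit sub-seed from a master seed
#'
#' Deterministic affine-modular scheme: adding a participant never
#' perturbs the draws of the others. Values stay below 2^31.
#'
#' @param master integer master seed.
#' @param index 1-based unit index.
#' @param stream small integer distinguishing independent uses.
#' @keywords internal
#' @noRd
derive_seed <- function(master, index, stream = 0L) {
  master <- as.double(master)
  ((master %% 2147483647) * 48271 + index * 69621 + stream * 30269) %% 2147483563
}

# Unwrap wrapped phase (radians): cumulative correction of 2*pi jumps.
unwrap_phase <- function(phase) {
  d <- diff(phase)
  jumps <- round(d / (2 * pi))
  phase - c(0, cumsum(jumps)) * 2 * pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
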