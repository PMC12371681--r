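# Circadian phase via the Hilbert transform, cycle splitting at phase
# troughs, and the three per-cycle properties (period, acrophase,
# amplitude).

# Discrete analytic signal: zero out negative frequencies, double
# positive ones (DC and Nyquist untouched).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous circadian phase of an extracted rhythm
#'
#' Applies the Hilbert transform to the (near-zero-mean, narrowband)
#' circadian component, giving a complex analytic signal whose argument
#' is the instantaneous phase, wrapped into `(-pi, pi]` with phase 0 at
#' the oscillation peak and ±pi at troughs — a measure of circadian
#' cycle progression.
#'
#' @param crhr a `circadian_component` (see [select_circadian()]), or a
#'   plain numeric vector for direct use.
#' @param interval_s sampling interval, required when `crhr` is a bare
#'   vector.
#' @return a `phase_series`: wrapped `phase` (radians), the `values`
#'   they were computed from, and grid metadata.
#' @export
hilbert_phase <- function(crhr, interval_s = NULL) {
  if (inherits(crhr, "circadian_component")) {
    v <- crhr$values
    interval_s <- crhr$interval_s
    start_time <- crhr$start_time
    tz <- crhr$tz_offset_min
  } else {
    v <- as.numeric(crhr)
    if (is.null(interval_s)) stop("interval_s required for a bare vector",
                                  call. = FALSE)
    start_time <- 0
    tz <- 0
  }
  if (length(v) * interval_s < 2 * 86400) {
    stop("component shorter than 2 days; run skipped", call. = FALSE)
  }
  a <- analytic_signal(v - mean(v))
  structure(list(phase = wrap_pi(Arg(a)), values = v,
                 interval_s = interval_s, start_time = start_time,
                 tz_offset_min = tz),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples at %g s\n",
              length(x$phase), x$interval_s))
  invisible(x)
}

#' Split a phase series into circadian cycles at phase troughs
#'
#' A cycle boundary is placed at every trough of the wrapped phase —
#' the wrap event where phase steps from near `+pi` back to `-pi` —
#' refined to the exact crossing by linear interpolation of the
#' unwrapped phase. Half a cycle (`edge_trim_h`, default 12 h) is
#' discarded at each end of the run to suppress Hilbert edge
#' distortion, and boundaries implausibly close together (< `min_sep_h`)
#' are merged, keeping the first.
#'
#' @param phase a `phase_series` from [hilbert_phase()].
#' @param edge_trim_h hours discarded at each run end (default 12).
#' @param min_sep_h minimum plausible cycle length in hours (default
#'   12); closer boundaries are merged.
#' @return numeric vector of boundary times (seconds, same clock as the
#'   run); fewer than 2 boundaries means no complete cycle.
#' @export
split_cycles <- function(phase, edge_trim_h = 12, min_sep_h = 12) {
  stopifnot(inherits(phase, "phase_series"))
  unw <- unwrap_phase(phase$phase)
  n <- length(unw)
  t_s <- phase$start_time + (seq_len(n) - 1) * phase$interval_s
  # boundaries: unwrapped phase crossing odd multiples of pi upward
  lev <- (floor((unw + pi) / (2 * pi))) # index of the last trough passed
  cross <- which(diff(lev) >= 1L)
  if (length(cross) == 0L) return(numeric(0))
  bounds <- vapply(cross, function(i) {
    target <- (lev[i] + 1) * 2 * pi - pi  # the odd-pi level crossed
    frac <- (target - unw[i]) / (unw[i + 1L] - unw[i])
    t_s[i] + frac * phase$interval_s
  }, 0)
  # half-sample slop so a trough landing exactly on the trim edge is kept
  lo <- t_s[1L] + edge_trim_h * 3600 - phase$interval_s / 2
  hi <- t_s[n] - edge_trim_h * 3600 + phase$interval_s / 2
  bounds <- bounds[bounds >= lo & bounds <= hi]
  if (length(bounds) >= 2L) {
    keep <- c(TRUE, diff(bounds) >= min_sep_h * 3600)
    while (!all(keep)) {  # re-check separations after each merge
      bounds <- bounds[keep]
      if (length(bounds) < 2L) break
      keep <- c(TRUE, diff(bounds) >= min_sep_h * 3600)
    }
  }
  bounds
}

# Interpolated CRHR value at an arbitrary time inside the run.
crhr_value_at <- function(phase, time_s) {
  n <- length(phase$values)
  t_s <- phase$start_time + (seq_len(n) - 1) * phase$interval_s
  stats::approx(t_s, phase$values, xout = time_s, rule = 2)$y
}

# Local extremum of the CRHR within +-window_s of a located peak or
# trough time. The phase crossing locates the event; the magnitude is
# the extremum itself, so a small timing error does not bias the read.
crhr_extremum_near <- function(phase, time_s, window_s, which = c("max", "min")) {
  which <- match.arg(which)
  n <- length(phase$values)
  t_s <- phase$start_time + (seq_len(n) - 1) * phase$interval_s
  idx <- which(t_s >= time_s - window_s & t_s <= time_s + window_s)
  cand <- c(phase$values[idx], crhr_value_at(phase, time_s))
  if (which == "max") max(cand) else min(cand)
}

# Times inside (t0, t1) where the unwrapped phase crosses an even
# multiple of 2*pi (the peak); linear sub-sample refinement.
zero_phase_crossings <- function(phase, t0, t1) {
  unw <- unwrap_phase(phase$phase)
  n <- length(unw)
  t_s <- phase$start_time + (seq_len(n) - 1) * phase$interval_s
  lev <- floor(unw / (2 * pi) + 0.5)  # nearest-peak index below
  cross <- which(diff(lev) >= 1L)
  out <- vapply(cross, function(i) {
    target <- (lev[i] + 1) * 2 * pi
    frac <- (target - unw[i]) / (unw[i + 1L] - unw[i])
    t_s[i] + frac * phase$interval_s
  }, 0)
  out[out > t0 & out < t1]
}

#' Per-cycle circadian properties from phase-split boundaries
#'
#' For each pair of consecutive trough boundaries: *period* is the
#' duration of the cycle in minutes; *acrophase* is the local clock
#' time (minutes-of-day) of the zero-phase crossing — the cycle peak —
#' inside the cycle; *amplitude* is the difference in magnitude between
#' the cycle peak and the preceding trough, read as the CRHR maximum
#' near the acrophase minus its minimum near the starting boundary
#' (search half-width `extremum_window_h`), so that a small error in
#' locating the phase crossing does not bias the magnitude. Cycles
#' without a zero-phase crossing, or with a negative amplitude (both
#' pathological), are dropped with a message.
#'
#' @param phase a `phase_series` from [hilbert_phase()].
#' @param boundaries trough times from [split_cycles()].
#' @param run_id identifier copied into the output.
#' @param extremum_window_h half-width in hours of the peak/trough
#'   magnitude search around the located times (default 2).
#' @return data frame with one row per retained cycle: `run_id`,
#'   `cycle`, `start_s`, `end_s`, `period_min`, `acrophase_min`,
#'   `amplitude_bpm`.
#' @export
cycle_properties <- function(phase, boundaries, run_id = 1L,
                             extremum_window_h = 2) {
  stopifnot(inherits(phase, "phase_series"))
  n_cyc <- length(boundaries) - 1L
  if (n_cyc < 1L) {
    return(data.frame(run_id = integer(0), cycle = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      period_min = numeric(0), acrophase_min = numeric(0),
                      amplitude_bpm = numeric(0)))
  }
  rows <- lapply(seq_len(n_cyc), function(d) {
    t0 <- boundaries[d]
    t1 <- boundaries[d + 1L]
    peaks <- zero_phase_crossings(phase, t0, t1)
    if (length(peaks) == 0L) {
      message("cycle ", d, ": no zero-phase crossing; dropped")
      return(NULL)
    }
    peak_t <- peaks[1L]
    w_s <- extremum_window_h * 3600
    amp <- crhr_extremum_near(phase, peak_t, w_s, "max") -
      crhr_extremum_near(phase, t0, w_s, "min")
    if (amp < 0) {
      message("cycle ", d, ": negative amplitude; dropped")
      return(NULL)
    }
    data.frame(run_id = run_id, cycle = d, start_s = t0, end_s = t1,
               period_min = (t1 - t0) / 60,
               acrophase_min = wrap_mod(peak_t / 60 + phase$tz_offset_min),
               amplitude_bpm = amp)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Full per-run cycle table from an extracted circadian component
#'
#' Wrapper: Hilbert phase, trough splitting, per-cycle properties.
#'
#' @param crhr a `circadian_component`.
#' @param run_id identifier copied into the output.
#' @inheritParams split_cycles
#' @inheritParams cycle_properties
#' @return the [cycle_properties()] data frame (zero rows when the run
#'   yields no complete cycle).
#' @export
run_cycles <- function(crhr, run_id = 1L, edge_trim_h = 12, min_sep_h = 12,
                       extremum_window_h = 2) {
  ph <- hilbert_phase(crhr)
  bounds <- split_cycles(ph, edge_trim_h = edge_trim_h, min_sep_h = min_sep_h)
  cycle_properties(ph, bounds, run_id = run_id,
                   extremum_window_h = extremum_window_h)
}
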