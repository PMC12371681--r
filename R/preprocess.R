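#' A timestamped heart-rate series
#'
#' The raw input representation: strictly increasing timestamps (seconds
#' since an arbitrary epoch; local midnight of day 0 is at
#' `-tz_offset_min * 60`), positive bpm values, and the device's nominal
#' sampling interval. Missing data are represented by absent timestamps,
#' never by sentinel values.
#'
#' @param participant_id identifier string.
#' @param time numeric timestamps in seconds, strictly increasing.
#' @param bpm heart-rate values (> 0), same length as `time`.
#' @param nominal_interval device sampling interval in seconds.
#' @param tz_offset_min fixed offset of the participant's local midnight
#'   from the timestamp epoch, in minutes.
#' @return an object of class `hr_series`.
#' @export
hr_series <- function(participant_id, time, bpm, nominal_interval = 5,
                      tz_offset_min = 0) {
  if (length(time) != length(bpm)) {
    stop("`time` and `bpm` must have equal length", call. = FALSE)
  }
  if (length(time) == 0L) stop("empty heart-rate series", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    o <- order(time)
    time <- time[o]
    bpm <- bpm[o]
    if (anyDuplicated(time)) stop("duplicate timestamps", call. = FALSE)
  }
  if (any(!is.finite(bpm)) || any(bpm <= 0)) {
    stop("bpm values must be finite and positive", call. = FALSE)
  }
  structure(list(participant_id = as.character(participant_id),
                 time = as.numeric(time), bpm = as.numeric(bpm),
                 nominal_interval = nominal_interval,
                 tz_offset_min = tz_offset_min),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %s: %d samples, %.1f days, %g-s nominal interval\n",
              x$participant_id, length(x$time),
              (max(x$time) - min(x$time)) / 86400, x$nominal_interval))
  invisible(x)
}

#' A contiguous uniformly sampled run
#'
#' @param start_time first timestamp (seconds).
#' @param interval sampling interval (seconds).
#' @param values bpm on the uniform grid; no missing samples.
#' @param interpolated logical mask flagging gap-filled samples.
#' @param tz_offset_min inherited local-midnight offset, minutes.
#' @return an object of class `hr_run`.
#' @export
hr_run <- function(start_time, interval, values,
                   interpolated = rep(FALSE, length(values)),
                   tz_offset_min = 0) {
  stopifnot(length(values) >= 2L, interval > 0,
            length(interpolated) == length(values))
  structure(list(start_time = start_time, interval = interval,
                 values = as.numeric(values), interpolated = interpolated,
                 tz_offset_min = tz_offset_min),
            class = "hr_run")
}

run_times <- function(run) run$start_time + (seq_along(run$values) - 1) * run$interval
run_duration_s <- function(run) (length(run$values) - 1) * run$interval

#' @export
print.hr_run <- function(x, ...) {
  cat(sprintf("<hr_run> %.1f days at %g s (%d samples, %.1f%% interpolated)\n",
              run_duration_s(x) / 86400, x$interval, length(x$values),
              100 * mean(x$interpolated)))
  invisible(x)
}

# Inter-sample spacings that count as gaps: anything beyond twice the
# nominal interval, tolerating device timing jitter.
gap_indices <- function(time, nominal) which(diff(time) > 2 * nominal)

#' Linearly interpolate short recording gaps
#'
#' Gaps strictly shorter than `max_gap_h` hours are filled by linear
#' interpolation onto the nominal grid (anchored at the sample before
#' the gap); filled samples are flagged. Gaps of `max_gap_h` or longer
#' are left untouched and later split the series into runs.
#'
#' @param series a [hr_series()].
#' @param max_gap_h threshold in hours (default 8); strictly shorter
#'   gaps are interpolated.
#' @return a [hr_series()] with an added `interpolated` logical field.
#' @export
interpolate_short_gaps <- function(series, max_gap_h = 8) {
  stopifnot(inherits(series, "hr_series"))
  dt <- series$nominal_interval
  gaps <- gap_indices(series$time, dt)
  interp_flag <- series$interpolated %||% rep(FALSE, length(series$time))
  if (length(gaps) == 0L) {
    series$interpolated <- interp_flag
    return(series)
  }
  new_t <- list()
  new_v <- list()
  for (i in gaps) {
    span <- series$time[i + 1L] - series$time[i]
    if (span >= max_gap_h * 3600) next
    tt <- seq(series$time[i] + dt, series$time[i + 1L] - dt / 2, by = dt)
    tt <- tt[tt < series$time[i + 1L] - 1e-9]
    if (length(tt) == 0L) next
    vv <- series$bpm[i] + (series$bpm[i + 1L] - series$bpm[i]) *
      (tt - series$time[i]) / span
    new_t[[length(new_t) + 1L]] <- tt
    new_v[[length(new_v) + 1L]] <- vv
  }
  if (length(new_t) == 0L) {
    series$interpolated <- interp_flag
    return(series)
  }
  t_all <- c(series$time, unlist(new_t))
  v_all <- c(series$bpm, unlist(new_v))
  f_all <- c(interp_flag, rep(TRUE, length(unlist(new_t))))
  o <- order(t_all)
  out <- hr_series(series$participant_id, t_all[o], v_all[o],
                   series$nominal_interval, series$tz_offset_min)
  out$interpolated <- f_all[o]
  out
}

#' Split a series into runs between long gaps
#'
#' Runs are maximal contiguous stretches separated by gaps of
#' `min_gap_h` hours or more; each run is resampled onto a uniform grid
#' at the nominal interval anchored at its first timestamp, which
#' absorbs sub-interval device timing jitter.
#'
#' @param series a [hr_series()] whose short gaps have been
#'   interpolated.
#' @param min_gap_h gap length in hours (default 8) at or above which
#'   the series is split.
#' @return list of [hr_run()]s in time order (possibly empty: stretches
#'   of fewer than two samples are dropped).
#' @export
split_runs <- function(series, min_gap_h = 8) {
  stopifnot(inherits(series, "hr_series"))
  dt <- series$nominal_interval
  interp_flag <- series$interpolated %||% rep(FALSE, length(series$time))
  breaks <- which(diff(series$time) >= min_gap_h * 3600)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(series$time))
  runs <- list()
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    if (length(idx) < 2L) next
    tt <- series$time[idx]
    grid <- seq(tt[1L], tt[length(idx)], by = dt)
    vals <- stats::approx(tt, series$bpm[idx], xout = grid, rule = 2)$y
    fl <- stats::approx(tt, as.numeric(interp_flag[idx]), xout = grid,
                        method = "constant", rule = 2)$y > 0
    runs[[length(runs) + 1L]] <- hr_run(grid[1L], dt, vals, fl,
                                        series$tz_offset_min)
  }
  runs
}

#' Does a participant have at least one run long enough to analyse?
#'
#' Participants whose longest run is not strictly longer than
#' `min_run_days` are excluded from all downstream analysis.
#'
#' @param runs list of [hr_run()]s.
#' @param min_run_days eligibility threshold in days (default 7).
#' @return logical.
#' @export
eligible <- function(runs, min_run_days = 7) {
  if (length(runs) == 0L) return(FALSE)
  any(vapply(runs, run_duration_s, 0) > min_run_days * 86400)
}

#' Downsample a run by non-overlapping window means
#'
#' Reduces the working resolution before decomposition. The working
#' interval must be an integer multiple of the run's interval; each
#' output sample is the mean of one window, timestamped at the window
#' centre. A 24-h rhythm is attenuated only by the factor
#' `sinc(pi * window / period)`, negligible for windows of minutes.
#'
#' @param run a [hr_run()].
#' @param working_interval_s target interval in seconds (default 300).
#' @return a [hr_run()] at the working interval.
#' @export
downsample <- function(run, working_interval_s = 300) {
  stopifnot(inherits(run, "hr_run"))
  k <- working_interval_s / run$interval
  if (k < 1 || abs(k - round(k)) > 1e-9) {
    stop("working interval must be an integer multiple of the run interval (>= 1)",
         call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k == 1L) return(run)
  n_win <- length(run$values) %/% k
  if (n_win < 2L) stop("run too short for this working interval", call. = FALSE)
  idx <- seq_len(n_win * k)
  vals <- colMeans(matrix(run$values[idx], nrow = k))
  fl <- colSums(matrix(run$interpolated[idx], nrow = k)) > k / 2
  hr_run(run$start_time + (k - 1) / 2 * run$interval,
         working_interval_s, vals, fl, run$tz_offset_min)
}

#' Preprocess one participant's series into analysable runs
#'
#' Convenience wrapper: interpolate short gaps, split into runs, check
#' eligibility, downsample eligible runs to the working interval, and
#' report the accounting (days kept in runs longer than the eligibility
#' threshold, days lost to gaps, days in short discarded runs).
#'
#' @inheritParams interpolate_short_gaps
#' @inheritParams split_runs
#' @inheritParams eligible
#' @param working_interval_s working resolution passed to
#'   [downsample()]; `NULL` keeps the nominal resolution.
#' @return list with `runs` (only runs longer than `min_run_days`,
#'   downsampled), `eligible`, and `report` (per-participant accounting).
#' @export
preprocess_series <- function(series, max_gap_h = 8, min_gap_h = 8,
                              min_run_days = 7, working_interval_s = 300) {
  filled <- interpolate_short_gaps(series, max_gap_h)
  runs <- split_runs(filled, min_gap_h)
  ok <- eligible(runs, min_run_days)
  durs <- vapply(runs, run_duration_s, 0)
  keep <- durs > min_run_days * 86400
  span_d <- (max(series$time) - min(series$time)) / 86400
  report <- list(
    participant_id = series$participant_id,
    eligible = ok,
    n_runs_total = length(runs),
    n_runs_kept = sum(keep),
    days_span = span_d,
    days_in_kept_runs = sum(durs[keep]) / 86400,
    days_in_short_runs = sum(durs[!keep]) / 86400,
    days_in_gaps = span_d - sum(durs) / 86400
  )
  kept <- runs[keep]
  if (!is.null(working_interval_s)) {
    kept <- lapply(kept, downsample, working_interval_s = working_interval_s)
  }
  list(runs = kept, eligible = ok, report = report)
}
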