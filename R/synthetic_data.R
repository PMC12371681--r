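#' Configuration for the synthetic wearable heart-rate generator
#'
#' Builds and validates the parameter set controlling one simulated
#' participant: a ~24-h heart-rate oscillation with day-to-day jitter in
#' period, acrophase, and amplitude, optional ultradian components,
#' autocorrelated (AR(1)) sensor noise, missing-data gaps, and a Poisson
#' seizure diary.
#'
#' Day-to-day dynamics: each circadian cycle `d` has its own period
#' `P_d` and half-amplitude `A_d`. The period is
#' `P_d = period_mean - mean_reversion * a_d + e_d`, where `a_d` is the
#' accumulated acrophase offset (minutes) from `acrophase_anchor` and
#' `e_d ~ N(0, period_sd)`. The mean-reversion term pulls the peak time
#' back toward the anchor, so acrophase stays bounded over months the
#' way an entrained rhythm does, while the realized per-cycle period SD
#' stays close to `period_sd` for small `mean_reversion`.
#'
#' @param n_days length of the recording in days.
#' @param sampling_interval_s sampling interval in seconds (wearable
#'   nominal resolution; default 5 s).
#' @param mesor baseline heart rate in bpm.
#' @param amplitude_mean,amplitude_sd mean and day-to-day SD of the
#'   circadian half-amplitude `A_d` (bpm); `A_d` is truncated positive.
#' @param period_mean,period_sd mean and day-to-day SD of the cycle
#'   period, in minutes.
#' @param acrophase_anchor clock time (minutes-of-day) the peak is
#'   entrained to.
#' @param mean_reversion strength in `[0, 1]` of the pull of the peak
#'   time back toward the anchor (0 = pure random walk of acrophase).
#' @param ultradian list of `c(period_h, amplitude_bpm)` pairs added as
#'   fixed-phase cosines (e.g. a 12-h harmonic).
#' @param noise_ar1_phi lag-one autocorrelation of the additive noise at
#'   the sampling resolution, in `[0, 1)`.
#' @param noise_sd stationary SD of the additive noise (bpm).
#' @param gap_rate expected number of missing-data gaps per day.
#' @param gap_duration_log_mean,gap_duration_log_sd meanlog and sdlog of
#'   the log-normal gap duration, in log-hours.
#' @param seizures_per_week rate of the homogeneous Poisson seizure
#'   diary (>= 0).
#' @param tz_offset_min fixed local-midnight offset from UTC in minutes.
#' @param seed integer seed; all generator output is a pure function of
#'   the configuration including the seed.
#'
#' @return an object of class `crhr_config` (a validated list).
#' @export
#' @examples
#' cfg <- crhr_config(n_days = 10, period_sd = 30, seed = 1)
#' sim <- generate_participant(cfg)
#' sd(sim$ground_truth$period_min)
crhr_config <- function(n_days = 70,
                        sampling_interval_s = 5,
                        mesor = 75,
                        amplitude_mean = 10,
                        amplitude_sd = 1.5,
                        period_mean = 1440,
                        period_sd = 60,
                        acrophase_anchor = 15 * 60,
                        mean_reversion = 0.2,
                        ultradian = list(c(12, 2)),
                        noise_ar1_phi = 0.9,
                        noise_sd = 6,
                        gap_rate = 0.3,
                        gap_duration_log_mean = log(2),
                        gap_duration_log_sd = 1.2,
                        seizures_per_week = 0,
                        tz_offset_min = 0,
                        seed = 1L) {
  cfg <- list(
    n_days = n_days, sampling_interval_s = sampling_interval_s,
    mesor = mesor, amplitude_mean = amplitude_mean,
    amplitude_sd = amplitude_sd, period_mean = period_mean,
    period_sd = period_sd, acrophase_anchor = acrophase_anchor,
    mean_reversion = mean_reversion, ultradian = ultradian,
    noise_ar1_phi = noise_ar1_phi, noise_sd = noise_sd,
    gap_rate = gap_rate, gap_duration_log_mean = gap_duration_log_mean,
    gap_duration_log_sd = gap_duration_log_sd,
    seizures_per_week = seizures_per_week,
    tz_offset_min = tz_offset_min, seed = seed
  )
  validate_crhr_config(cfg)
  structure(cfg, class = "crhr_config")
}

validate_crhr_config <- function(cfg) {
  stop_field <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid config: `%s` %s", field, why), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stop_field(num1(cfg$n_days) && cfg$n_days > 0, "n_days", "must be a positive number")
  stop_field(num1(cfg$sampling_interval_s) && cfg$sampling_interval_s > 0,
             "sampling_interval_s", "must be > 0")
  stop_field(num1(cfg$period_sd) && cfg$period_sd >= 0, "period_sd", "must be >= 0")
  stop_field(num1(cfg$amplitude_mean) && cfg$amplitude_mean > 0,
             "amplitude_mean", "must be > 0")
  stop_field(num1(cfg$amplitude_sd) && cfg$amplitude_sd >= 0,
             "amplitude_sd", "must be >= 0")
  stop_field(num1(cfg$mesor) && cfg$mesor > cfg$amplitude_mean,
             "mesor", "must exceed amplitude_mean so heart rate stays positive")
  stop_field(num1(cfg$period_mean) && cfg$period_mean > 0, "period_mean", "must be > 0")
  stop_field(num1(cfg$mean_reversion) && cfg$mean_reversion >= 0 && cfg$mean_reversion <= 1,
             "mean_reversion", "must lie in [0, 1]")
  stop_field(num1(cfg$noise_ar1_phi) && cfg$noise_ar1_phi >= 0 && cfg$noise_ar1_phi < 1,
             "noise_ar1_phi", "must lie in [0, 1)")
  stop_field(num1(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  stop_field(num1(cfg$gap_rate) && cfg$gap_rate >= 0, "gap_rate", "must be >= 0")
  stop_field(num1(cfg$seizures_per_week) && cfg$seizures_per_week >= 0,
             "seizures_per_week", "must be >= 0")
  stop_field(is.list(cfg$ultradian), "ultradian", "must be a list of (period_h, amplitude_bpm)")
  invisible(cfg)
}

#' Simulate one participant's heart-rate recording with known ground truth
#'
#' Generates `HR(t) = mesor + A_d cos(Phi(t)) + ultradian terms + AR(1)
#' noise` on a uniform grid, where the phase `Phi` advances at rate
#' `2*pi / P_d` within cycle `d` (trough to trough) and the peak of cycle
#' `d` falls mid-cycle. Ground truth records, per complete cycle inside
#' the sampled span: the realized period, the peak clock time
#' (acrophase), the peak-minus-preceding-trough amplitude (`2 * A_d` for
#' a cosine), and the trough boundary times.
#'
#' @param config a [crhr_config()].
#' @return a list with elements `series` (a [hr_series()]) and
#'   `ground_truth` (data frame: `cycle`, `start_s`, `end_s`,
#'   `period_min`, `acrophase_min`, `amplitude_bpm`).
#' @export
generate_participant <- function(config) {
  validate_crhr_config(config)
  set.seed(config$seed %% 2147483647)

  span_s <- config$n_days * 86400
  dt <- config$sampling_interval_s
  t_s <- seq(0, span_s, by = dt)

  # Per-cycle period / amplitude draws, with two spare cycles of margin.
  n_cyc <- ceiling(span_s / 60 / config$period_mean) + 3L
  eps <- stats::rnorm(n_cyc, 0, config$period_sd)
  periods <- numeric(n_cyc)
  offset <- 0  # acrophase offset from anchor, minutes
  offsets <- numeric(n_cyc)
  for (d in seq_len(n_cyc)) {
    offsets[d] <- offset
    periods[d] <- config$period_mean - config$mean_reversion * offset + eps[d]
    if (periods[d] < 0.5 * config$period_mean) periods[d] <- 0.5 * config$period_mean
    offset <- offset + (periods[d] - config$period_mean)
  }
  amp <- stats::rnorm(n_cyc, config$amplitude_mean, config$amplitude_sd)
  amp <- abs(amp)
  amp[amp < 1e-9] <- 1e-9

  # First cycle: peak at anchor + initial offset, trough half a period before.
  peak1_s <- (config$acrophase_anchor + offsets[1L] - config$tz_offset_min) * 60
  start1_s <- peak1_s - periods[1L] * 60 / 2
  while (start1_s > 0) start1_s <- start1_s - periods[1L] * 60  # cover t = 0
  bounds_s <- start1_s + c(0, cumsum(periods * 60))

  # Continuous unwrapped phase: -pi at each trough boundary, linear within.
  cyc_of <- findInterval(t_s, bounds_s, rightmost.closed = FALSE)
  cyc_of[cyc_of < 1L] <- 1L
  cyc_of[cyc_of > n_cyc] <- n_cyc
  frac <- (t_s - bounds_s[cyc_of]) / (periods[cyc_of] * 60)
  phase <- -pi + 2 * pi * frac
  hr <- config$mesor + amp[cyc_of] * cos(phase)

  for (u in config$ultradian) {
    hr <- hr + u[2L] * cos(2 * pi * t_s / (u[1L] * 3600))
  }

  if (config$noise_sd > 0) {
    innov_sd <- config$noise_sd * sqrt(1 - config$noise_ar1_phi^2)
    noise <- stats::filter(stats::rnorm(length(t_s), 0, innov_sd),
                           config$noise_ar1_phi, method = "recursive")
    hr <- hr + as.numeric(noise)
  }
  hr[hr < 1] <- 1  # physiological floor; unreachable under valid configs

  # Ground truth restricted to cycles entirely inside the sampled span.
  cyc_start <- bounds_s[seq_len(n_cyc)]
  cyc_end <- bounds_s[-1L]
  complete <- which(cyc_start >= 0 & cyc_end <= span_s)
  gt <- data.frame(
    cycle = seq_along(complete),
    start_s = bounds_s[complete],
    end_s = bounds_s[complete + 1L],
    period_min = periods[complete],
    acrophase_min = wrap_mod((bounds_s[complete] + periods[complete] * 60 / 2) / 60 +
                               config$tz_offset_min),
    amplitude_bpm = 2 * amp[complete]
  )

  series <- hr_series(
    participant_id = sprintf("sim-%d", config$seed),
    time = t_s, bpm = hr,
    nominal_interval = dt,
    tz_offset_min = config$tz_offset_min
  )
  list(series = series, ground_truth = gt)
}

#' Remove samples inside randomly drawn recording gaps
#'
#' Gap onsets follow a Poisson count (`gap_rate` per day, uniform
#' placement); durations are log-normal in hours, so a single mechanism
#' produces both short interpolatable gaps and long run-splitting ones.
#'
#' @param series a [hr_series()].
#' @param config a [crhr_config()]; only the gap fields and `seed` are
#'   used (stream-offset from the participant seed, so the same series
#'   is punched identically on repeated calls).
#' @return a [hr_series()] with samples inside gaps removed.
#' @export
inject_gaps <- function(series, config) {
  validate_crhr_config(config)
  if (config$gap_rate == 0) return(series)
  set.seed(derive_seed(config$seed, 1L, stream = 7L))
  span_s <- max(series$time) - min(series$time)
  n_gaps <- stats::rpois(1L, config$gap_rate * span_s / 86400)
  if (n_gaps == 0L) return(series)
  starts <- stats::runif(n_gaps, min(series$time), max(series$time))
  durs_s <- stats::rlnorm(n_gaps, config$gap_duration_log_mean,
                          config$gap_duration_log_sd) * 3600
  keep <- rep(TRUE, length(series$time))
  for (g in seq_len(n_gaps)) {
    keep <- keep & !(series$time >= starts[g] & series$time < starts[g] + durs_s[g])
  }
  hr_series(series$participant_id, series$time[keep], series$bpm[keep],
            series$nominal_interval, series$tz_offset_min)
}

#' Simulate a seizure diary as a homogeneous Poisson process
#'
#' @param rate expected seizures per week (>= 0).
#' @param span_s two-element numeric, start and end of the diary span in
#'   seconds.
#' @param seed integer seed.
#' @param participant_id identifier attached to the diary.
#' @return a `seizure_diary`: list with `participant_id`, sorted
#'   `events` (seconds), and `span` (the reporting interval).
#' @export
generate_seizure_diary <- function(rate, span_s, seed = 1L,
                                   participant_id = "sim") {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0) {
    stop("invalid diary rate: must be a single number >= 0", call. = FALSE)
  }
  set.seed(seed %% 2147483647)
  weeks <- (span_s[2L] - span_s[1L]) / (7 * 86400)
  n <- stats::rpois(1L, rate * weeks)
  events <- sort(stats::runif(n, span_s[1L], span_s[2L]))
  structure(list(participant_id = participant_id, events = events,
                 span = as.numeric(span_s)),
            class = "seizure_diary")
}

#' Generate a two-group labelled cohort
#'
#' Participants are simulated independently with per-participant
#' sub-seeds derived deterministically from the master seed, so group
#' sizes can change without perturbing existing participants' draws.
#'
#' @param config_a,config_b group-level [crhr_config()] templates
#'   (group "a" is conventionally the patient group).
#' @param n_a,n_b participants per group (>= 1).
#' @param seed master integer seed.
#' @param with_gaps puncture each series with [inject_gaps()].
#' @param labels two group labels, default `c("pwe", "control")`.
#' @return list of participant entries: `id`, `group`, `series`,
#'   `ground_truth`, `diary` (present when the group's
#'   `seizures_per_week > 0`).
#' @export
generate_cohort <- function(config_a, config_b, n_a, n_b, seed = 1L,
                            with_gaps = TRUE,
                            labels = c("pwe", "control")) {
  stopifnot(n_a >= 1L, n_b >= 1L)
  make_group <- function(cfg, n, label, stream) {
    lapply(seq_len(n), function(i) {
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(seed, i, stream = stream)
      sim <- generate_participant(cfg_i)
      id <- sprintf("%s-%02d", label, i)
      sim$series$participant_id <- id
      entry <- list(id = id, group = label, series = sim$series,
                    ground_truth = sim$ground_truth)
      if (with_gaps) entry$series <- inject_gaps(entry$series, cfg_i)
      if (cfg$seizures_per_week > 0) {
        entry$diary <- generate_seizure_diary(
          cfg$seizures_per_week, range(sim$series$time),
          seed = derive_seed(seed, i, stream = stream + 100L),
          participant_id = id
        )
      }
      entry
    })
  }
  c(make_group(config_a, n_a, labels[1L], 1L),
    make_group(config_b, n_b, labels[2L], 2L))
}
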