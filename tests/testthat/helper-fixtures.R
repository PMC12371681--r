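# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

# Uniform series of a pure cosine with given period (hours), half
# amplitude (bpm), and peak clock time (minutes-of-day), at dt seconds.
cosine_series <- function(days, period_h = 24, half_amp = 10, mesor = 70,
                          peak_min = 900, dt = 300, id = "fix") {
  t_s <- seq(0, days * 86400, by = dt)
  hr <- mesor + half_amp * cos(2 * pi * (t_s - peak_min * 60) / (period_h * 3600))
  hr_series(id, t_s, hr, nominal_interval = dt)
}

# Same cosine as a ready-made hr_run.
cosine_run <- function(days, period_h = 24, half_amp = 10, mesor = 70,
                       peak_min = 900, dt = 300) {
  t_s <- seq(0, days * 86400, by = dt)
  hr_run(0, dt, mesor + half_amp *
           cos(2 * pi * (t_s - peak_min * 60) / (period_h * 3600)))
}

# Punch a gap of `hours` starting at `at_s` seconds into a series.
punch_gap <- function(series, at_s, hours) {
  keep <- series$time < at_s | series$time >= at_s + hours * 3600
  hr_series(series$participant_id, series$time[keep], series$bpm[keep],
            series$nominal_interval, series$tz_offset_min)
}

# Noise-free generator config at coarse sampling, for fast unit tests.
quiet_config <- function(..., seed = 1) {
  crhr_config(sampling_interval_s = 60, noise_sd = 0, amplitude_sd = 0,
              period_sd = 0, ultradian = list(), gap_rate = 0,
              seed = seed, ...)
}

# Build a cycle table directly (for segmenting/summary tests).
make_cycles <- function(periods, acrophases = rep(900, length(periods)),
                        amplitudes = rep(10, length(periods)), run_id = 1L,
                        start0 = 0) {
  starts <- start0 + c(0, cumsum(periods[-length(periods)])) * 60
  data.frame(run_id = run_id, cycle = seq_along(periods),
             start_s = starts, end_s = starts + periods * 60,
             period_min = periods, acrophase_min = acrophases,
             amplitude_bpm = amplitudes)
}

# Segment-stats rows with prescribed SDs/means (for summary tests).
make_seg_stats <- function(sd_acrophase, mean_acrophase = 900,
                           sd_period = 10, mean_period = 1440,
                           sd_amplitude = 1, mean_amplitude = 10,
                           start0 = 0) {
  n <- length(sd_acrophase)
  starts <- start0 + (seq_len(n) - 1) * 7 * 86400
  data.frame(segment = seq_len(n), run_id = rep_len(1L, n),
             start_s = starts, end_s = starts + 7 * 86400,
             n_cycles = rep_len(7L, n),
             mean_period = rep_len(mean_period, n),
             sd_period = rep_len(sd_period, n),
             mean_acrophase = rep_len(mean_acrophase, n),
             sd_acrophase = sd_acrophase,
             mean_amplitude = rep_len(mean_amplitude, n),
             sd_amplitude = rep_len(sd_amplitude, n))
}
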