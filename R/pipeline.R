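# End-to-end orchestration: simulate or load -> preprocess -> extract
# -> cycles -> segments/summaries -> cohort statistics, with a manifest
# recording configuration, seed, and per-stage participant attrition.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the defaults used
#' throughout: 8-h gap threshold, 7-day run eligibility, 5-min working
#' resolution, 1.5-day SSA window with 20 eigentriples and ±0.5
#' cycles/day sideband absorption, 7-cycle segments, and the 28-patient
#' / 10000-iteration subsampling control.
#'
#' @param max_gap_h gaps strictly shorter than this (hours) are
#'   interpolated.
#' @param min_gap_h gaps at or above this (hours) split runs.
#' @param min_run_days eligibility: a run strictly longer than this is
#'   required.
#' @param working_interval_s working grid for decomposition (seconds).
#' @param window_days SSA embedding window (days).
#' @param rank SSA truncation rank (eigentriples).
#' @param rel_tol eigentriple grouping frequency tolerance.
#' @param sideband_cpd sideband absorption band around the selected
#'   circadian group, cycles/day (see [select_circadian()]).
#' @param edge_trim_h hours trimmed at each run end before cycle
#'   construction.
#' @param cycles_per_segment segment size (cycles).
#' @param n_sub,iterations subsampling control settings.
#' @param seed master seed for all stochastic stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(max_gap_h = 8, min_gap_h = 8, min_run_days = 7,
                            working_interval_s = 300, window_days = 1.5,
                            rank = 20L, rel_tol = 0.05, sideband_cpd = 0.5,
                            edge_trim_h = 12,
                            cycles_per_segment = 7L, n_sub = 28L,
                            iterations = 10000L, seed = 1L) {
  cfg <- list(max_gap_h = max_gap_h, min_gap_h = min_gap_h,
              min_run_days = min_run_days,
              working_interval_s = working_interval_s,
              window_days = window_days, rank = rank, rel_tol = rel_tol,
              sideband_cpd = sideband_cpd,
              edge_trim_h = edge_trim_h,
              cycles_per_segment = cycles_per_segment,
              n_sub = n_sub, iterations = iterations, seed = seed)
  if (any(vapply(cfg, function(v) is.numeric(v) && v <= 0, TRUE)[
    setdiff(names(cfg), c("seed", "sideband_cpd"))])) {
    stop("all pipeline thresholds must be positive", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Per-participant analysis: series to cycles, segments, and summary
#'
#' Runs the full single-participant chain and returns every
#' intermediate table, or a skip reason when the participant drops out
#' (ineligible recording, no oscillatory component, too few cycles or
#' segments).
#'
#' @param series a [hr_series()].
#' @param config a [pipeline_config()].
#' @param diary optional `seizure_diary` for labelling.
#' @param group group label copied into the summary.
#' @return list: `summary` (one row or `NULL`), `cycles`, `segments`
#'   (labelled), `seizure_freq`, `paired` (label-split summaries or
#'   `NULL`), `report`, `skip_reason` (`NA` when analysed).
#' @export
participant_metrics <- function(series, config = pipeline_config(),
                                diary = NULL, group = NA) {
  pre <- preprocess_series(series,
                           max_gap_h = config$max_gap_h,
                           min_gap_h = config$min_gap_h,
                           min_run_days = config$min_run_days,
                           working_interval_s = config$working_interval_s)
  out <- list(summary = NULL, cycles = NULL, segments = NULL,
              seizure_freq = NA_real_, paired = NULL,
              report = pre$report, skip_reason = NA_character_)
  if (!pre$eligible) {
    out$skip_reason <- "no run longer than the eligibility threshold"
    return(out)
  }
  cyc <- list()
  for (k in seq_along(pre$runs)) {
    crhr <- extract_crhr(pre$runs[[k]], window_days = config$window_days,
                         rank = config$rank, rel_tol = config$rel_tol,
                         sideband_cpd = config$sideband_cpd)
    if (is.null(crhr)) next
    cyc[[length(cyc) + 1L]] <- run_cycles(crhr, run_id = k,
                                          edge_trim_h = config$edge_trim_h)
  }
  cycles <- if (length(cyc)) do.call(rbind, cyc) else NULL
  if (is.null(cycles) || nrow(cycles) == 0L) {
    out$skip_reason <- "no circadian cycles recovered"
    return(out)
  }
  out$cycles <- cycles
  segmented <- segment_cycles(cycles, config$cycles_per_segment)
  if (nrow(segmented) == 0L) {
    out$skip_reason <- "no complete segment"
    return(out)
  }
  segs <- label_segments(segment_stats(segmented), diary)
  out$segments <- segs
  out$summary <- intraindividual_summary(segs, series$participant_id, group)
  if (!is.null(diary)) {
    out$seizure_freq <- seizure_frequency(segs, diary)
    out$paired <- split_summary_by_label(segs, series$participant_id, group)
  }
  out
}

#' Run the full cohort pipeline
#'
#' Analyses every participant, assembles the cohort summary table, and
#' runs the group, subsampling, correlation, and paired seizure-segment
#' analyses where the cohort supports them. A manifest records the
#' configuration, seed, and attrition counts at each stage.
#'
#' @param cohort list of participant entries as produced by
#'   [generate_cohort()] (`id`, `group`, `series`, optional `diary`).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-cycle,
#'   per-segment, and summary CSVs plus the stats and manifest JSON are
#'   written there.
#' @return list: `summaries`, `cycles`, `segments`, `group_comparison`,
#'   `subsample` (period variability), `correlation`, `paired_test`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  res <- lapply(cohort, function(p) {
    m <- tryCatch(
      participant_metrics(p$series, config, diary = p$diary, group = p$group),
      error = function(e) {
        stop(sprintf("pipeline failed for participant %s: %s",
                     p$id, conditionMessage(e)), call. = FALSE)
      })
    m$id <- p$id
    m$group <- p$group
    m
  })
  analysed <- Filter(function(m) !is.null(m$summary), res)
  summaries <- do.call(rbind, lapply(analysed, `[[`, "summary"))
  if (!is.null(summaries)) {
    summaries$seizure_freq <- vapply(analysed, `[[`, 0, "seizure_freq")
  }
  cycles <- do.call(rbind, lapply(analysed, function(m) {
    if (is.null(m$cycles)) return(NULL)
    cbind(participant_id = m$id, m$cycles)
  }))
  segments <- do.call(rbind, lapply(analysed, function(m) {
    if (is.null(m$segments)) return(NULL)
    cbind(participant_id = m$id, m$segments)
  }))

  groups <- unique(vapply(cohort, `[[`, "", "group"))
  comparison <- NULL
  subsample <- NULL
  if (length(groups) == 2L && !is.null(summaries)) {
    na <- sum(summaries$group == groups[1L])
    nb <- sum(summaries$group == groups[2L])
    if (na >= 2L && nb >= 2L) {
      comparison <- compare_groups(summaries, groups[1L], groups[2L])
      if (na >= config$n_sub) {
        subsample <- subsample_comparison(
          summaries$var_period[summaries$group == groups[1L]],
          summaries$var_period[summaries$group == groups[2L]],
          n_sub = config$n_sub, iterations = config$iterations,
          seed = derive_seed(config$seed, 1L, stream = 11L))
      }
    }
  }

  correlation <- NULL
  if (!is.null(summaries)) {
    vcols <- c("var_period", "var_acrophase", "var_amplitude")
    with_sz <- !is.na(summaries$seizure_freq) & summaries$seizure_freq > 0
    if (sum(with_sz) >= 3L) {
      vb <- summaries[with_sz, vcols]
      mask <- exclude_outliers(vb)$keep
      if (sum(mask) >= 3L) {
        correlation <- seizure_frequency_correlation(
          summaries$seizure_freq[with_sz][mask], vb[mask, ])
      }
    }
  }

  pairs <- Filter(Negate(is.null), lapply(analysed, `[[`, "paired"))
  paired <- if (length(pairs) >= 2L) paired_seizure_test(pairs) else NULL

  manifest <- list(
    config = unclass(config),
    n_input = length(cohort),
    n_eligible = length(analysed),
    n_excluded = length(cohort) - length(analysed),
    skip_reasons = table(vapply(res, `[[`, "", "skip_reason"), useNA = "ifany"),
    n_correlation = if (is.null(correlation)) 0L else correlation$n[1L],
    n_paired = length(pairs)
  )

  out <- list(summaries = summaries, cycles = cycles, segments = segments,
              group_comparison = comparison, subsample = subsample,
              correlation = correlation, paired_test = paired,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$cycles)) {
    utils::write.csv(out$cycles, file.path(out_dir, "cycles.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$segments)) {
    utils::write.csv(out$segments, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$summaries)) {
    utils::write.csv(out$summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
  }
  stats_json <- list(
    group_comparison = out$group_comparison,
    subsample = if (!is.null(out$subsample)) {
      out$subsample[c("frac_significant", "median_d", "n_sub", "iterations")]
    },
    correlation = out$correlation,
    paired_test = out$paired_test
  )
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Write / read the heart-rate and diary CSV interchange formats
#'
#' Heart-rate CSV columns: `participant_id`, `timestamp` (ISO-8601
#' UTC), `bpm`. Diary CSV columns: `participant_id`, `seizure_time`
#' (ISO-8601 UTC). Timestamps are interpreted against an epoch of
#' 2020-01-01T00:00:00Z; malformed rows are hard errors naming the
#' line.
#'
#' @param serieses list of [hr_series()].
#' @param path CSV file path.
#' @return `write_heart_rate_csv` returns `path`;
#'   `load_heart_rate_csv` a list of [hr_series()];
#'   `load_diary_csv` a list of `seizure_diary`.
#' @export
write_heart_rate_csv <- function(serieses, path) {
  rows <- do.call(rbind, lapply(serieses, function(s) {
    data.frame(participant_id = s$participant_id,
               timestamp = format(csv_epoch() + s$time,
                                  "%Y-%m-%dT%H:%M:%OS1Z", tz = "UTC"),
               bpm = s$bpm)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

csv_epoch <- function() as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

parse_iso8601 <- function(x, what) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad)) {
    stop(sprintf("unparseable %s timestamp at data row %d: %s",
                 what, bad[1L], x[bad[1L]]), call. = FALSE)
  }
  as.numeric(t) - as.numeric(csv_epoch())
}

#' @rdname write_heart_rate_csv
#' @param nominal_interval,tz_offset_min metadata attached to every
#'   loaded series.
#' @export
load_heart_rate_csv <- function(path, nominal_interval = 5, tz_offset_min = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(sort(names(df)), sort(c("participant_id", "timestamp", "bpm")))) {
    stop("heart-rate CSV must have columns participant_id, timestamp, bpm",
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  if (any(!is.finite(df$bpm)) || any(df$bpm <= 0)) {
    stop(sprintf("non-positive bpm at data row %d",
                 which(!is.finite(df$bpm) | df$bpm <= 0)[1L]), call. = FALSE)
  }
  df$time <- parse_iso8601(df$timestamp, "heart-rate")
  lapply(split(df, df$participant_id), function(g) {
    g <- g[order(g$time), ]
    hr_series(g$participant_id[1L], g$time, g$bpm, nominal_interval,
              tz_offset_min)
  })
}

#' @rdname write_heart_rate_csv
#' @param diaries list of `seizure_diary`.
#' @export
write_diary_csv <- function(diaries, path) {
  rows <- do.call(rbind, lapply(diaries, function(d) {
    if (length(d$events) == 0L) return(NULL)
    data.frame(participant_id = d$participant_id,
               seizure_time = format(csv_epoch() + d$events,
                                     "%Y-%m-%dT%H:%M:%OS1Z", tz = "UTC"))
  }))
  if (is.null(rows)) {
    rows <- data.frame(participant_id = character(0),
                       seizure_time = character(0))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heart_rate_csv
#' @export
load_diary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(sort(names(df)), sort(c("participant_id", "seizure_time")))) {
    stop("diary CSV must have columns participant_id, seizure_time",
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  df$time <- parse_iso8601(df$seizure_time, "diary")
  lapply(split(df, df$participant_id), function(g) {
    ev <- sort(g$time)
    structure(list(participant_id = g$participant_id[1L], events = ev,
                   span = range(ev)),
              class = "seizure_diary")
  })
}
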