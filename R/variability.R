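# Intraindividual variability: per-cycle circadian properties are
# grouped into consecutive non-overlapping 7-cycle (~7-day) segments;
# within each segment the mean and SD of each property are taken, and a
# participant's summary is the unweighted mean of segment means
# (intraindividual average) and of segment SDs (intraindividual
# variability). The fixed segment size keeps the SD's sample size equal
# across participants regardless of recording length.

#' Group a participant's cycles into consecutive 7-cycle segments
#'
#' Within each run, consecutive blocks of exactly `cycles_per_segment`
#' cycles form one segment; trailing partial blocks are discarded and
#' segments never span runs.
#'
#' @param cycles per-participant cycle table ([cycle_properties()]
#'   rows, possibly from several runs), ordered in time within run.
#' @param cycles_per_segment segment size in cycles (default 7, one per
#'   nominal day).
#' @return data frame with one row per cycle that falls in a complete
#'   segment, with an added `segment` index (unique across runs).
#' @export
segment_cycles <- function(cycles, cycles_per_segment = 7L) {
  stopifnot(is.data.frame(cycles))
  if (nrow(cycles) == 0L) return(cbind(cycles, segment = integer(0)))
  out <- list()
  seg_base <- 0L
  for (rid in unique(cycles$run_id)) {
    cc <- cycles[cycles$run_id == rid, , drop = FALSE]
    cc <- cc[order(cc$start_s), , drop = FALSE]
    n_seg <- nrow(cc) %/% cycles_per_segment
    if (n_seg == 0L) next
    keep <- cc[seq_len(n_seg * cycles_per_segment), , drop = FALSE]
    keep$segment <- seg_base + rep(seq_len(n_seg), each = cycles_per_segment)
    seg_base <- seg_base + n_seg
    out[[length(out) + 1L]] <- keep
  }
  if (length(out) == 0L) return(cbind(cycles[0, , drop = FALSE], segment = integer(0)))
  do.call(rbind, out)
}

#' Per-segment mean and SD of each circadian property
#'
#' Period and amplitude use the arithmetic mean and sample SD (n - 1
#' denominator). Acrophase lives on the 24-h clock circle, so its mean
#' is the circular mean and its SD is the sample SD of signed minimal
#' deviations (each in `(-720, 720]` min) from that circular mean —
#' peaks straddling midnight would otherwise produce absurd
#' dispersions. Set `circular_acrophase = FALSE` for the naive linear
#' treatment in sensitivity analyses.
#'
#' @param segmented output of [segment_cycles()].
#' @param circular_acrophase logical; circular acrophase statistics
#'   (default) or naive linear ones.
#' @return data frame, one row per segment: `segment`, `run_id`,
#'   `start_s`, `end_s`, `n_cycles`, and `mean_` / `sd_` columns for
#'   `period`, `acrophase`, `amplitude`.
#' @export
segment_stats <- function(segmented, circular_acrophase = TRUE) {
  stopifnot(is.data.frame(segmented))
  segs <- unique(segmented$segment)
  rows <- lapply(segs, function(s) {
    cc <- segmented[segmented$segment == s, , drop = FALSE]
    acro_mean <- if (circular_acrophase) {
      circular_mean_min(cc$acrophase_min)
    } else {
      mean(cc$acrophase_min)
    }
    data.frame(
      segment = s,
      run_id = cc$run_id[1L],
      start_s = min(cc$start_s),
      end_s = max(cc$end_s),
      n_cycles = nrow(cc),
      mean_period = mean(cc$period_min),
      sd_period = stats::sd(cc$period_min),
      mean_acrophase = acro_mean,
      sd_acrophase = circular_sd_min(cc$acrophase_min,
                                     circular = circular_acrophase),
      mean_amplitude = mean(cc$amplitude_bpm),
      sd_amplitude = stats::sd(cc$amplitude_bpm)
    )
  })
  do.call(rbind, rows)
}

#' Intraindividual average and variability across segments
#'
#' The summary variability of each property is the unweighted mean of
#' the per-segment SDs; the summary average is the unweighted mean of
#' the per-segment means (circular mean of the segment circular means
#' for acrophase). With segment SDs of 34 and 59 min, the
#' intraindividual variability is (34 + 59) / 2 = 46.5 min.
#'
#' @param seg_stats per-segment statistics ([segment_stats()]), or any
#'   subset of its rows (e.g. one seizure label).
#' @param participant_id,group identifiers copied into the output.
#' @return one-row data frame: `participant_id`, `group`, `n_segments`,
#'   `avg_` and `var_` columns for `period`, `acrophase`, `amplitude`;
#'   `NULL` when no segment is supplied (participant excluded).
#' @export
intraindividual_summary <- function(seg_stats, participant_id = "p", group = NA) {
  if (is.null(seg_stats) || nrow(seg_stats) == 0L) return(NULL)
  data.frame(
    participant_id = participant_id,
    group = group,
    n_segments = nrow(seg_stats),
    avg_period = mean(seg_stats$mean_period),
    var_period = mean(seg_stats$sd_period),
    avg_acrophase = circular_mean_min(seg_stats$mean_acrophase),
    var_acrophase = mean(seg_stats$sd_acrophase),
    avg_amplitude = mean(seg_stats$mean_amplitude),
    var_amplitude = mean(seg_stats$sd_amplitude)
  )
}

#' Label segments by seizure content
#'
#' Segments lying fully inside the diary span are labelled
#' `"containing"` when at least one diary event falls in the segment's
#' half-open time span `[start, end)`, else `"free"`. Segments outside
#' or overlapping the span's edges — or all segments, when no diary
#' exists — are labelled `"outside-diary"` and excluded from seizure
#' analyses.
#'
#' @param seg_stats per-segment statistics ([segment_stats()]).
#' @param diary a `seizure_diary` (see [generate_seizure_diary()]) or
#'   `NULL`.
#' @return `seg_stats` with an added `seizure_label` column.
#' @export
label_segments <- function(seg_stats, diary = NULL) {
  if (is.null(seg_stats) || nrow(seg_stats) == 0L) return(seg_stats)
  lab <- rep("outside-diary", nrow(seg_stats))
  if (!is.null(diary)) {
    inside <- seg_stats$start_s >= diary$span[1L] & seg_stats$end_s <= diary$span[2L]
    has_event <- vapply(seq_len(nrow(seg_stats)), function(i) {
      any(diary$events >= seg_stats$start_s[i] & diary$events < seg_stats$end_s[i])
    }, TRUE)
    lab[inside & has_event] <- "containing"
    lab[inside & !has_event] <- "free"
  }
  seg_stats$seizure_label <- lab
  seg_stats
}

#' Seizure frequency per week of segmented recording
#'
#' Diary events are counted only when they fall inside an in-span
#' (labelled) segment; the denominator is the number of in-span
#' segments, one segment counting as one week.
#'
#' @param labelled output of [label_segments()].
#' @param diary the participant's `seizure_diary`.
#' @return seizures per week, or `NA` when the participant has no
#'   in-span segment (excluded from the correlation analysis).
#' @export
seizure_frequency <- function(labelled, diary) {
  inspan <- labelled[labelled$seizure_label != "outside-diary", , drop = FALSE]
  if (nrow(inspan) == 0L || is.null(diary)) return(NA_real_)
  n_events <- sum(vapply(seq_len(nrow(inspan)), function(i) {
    sum(diary$events >= inspan$start_s[i] & diary$events < inspan$end_s[i])
  }, 0))
  n_events / nrow(inspan)
}

#' Separate summaries over seizure-containing and seizure-free segments
#'
#' For participants with at least `min_each` segments of each label,
#' computes [intraindividual_summary()] restricted to each label;
#' others are excluded from the paired analysis.
#'
#' @param labelled output of [label_segments()].
#' @param participant_id,group identifiers copied into the outputs.
#' @param min_each minimum segments per label (default 5).
#' @return list with `containing` and `free` one-row summaries, or
#'   `NULL` when the participant does not qualify.
#' @export
split_summary_by_label <- function(labelled, participant_id = "p",
                                   group = NA, min_each = 5L) {
  cont <- labelled[labelled$seizure_label == "containing", , drop = FALSE]
  free <- labelled[labelled$seizure_label == "free", , drop = FALSE]
  if (nrow(cont) < min_each || nrow(free) < min_each) return(NULL)
  list(
    containing = intraindividual_summary(cont, participant_id, group),
    free = intraindividual_summary(free, participant_id, group)
  )
}
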