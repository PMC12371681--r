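test_that("cycles group into complete 7-cycle segments, partials discarded", {
  seg <- segment_cycles(make_cycles(rep(1440, 16)))
  expect_equal(nrow(seg), 14)
  expect_equal(as.integer(table(seg$segment)), c(7L, 7L))
  two_runs <- rbind(make_cycles(rep(1440, 10), run_id = 1L),
                    make_cycles(rep(1440, 10), run_id = 2L, start0 = 30 * 86400))
  seg2 <- segment_cycles(two_runs)
  expect_equal(length(unique(seg2$segment)), 2)
  expect_equal(nrow(seg2), 14)
  expect_true(all(tapply(seg2$run_id, seg2$segment, function(r) length(unique(r))) == 1))
  expect_equal(nrow(segment_cycles(make_cycles(rep(1440, 6)))), 0)
})

test_that("segment statistics: linear for period/amplitude, circular for acrophase", {
  ident <- segment_stats(segment_cycles(make_cycles(rep(1450, 7),
                                                    acrophases = rep(10, 7),
                                                    amplitudes = rep(8, 7))))
  expect_equal(ident$sd_period, 0)
  expect_equal(ident$sd_acrophase, 0)
  expect_equal(ident$sd_amplitude, 0)
  expect_equal(ident$mean_acrophase, 10)

  # acrophases straddling midnight: circular mean ~0, SD from the
  # brute-force circular oracle (grid-search mean, n-1 SD of signed
  # minimal deviations) = 10.80123; the naive linear SD is ~760
  acro <- c(1430, 10, 1435, 5, 1425, 15, 0)
  st <- segment_stats(segment_cycles(make_cycles(rep(1440, 7), acrophases = acro)))
  expect_lt(min(st$mean_acrophase, 1440 - st$mean_acrophase), 1e-6)
  expect_equal(st$sd_acrophase, 10.80123, tolerance = 1e-6)
  naive <- segment_stats(segment_cycles(make_cycles(rep(1440, 7), acrophases = acro)),
                         circular_acrophase = FALSE)
  expect_gt(naive$sd_acrophase, 700)

  # alternating periods: hand-computed sample SD
  per <- c(1440, 1500, 1440, 1500, 1440, 1500, 1440)
  stp <- segment_stats(segment_cycles(make_cycles(per)))
  expect_equal(stp$sd_period, 32.0713, tolerance = 1e-4)
  expect_equal(stp$mean_period, 10260 / 7, tolerance = 1e-10)
})

test_that("intraindividual variability averages segment SDs: (34+59)/2 = 46.5", {
  segs <- make_seg_stats(sd_acrophase = c(34, 59))
  s <- intraindividual_summary(segs)
  expect_identical(s$var_acrophase, 46.5)
  one <- intraindividual_summary(make_seg_stats(sd_acrophase = 17))
  expect_identical(one$var_acrophase, 17)
  expect_null(intraindividual_summary(make_seg_stats(numeric(0))))
})

test_that("summaries are permutation invariant and respect shifts", {
  segs <- make_seg_stats(sd_acrophase = c(10, 20, 30),
                         sd_period = c(5, 6, 7), mean_period = c(1430, 1440, 1450))
  a <- intraindividual_summary(segs)
  b <- intraindividual_summary(segs[c(3, 1, 2), ])
  expect_equal(a[-1], b[-1])

  # constant period offset: variability unchanged
  cyc <- make_cycles(1440 + c(-30, 10, 0, 25, -15, 5, 5, -20, 30, 0, 10, -10, 5, -25))
  cyc2 <- cyc
  cyc2$period_min <- cyc2$period_min + 100
  v1 <- intraindividual_summary(segment_stats(segment_cycles(cyc)))
  v2 <- intraindividual_summary(segment_stats(segment_cycles(cyc2)))
  expect_equal(v2$var_period, v1$var_period)
  expect_equal(v2$avg_period, v1$avg_period + 100)

  # common clock shift: acrophase variability unchanged
  acro <- c(1400, 20, 1430, 50, 10, 1420, 40, 0, 30, 1410, 1440 - 5, 25, 15, 1435)
  cyc3 <- make_cycles(rep(1440, 14), acrophases = acro)
  cyc4 <- make_cycles(rep(1440, 14), acrophases = (acro + 313) %% 1440)
  v3 <- intraindividual_summary(segment_stats(segment_cycles(cyc3)))
  v4 <- intraindividual_summary(segment_stats(segment_cycles(cyc4)))
  expect_equal(v4$var_acrophase, v3$var_acrophase, tolerance = 1e-8)
})

test_that("segments are labelled by diary content with half-open spans", {
  segs <- make_seg_stats(sd_acrophase = c(10, 10, 10, 10))  # 4 weeks from 0
  diary <- structure(list(participant_id = "p",
                          events = c(0, 14 * 86400),
                          span = c(0, 28 * 86400)),
                     class = "seizure_diary")
  lab <- label_segments(segs, diary)
  # event at t=0: first segment contains it; event at exactly the end of
  # segment 2 (14 d) belongs to segment 3
  expect_equal(lab$seizure_label, c("containing", "free", "containing", "free"))
  empty <- structure(list(participant_id = "p", events = numeric(0),
                          span = c(0, 28 * 86400)), class = "seizure_diary")
  expect_true(all(label_segments(segs, empty)$seizure_label == "free"))
  expect_true(all(label_segments(segs, NULL)$seizure_label == "outside-diary"))
  # diary covering only half the recording
  half <- structure(list(participant_id = "p", events = numeric(0),
                         span = c(0, 13 * 86400)), class = "seizure_diary")
  expect_equal(label_segments(segs, half)$seizure_label,
               c("free", rep("outside-diary", 3)))
})

test_that("seizure frequency counts events inside in-span segments only", {
  segs <- make_seg_stats(sd_acrophase = rep(10, 3))
  diary <- structure(list(participant_id = "p",
                          events = c(1, 2, 3, 8, 9, 16) * 86400,
                          span = c(0, 21 * 86400)), class = "seizure_diary")
  lab <- label_segments(segs, diary)
  expect_equal(seizure_frequency(lab, diary), 2)
  none <- structure(list(participant_id = "p", events = numeric(0),
                         span = c(0, 21 * 86400)), class = "seizure_diary")
  expect_equal(seizure_frequency(label_segments(segs, none), none), 0)
  # events beyond the segmented span are not counted
  late <- structure(list(participant_id = "p",
                         events = c(86400, 25 * 86400),
                         span = c(0, 40 * 86400)), class = "seizure_diary")
  expect_equal(seizure_frequency(label_segments(segs, late), late), 1 / 3)
})

test_that("label-split summaries need five segments of each kind", {
  segs <- make_seg_stats(sd_acrophase = rep(10, 10))
  segs$seizure_label <- rep(c("containing", "free"), each = 5)
  sp <- split_summary_by_label(segs)
  expect_equal(sp$containing$var_acrophase, sp$free$var_acrophase)
  segs$seizure_label <- c(rep("containing", 6), rep("free", 4))
  expect_null(split_summary_by_label(segs))
})
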