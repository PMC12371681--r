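test_that("full-rank SSA reconstructs the series exactly", {
  set.seed(31)
  x <- cumsum(rnorm(400)) + 5 * sin(2 * pi * (1:400) / 24)
  dec <- ssa_decompose(x, window_length = 40, rank = 40, interval_s = 3600)
  recon <- rowSums(dec$recon) + dec$mean
  expect_lt(sqrt(mean((recon - x)^2)) / sd(x), 1e-10)
  expect_true(all(diff(dec$sigma) <= 1e-8))
})

test_that("a pure cosine concentrates in the leading eigentriple pair", {
  r <- cosine_run(14, dt = 300)
  dec <- ssa_decompose(r, window_length = 2 * 288, rank = 20)
  energy <- dec$sigma^2
  expect_gt(sum(energy[1:2]) / sum(energy), 0.99)
  expect_equal(dec$period_h[1], 24, tolerance = 0.25 / 24)
  g <- group_components_by_frequency(dec)
  expect_setequal(g$groups[[1]]$members, 1:2)
})

test_that("a constant series has no oscillatory energy after mean removal", {
  dec <- ssa_decompose(rep(60, 500), window_length = 50, rank = 10,
                       interval_s = 300)
  expect_lt(max(dec$sigma), 1e-8)
  expect_true(all(is.na(dec$period_h)))
})

test_that("central period is located to the stated resolution", {
  t_s <- seq(0, 10 * 86400, by = 300)
  expect_equal(component_central_period(sin(2 * pi * t_s / 86400), 300),
               24, tolerance = 0.25 / 24)
  expect_equal(component_central_period(sin(2 * pi * t_s / 43200), 300),
               12, tolerance = 0.1 / 12)
  expect_true(is.na(component_central_period(rep(3, 1000), 300)))
})

test_that("two tones yield two oscillatory groups and 24 h is selected", {
  t_s <- seq(0, 14 * 86400, by = 300)
  x <- 8 * cos(2 * pi * t_s / 86400) + 4 * cos(2 * pi * t_s / 43200)
  dec <- ssa_decompose(x, window_length = 2 * 288, rank = 8, interval_s = 300)
  g <- group_components_by_frequency(dec)
  periods <- vapply(g$groups, `[[`, 0, "period_h")
  osc <- periods[!is.na(periods) & vapply(g$groups, `[[`, 0, "energy") >
                   0.001 * g$groups[[1]]$energy]
  expect_equal(sort(round(osc[1:2])), c(12, 24))
  sel <- select_circadian(g)
  expect_equal(sel$central_period, 24, tolerance = 0.02)
})

test_that("rel_tol = 0 disables merging", {
  r <- cosine_run(10, dt = 300)
  dec <- ssa_decompose(r, window_length = 288, rank = 6)
  g <- group_components_by_frequency(dec, rel_tol = 0)
  expect_length(g$groups, 6)
})

test_that("selection picks the candidate closest to 24 h, ties to energy", {
  fake <- function(periods, energies) {
    groups <- lapply(seq_along(periods), function(i) {
      list(members = i, values = sin(seq_len(600) / periods[i]),
           energy = energies[i], period_h = periods[i])
    })
    structure(list(groups = groups, start_time = 0, interval_s = 300,
                   tz_offset_min = 0, rank = length(periods)),
              class = "ssa_decomp")
  }
  sel <- select_circadian(fake(c(12, 24.2, 167), c(9, 5, 20)),
                          sideband_cpd = 0)
  expect_equal(sel$central_period, 24.2)
  sel2 <- select_circadian(fake(c(23.9, 24.05), c(1, 2)), sideband_cpd = 0)
  expect_equal(sel2$central_period, 24.05)
  expect_message(
    sel3 <- select_circadian(fake(c(23.8, 24.2), c(1, 5)), sideband_cpd = 0),
    "tie")
  expect_equal(sel3$central_period, 24.2)
  expect_message(expect_null(select_circadian(fake(167, 3))), "skipped")
})

test_that("sideband groups within half a cycle/day are absorbed", {
  t_s <- seq(0, 20 * 86400, by = 300)
  x <- 10 * cos(2 * pi * t_s / 86400) + 1.5 * cos(2 * pi * t_s / (16.5 * 3600)) +
    1.5 * cos(2 * pi * t_s / (40 * 3600))
  dec <- ssa_decompose(x, window_length = round(1.5 * 288), rank = 10,
                       interval_s = 300)
  g <- group_components_by_frequency(dec)
  sel <- select_circadian(g)
  # 16.5 h (+0.55 cpd away? 24/16.5 - 1 = 0.4545) and 40 h (0.4 cpd) absorbed
  expect_gt(length(sel$members), 2)
  narrow <- select_circadian(g, sideband_cpd = 0)
  expect_length(narrow$members, 2)
})

test_that("the randomized truncated SVD agrees with the dense decomposition", {
  set.seed(77)
  t_s <- seq(0, 40 * 86400, by = 300)
  x <- 10 * cos(2 * pi * t_s / 86400) + 3 * cos(2 * pi * t_s / 43200) +
    rnorm(length(t_s), 0, 2)
  L <- 432  # 1.5 days; L * K > 4e6 forces the randomized path at rank 8
  fast <- ssa_decompose(x, window_length = L, rank = 8L, interval_s = 300)
  expect_false(fast$exact)
  slow <- ssa_decompose(x, window_length = L, rank = 200L, interval_s = 300)
  expect_true(slow$exact)
  # the four leading (signal) singular values are resolved sharply; the
  # noise tail is not guaranteed by a randomized range finder
  expect_equal(fast$sigma[1:4], slow$sigma[1:4], tolerance = 1e-6)
  for (j in 1:4) {
    expect_gt(abs(cor(fast$recon[, j], slow$recon[, j])), 1 - 1e-8)
  }
})

test_that("noisy runs still select a near-24-h component", {
  set.seed(55)
  t_s <- seq(0, 12 * 86400, by = 300)
  x <- 10 * cos(2 * pi * t_s / 86400) + rnorm(length(t_s), 0, 6)
  run <- hr_run(0, 300, 70 + x)
  sel <- extract_crhr(run)
  expect_false(is.null(sel))
  expect_lt(abs(sel$central_period - 24), 1)
})
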