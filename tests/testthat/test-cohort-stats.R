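test_that("Cohen's d follows the pooled-SD formula and its symmetries", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(5, 6, 7), c(5, 6, 7)), 0)
  set.seed(8)
  a <- rnorm(9)
  b <- rnorm(14, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  sp <- sqrt((8 * var(a) + 13 * var(b)) / 21)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_warning(expect_true(is.na(cohens_d(c(1, 1), c(1, 1)))), "pooled")
})

test_that("rank-sum test: exact small-sample null and frozen examples", {
  rs <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p, 0.1)          # 2 of the 20 orderings are as extreme
  expect_equal(rs$method, "exact")
  same <- ranksum_test(c(3, 1, 4), c(4, 1, 3))
  expect_equal(same$p, 1)
  set.seed(14)
  for (i in 1:40) {
    na <- sample(1:7, 1)
    nb <- sample(seq_len(8 - na), 1)
    vals <- if (i %% 2) rnorm(na + nb) else sample(1:4, na + nb, replace = TRUE)
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    expect_equal(ranksum_test(a, b)$p, oracle_ranksum_p(a, b), tolerance = 1e-12)
  }
})

test_that("rank-sum test agrees with the classical implementation when tie-free", {
  set.seed(15)
  for (i in 1:25) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1))
    expect_equal(ranksum_test(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  for (i in 1:25) {
    a <- rnorm(20)
    b <- rnorm(15, 0.5)
    expect_equal(ranksum_test(a, b)$p,
                 wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("signed-rank test: exact null, zero-difference rule, paired d", {
  sr <- signedrank_test(c(1, 2, 3, 4, 5) + 10, rep(10, 5))
  expect_equal(sr$p, 0.0625)       # 2 of the 32 sign patterns as extreme
  expect_equal(sr$statistic, 15)
  ident <- signedrank_test(c(4, 4, 4), c(4, 4, 4))
  expect_equal(ident$p, 1)
  expect_equal(ident$d, 0)
  set.seed(16)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    x <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    y <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    expect_equal(signedrank_test(x, y)$p, oracle_signedrank_p(x, y),
                 tolerance = 1e-12)
  }
  for (i in 1:25) {
    x <- rnorm(25)
    y <- rnorm(25, 0.3)
    expect_equal(signedrank_test(x, y)$p,
                 wilcox.test(x, y, paired = TRUE, exact = FALSE,
                             correct = FALSE)$p.value, tolerance = 1e-12)
  }
  d <- rnorm(12)
  expect_equal(signedrank_test(d + 5, rep(5, 12))$d, mean(d) / sd(d))
})

test_that("subsampling control is reproducible and degenerates correctly", {
  set.seed(17)
  pwe <- rnorm(30, 1)
  ctrl <- rnorm(20)
  r1 <- subsample_comparison(pwe, ctrl, n_sub = 10, iterations = 200, seed = 3)
  r2 <- subsample_comparison(pwe, ctrl, n_sub = 10, iterations = 200, seed = 3)
  expect_identical(r1, r2)
  r3 <- subsample_comparison(pwe, ctrl, n_sub = 10, iterations = 200, seed = 4)
  expect_false(identical(r1$p, r3$p))
  # subsample size equal to the pool: every iteration is the full test
  full <- subsample_comparison(pwe, ctrl, n_sub = 30, iterations = 50, seed = 5)
  expect_equal(unique(full$p), ranksum_test(pwe, ctrl)$p)
  expect_equal(unique(full$d), cohens_d(pwe, ctrl))
  expect_error(subsample_comparison(rnorm(10), ctrl, n_sub = 28), "fewer")
})

test_that("outlier exclusion applies the |z| > 3 rule across properties", {
  allsame <- data.frame(a = rep(2, 5), b = rep(3, 5))
  expect_warning(m <- exclude_outliers(allsame), "zero SD")
  expect_true(all(m$keep))

  v <- c(rep(0, 9), 100)
  z_direct <- (v - mean(v)) / sd(v)   # z of the extreme value: 2.846
  m2 <- exclude_outliers(data.frame(x = v))
  expect_equal(unname(m2$z[, 1]), z_direct)
  expect_identical(unname(m2$keep), abs(z_direct) <= 3)
  expect_true(m2$keep[10])            # 2.846 < 3: retained

  # outlying in one property removes the participant entirely
  df <- data.frame(a = c(rnorm(12), 50), b = rnorm(13))
  m3 <- exclude_outliers(df)
  expect_false(m3$keep[13])
  expect_equal(sum(!m3$keep), 1)
})

test_that("seizure-frequency correlation is Pearson on log10 frequency", {
  freq <- c(0.25, 0.5, 1, 2, 4, 8)
  vb <- data.frame(var_period = 10 + 3 * log10(freq))
  res <- seizure_frequency_correlation(freq, vb)
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_lte(res$ci_lo, 1)
  set.seed(18)
  x <- abs(rnorm(20)) + 0.1
  y <- rnorm(20)
  r_xy <- seizure_frequency_correlation(x, data.frame(v = y))$r
  expect_equal(r_xy, cor(log10(x), y), tolerance = 1e-12)
  expect_error(seizure_frequency_correlation(c(0, 1, 2), data.frame(v = 1:3)),
               "log10")
  # null: mean correlation near zero across replicates
  rs <- vapply(1:100, function(i) {
    set.seed(300 + i)
    seizure_frequency_correlation(abs(rnorm(25)) + 0.1,
                                  data.frame(v = rnorm(25)))$r
  }, 0)
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("paired seizure-segment test handles identical and shifted pairs", {
  mk_summary <- function(vp) {
    data.frame(participant_id = "p", group = "pwe", n_segments = 6,
               avg_period = 1440, var_period = vp, avg_acrophase = 900,
               var_acrophase = 50, avg_amplitude = 10, var_amplitude = 2)
  }
  ident <- lapply(1:6, function(i) {
    list(containing = mk_summary(60 + i), free = mk_summary(60 + i))
  })
  res <- paired_seizure_test(ident)
  expect_true(all(res$p == 1))
  expect_true(all(res$d == 0))
  shifted <- lapply(1:6, function(i) {
    list(containing = mk_summary(60 + i + 5 + 0.3 * i), free = mk_summary(60 + i))
  })
  res2 <- paired_seizure_test(shifted)
  vp <- res2[res2$measure == "var_period", ]
  expect_equal(vp$p, 2 / 64)   # all six differences positive, exact null
  expect_gt(vp$d, 1)
})

test_that("group comparison reports medians, p, and d per measure", {
  set.seed(19)
  mk <- function(id, grp, vp) {
    data.frame(participant_id = id, group = grp, n_segments = 8,
               avg_period = rnorm(1, 1441), var_period = vp,
               avg_acrophase = rnorm(1, 900, 15), var_acrophase = vp * 0.8,
               avg_amplitude = rnorm(1, 10), var_amplitude = rnorm(1, 2, 0.1))
  }
  summaries <- rbind(
    do.call(rbind, lapply(1:12, function(i) mk(paste0("a", i), "pwe", 70 + rnorm(1, 0, 8)))),
    do.call(rbind, lapply(1:12, function(i) mk(paste0("b", i), "control", 50 + rnorm(1, 0, 8))))
  )
  cmp <- compare_groups(summaries)
  row <- cmp[cmp$measure == "var_period", ]
  expect_gt(row$d, 0)
  expect_lt(row$p, 0.05)
  expect_equal(row$n_a, 12)
  expect_equal(row$median_b,
               median(summaries$var_period[summaries$group == "control"]))
})
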