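# Nonparametric cohort statistics: rank-sum and signed-rank tests with
# exact small-sample nulls (midranks under ties), Cohen's d effect
# sizes, the 28-of-PWE subsampling control, outlier exclusion, and the
# log10 seizure-frequency correlation. All p-values are reported raw,
# uncorrected.

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_pooled` with
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' The sign convention is first group (patients) minus second
#' (controls).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return Cohen's d; `NA` (with a warning) when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks are used under ties. For combined samples of at most
#' `exact_max` observations the null is computed exactly by
#' enumerating every assignment of the observed (mid)ranks to the two
#' groups; beyond that, the normal approximation with tie-corrected
#' variance is used (no continuity correction).
#'
#' @param a,b numeric vectors (>= 1 observation each).
#' @param exact_max combined-size threshold for the exact null
#'   (default 12).
#' @return list: `statistic` (Mann-Whitney U of the first sample), `p`
#'   (two-sided), `method` (`"exact"` or `"normal"`).
#' @export
ranksum_test <- function(a, b, exact_max = 12L) {
  na <- length(a)
  nb <- length(b)
  stopifnot(na >= 1L, nb >= 1L)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  if (n <= exact_max) {
    splits <- utils::combn(n, na)
    us <- colSums(matrix(r[splits], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(list(statistic = U, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(statistic = U, p = 1, method = "normal"))
  z <- (U - mu) / sqrt(sig2)
  list(statistic = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Wilcoxon signed-rank paired test with paired Cohen's d
#'
#' Zero differences are dropped (classical Wilcoxon convention) and
#' midranks of the absolute differences are used. For at most
#' `exact_max` non-zero differences the null is exact, enumerating all
#' `2^n` sign assignments; otherwise the tie-corrected normal
#' approximation is used. The paired effect size is the mean difference
#' over the SD of differences (computed before dropping zeros).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max threshold for the exact null (default 15).
#' @return list: `statistic` (V, sum of positive ranks), `p`
#'   (two-sided), `d` (paired Cohen's d), `n_nonzero`, `method`.
#' @export
signedrank_test <- function(x, y, exact_max = 15L) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- x - y
  sd_d <- stats::sd(d)
  d_eff <- if (is.na(sd_d) || sd_d == 0) 0 else mean(d) / sd_d
  dz <- d[d != 0]
  n <- length(dz)
  if (n == 0L) {
    return(list(statistic = 0, p = 1, d = d_eff, n_nonzero = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(dz))
  V <- sum(r[dz > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    mu <- sum(r) / 2
    p <- mean(abs(vs - mu) >= abs(V - mu) - 1e-9)
    return(list(statistic = V, p = p, d = d_eff, n_nonzero = n,
                method = "exact"))
  }
  mu <- sum(r) / 2
  sig2 <- sum(r^2) / 4
  z <- (V - mu) / sqrt(sig2)
  list(statistic = V, p = min(1, 2 * stats::pnorm(-abs(z))), d = d_eff,
       n_nonzero = n, method = "normal")
}

#' Random-subsampling control for unbalanced group sizes
#'
#' Repeatedly compares the whole control sample against a random
#' subsample of `n_sub` patients, recording the rank-sum p and Cohen's
#' d of every iteration. Sampling is without replacement within an
#' iteration and with replacement across iterations; seeded and
#' reproducible.
#'
#' @param pwe,ctrl numeric vectors (patients, controls).
#' @param n_sub patients drawn per iteration (default 28; must not
#'   exceed `length(pwe)`).
#' @param iterations number of subsample draws (default 10000).
#' @param seed integer seed.
#' @param alpha significance level summarised over iterations.
#' @return list: per-iteration `p` and `d`, `frac_significant`,
#'   `median_d`, `n_sub`, `iterations`.
#' @export
subsample_comparison <- function(pwe, ctrl, n_sub = 28L, iterations = 10000L,
                                 seed = 1L, alpha = 0.05) {
  if (length(pwe) < n_sub) {
    stop("fewer patients than the subsample size", call. = FALSE)
  }
  set.seed(seed %% 2147483647)
  p <- numeric(iterations)
  d <- numeric(iterations)
  for (i in seq_len(iterations)) {
    sub <- pwe[sample.int(length(pwe), n_sub)]
    p[i] <- ranksum_test(sub, ctrl)$p
    d[i] <- cohens_d(sub, ctrl)
  }
  list(p = p, d = d,
       frac_significant = mean(p < alpha),
       median_d = stats::median(d),
       n_sub = n_sub, iterations = iterations)
}

#' Outlier exclusion mask on intraindividual variability
#'
#' Z-scores are computed per property across the supplied participants
#' (patients only, in the cohort analysis); a participant is excluded
#' when any property's absolute z-score exceeds `z_max`.
#'
#' @param variability data frame (or matrix) of per-participant
#'   variability values, one column per property.
#' @param z_max exclusion threshold (default 3).
#' @return list: `keep` logical mask, `z` the z-score matrix.
#' @export
exclude_outliers <- function(variability, z_max = 3) {
  m <- as.matrix(variability)
  stopifnot(nrow(m) >= 3L)
  z <- scale(m)
  degenerate <- attr(z, "scaled:scale") == 0 | !is.finite(attr(z, "scaled:scale"))
  if (any(degenerate)) {
    warning("zero SD in property: ",
            paste(colnames(m)[degenerate], collapse = ", "),
            "; no exclusions from it")
    z[, degenerate] <- 0
  }
  keep <- apply(abs(z) <= z_max, 1L, all)
  list(keep = keep, z = z)
}

#' Correlation of intraindividual variability with seizure frequency
#'
#' Pearson correlation between `log10(seizures per week)` and each
#' property's variability, with the two-sided p-value and Fisher-z 95%
#' confidence interval. Participants with zero recorded seizures or
#' outlying variability must be removed beforehand (see
#' [exclude_outliers()]).
#'
#' @param freq_per_week positive seizure frequencies.
#' @param variability data frame of variability values, one column per
#'   property, rows matching `freq_per_week`.
#' @return data frame: `property`, `r`, `p`, `ci_lo`, `ci_hi`, `n`.
#' @export
seizure_frequency_correlation <- function(freq_per_week, variability) {
  stopifnot(length(freq_per_week) == nrow(variability))
  if (length(freq_per_week) < 3L) stop("need at least 3 participants",
                                       call. = FALSE)
  if (any(freq_per_week <= 0)) {
    stop("zero-frequency participants must be removed before the log10 transform",
         call. = FALSE)
  }
  lf <- log10(freq_per_week)
  rows <- lapply(names(variability), function(prop) {
    ct <- stats::cor.test(lf, variability[[prop]], method = "pearson")
    ci <- if (is.null(ct$conf.int)) c(NA_real_, NA_real_) else ct$conf.int
    data.frame(property = prop, r = unname(ct$estimate), p = ct$p.value,
               ci_lo = ci[1L], ci_hi = ci[2L],
               n = length(lf))
  })
  do.call(rbind, rows)
}

#' Paired comparison of seizure-containing vs seizure-free summaries
#'
#' For every property and measure (average, variability), runs the
#' signed-rank test on the per-participant paired differences
#' (containing minus free) with the paired Cohen's d.
#'
#' @param pairs list of per-participant [split_summary_by_label()]
#'   results (non-`NULL` entries only).
#' @return data frame: `measure`, `statistic`, `p`, `d`, `n`.
#' @export
paired_seizure_test <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  cols <- c("avg_period", "var_period", "avg_acrophase", "var_acrophase",
            "avg_amplitude", "var_amplitude")
  cont <- do.call(rbind, lapply(pairs, `[[`, "containing"))
  free <- do.call(rbind, lapply(pairs, `[[`, "free"))
  rows <- lapply(cols, function(cl) {
    ts <- signedrank_test(cont[[cl]], free[[cl]])
    data.frame(measure = cl, statistic = ts$statistic, p = ts$p, d = ts$d,
               n = nrow(cont))
  })
  do.call(rbind, rows)
}

#' Group comparison of every property and measure
#'
#' Rank-sum test and Cohen's d (patients minus controls) for the
#' intraindividual average and variability of each circadian property.
#'
#' @param summaries data frame of per-participant summaries
#'   ([intraindividual_summary()] rows) with a `group` column.
#' @param group_a,group_b labels of the patient and control groups.
#' @return data frame: `measure`, `median_a`, `median_b`, `statistic`,
#'   `p`, `d`, `n_a`, `n_b`.
#' @export
compare_groups <- function(summaries, group_a = "pwe", group_b = "control") {
  cols <- c("avg_period", "var_period", "avg_acrophase", "var_acrophase",
            "avg_amplitude", "var_amplitude")
  a <- summaries[summaries$group == group_a, , drop = FALSE]
  b <- summaries[summaries$group == group_b, , drop = FALSE]
  stopifnot(nrow(a) >= 2L, nrow(b) >= 2L)
  rows <- lapply(cols, function(cl) {
    rs <- ranksum_test(a[[cl]], b[[cl]])
    data.frame(measure = cl,
               median_a = stats::median(a[[cl]]),
               median_b = stats::median(b[[cl]]),
               statistic = rs$statistic, p = rs$p,
               d = cohens_d(a[[cl]], b[[cl]]),
               n_a = nrow(a), n_b = nrow(b))
  })
  do.call(rbind, rows)
}
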