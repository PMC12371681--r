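# Singular spectrum analysis of heart-rate runs and selection of the
# circadian (~24-h) component.
#
# The trajectory (Hankel) matrix of a months-long run is never
# materialised in the truncated path: matrix-vector products with a
# Hankel matrix are cross-correlations, computed with padded FFTs, and
# the leading subspace is found by a randomized range finder. Each
# eigentriple is reconstructed by anti-diagonal (Hankel) averaging of
# its rank-one term, which is again a convolution.

# Run a block with a private, fixed RNG stream; caller's RNG untouched.
with_local_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FFT-based products with the L x K Hankel matrix of series x.
hankel_ops <- function(x, L, K) {
  n <- L + K - 1L
  m <- stats::nextn(2L * n, c(2L, 3L, 5L))
  fx <- stats::fft(c(x, numeric(m - n)))
  corr <- function(v, take) {
    fv <- stats::fft(c(rev(v), numeric(m - length(v))))
    w <- Re(stats::fft(fx * fv, inverse = TRUE)) / m
    w[take]
  }
  list(
    # X %*% v, v of length K
    mv = function(v) corr(v, K:(K + L - 1L)),
    # t(X) %*% u, u of length L
    tmv = function(u) corr(u, L:(L + K - 1L))
  )
}

# Anti-diagonal averaging of sigma * u v^T back to a series of length
# L + K - 1; the anti-diagonal sums are conv(u, v).
hankelize_rank1 <- function(u, v, sigma, counts) {
  sigma * conv_full(u, v) / counts
}

#' Singular spectrum analysis of a uniform series
#'
#' Embeds the (mean-removed) series into its trajectory matrix with the
#' given window, takes a truncated singular value decomposition, and
#' reconstructs every eigentriple by anti-diagonal averaging. For small
#' problems, or when `rank` approaches the window length, the
#' decomposition is exact (dense SVD); for long runs a randomized
#' truncated SVD with FFT-based Hankel products is used, so neither the
#' trajectory matrix nor its cross-product is ever formed.
#'
#' @param run a [hr_run()] or a plain numeric vector.
#' @param window_length embedding window in samples (2 to `n - 1`).
#' @param rank number of leading eigentriples to keep (<=
#'   `window_length`).
#' @param interval_s sampling interval in seconds (taken from the run
#'   when one is supplied); used only to attach periods to eigentriples.
#' @return an `ssa_decomp`: singular values `sigma` (non-increasing),
#'   per-eigentriple reconstructions (columns of `recon`), estimated
#'   central period per eigentriple (`period_h`), the removed `mean`,
#'   window, and grid metadata.
#' @export
ssa_decompose <- function(run, window_length, rank = 20L, interval_s = NULL) {
  if (inherits(run, "hr_run")) {
    x <- run$values
    interval_s <- run$interval
    start_time <- run$start_time
    tz <- run$tz_offset_min
  } else {
    x <- as.numeric(run)
    start_time <- 0
    tz <- 0
    if (is.null(interval_s)) interval_s <- 1
  }
  n <- length(x)
  L <- as.integer(window_length)
  if (L < 2L || L > n - 1L) {
    stop("window_length must lie in [2, length - 1]", call. = FALSE)
  }
  if (n < 2L * L) {
    stop("run shorter than twice the window; lower the window length",
         call. = FALSE)
  }
  rank <- as.integer(min(rank, L))
  K <- n - L + 1L
  mu <- mean(x)
  xc <- x - mu

  dense <- (as.double(L) * K <= 4e6) || (rank > L %/% 3L)
  if (dense) {
    X <- matrix(0, L, K)
    for (i in seq_len(L)) X[i, ] <- xc[i:(i + K - 1L)]
    sv <- svd(X, nu = rank, nv = rank)
    sigma <- sv$d[seq_len(rank)]
    U <- sv$u
    V <- sv$v
  } else {
    ops <- hankel_ops(xc, L, K)
    p <- min(L, rank + 8L)
    with_local_rng(760111L + n, {
      Y <- vapply(seq_len(p), function(j) ops$mv(stats::rnorm(K)), numeric(L))
      for (it in 1:2) {  # power iterations sharpen the spectrum
        Z <- apply(Y, 2L, ops$tmv)
        Y <- apply(Z, 2L, ops$mv)
        Y <- qr.Q(qr(Y))
      }
      Q <- qr.Q(qr(Y))
    })
    B <- t(apply(Q, 2L, ops$tmv))  # p x K
    sv <- svd(B, nu = p, nv = p)
    sigma <- sv$d[seq_len(rank)]
    U <- (Q %*% sv$u)[, seq_len(rank), drop = FALSE]
    V <- sv$v[, seq_len(rank), drop = FALSE]
  }

  counts <- conv_full(rep(1, L), rep(1, K))  # anti-diagonal lengths
  recon <- vapply(seq_len(rank), function(j) {
    hankelize_rank1(U[, j], V[, j], sigma[j], counts)
  }, numeric(n))
  period_h <- vapply(seq_len(rank), function(j) {
    component_central_period(recon[, j], interval_s)
  }, numeric(1))

  structure(list(sigma = sigma, recon = recon, period_h = period_h,
                 mean = mu, window_length = L, rank = rank, n = n,
                 interval_s = interval_s, start_time = start_time,
                 tz_offset_min = tz, exact = dense),
            class = "ssa_decomp")
}

#' @export
print.ssa_decomp <- function(x, ...) {
  cat(sprintf("<ssa_decomp> n = %d, window = %d, rank = %d (%s SVD)\n",
              x$n, x$window_length, x$rank,
              if (x$exact) "dense" else "randomized"))
  cat("leading periods (h):",
      paste(signif(utils::head(x$period_h, 8L), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Central period of one component by Fourier analysis
#'
#' Periodogram of the (demeaned) component, zero-padded so the
#' frequency grid near 24 h is finer than 0.25 h in period; the period
#' is the reciprocal of the frequency at the periodogram maximum.
#'
#' @param values component series.
#' @param interval_s sampling interval in seconds.
#' @return central period in hours, or `NA` for an (all but) constant
#'   component, flagged aperiodic.
#' @export
component_central_period <- function(values, interval_s) {
  v <- values - mean(values)
  n <- length(v)
  if (stats::sd(values) < 1e-10 || n < 4L) return(NA_real_)
  # pad so that d(period) at 24 h = P^2 * df < 0.25 h
  need <- max(4L * n, ceiling(24^2 / 0.25 * 3600 / interval_s))
  m <- stats::nextn(need, c(2L, 3L, 5L))
  spec <- Mod(stats::fft(c(v, numeric(m - n))))[seq_len(m %/% 2L)]^2
  spec[1L] <- 0  # DC
  k <- which.max(spec)
  if (k == 1L || spec[k] <= 0) return(NA_real_)
  f_hz <- (k - 1L) / (m * interval_s)
  1 / f_hz / 3600
}

#' Merge eigentriples of matching frequency into components
#'
#' SSA represents one oscillation as a pair of frequency-matched
#' eigentriples (sine and cosine phase); adjacent pairs can also share
#' a drifting rhythm's energy. Eigentriples whose central frequencies
#' differ by less than `rel_tol` (relative) and whose singular values
#' are within a factor of 2 are merged; each merged group is re-scored
#' by [component_central_period()] on its summed reconstruction.
#'
#' @param decomp an [ssa_decompose()] result.
#' @param rel_tol relative frequency tolerance (default 0.05); 0 keeps
#'   every eigentriple separate.
#' @return the decomposition with a `groups` element: per group, member
#'   indices, summed reconstruction, total squared singular value, and
#'   central period (groups ordered by decreasing energy).
#' @export
group_components_by_frequency <- function(decomp, rel_tol = 0.05) {
  stopifnot(inherits(decomp, "ssa_decomp"))
  r <- decomp$rank
  freq <- ifelse(is.na(decomp$period_h), 0, 1 / decomp$period_h)
  assigned <- integer(r)
  g <- 0L
  for (i in seq_len(r)) {
    if (assigned[i] > 0L) next
    g <- g + 1L
    assigned[i] <- g
    if (rel_tol <= 0) next
    for (j in seq_len(r)) {
      if (assigned[j] > 0L) next
      fbar <- (freq[i] + freq[j]) / 2
      close_f <- if (fbar == 0) TRUE else abs(freq[i] - freq[j]) / fbar < rel_tol
      close_s <- max(decomp$sigma[i], decomp$sigma[j]) <=
        2 * min(decomp$sigma[i], decomp$sigma[j])
      if (close_f && close_s) assigned[j] <- g
    }
  }
  groups <- lapply(seq_len(g), function(k) {
    idx <- which(assigned == k)
    vals <- rowSums(decomp$recon[, idx, drop = FALSE])
    list(members = idx,
         values = vals,
         energy = sum(decomp$sigma[idx]^2),
         period_h = component_central_period(vals, decomp$interval_s))
  })
  groups <- groups[order(-vapply(groups, `[[`, 0, "energy"))]
  decomp$groups <- groups
  decomp$rel_tol <- rel_tol
  decomp
}

#' Select the circadian component of a grouped decomposition
#'
#' Among oscillatory groups (central period defined and at most
#' `max_period_h`, so multiday trends cannot masquerade as circadian),
#' the group whose period is closest to 24 h wins; ties go to the group
#' with the larger singular-value mass. A winner outside
#' `plausible_band_h` is kept but warned about.
#'
#' A rhythm whose period wanders from day to day is not a single
#' spectral line: SSA spreads it over the carrier pair plus weaker
#' sideband eigentriples within the modulation bandwidth. After
#' selection, every other group whose central frequency lies within
#' `sideband_cpd` cycles/day of the winner (default 0.5 — the Nyquist
#' band of daily phase increments, spanning periods of roughly 16-48 h,
#' which stays above the 12-h ultradian harmonic and below the trend
#' ceiling) is absorbed into the circadian component, so the
#' reconstructed rhythm retains its day-to-day phase wander. Set
#' `sideband_cpd = 0` to keep the winning group alone.
#'
#' @param decomp a grouped decomposition
#'   ([group_components_by_frequency()]).
#' @param max_period_h candidacy ceiling in hours (default 48).
#' @param plausible_band_h band outside which a warning is raised
#'   (default `c(20, 28)`).
#' @param sideband_cpd half-width, in cycles/day, of the band around
#'   the selected group absorbed as sidebands (default 0.5).
#' @return a `circadian_component`: the selected group's values on the
#'   run grid, its central period, grid metadata, and the candidate
#'   diagnostics; or `NULL` (with a message) when no oscillatory group
#'   exists.
#' @export
select_circadian <- function(decomp, max_period_h = 48,
                             plausible_band_h = c(20, 28),
                             sideband_cpd = 0.5) {
  stopifnot(inherits(decomp, "ssa_decomp"))
  if (is.null(decomp$groups)) decomp <- group_components_by_frequency(decomp)
  periods <- vapply(decomp$groups, `[[`, 0, "period_h")
  energies <- vapply(decomp$groups, `[[`, 0, "energy")
  cand <- which(!is.na(periods) & periods <= max_period_h)
  if (length(cand) == 0L) {
    message("no oscillatory component with period <= ", max_period_h,
            " h; run skipped")
    return(NULL)
  }
  dist <- abs(periods[cand] - 24)
  best <- cand[dist <= min(dist) + 1e-12]
  if (length(best) > 1L) {
    message("circadian selection tie at |period - 24 h| = ",
            signif(min(dist), 4), "; choosing the higher-energy group")
    best <- best[which.max(energies[best])]
  }
  sel <- decomp$groups[[best]]
  if (sel$period_h < plausible_band_h[1L] || sel$period_h > plausible_band_h[2L]) {
    warning(sprintf("selected circadian period %.2f h lies outside [%g, %g] h",
                    sel$period_h, plausible_band_h[1L], plausible_band_h[2L]))
  }
  absorbed <- integer(0)
  if (sideband_cpd > 0) {
    f_sel <- 24 / sel$period_h          # cycles/day
    f_all <- ifelse(is.na(periods), NA, 24 / periods)
    side <- which(!is.na(f_all) & periods <= max_period_h &
                    abs(f_all - f_sel) < sideband_cpd)
    side <- setdiff(side, best)
    for (k in side) {
      sel$values <- sel$values + decomp$groups[[k]]$values
      sel$energy <- sel$energy + decomp$groups[[k]]$energy
      sel$members <- c(sel$members, decomp$groups[[k]]$members)
    }
    absorbed <- side
  }
  structure(list(values = sel$values, central_period = sel$period_h,
                 start_time = decomp$start_time,
                 interval_s = decomp$interval_s,
                 tz_offset_min = decomp$tz_offset_min,
                 candidates = data.frame(period_h = periods, energy = energies),
                 members = sort(sel$members), absorbed = absorbed),
            class = "circadian_component")
}

#' @export
print.circadian_component <- function(x, ...) {
  cat(sprintf("<circadian_component> period %.2f h, %d samples at %g s\n",
              x$central_period, length(x$values), x$interval_s))
  invisible(x)
}

#' Extract the circadian rhythm of heart rate from one run
#'
#' Convenience wrapper: [ssa_decompose()] with a window of
#' `window_days`, frequency grouping, and circadian selection.
#'
#' @param run a [hr_run()].
#' @param window_days embedding window in days (default 2; must exceed
#'   one circadian period to resolve it).
#' @param rank leading eigentriples kept (default 20).
#' @param rel_tol grouping tolerance, see
#'   [group_components_by_frequency()].
#' @param sideband_cpd sideband absorption band, see
#'   [select_circadian()].
#' @return a `circadian_component`, or `NULL` when the run has no
#'   oscillatory component.
#' @export
extract_crhr <- function(run, window_days = 1.5, rank = 20L, rel_tol = 0.05,
                         sideband_cpd = 0.5) {
  L <- as.integer(round(window_days * 86400 / run$interval))
  dec <- ssa_decompose(run, window_length = L, rank = rank)
  dec <- group_components_by_frequency(dec, rel_tol = rel_tol)
  select_circadian(dec, sideband_cpd = sideband_cpd)
}
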