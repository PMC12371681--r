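# Brute-force null-distribution oracles, written independently of the
# package implementations they check.

# Rank-sum: enumerate every assignment of the observed midranks to
# group A; two-sided p by symmetric distance from the null mean.
oracle_ranksum_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  all_u <- apply(utils::combn(length(r), na), 2L, function(idx) sum(r[idx]))
  mu <- mean(all_u)
  mean(abs(all_u - mu) >= abs(obs - mu) - 1e-9)
}

# Signed-rank: enumerate every sign pattern over the non-zero
# differences' midranks.
oracle_signedrank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  all_v <- apply(grid, 1L, function(s) sum(r[as.logical(s)]))
  mu <- mean(all_v)
  mean(abs(all_v - mu) >= abs(obs - mu) - 1e-9)
}
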