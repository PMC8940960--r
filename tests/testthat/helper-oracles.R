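# Independent brute-force oracles used across the suite. These deliberately
# use plain double loops and naive arithmetic, sharing no code with the
# package implementations they check.

# Sample entropy by explicit O(n^2) double loop with the same convention as
# the package: N - m*tau templates at both orders, Chebyshev distance,
# self-matches excluded, SampEn = ln(Phi^m / Phi^{m+1}).
sampen_bruteforce <- function(x, m = 2, r, tau = 1) {
  n <- length(x)
  n_t <- n - m * tau
  count_matches <- function(dim) {
    cnt <- 0L
    for (i in seq_len(n_t)) {
      for (j in seq_len(n_t)) {
        if (i == j) next
        dmax <- 0
        for (k in seq_len(dim)) {
          d <- abs(x[i + (k - 1) * tau] - x[j + (k - 1) * tau])
          if (d > dmax) dmax <- d
        }
        if (dmax <= r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  b <- count_matches(m)
  a <- count_matches(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  log(b / a)
}

# Exact two-sided Mann-Whitney p by direct enumeration over group labels,
# written independently of the package's enumeration.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  all_u <- apply(utils::combn(length(pooled), na), 2, u_of)
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random RR series spanning roughly `dur` seconds (plain iid intervals; for
# property tests that need arbitrary valid tachograms, not realistic ones).
random_rr <- function(dur = 60, mean_ms = 800, sd_ms = 50) {
  n <- ceiling(dur * 1000 / mean_ms) + 5
  rr_series(pmax(stats::rnorm(n, mean_ms, sd_ms), 300))
}
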