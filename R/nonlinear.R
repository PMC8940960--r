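#' Poincare plot descriptors SD1 and SD2
#'
#' The Poincare plot scatters each RR interval against its successor. SD1
#' (dispersion across the identity line, short-term variability) and SD2
#' (dispersion along it, mixed short/long-term variability) are computed as
#' the standard deviations of the projections of the points
#' `(RR_i, RR_{i+1})` onto the lines `y = -x + 2*meanRR` and `y = x`.
#' Equivalent closed forms in terms of time-domain statistics are
#' `SD1 = (sqrt(2)/2) * SDSD` and `SD2 = sqrt(2*SDNN^2 - SDSD^2/2)`, where
#' the SDNN term is the variance of the lagged-pair ensemble (the `N - 1`
#' leading and trailing intervals pooled); with that convention both routes
#' agree to machine precision and the function asserts their agreement to
#' 1e-9 relative tolerance.
#'
#' @param rr [rr_series] with at least 3 intervals.
#' @return object of class `poincare_summary`: `sd1`, `sd2` (ms), `ratio`
#'   (`sd1/sd2`, `NA` when `sd2` is 0), and `points`, a data frame of the
#'   `(RR_i, RR_{i+1})` pairs for scatter export.
#' @examples
#' poincare_descriptors(rr_series(c(800, 780, 820, 790, 810)))
#' @export
poincare_descriptors <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  iv <- rr$intervals
  n <- length(iv)
  if (n < 3L) stop("need at least 3 intervals for Poincare descriptors")
  x1 <- iv[-n]
  x2 <- iv[-1L]
  popvar <- function(v) sum((v - mean(v))^2) / length(v)
  # direct projections onto the rotated axes
  sd1 <- sqrt(popvar((x1 - x2) / sqrt(2)))
  sd2 <- sqrt(popvar((x1 + x2) / sqrt(2)))
  # closed forms: SDSD over the same diffs; pair-ensemble SDNN term
  sdsd <- sqrt(popvar(x1 - x2))
  sdnn_pair_sq <- (popvar(x1) + popvar(x2)) / 2
  sd1_cf <- sqrt(2) / 2 * sdsd
  sd2_cf_sq <- 2 * sdnn_pair_sq - sdsd^2 / 2
  if (sd2_cf_sq < -1e-9 * max(sdnn_pair_sq, 1)) {
    stop("internal inconsistency: negative SD2 radicand")
  }
  sd2_cf <- sqrt(max(sd2_cf_sq, 0))
  tol <- 1e-9 * max(sd1, sd2, 1e-12)
  if (abs(sd1 - sd1_cf) > tol || abs(sd2 - sd2_cf) > tol) {
    stop("internal inconsistency: projection and closed-form SD1/SD2 disagree")
  }
  structure(
    list(sd1 = sd1, sd2 = sd2,
         ratio = if (sd2 > 0) sd1 / sd2 else NA_real_,
         points = data.frame(rr_i = x1, rr_next = x2)),
    class = "poincare_summary"
  )
}

#' @export
print.poincare_summary <- function(x, ...) {
  cat(sprintf("<poincare_summary> SD1 %.3f ms, SD2 %.3f ms, SD1/SD2 %s (%d points)\n",
              x$sd1, x$sd2,
              if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio),
              nrow(x$points)))
  invisible(x)
}

#' Sample entropy
#'
#' Sample entropy (SampEn) of a numeric series: the negative logarithm of
#' the conditional probability that two subsequences matching for `m` points
#' (Chebyshev distance at most `r`, self-matches excluded) also match for
#' `m + 1` points. The series is embedded with dimension `m` and delay
#' `tau`; both template orders use the same `N - m*tau` template vectors so
#' the match counts are directly comparable, and
#' `SampEn = ln(Phi^m / Phi^{m+1})` where `Phi` is the mean fraction of
#' matching template pairs. Higher values indicate a more irregular series;
#' a perfectly regular (constant or strictly periodic) series gives 0.
#'
#' The tolerance defaults to `r_coef * sd(series)` (the conventional
#' `0.2 * STD`); an absolute `r` can be supplied instead. When no pair of
#' templates matches at order `m + 1` the entropy is undefined and returned
#' as `NA` (never infinity), with the match fractions still reported.
#'
#' @param series numeric vector, length at least `m*tau + 10`.
#' @param m embedding dimension (default 2).
#' @param r_coef tolerance as a fraction of the series standard deviation
#'   (default 0.2).
#' @param tau embedding delay in samples (default 1).
#' @param r absolute tolerance; overrides `r_coef` when given.
#' @return object of class `sampen_result`: `m`, `tau`, `r`, `r_coef`,
#'   `phi_m`, `phi_m1`, `value` (nats; `NA` when undefined), `n`.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(200))
#' @export
sample_entropy <- function(series, m = 2, r_coef = 0.2, tau = 1, r = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  if (m < 1 || tau < 1) stop("m and tau must be positive integers")
  if (n < m * tau + 10) stop("series too short for the requested embedding")
  if (is.null(r)) {
    s <- stats::sd(x)
    # absolute floor so constant series resolve to a usable tolerance
    r <- max(r_coef * s, .Machine$double.eps)
  }
  if (r <= 0) stop("tolerance r must be positive")
  n_t <- n - m * tau  # templates shared by both orders
  if (n_t < 2L) stop("series too short for the requested embedding")
  # Chebyshev distances built coordinate by coordinate
  cheb <- function(dim) {
    dmax <- matrix(0, n_t, n_t)
    for (j in seq_len(dim)) {
      col <- x[seq_len(n_t) + (j - 1L) * tau]
      dmax <- pmax(dmax, abs(outer(col, col, "-")))
    }
    dmax
  }
  d_m <- cheb(m)
  matches_m <- sum(d_m <= r) - n_t    # exclude self-matches
  d_m1 <- pmax(d_m, {
    col <- x[seq_len(n_t) + m * tau]
    abs(outer(col, col, "-"))
  })
  matches_m1 <- sum(d_m1 <= r) - n_t
  denom <- n_t * (n_t - 1)
  phi_m <- matches_m / denom
  phi_m1 <- matches_m1 / denom
  value <- if (matches_m1 > 0 && matches_m > 0) {
    log(phi_m / phi_m1)
  } else {
    NA_real_
  }
  structure(
    list(m = m, tau = tau, r = r, r_coef = r_coef,
         phi_m = phi_m, phi_m1 = phi_m1, value = value, n = n),
    class = "sampen_result"
  )
}

#' @export
print.sampen_result <- function(x, ...) {
  cat(sprintf("<sampen_result> m=%d tau=%d r=%.4g : SampEn %s (n=%d)\n",
              x$m, x$tau, x$r,
              if (is.na(x$value)) "undefined" else sprintf("%.4f", x$value),
              x$n))
  invisible(x)
}

#' Sample-entropy panel over the three HRV channels
#'
#' Computes sample entropy with shared parameters for the RR-interval
#' series, the instantaneous-heart-rate series and (when the series carries
#' R-peak amplitudes) the peak-amplitude series.
#'
#' @param rr [rr_series]
#' @param m,r_coef,tau passed to [sample_entropy] (defaults 2, 0.2, 1).
#' @return list with elements `rr`, `ihr`, `peak`; each a `sampen_result`,
#'   or `NULL` for `peak` when the series has no amplitudes.
#' @export
entropy_panel <- function(rr, m = 2, r_coef = 0.2, tau = 1) {
  stopifnot(inherits(rr, "rr_series"))
  list(
    rr = sample_entropy(rr$intervals, m = m, r_coef = r_coef, tau = tau),
    ihr = sample_entropy(instantaneous_hr(rr), m = m, r_coef = r_coef,
                         tau = tau),
    peak = if (is.null(rr$amplitudes)) NULL else {
      sample_entropy(rr$amplitudes, m = m, r_coef = r_coef, tau = tau)
    }
  )
}
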