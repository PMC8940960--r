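#' Time-domain HRV statistics
#'
#' The eight standard short-term time-domain descriptors of an RR series:
#'
#' * `mean_rr` — mean RR interval (ms);
#' * `mean_hr` — mean heart rate, `60000 / mean_rr` (beats/min);
#' * `sdnn` — standard deviation of all RR intervals (ms);
#' * `rmssd` — root mean square of the `N - 1` successive differences (ms);
#' * `sdsd` — standard deviation of the successive differences (ms);
#' * `cv` — coefficient of variation `sdnn / mean_rr`, reported as a
#'   dimensionless fraction;
#' * `pnn20`, `pnn50` — percentage of successive-interval pairs whose
#'   absolute difference strictly exceeds 20 ms / 50 ms, out of `N - 1`.
#'
#' Standard deviations default to the population form (divisor `N`), with a
#' `sd_type = "sample"` switch for the `N - 1` convention.
#'
#' @param rr [rr_series] with at least 2 intervals.
#' @param sd_type `"population"` (divisor `N`, default) or `"sample"`
#'   (divisor `N - 1`) for `sdnn` and `sdsd`.
#' @return object of class `time_domain_summary`: a list with the fields
#'   above plus `nn20`, `nn50` (counts) and `n`.
#' @examples
#' compute_time_domain(rr_series(c(700, 900)))
#' @export
compute_time_domain <- function(rr, sd_type = c("population", "sample")) {
  stopifnot(inherits(rr, "rr_series"))
  sd_type <- match.arg(sd_type)
  iv <- rr$intervals
  n <- length(iv)
  if (n < 2L) stop("need at least 2 RR intervals")
  popsd <- function(x, m = length(x)) sqrt(sum((x - mean(x))^2) / m)
  denom <- function(k) if (sd_type == "population") k else k - 1L
  d <- diff(iv)
  mean_rr <- mean(iv)
  sdnn <- sqrt(sum((iv - mean_rr)^2) / denom(n))
  rmssd <- sqrt(sum(d^2) / (n - 1L))
  sdsd <- sqrt(sum((d - mean(d))^2) / denom(n - 1L))
  nn20 <- sum(abs(d) > 20)
  nn50 <- sum(abs(d) > 50)
  structure(
    list(
      mean_rr = mean_rr,
      mean_hr = 60000 / mean_rr,
      sdnn = sdnn,
      rmssd = rmssd,
      sdsd = sdsd,
      cv = sdnn / mean_rr,
      nn20 = nn20,
      pnn20 = 100 * nn20 / (n - 1L),
      nn50 = nn50,
      pnn50 = 100 * nn50 / (n - 1L),
      n = n,
      sd_type = sd_type
    ),
    class = "time_domain_summary"
  )
}

#' @export
print.time_domain_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<time_domain_summary> n = %d\n",
    "  meanRR %.2f ms   meanHR %.2f bpm   SDNN %.2f ms\n",
    "  RMSSD %.2f ms    SDSD %.2f ms      CV %.4f\n",
    "  pNN20 %.2f%%      pNN50 %.2f%%\n"),
    x$n, x$mean_rr, x$mean_hr, x$sdnn, x$rmssd, x$sdsd, x$cv,
    x$pnn20, x$pnn50))
  invisible(x)
}
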