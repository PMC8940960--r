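#' Resample an RR tachogram onto a uniform grid
#'
#' The tachogram is irregularly sampled by construction (one value per
#' beat). Spectral estimation by FFT methods needs uniform sampling, so the
#' (beat time, interval) pairs are interpolated with a cubic spline onto a
#' regular grid. Each interval is indexed at the time of the beat that
#' terminates it. 4 Hz is the conventional rate for short-term HRV (Nyquist
#' 2 Hz, well above the 0.4 Hz upper analysis limit).
#'
#' @param rr [rr_series] with at least 4 intervals spanning at least 10 s.
#' @param rate target sampling rate, Hz; must exceed 0.8 Hz (twice the top
#'   of the HF band).
#' @return object of class `uniform_tachogram`: list with `values` (ms),
#'   `rate` (Hz), `t_start` (s) and `mean_removed` flag (`FALSE`; the mean
#'   is left in and handled by detrending in [estimate_psd]).
#' @export
resample_tachogram <- function(rr, rate = 4) {
  stopifnot(inherits(rr, "rr_series"))
  if (rr$n < 4L) stop("need at least 4 intervals to resample")
  if (rate <= 2 * 0.4) stop("rate must exceed 0.8 Hz (twice the HF band top)")
  tt <- rr$beat_times[-1L] / 1000  # s; interval known at its terminating beat
  span <- tt[length(tt)] - tt[1L]
  if (span < 10) stop("series spans less than 10 s")
  grid <- seq(tt[1L], tt[length(tt)], by = 1 / rate)
  vals <- stats::spline(tt, rr$intervals, xout = grid, method = "fmm")$y
  structure(list(values = vals, rate = rate, t_start = grid[1L],
                 mean_removed = FALSE),
            class = "uniform_tachogram")
}

# Welch's averaged modified periodogram. One-sided density in x-units^2/Hz;
# the integral over (0, rate/2] matches the variance of the detrended input
# (up to window edge effects with few segments).
welch_psd <- function(x, rate, segment_s = 120, overlap = 0.5,
                      detrend = c("linear", "mean", "none")) {
  detrend <- match.arg(detrend)
  n <- length(x)
  x <- switch(detrend,
    linear = unname(stats::residuals(stats::lm(x ~ seq_len(n)))),
    mean = x - mean(x),
    none = x
  )
  len <- min(n, round(segment_s * rate))
  step <- max(1L, floor(len * (1 - overlap)))
  starts <- seq(1L, n - len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))  # Hann
  scale <- rate * sum(w^2)
  nf <- floor(len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + len - 1L)]
    seg <- seg - mean(seg)
    spec <- Mod(stats::fft(seg * w)[seq_len(nf)])^2 / scale
    acc <- acc + spec
  }
  dens <- acc / length(starts)
  dens[2:(nf - 1L)] <- 2 * dens[2:(nf - 1L)]  # one-sided
  list(freqs = (seq_len(nf) - 1L) * rate / len, density = dens)
}

#' Power spectral density of a uniform tachogram
#'
#' Welch's method (default) or a Yule-Walker autoregressive spectrum. Welch
#' defaults: 120 s Hann segments, 50% overlap, linear detrend — conventional
#' for 5-min HRV epochs. The AR density is rescaled so its integral over
#' (0, Nyquist] equals the variance of the detrended series, making the two
#' methods directly comparable band by band.
#'
#' @param uniform a `uniform_tachogram` from [resample_tachogram] (or any
#'   list with `values` and `rate`), covering at least 60 s.
#' @param method `"welch"` or `"ar"`.
#' @param segment_s Welch segment length, s.
#' @param overlap Welch segment overlap fraction.
#' @param detrend `"linear"`, `"mean"` or `"none"`.
#' @param ar_order AR model order for `method = "ar"`.
#' @return object of class `psd_estimate`: `freqs` (Hz, ascending from 0),
#'   `density` (ms^2/Hz, one-sided), `method`, `resample_rate`, `detrend`.
#' @export
estimate_psd <- function(uniform, method = c("welch", "ar"),
                         segment_s = 120, overlap = 0.5,
                         detrend = c("linear", "mean", "none"),
                         ar_order = 16) {
  method <- match.arg(method)
  detrend <- match.arg(detrend)
  x <- uniform$values
  rate <- uniform$rate
  if (length(x) < 60 * rate) stop("need at least 60 s of uniform data")
  if (method == "welch") {
    ps <- welch_psd(x, rate, segment_s, overlap, detrend)
  } else {
    xd <- if (detrend == "linear") {
      unname(stats::residuals(stats::lm(x ~ seq_along(x))))
    } else {
      x - mean(x)
    }
    sp <- stats::spec.ar(stats::ts(xd, frequency = rate), plot = FALSE,
                         order = ar_order, n.freq = 1024)
    dens <- as.numeric(sp$spec)
    f <- as.numeric(sp$freq)
    integral <- pracma::trapz(f, dens)
    if (integral > 0) dens <- dens * stats::var(xd) / integral
    ps <- list(freqs = f, density = dens)
  }
  structure(list(freqs = ps$freqs, density = pmax(ps$density, 0),
                 method = method, resample_rate = rate, detrend = detrend),
            class = "psd_estimate")
}

# trapezoid over [lo, hi] with density interpolated at the exact band edges
band_integral <- function(freqs, density, lo, hi) {
  inside <- freqs > lo & freqs < hi
  if (!any(inside) && (lo > max(freqs) || hi < min(freqs))) return(0)
  f <- c(lo, freqs[inside], hi)
  d <- c(stats::approx(freqs, density, lo, rule = 2)$y,
         density[inside],
         stats::approx(freqs, density, hi, rule = 2)$y)
  unname(pracma::trapz(f, d))
}

#' Spectral band powers and derived indices
#'
#' Integrates a one-sided tachogram PSD over the standard short-term HRV
#' bands — VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz — by
#' trapezoidal quadrature with the density interpolated at the exact band
#' edges. Relative powers are percentages of the total 0.003-0.4 Hz power;
#' normalized powers use the LF + HF denominator (the convention that
#' excludes VLF, so `lf_norm + hf_norm == 1`); `lf_hf` is the LF/HF power
#' ratio, reported as `NA` when HF power is exactly zero.
#'
#' @param psd a `psd_estimate` from [estimate_psd].
#' @param vlf,lf,hf band edges, Hz (length-2 vectors).
#' @return object of class `spectral_summary` with `vlf_power`, `lf_power`,
#'   `hf_power`, `total_power` (ms^2), `vlf_percent`, `lf_percent`,
#'   `hf_percent` (%), `lf_norm`, `hf_norm` (fractions in `[0, 1]`) and
#'   `lf_hf`.
#' @export
band_powers <- function(psd, vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                        hf = c(0.15, 0.4)) {
  stopifnot(inherits(psd, "psd_estimate"))
  p_vlf <- band_integral(psd$freqs, psd$density, vlf[1], vlf[2])
  p_lf <- band_integral(psd$freqs, psd$density, lf[1], lf[2])
  p_hf <- band_integral(psd$freqs, psd$density, hf[1], hf[2])
  total <- band_integral(psd$freqs, psd$density, vlf[1], hf[2])
  pct <- function(p) if (total > 0) 100 * p / total else NA_real_
  lfhf_denom <- p_lf + p_hf
  structure(
    list(
      vlf_power = p_vlf, lf_power = p_lf, hf_power = p_hf,
      total_power = total,
      vlf_percent = pct(p_vlf), lf_percent = pct(p_lf),
      hf_percent = pct(p_hf),
      lf_norm = if (lfhf_denom > 0) p_lf / lfhf_denom else NA_real_,
      hf_norm = if (lfhf_denom > 0) p_hf / lfhf_denom else NA_real_,
      lf_hf = if (p_hf > 0) p_lf / p_hf else NA_real_
    ),
    class = "spectral_summary"
  )
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<spectral_summary> total %.1f ms^2\n",
    "  VLF %.1f (%.1f%%)  LF %.1f (%.1f%%)  HF %.1f (%.1f%%)\n",
    "  LFnorm %.3f  HFnorm %.3f  LF/HF %s\n"),
    x$total_power, x$vlf_power, x$vlf_percent, x$lf_power, x$lf_percent,
    x$hf_power, x$hf_percent, x$lf_norm, x$hf_norm,
    if (is.na(x$lf_hf)) "undefined" else sprintf("%.3f", x$lf_hf)))
  invisible(x)
}

#' Write a PSD as a two-column CSV
#'
#' @param psd `psd_estimate`
#' @param path output path.
#' @export
write_psd_csv <- function(psd, path) {
  utils::write.csv(data.frame(frequency_hz = psd$freqs,
                              density_ms2_per_hz = psd$density),
                   path, row.names = FALSE)
  invisible(path)
}
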