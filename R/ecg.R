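#' Single-channel ECG record
#'
#' @param samples numeric amplitude vector (mV).
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample, s.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz")
  }
  if (length(samples) < 2L) stop("an ECG record needs at least 2 samples")
  structure(list(samples = samples, fs = fs, t0 = t0), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read an ECG trace from a two-column CSV
#'
#' Expects a header and (time, amplitude) columns; the sampling rate is taken
#' from the time column unless overridden.
#'
#' @param path CSV file path.
#' @param time_col,amp_col column names (defaults `"time"` and
#'   `"amplitude"`).
#' @param fs optional sampling-rate override, Hz.
#' @return [ecg_record]
#' @export
read_ecg_csv <- function(path, time_col = "time", amp_col = "amplitude",
                         fs = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c(time_col, amp_col) %in% names(d))) {
    stop(sprintf("columns '%s' and '%s' not found in %s",
                 time_col, amp_col, path))
  }
  tm <- d[[time_col]]
  if (is.null(fs)) {
    dt <- stats::median(diff(tm))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from time column")
    fs <- 1 / dt
  }
  ecg_record(d[[amp_col]], fs = fs, t0 = tm[1L])
}

#' Write an ECG trace as a two-column CSV
#'
#' @param ecg [ecg_record]
#' @param path output path.
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_record"))
  tm <- ecg$t0 + (seq_along(ecg$samples) - 1L) / ecg$fs
  utils::write.csv(data.frame(time = tm, amplitude = ecg$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' Butterworth low-pass (order 8) and high-pass (order 2) sections applied
#' forward-backward ([signal::filtfilt]), giving a zero-phase band-limited
#' trace of the same length. The default 0.5-40 Hz band is a conventional
#' ECG preprocessing band that removes baseline wander and mains
#' interference while keeping the QRS complex.
#'
#' @param ecg [ecg_record]
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return filtered [ecg_record]
#' @export
bandpass_filter <- function(ecg, low = 0.5, high = 40) {
  stopifnot(inherits(ecg, "ecg_record"))
  nyq <- ecg$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  lp <- signal::butter(8, high / nyq, type = "low")
  hp <- signal::butter(2, low / nyq, type = "high")
  y <- signal::filtfilt(hp, signal::filtfilt(lp, ecg$samples))
  ecg_record(as.numeric(y), fs = ecg$fs, t0 = ecg$t0)
}

#' Detected R peaks
#'
#' @param indices 1-based sample positions of the R peaks.
#' @param times peak times in ms (relative to the record's `t0`).
#' @param amplitudes peak amplitudes, mV.
#' @return object of class `r_peaks`.
#' @export
r_peaks <- function(indices, times, amplitudes) {
  stopifnot(length(indices) == length(times),
            length(times) == length(amplitudes))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("peak times must be strictly increasing")
  }
  structure(list(indices = as.integer(indices), times = as.numeric(times),
                 amplitudes = as.numeric(amplitudes), n = length(times)),
            class = "r_peaks")
}

#' @export
print.r_peaks <- function(x, ...) {
  cat(sprintf("<r_peaks> %d peaks\n", x$n))
  invisible(x)
}

#' R-peak detection
#'
#' Derivative-square-integrate detector with an adaptive threshold
#' (Pan-Tompkins style): the trace is band-passed to the QRS band
#' (5-20 Hz), differentiated, squared and integrated over a 150 ms moving
#' window; candidate beats are local maxima of the integrated energy above
#' an adaptive threshold, no closer together than the 200 ms physiological
#' refractory period. Each candidate is then refined to the largest absolute
#' excursion of the band-passed trace within +/-100 ms, and the reported
#' amplitude is read from the raw trace at that sample.
#'
#' @param ecg [ecg_record], at least 2 s long.
#' @param refractory_ms minimum separation between detected peaks (ms).
#' @param threshold_frac fraction of the robust energy ceiling (99th
#'   percentile of the integrated energy) used as detection threshold.
#' @return [r_peaks]; zero peaks (with a warning) on flat input.
#' @export
detect_r_peaks <- function(ecg, refractory_ms = 200, threshold_frac = 0.25) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  x <- ecg$samples
  if (length(x) < 2 * fs) stop("ECG trace must be at least 2 s long")
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    warning("flat ECG trace: no peaks detected")
    return(r_peaks(integer(0), numeric(0), numeric(0)))
  }
  qrs <- signal::butter(3, c(5, min(20, 0.45 * fs)) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(qrs, x))
  energy <- c(0, diff(bp))^2
  win <- max(3L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- threshold_frac * stats::quantile(integ, 0.99, names = FALSE)
  if (thr <= 0) {
    warning("no QRS energy above threshold: no peaks detected")
    return(r_peaks(integer(0), numeric(0), numeric(0)))
  }
  pk <- pracma::findpeaks(integ, minpeakheight = thr,
                          minpeakdistance = max(1L, round(refractory_ms / 1000 * fs)))
  if (is.null(pk)) {
    warning("no peaks found above threshold")
    return(r_peaks(integer(0), numeric(0), numeric(0)))
  }
  locs <- sort(as.integer(pk[, 2]))
  half <- as.integer(round(0.100 * fs))
  fine <- as.integer(round(0.020 * fs))
  refined <- vapply(locs, function(i) {
    # coarse: largest band-passed excursion near the energy peak
    a <- max(1L, i - half); b <- min(length(bp), i + half)
    j <- as.integer(a + which.max(abs(bp[a:b])) - 1L)
    # fine: true extremum of the raw trace in a tight window
    a2 <- max(1L, j - fine); b2 <- min(length(x), j + fine)
    as.integer(a2 + which.max(abs(x[a2:b2])) - 1L)
  }, integer(1))
  refined <- unique(refined)
  # amplitude gate: noise-triggered candidates sit well below the QRS
  # excursion level; gate against the cohort of candidates themselves
  cand_amp <- abs(bp[refined])
  med_amp <- stats::median(cand_amp)
  accepted <- refined[cand_amp >= 0.65 * med_amp]
  rejected <- setdiff(refined, accepted)
  # search-back: a gap much longer than the running beat interval usually
  # hides a beat whose energy dipped under the gate; re-admit the largest
  # rejected candidate inside such gaps at a lower amplitude bar
  if (length(accepted) >= 3L && length(rejected)) {
    med_gap <- stats::median(diff(accepted))
    repeat {
      gaps <- which(diff(accepted) > 1.6 * med_gap)
      filled <- FALSE
      for (gi in gaps) {
        inside <- rejected[rejected > accepted[gi] &
                             rejected < accepted[gi + 1L]]
        inside <- inside[abs(bp[inside]) >= 0.4 * med_amp]
        if (length(inside)) {
          best <- inside[which.max(abs(bp[inside]))]
          accepted <- sort(c(accepted, best))
          rejected <- setdiff(rejected, best)
          filled <- TRUE
          break
        }
      }
      if (!filled) break
    }
  }
  refined <- accepted
  # re-enforce refractory after refinement
  keep <- rep(TRUE, length(refined))
  last <- refined[1L]
  for (i in seq_along(refined)[-1L]) {
    if ((refined[i] - last) / fs * 1000 < refractory_ms) {
      keep[i] <- FALSE
    } else {
      last <- refined[i]
    }
  }
  refined <- refined[keep]
  r_peaks(refined, (refined - 1L) / fs * 1000 + ecg$t0 * 1000, x[refined])
}
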