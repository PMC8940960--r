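#' RR-interval series
#'
#' Container for a beat-to-beat (RR) interval series: the tachogram. Intervals
#' are in milliseconds; `beat_times` are the cumulative R-peak times (ms,
#' relative to `t0`) and always satisfy
#' `intervals == diff(beat_times)`. Optional per-peak R-wave amplitudes (mV)
#' are carried along so the amplitude channel of the sample-entropy panel can
#' be computed.
#'
#' @param intervals numeric vector of RR intervals in ms, all positive.
#' @param t0 start time of the first beat, ms. Default 0.
#' @param amplitudes optional numeric vector of R-peak amplitudes (mV), one
#'   per beat, i.e. `length(intervals) + 1` values.
#' @return an object of class `rr_series` with elements `intervals`,
#'   `beat_times` (length `N + 1`), `amplitudes` (or `NULL`) and `n`.
#' @examples
#' rr <- rr_series(c(800, 750, 820))
#' rr$beat_times
#' @export
rr_series <- function(intervals, t0 = 0, amplitudes = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L || anyNA(intervals)) {
    stop("`intervals` must be a non-empty numeric vector without NA")
  }
  if (any(intervals <= 0)) stop("all RR intervals must be positive")
  if (!is.null(amplitudes)) {
    amplitudes <- as.numeric(amplitudes)
    if (length(amplitudes) != length(intervals) + 1L) {
      stop("`amplitudes` must have one value per beat (length N + 1)")
    }
  }
  structure(
    list(
      intervals  = intervals,
      beat_times = t0 + c(0, cumsum(intervals)),
      amplitudes = amplitudes,
      n          = length(intervals)
    ),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d intervals spanning %.1f s, mean RR %.1f ms%s\n",
    x$n, diff(range(x$beat_times)) / 1000, mean(x$intervals),
    if (is.null(x$amplitudes)) "" else ", with R-peak amplitudes"
  ))
  invisible(x)
}

#' @export
length.rr_series <- function(x) x$n

#' RR intervals from detected R peaks
#'
#' Successive differences of R-peak times: `N` intervals from `N + 1` peaks,
#' with peak amplitudes carried through to the series.
#'
#' @param peaks an [r_peaks] object (or list with `times` in ms and optional
#'   `amplitudes`).
#' @return [rr_series]
#' @export
rr_from_peaks <- function(peaks) {
  times <- peaks$times
  if (length(times) < 2L) {
    stop("need at least 2 R peaks to form an RR interval")
  }
  rr_series(diff(times), t0 = times[1L], amplitudes = peaks$amplitudes)
}

#' Instantaneous heart rate
#'
#' Per-beat heart rate `60000 / RR_i` in beats/min.
#'
#' @param rr [rr_series]
#' @return numeric vector, beats/min, one element per interval.
#' @export
instantaneous_hr <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  60000 / rr$intervals
}

#' Rule-based RR artifact filter
#'
#' Removes physiologically implausible intervals: anything outside
#' `[min_ms, max_ms]`, or differing from the previous *accepted* interval by
#' more than `max_rel_jump` (relative). Beat times are recomputed from the
#' retained intervals, so the filtered series is again a contiguous tachogram.
#' The defaults (300-2000 ms, 30% jump) are conventional for short-term HRV
#' preprocessing.
#'
#' The filter is idempotent: applying it to its own output removes nothing.
#'
#' @param rr [rr_series]
#' @param max_rel_jump maximum allowed relative change between consecutive
#'   accepted intervals (fraction, default 0.3).
#' @param min_ms,max_ms admissible interval range in ms.
#' @return list with `series` (the filtered [rr_series]), `removed`
#'   (1-based indices into the input intervals), `fraction_removed` and
#'   `status` (`"ok"`, or `"quality_failure"` when more than 20% of the
#'   intervals were removed; the series is still returned).
#' @export
artifact_filter <- function(rr, max_rel_jump = 0.3, min_ms = 300,
                            max_ms = 2000) {
  stopifnot(inherits(rr, "rr_series"))
  if (max_rel_jump <= 0 || min_ms <= 0 || max_ms <= 0 || min_ms >= max_ms) {
    stop("thresholds must be positive with min_ms < max_ms")
  }
  iv <- rr$intervals
  keep <- logical(length(iv))
  last <- NA_real_
  for (i in seq_along(iv)) {
    ok <- iv[i] >= min_ms && iv[i] <= max_ms
    if (ok && !is.na(last)) {
      ok <- abs(iv[i] / last - 1) <= max_rel_jump
    }
    keep[i] <- ok
    if (ok) last <- iv[i]
  }
  removed <- which(!keep)
  if (all(!keep)) {
    return(list(series = NULL, removed = removed, fraction_removed = 1,
                status = "quality_failure"))
  }
  amp <- rr$amplitudes
  if (!is.null(amp)) {
    # amplitude i+1 belongs to the beat ending interval i; keep the first
    # peak plus the terminating peaks of the retained intervals
    amp <- amp[c(1L, which(keep) + 1L)]
  }
  out <- rr_series(iv[keep], t0 = rr$beat_times[1L], amplitudes = amp)
  frac <- length(removed) / length(iv)
  list(
    series = out,
    removed = removed,
    fraction_removed = frac,
    status = if (frac > 0.2) "quality_failure" else "ok"
  )
}

#' Read / write RR series as plain text
#'
#' One interval per line, in ms.
#'
#' @param path file path.
#' @return [rr_series] for `read_rr`; invisibly `path` for `write_rr`.
#' @export
read_rr <- function(path) {
  rr_series(scan(path, what = numeric(), quiet = TRUE))
}

#' @param rr [rr_series]
#' @rdname read_rr
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(format(rr$intervals, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}
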