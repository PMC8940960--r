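#' Autonomic modulation profile for synthetic RR generation
#'
#' Parameter bundle describing the statistical structure of a synthetic
#' 5-minute RR tachogram: a mean interval plus three band-limited
#' modulations (VLF, LF, HF) with configured variances, and additive white
#' noise. Band centers are constrained to the standard short-term HRV
#' analysis bands (LF 0.04-0.15 Hz, HF 0.15-0.4 Hz).
#'
#' @param mean_rr mean RR interval, ms (> 0).
#' @param vlf_power,lf_power,hf_power band variances of the modulation
#'   process, ms^2 (>= 0).
#' @param lf_center_freq,hf_center_freq modulation center frequencies, Hz.
#' @param white_noise_sd SD of the per-beat white noise, ms.
#' @param duration record length, s (default 300: the standard 5-min epoch).
#' @param ectopic_rate fraction of beats replaced by isolated ectopic-like
#'   interval halvings/doublings, in `[0, 1)`.
#' @param sd_target optional approximate SDNN this profile is meant to
#'   achieve, ms (informational).
#' @param seed default RNG seed used by [generate_rr_tachogram].
#' @return object of class `ans_profile`.
#' @export
ans_profile <- function(mean_rr, vlf_power = 0, lf_power = 0, hf_power = 0,
                        lf_center_freq = 0.1, hf_center_freq = 0.25,
                        white_noise_sd = 0, duration = 300,
                        ectopic_rate = 0, sd_target = NULL, seed = NULL) {
  if (!is.numeric(mean_rr) || mean_rr <= 0) stop("mean_rr must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (any(c(vlf_power, lf_power, hf_power) < 0)) {
    stop("band powers must be non-negative")
  }
  if (lf_center_freq < 0.04 || lf_center_freq > 0.15) {
    stop("lf_center_freq must lie in [0.04, 0.15] Hz")
  }
  if (hf_center_freq < 0.15 || hf_center_freq > 0.4) {
    stop("hf_center_freq must lie in [0.15, 0.4] Hz")
  }
  if (white_noise_sd < 0) stop("white_noise_sd must be non-negative")
  if (ectopic_rate < 0 || ectopic_rate >= 1) {
    stop("ectopic_rate must be in [0, 1)")
  }
  structure(
    list(mean_rr = mean_rr, sd_target = sd_target,
         vlf_power = vlf_power, lf_power = lf_power, hf_power = hf_power,
         lf_center_freq = lf_center_freq, hf_center_freq = hf_center_freq,
         white_noise_sd = white_noise_sd, duration = duration,
         ectopic_rate = ectopic_rate, seed = seed),
    class = "ans_profile"
  )
}

# Constant-envelope narrowband oscillator: sqrt(2*power)*cos(2*pi*fc*t + phase
# random walk). The Brownian phase spreads the line into a narrow band of
# width ~linewidth_hz around fc while the realised power stays exactly
# `power` in every time window, which keeps measured band powers close to
# their configured values even on a single 300-s realisation.
phase_diffusion_osc <- function(tg, fc, power, linewidth_hz) {
  if (power <= 0) return(numeric(length(tg)))
  dt <- tg[2L] - tg[1L]
  sig <- sqrt(2 * pi * linewidth_hz)
  ph <- cumsum(stats::rnorm(length(tg), 0, sig * sqrt(dt)))
  sqrt(2 * power) * cos(2 * pi * fc * tg + stats::runif(1) * 2 * pi + ph)
}

#' Generate a synthetic RR tachogram
#'
#' Beats are laid down sequentially: each interval is the profile mean plus
#' the sum of three narrowband modulations evaluated at the running beat
#' time, plus white noise. The modulations are constant-envelope
#' phase-diffusion oscillators centered at 0.02 Hz (VLF) and at the
#' configured LF/HF center frequencies — a non-physiological statistical
#' surrogate whose band variances equal the configured powers. Optional
#' ectopic-like artifacts replace isolated intervals with halvings or
#' doublings. R-peak amplitudes (mV) are synthesized as 1 plus a weak
#' respiratory-band modulation and white noise, giving the amplitude channel
#' realistic irregularity.
#'
#' @param profile [ans_profile]
#' @param seed RNG seed; defaults to the profile's own seed. The result is
#'   fully reproducible from (profile, seed).
#' @return [rr_series] with amplitudes, spanning approximately
#'   `profile$duration` seconds.
#' @examples
#' p <- ans_profile(mean_rr = 800, lf_power = 900, hf_power = 300,
#'                  white_noise_sd = 5, seed = 1)
#' generate_rr_tachogram(p)
#' @export
generate_rr_tachogram <- function(profile, seed = profile$seed) {
  stopifnot(inherits(profile, "ans_profile"))
  if (!is.null(seed)) set.seed(seed)
  dur <- profile$duration
  dt <- 0.25
  ng <- ceiling(dur / dt) + 8L
  tg <- (seq_len(ng) - 1L) * dt
  mod <- phase_diffusion_osc(tg, 0.02, profile$vlf_power, 0.003) +
    phase_diffusion_osc(tg, profile$lf_center_freq, profile$lf_power, 0.01) +
    phase_diffusion_osc(tg, profile$hf_center_freq, profile$hf_power, 0.02)
  modf <- stats::splinefun(tg, mod)
  # amplitude modulation grid (respiratory-band) for the R-peak channel
  amp_mod <- phase_diffusion_osc(tg, profile$hf_center_freq, 0.0025, 0.02)
  ampf <- stats::splinefun(tg, amp_mod)
  est_n <- ceiling(dur / (profile$mean_rr / 1000)) + 16L
  noise <- if (profile$white_noise_sd > 0) {
    stats::rnorm(est_n, 0, profile$white_noise_sd)
  } else {
    numeric(est_n)
  }
  iv <- numeric(0)
  tcur <- 0
  k <- 0L
  while (tcur < dur) {
    k <- k + 1L
    if (k > length(noise)) noise <- c(noise, stats::rnorm(est_n, 0, max(profile$white_noise_sd, 0)))
    val <- profile$mean_rr + modf(tcur) + noise[k]
    val <- max(val, 250)  # physiological floor
    iv <- c(iv, val)
    tcur <- tcur + val / 1000
  }
  if (profile$ectopic_rate > 0 && length(iv) > 2L) {
    hit <- which(stats::runif(length(iv)) < profile$ectopic_rate)
    # keep ectopics isolated
    hit <- hit[!c(FALSE, diff(hit) == 1)]
    fac <- ifelse(stats::runif(length(hit)) < 0.5, 0.5, 2)
    iv[hit] <- iv[hit] * fac
  }
  amps <- 1 + ampf(c(0, cumsum(iv / 1000))[seq_len(length(iv) + 1L)]) +
    stats::rnorm(length(iv) + 1L, 0, 0.025)
  rr_series(iv, amplitudes = amps)
}

#' Render an ECG trace from an RR series
#'
#' Places one narrow positive Gaussian template at each beat time of the
#' series, scaled by the per-beat amplitude when the series carries
#' amplitudes. The ground-truth beat times are returned alongside the
#' trace for round-trip benchmarking of detectors.
#'
#' @param rr [rr_series]
#' @param fs sampling rate, Hz (>= 100; default 256, a typical wearable-ECG
#'   rate).
#' @param qrs_amplitude template peak amplitude, mV.
#' @param qrs_width full width of the template, ms; must be smaller than
#'   the shortest interval.
#' @return list with `ecg` ([ecg_record]) and `beat_times` (ms).
#' @export
generate_ecg_from_rr <- function(rr, fs = 256, qrs_amplitude = 1,
                                 qrs_width = 80) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 100) stop("fs must be at least 100 Hz")
  if (qrs_width >= min(rr$intervals)) {
    stop("qrs_width must be smaller than the shortest RR interval")
  }
  # 0.3 s lead-in keeps the first QRS clear of filter edge transients
  bt <- (rr$beat_times - rr$beat_times[1L]) / 1000 + 0.3
  total_s <- bt[length(bt)] + 0.5
  n <- ceiling(total_s * fs)
  tt <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  sigma <- qrs_width / 1000 / 6  # template essentially contained in width
  amp <- if (is.null(rr$amplitudes)) rep(qrs_amplitude, length(bt)) else {
    qrs_amplitude * rr$amplitudes
  }
  half <- ceiling(4 * sigma * fs)
  for (b in seq_along(bt)) {
    c_idx <- round(bt[b] * fs) + 1L
    idx <- max(1L, c_idx - half):min(n, c_idx + half)
    x[idx] <- x[idx] + amp[b] * exp(-(tt[idx] - bt[b])^2 / (2 * sigma^2))
  }
  list(ecg = ecg_record(x, fs = fs, t0 = 0), beat_times = bt * 1000)
}

#' Calibrated nonfatigue and fatigue study profiles
#'
#' Default [ans_profile] pair emulating the group structure of a field
#' cohort of orchard workers measured before and after a day's work:
#' nonfatigue mean RR 845 ms with SDNN about 67 ms, fatigue mean RR 698 ms
#' with SDNN about 45 ms; total modulation power split so VLF carries about
#' 46% (nonfatigue) / 43.5% (fatigue) of total power and the LF:HF variance
#' ratio is 3.0 (nonfatigue) versus 4.8 (fatigue). The fatigue state gets a
#' slightly larger white-noise floor, which raises the relative
#' irregularity (sample entropy) of the shrunken-variance fatigued series.
#'
#' @return list with elements `nonfatigue` and `fatigue`.
#' @export
fatigue_study_profiles <- function() {
  build <- function(mean_rr, sdnn, vlf_frac, lfhf, wn) {
    # the per-beat white noise is broadband: it contributes to the measured
    # analysis bands too (empirical fractions of wn^2 per band under 4 Hz
    # cubic resampling), so the oscillator powers are solved for the target
    # *measured* band composition, noise included
    nv <- 0.045 * wn^2; nl <- 0.158 * wn^2; nh <- 0.342 * wn^2
    total <- sdnn^2
    vlf <- max(vlf_frac * total - nv, 0)
    rest <- total - wn^2 - vlf
    hf <- max((rest + nl - lfhf * nh) / (1 + lfhf), 0.02 * rest)
    lf <- rest - hf
    ans_profile(mean_rr = mean_rr, sd_target = sdnn,
                vlf_power = vlf, lf_power = lf, hf_power = hf,
                white_noise_sd = wn, duration = 300)
  }
  list(
    nonfatigue = build(845, 67, 0.46, 3.0, 2),
    fatigue    = build(698, 45, 0.435, 4.8, 12)
  )
}

# Latent means/SDs of the truncated-discretised normal item model, solved
# once so expected item scores reproduce the questionnaire's cohort means
# (total 21.5 nonfatigue / 49.4 fatigue; physical 12.6 -> 34.2, mental
# 9.0 -> 15.2).
.fs14_calib <- list(
  nonfatigue = list(mu_physical = 1.5253, mu_mental = 1.4330, sigma = 0.62),
  fatigue    = list(mu_physical = 4.4503, mu_mental = 2.5089, sigma = 1.02)
)

#' Generate synthetic FS-14 questionnaire responses
#'
#' Item scores are drawn from a truncated, discretised normal per item with
#' state-dependent latent means calibrated so that cohort-level mean totals
#' approximate 21.5 (nonfatigue) and 49.4 (fatigue), with the physical
#' (items 1-8) and mental (items 9-14) subscales tracking 12.6/9.0 and
#' 34.2/15.2 respectively.
#'
#' @param state `"nonfatigue"` or `"fatigue"`.
#' @param seed optional RNG seed.
#' @return an `fs14_record` (see [score_fs14]).
#' @export
generate_fs14_responses <- function(state = c("nonfatigue", "fatigue"),
                                    seed = NULL) {
  state <- match.arg(state)
  if (!is.null(seed)) set.seed(seed)
  cal <- .fs14_calib[[state]]
  draw <- function(mu, k) {
    pmin(pmax(round(stats::rnorm(k, mu, cal$sigma)), 1L), 5L)
  }
  score_fs14(c(draw(cal$mu_physical, 8L), draw(cal$mu_mental, 6L)))
}

#' Generate a paired synthetic cohort
#'
#' Creates `n_male + n_female` synthetic subjects, each with a nonfatigue
#' and a fatigue RR tachogram plus FS-14 responses for both states.
#' Per-subject profiles are jittered copies of the two state profiles:
#' the mean RR is scaled by a log-normal factor with log-SD
#' `between_subject_sd`, and the band powers by log-normal factors with
#' log-SD `4 * between_subject_sd` (variance-type quantities spread much
#' wider across subjects than the mean interval does). Mild gender
#' modifiers shift the mean RR (females slightly longer nonfatigue
#' intervals, shorter fatigued ones) and shrink the fatigued females'
#' modulation power, mirroring the usual direction of gender differences in
#' field cohorts.
#'
#' @param n_male,n_female subject counts (total >= 2).
#' @param nonfatigue_profile,fatigue_profile state [ans_profile]s; defaults
#'   from [fatigue_study_profiles].
#' @param between_subject_sd log-SD of the per-subject mean-RR jitter
#'   (default 0.12). 0 makes all same-gender subjects identical.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return object of class `synthetic_cohort`: a list of subjects, each a
#'   list with `subject_id`, `gender`, `rr_nonfatigue`, `rr_fatigue`,
#'   `fs14_nonfatigue`, `fs14_fatigue`.
#' @export
generate_cohort <- function(n_male = 38, n_female = 27,
                            nonfatigue_profile = NULL,
                            fatigue_profile = NULL,
                            between_subject_sd = 0.12, seed = 1) {
  if (n_male + n_female < 2L) stop("need at least 2 subjects")
  defaults <- fatigue_study_profiles()
  if (is.null(nonfatigue_profile)) nonfatigue_profile <- defaults$nonfatigue
  if (is.null(fatigue_profile)) fatigue_profile <- defaults$fatigue
  set.seed(seed)
  genders <- c(rep("male", n_male), rep("female", n_female))
  n <- length(genders)
  # gender modifiers on mean RR per state and on fatigued modulation power
  g_rr <- list(male = c(nonfatigue = 0.978, fatigue = 1.023),
               female = c(nonfatigue = 1.032, fatigue = 0.968))
  g_pow <- list(male = c(nonfatigue = 1, fatigue = 1.29),
                female = c(nonfatigue = 1, fatigue = 0.65))
  rr_jit <- exp(stats::rnorm(2 * n, 0, between_subject_sd))
  # independent per-band power jitter: between-subject variation of the
  # sympathetic (LF) and vagal (HF) drives is far from perfectly coupled,
  # and independent factors give the LF/HF ratio a realistic spread
  pw_jit <- matrix(exp(stats::rnorm(6 * n, 0, 4 * between_subject_sd)),
                   ncol = 3)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n)
  fs_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n)
  jitter_profile <- function(p, gender, state, rrf, pwf) {
    gp <- g_pow[[gender]][[state]] * pwf
    ans_profile(
      mean_rr = p$mean_rr * g_rr[[gender]][[state]] * rrf,
      sd_target = p$sd_target,
      vlf_power = p$vlf_power * gp[1],
      lf_power = p$lf_power * gp[2],
      hf_power = p$hf_power * gp[3],
      lf_center_freq = p$lf_center_freq,
      hf_center_freq = p$hf_center_freq,
      white_noise_sd = p$white_noise_sd,
      duration = p$duration,
      ectopic_rate = p$ectopic_rate
    )
  }
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    pn <- jitter_profile(nonfatigue_profile, genders[i], "nonfatigue",
                         rr_jit[2 * i - 1L], pw_jit[2 * i - 1L, ])
    pf <- jitter_profile(fatigue_profile, genders[i], "fatigue",
                         rr_jit[2 * i], pw_jit[2 * i, ])
    subjects[[i]] <- list(
      subject_id = sprintf("S%03d", i),
      gender = genders[i],
      rr_nonfatigue = generate_rr_tachogram(pn, seed = sub_seeds[2 * i - 1L]),
      rr_fatigue = generate_rr_tachogram(pf, seed = sub_seeds[2 * i]),
      fs14_nonfatigue = generate_fs14_responses("nonfatigue",
                                                seed = fs_seeds[2 * i - 1L]),
      fs14_fatigue = generate_fs14_responses("fatigue", seed = fs_seeds[2 * i])
    )
  }
  structure(subjects, class = "synthetic_cohort",
            seed = seed, n_male = n_male, n_female = n_female)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d male, %d female), seed %s\n",
              length(x), attr(x, "n_male"), attr(x, "n_female"),
              attr(x, "seed")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' RR series as one-interval-per-line text files, FS-14 responses as a CSV
#' with 14 item columns, and a manifest CSV (subject_id, gender, state,
#' file).
#'
#' @param cohort `synthetic_cohort`
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  fs_rows <- list()
  for (s in cohort) {
    for (state in c("nonfatigue", "fatigue")) {
      fn <- sprintf("%s_%s.rr", s$subject_id, state)
      write_rr(s[[paste0("rr_", state)]], file.path(dir, fn))
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = s$subject_id, gender = s$gender, state = state,
        file = fn)
      rec <- s[[paste0("fs14_", state)]]
      row <- as.data.frame(as.list(stats::setNames(
        rec$item_scores, paste0("item", 1:14))))
      fs_rows[[length(fs_rows) + 1L]] <- cbind(
        data.frame(subject_id = s$subject_id, gender = s$gender,
                   state = state), row)
    }
  }
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, manifest), man_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, fs_rows), file.path(dir, "fs14.csv"),
                   row.names = FALSE)
  invisible(man_path)
}
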