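uniform_from <- function(values, rate = 4) {
  structure(list(values = values, rate = rate, t_start = 0,
                 mean_removed = FALSE),
            class = "uniform_tachogram")
}

test_that("tachogram resampling is exact on constants and cubics", {
  rr <- rr_series(rep(800, 30))
  u <- resample_tachogram(rr, rate = 4)
  expect_true(all(abs(u$values - 800) < 1e-9))

  # intervals that are a linear function of elapsed time: the cubic
  # spline is exact on polynomials, so the resampled values must lie on
  # the same line
  a <- 700; b <- 4  # ms per s of elapsed time
  iv <- numeric(0); tcur <- 0
  for (i in 1:40) {
    v <- a + b * (tcur + (a + b * tcur) / 1000)  # value at the ending beat
    # solve v = a + b * t_end with t_end = tcur + v/1000
    v <- (a + b * tcur) / (1 - b / 1000)
    iv <- c(iv, v); tcur <- tcur + v / 1000
  }
  rr <- rr_series(iv)
  u <- resample_tachogram(rr, rate = 4)
  grid <- seq(rr$beat_times[2] / 1000, rr$beat_times[length(rr$beat_times)] / 1000,
              by = 0.25)
  expect_equal(u$values, a + b * grid, tolerance = 1e-8)

  expect_error(resample_tachogram(rr_series(rep(800, 5)), rate = 0.5),
               "rate")
  expect_error(resample_tachogram(rr_series(rep(800, 6))), "10 s")
})

test_that("resampling a 300 s record at 4 Hz yields ~1200 samples", {
  rr <- generate_rr_tachogram(fatigue_study_profiles()$nonfatigue, seed = 2)
  u <- resample_tachogram(rr, rate = 4)
  expect_gte(length(u$values), 1195)
  expect_lte(length(u$values), 1205)
})

test_that("Welch PSD satisfies Parseval identities", {
  rate <- 4
  tt <- seq(0, 300 - 1 / rate, by = 1 / rate)
  # pure 0.1 Hz tone, amplitude a: total power a^2/2, all in the LF band
  a <- 30
  ps <- estimate_psd(uniform_from(a * sin(2 * pi * 0.1 * tt)))
  total <- pracma::trapz(ps$freqs, ps$density)
  expect_equal(total, a^2 / 2, tolerance = 0.05)
  bp <- band_powers(ps)
  expect_gt(bp$lf_power / total, 0.9)

  # white noise: integral matches variance within 10%, band powers roughly
  # proportional to bandwidths
  set.seed(8)
  x <- rnorm(1200, sd = 20)
  ps <- estimate_psd(uniform_from(x))
  expect_equal(pracma::trapz(ps$freqs, ps$density), var(x),
               tolerance = 0.1)
  bp <- band_powers(ps)
  expect_equal(bp$lf_power / bp$hf_power, 0.11 / 0.25, tolerance = 0.25)

  # zero signal: zero density
  ps <- estimate_psd(uniform_from(rep(0, 1200)))
  expect_true(all(ps$density == 0))
})

test_that("two-tone tachogram reproduces configured variance ratios", {
  rate <- 4
  tt <- seq(0, 300 - 1 / rate, by = 1 / rate)
  # LF tone variance 3x the HF tone variance
  x <- sqrt(2 * 3) * sin(2 * pi * 0.1 * tt) + sqrt(2) * sin(2 * pi * 0.25 * tt)
  bp <- band_powers(estimate_psd(uniform_from(x)))
  expect_equal(bp$lf_power, 3, tolerance = 0.2)
  expect_equal(bp$hf_power, 1, tolerance = 0.2)
  expect_equal(bp$lf_hf, 3, tolerance = 0.2)
})

test_that("AR spectrum agrees with Welch on band attribution", {
  rate <- 4
  tt <- seq(0, 300 - 1 / rate, by = 1 / rate)
  x <- 25 * sin(2 * pi * 0.1 * tt)
  bpw <- band_powers(estimate_psd(uniform_from(x), method = "welch"))
  bpa <- band_powers(estimate_psd(uniform_from(x), method = "ar"))
  expect_gt(bpa$lf_percent, 90)
  expect_equal(bpa$total_power, bpw$total_power, tolerance = 0.15)
})

test_that("band_powers arithmetic follows the LF+HF normalization", {
  # density concentrated at 0.1 Hz only
  f <- seq(0, 2, by = 0.002)
  d <- ifelse(abs(f - 0.1) < 0.005, 1000, 0)
  psd <- structure(list(freqs = f, density = d, method = "welch",
                        resample_rate = 4, detrend = "linear"),
                   class = "psd_estimate")
  bp <- band_powers(psd)
  expect_gt(bp$lf_percent, 99)
  expect_equal(bp$lf_norm, 1)
  expect_equal(bp$hf_norm, 0)
  expect_true(is.na(bp$lf_hf))  # HF exactly 0: undefined, not Inf

  # synthetic densities with LF:HF = 3:1 -> norms 0.75/0.25, ratio 3
  d2 <- ifelse(f > 0.05 & f < 0.15, 30, 0) + ifelse(f > 0.15 & f < 0.35, 5, 0)
  psd2 <- structure(list(freqs = f, density = d2, method = "welch",
                         resample_rate = 4, detrend = "linear"),
                    class = "psd_estimate")
  bp2 <- band_powers(psd2)
  expect_equal(bp2$lf_norm, 0.75, tolerance = 0.01)
  expect_equal(bp2$hf_norm, 0.25, tolerance = 0.01)
  expect_equal(bp2$lf_hf, 3, tolerance = 0.05)
  expect_equal(bp2$lf_norm + bp2$hf_norm, 1)
})

test_that("normalization identity holds on random spectra", {
  set.seed(21)
  f <- seq(0, 2, by = 0.004)
  for (i in 1:10) {
    d <- runif(length(f))
    psd <- structure(list(freqs = f, density = d, method = "welch",
                          resample_rate = 4, detrend = "linear"),
                     class = "psd_estimate")
    bp <- band_powers(psd)
    expect_equal(bp$lf_norm + bp$hf_norm, 1, tolerance = 1e-12)
    expect_lte(bp$vlf_percent + bp$lf_percent + bp$hf_percent, 100 + 1e-6)
    expect_equal(bp$lf_hf, bp$lf_power / bp$hf_power, tolerance = 1e-12)
  }
})
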