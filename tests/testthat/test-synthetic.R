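test_that("profile validation rejects invalid parameters", {
  expect_error(ans_profile(mean_rr = -5), "positive")
  expect_error(ans_profile(800, duration = 0), "duration")
  expect_error(ans_profile(800, lf_power = -1), "non-negative")
  expect_error(ans_profile(800, lf_center_freq = 0.3), "lf_center_freq")
  expect_error(ans_profile(800, ectopic_rate = 1), "ectopic_rate")
})

test_that("degenerate profile produces a constant tachogram", {
  p <- ans_profile(mean_rr = 800, duration = 60)
  rr <- generate_rr_tachogram(p, seed = 1)
  expect_true(all(rr$intervals == 800))
  expect_equal(compute_time_domain(rr)$sdnn, 0)
})

test_that("tachogram generation is deterministic in the seed", {
  p <- fatigue_study_profiles()$nonfatigue
  a <- generate_rr_tachogram(p, seed = 123)
  b <- generate_rr_tachogram(p, seed = 123)
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$amplitudes, b$amplitudes)
  c_ <- generate_rr_tachogram(p, seed = 124)
  expect_false(identical(a$intervals, c_$intervals))
})

test_that("realized mean RR is within 2% of the configured mean", {
  p <- fatigue_study_profiles()$nonfatigue
  for (s in 1:5) {
    rr <- generate_rr_tachogram(p, seed = s)
    expect_lt(abs(mean(rr$intervals) / p$mean_rr - 1), 0.02)
  }
})

test_that("spectral module recovers configured band structure", {
  # LF:HF = 3:1, no VLF, no noise -> measured LF/HF in [2.4, 3.75]
  p <- ans_profile(mean_rr = 845, lf_power = 1500, hf_power = 500,
                   duration = 300)
  bp <- band_powers(estimate_psd(resample_tachogram(
    generate_rr_tachogram(p, seed = 1))))
  expect_gte(bp$lf_hf, 2.4)
  expect_lte(bp$lf_hf, 3.75)

  # full three-band profile: band powers within 20% at the reference seed
  p2 <- ans_profile(mean_rr = 845, vlf_power = 2073, lf_power = 1824,
                    hf_power = 608, white_noise_sd = 5, duration = 300)
  bp2 <- band_powers(estimate_psd(resample_tachogram(
    generate_rr_tachogram(p2, seed = 1))))
  expect_lt(abs(bp2$vlf_power / 2073 - 1), 0.2)
  expect_lt(abs(bp2$lf_power / 1824 - 1), 0.2)
  expect_lt(abs(bp2$hf_power / 608 - 1), 0.2)
})

test_that("single-band profiles put >= 80% of modulation power in band", {
  for (s in 1:5) {
    for (band in c("vlf", "lf", "hf")) {
      pow <- list(vlf_power = 0, lf_power = 0, hf_power = 0)
      pow[[paste0(band, "_power")]] <- 1200
      p <- do.call(ans_profile, c(list(mean_rr = 845, duration = 300), pow))
      bp <- band_powers(estimate_psd(resample_tachogram(
        generate_rr_tachogram(p, seed = s))))
      total <- bp$vlf_power + bp$lf_power + bp$hf_power
      expect_gte(bp[[paste0(band, "_power")]] / total, 0.8)
    }
  }
})

test_that("ectopic simulation inserts isolated halvings/doublings", {
  p <- ans_profile(mean_rr = 800, white_noise_sd = 2, duration = 120,
                   ectopic_rate = 0.05)
  rr <- generate_rr_tachogram(p, seed = 10)
  flagged <- artifact_filter(rr)
  expect_gt(length(flagged$removed), 0)
  # filtering restores a plausible series
  expect_lt(compute_time_domain(flagged$series)$sdnn, 50)
})

test_that("FS-14 generator tracks the questionnaire calibration", {
  set.seed(77)
  nf <- replicate(300, generate_fs14_responses("nonfatigue")$total)
  f <- replicate(300, generate_fs14_responses("fatigue")$total)
  expect_gt(mean(nf), 19); expect_lt(mean(nf), 24)
  expect_gt(mean(f), 45); expect_lt(mean(f), 54)
  rec <- generate_fs14_responses("fatigue", seed = 1)
  expect_equal(rec$total, rec$physical + rec$mental)
})

test_that("cohort generation is reproducible and respects its knobs", {
  a <- generate_cohort(3, 2, seed = 42)
  b <- generate_cohort(3, 2, seed = 42)
  expect_identical(a[[1]]$rr_nonfatigue$intervals,
                   b[[1]]$rr_nonfatigue$intervals)
  expect_identical(a[[5]]$rr_fatigue$intervals, b[[5]]$rr_fatigue$intervals)
  expect_equal(vapply(a, `[[`, "", "gender"),
               c(rep("male", 3), rep("female", 2)))
  expect_error(generate_cohort(1, 0), "at least 2")
})

test_that("zero between-subject spread gives same-gender subjects identical profiles", {
  coh <- generate_cohort(2, 2, between_subject_sd = 0, seed = 3)
  m1 <- mean(coh[[1]]$rr_nonfatigue$intervals)
  m2 <- mean(coh[[2]]$rr_nonfatigue$intervals)
  # same profile, different realization: means agree closely
  expect_lt(abs(m1 - m2), 0.03 * m1)
})

test_that("fatigue shifts have the configured directions at cohort level", {
  coh <- generate_cohort(8, 6, seed = 11)
  nf_rr <- sapply(coh, function(s) mean(s$rr_nonfatigue$intervals))
  f_rr <- sapply(coh, function(s) mean(s$rr_fatigue$intervals))
  expect_gt(mean(nf_rr), mean(f_rr))  # shorter RR under fatigue
})

test_that("a 1+1 cohort still flows through comparison with low-n flag", {
  coh <- generate_cohort(1, 1, seed = 2)
  feats <- do.call(rbind, lapply(coh, function(s) {
    rbind(
      cbind(data.frame(subject_id = s$subject_id, gender = s$gender,
                       state = "nonfatigue"),
            hrv_features(s$rr_nonfatigue)),
      cbind(data.frame(subject_id = s$subject_id, gender = s$gender,
                       state = "fatigue"),
            hrv_features(s$rr_fatigue)))
  }))
  cmp <- compare_states(feats)
  expect_true(all(is.finite(cmp$p_value[cmp$feature == "meanRR"])))
  expect_true(all(cmp$n_nonfatigue[cmp$group == "all"] == 2))
})

test_that("cohort files round-trip through the manifest format", {
  coh <- generate_cohort(2, 1, seed = 9)
  d <- tempfile("cohort")
  man <- write_cohort(coh, d)
  tab <- read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(tab), 6)  # 3 subjects x 2 states
  rr <- read_rr(file.path(d, tab$file[1]))
  expect_equal(rr$intervals, coh[[1]]$rr_nonfatigue$intervals,
               tolerance = 1e-6)
  fs <- read.csv(file.path(d, "fs14.csv"))
  expect_equal(nrow(fs), 6)
  expect_true(all(paste0("item", 1:14) %in% names(fs)))
})
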