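test_that("FS-14 scoring respects the subscale partition", {
  rec <- score_fs14(rep(1, 14))
  expect_equal(rec$total, 14)
  expect_equal(rec$physical, 8)
  expect_equal(rec$mental, 6)
  expect_equal(score_fs14(rep(5, 14))$total, 70)
  rec <- score_fs14(c(rep(5, 8), rep(1, 6)))
  expect_equal(rec$physical, 40)
  expect_equal(rec$mental, 6)
  expect_equal(rec$total, 46)
  expect_error(score_fs14(c(rep(3, 13), 6)), "1-5")
  expect_error(score_fs14(rep(3, 13)), "14")
  # custom partition
  rec <- score_fs14(c(rep(5, 6), rep(1, 8)),
                    physical_items = 7:14, mental_items = 1:6)
  expect_equal(rec$mental, 30)
  expect_equal(rec$physical, 8)
})

test_that("Spearman correlation matches hand-ranked cases", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:2, 1:2), "3")
})

test_that("Mann-Whitney exact mode reproduces enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1)
  # identical multisets: p = 1 by symmetry
  res <- mann_whitney_u(c(2, 5, 9), c(2, 5, 9), mode = "exact")
  expect_equal(res$p, 1)
  # against the independent enumeration oracle, including ties
  set.seed(14)
  for (i in 1:8) {
    a <- sample(1:6, 5, replace = TRUE)
    b <- sample(2:8, 6, replace = TRUE)
    expect_equal(mann_whitney_u(a, b, mode = "exact")$p,
                 mw_exact_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(rnorm(15), rnorm(15), mode = "exact"),
               "limited")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact and normal-approximation p-values agree for moderate n", {
  set.seed(25)
  for (i in 1:10) {
    a <- rnorm(9)
    b <- rnorm(9, mean = runif(1, 0, 1.5))
    pe <- mann_whitney_u(a, b, mode = "exact")$p
    pa <- mann_whitney_u(a, b, mode = "normal_approx")$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("normal approximation on large shifted samples agrees with exact on subsamples", {
  set.seed(31)
  a <- rnorm(30); b <- rnorm(30, 1.2)
  pl <- mann_whitney_u(a, b, mode = "normal_approx")$p
  expect_lt(pl, 0.05)
  ps <- mann_whitney_u(a[1:10], b[1:10], mode = "exact")$p
  pa <- mann_whitney_u(a[1:10], b[1:10], mode = "normal_approx")$p
  expect_lt(abs(ps - pa), 0.01)
})

test_that("Lilliefors screen is calibrated and has power", {
  set.seed(19)
  pn <- replicate(40, ks_normality(rnorm(200))$p)
  expect_gte(mean(pn > 0.05), 0.9)
  pe <- replicate(40, ks_normality(rexp(200))$p)
  expect_gte(mean(pe < 0.05), 0.9)
  expect_error(ks_normality(rnorm(3)), "at least 5")
  expect_equal(ks_normality(rep(2, 10))$method, "degenerate")
})

test_that("percent change matches the reporting convention", {
  expect_equal(percent_change(72.154, 86.692), 20.15)
  expect_equal(percent_change(46.996, 28.615), -39.11)
  expect_equal(percent_change(5, 5), 0)
  expect_true(is.na(percent_change(0, 5)))
})

test_that("significance stars follow the star convention exactly", {
  expect_equal(significance_stars(c(0.0005, 0.001, 0.04, 0.05, 0.5)),
               c("**", "*", "*", "NS", "NS"))
  expect_true(is.na(significance_stars(NA_real_)))
})

test_that("kernel density estimates integrate to one", {
  set.seed(50)
  x <- rnorm(1000)
  de <- estimate_pdf(x)
  expect_equal(pracma::trapz(de$grid, de$density), 1, tolerance = 1e-6)
  # N(0,1) density at zero is 1/sqrt(2*pi)
  at0 <- approx(de$grid, de$density, 0)$y
  expect_gt(at0, 0.3); expect_lt(at0, 0.5)
  # constructed bimodal sample shows two local maxima
  y <- c(rnorm(500, -3, 0.5), rnorm(500, 3, 0.5))
  db <- estimate_pdf(y)
  peaks <- pracma::findpeaks(db$density,
                             minpeakheight = 0.2 * max(db$density))
  expect_gte(nrow(peaks), 2)
  expect_equal(estimate_pdf(rep(3, 10))$type, "point_mass")
  expect_error(estimate_pdf(1:3), "at least 5")
})

make_feature_table <- function(n_per_gender = 10, shift = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  k <- 0
  for (g in c("male", "female")) for (i in seq_len(n_per_gender)) {
    k <- k + 1
    base <- rnorm(1, 800, 40)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = sprintf("P%02d", k), gender = g, state = "nonfatigue",
      meanRR = base + rnorm(1, 0, 15), LF_HF = exp(rnorm(1, 1, 0.3)))
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = sprintf("P%02d", k), gender = g, state = "fatigue",
      meanRR = base - shift + rnorm(1, 0, 15),
      LF_HF = exp(rnorm(1, 1 + shift / 150, 0.3)))
  }
  do.call(rbind, rows)
}

test_that("compare_states detects configured effects with correct layout", {
  feats <- make_feature_table(n_per_gender = 16, shift = 120, seed = 4)
  cmp <- compare_states(feats, stratify_by_gender = TRUE)
  expect_setequal(unique(cmp$group), c("all", "male", "female"))
  all_rr <- cmp[cmp$group == "all" & cmp$feature == "meanRR", ]
  expect_lt(all_rr$p_value, 0.001)
  expect_equal(all_rr$stars, "**")
  expect_lt(all_rr$percent_change, 0)
  all_lfhf <- cmp[cmp$group == "all" & cmp$feature == "LF_HF", ]
  expect_gt(all_lfhf$percent_change, 0)
  # percent change traceable to the reported means
  expect_equal(all_rr$percent_change,
               percent_change(all_rr$nonfatigue_mean, all_rr$fatigue_mean))
})

test_that("compare_states controls type-I error on null cohorts", {
  stars <- replicate(30, {
    feats <- make_feature_table(n_per_gender = 10, shift = 0,
                                seed = sample.int(1e6, 1))
    cmp <- compare_states(feats)
    cmp$stars[cmp$feature == "meanRR"]
  })
  expect_gte(mean(stars == "NS"), 0.9)
})

test_that("compare_states is invariant to row order and relabeling", {
  feats <- make_feature_table(n_per_gender = 8, shift = 80, seed = 7)
  cmp1 <- compare_states(feats)
  shuffled <- feats[sample(nrow(feats)), ]
  cmp2 <- compare_states(shuffled)
  expect_equal(cmp1$p_value, cmp2$p_value)
  expect_equal(cmp1$spearman_rho, cmp2$spearman_rho)
  relabeled <- feats
  relabeled$subject_id <- paste0("X_", relabeled$subject_id)
  cmp3 <- compare_states(relabeled)
  expect_equal(cmp1$p_value, cmp3$p_value)
})

test_that("single-gender input leaves the other gender's rows absent-marked", {
  feats <- make_feature_table(n_per_gender = 8, shift = 80, seed = 13)
  feats <- feats[feats$gender == "male", ]
  cmp <- compare_states(feats, stratify_by_gender = TRUE)
  fem <- cmp[cmp$group == "female", ]
  expect_true(all(is.na(fem$p_value)))
  expect_true(all(fem$n_nonfatigue == 0))
  male <- cmp[cmp$group == "male", ]
  expect_true(all(is.finite(male$p_value)))
})

test_that("unpaired subjects are flagged, not silently dropped", {
  feats <- make_feature_table(n_per_gender = 6, shift = 100, seed = 3)
  # remove every fatigue row: no pairing at all
  nf_only <- feats[feats$state == "nonfatigue", ]
  cmp <- compare_states(nf_only)
  expect_true(all(is.na(cmp$p_value)))
  expect_true(all(cmp$n_fatigue == 0))
})
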