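#' Score an FS-14 questionnaire record
#'
#' The 14-item fatigue scale is scored on 5-point Likert items; the scale
#' splits into a physical subscale (8 items) and a mental subscale
#' (6 items). Which items belong to which subscale is configurable; the
#' default takes items 1-8 as physical and 9-14 as mental.
#'
#' @param items integer vector of 14 item scores, each in 1-5.
#' @param physical_items,mental_items index partitions of `1:14` (8 and 6
#'   items respectively).
#' @return object of class `fs14_record` with `item_scores`, `physical`,
#'   `mental` and `total` (`total == physical + mental`).
#' @examples
#' score_fs14(rep(1, 14))$total  # 14, the scale floor
#' @export
score_fs14 <- function(items, physical_items = 1:8, mental_items = 9:14) {
  items <- as.integer(items)
  if (length(items) != 14L || anyNA(items) || any(items < 1L | items > 5L)) {
    stop("FS-14 requires 14 item scores, each an integer in 1-5")
  }
  if (length(physical_items) != 8L || length(mental_items) != 6L ||
      !setequal(c(physical_items, mental_items), 1:14)) {
    stop("physical_items (8) and mental_items (6) must partition 1:14")
  }
  physical <- sum(items[physical_items])
  mental <- sum(items[mental_items])
  structure(
    list(item_scores = items, physical_items = physical_items,
         mental_items = mental_items, physical = physical, mental = mental,
         total = physical + mental),
    class = "fs14_record"
  )
}

#' @export
print.fs14_record <- function(x, ...) {
  cat(sprintf("<fs14_record> total %d (physical %d, mental %d)\n",
              x$total, x$physical, x$mental))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Returns `NA` when either
#' vector is constant (ranks undefined).
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must be paired vectors of equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# U statistic for sample a (rank-sum form, average ranks for ties)
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for a location difference between two groups.
#' The reported `u` is the U statistic of the first sample. In
#' `"exact"` mode the null distribution of U is built by full enumeration
#' of all group assignments of the pooled values (ties handled exactly;
#' limited to `n_a + n_b <= 20`). In `"normal_approx"` mode the test is
#' delegated to [stats::wilcox.test] with tie and continuity corrections.
#' `"auto"` picks exact for pooled sizes up to 20 and the approximation
#' otherwise.
#'
#' @param a,b numeric samples (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `u`, `p` (two-sided) and `mode` used.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  if (mode == "auto") {
    mode <- if (na + nb <= 20L) "exact" else "normal_approx"
  }
  u_obs <- u_statistic(a, b)
  if (mode == "exact") {
    if (na + nb > 20L) stop("exact mode is limited to n_a + n_b <= 20")
    pooled <- c(a, b)
    r <- rank(pooled)
    combs <- utils::combn(na + nb, na)
    usum <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    # two-sided: arrangements at least as extreme as |U - mu|
    p <- mean(abs(usum - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  list(u = u_obs, p = min(p, 1), mode = mode)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample K-S test against a normal distribution with mean and SD
#' estimated from the data, i.e. the Lilliefors-corrected test
#' ([nortest::lillie.test]); the plain K-S p-value would be badly
#' anticonservative with estimated parameters. Used to justify the choice
#' of nonparametric cohort tests.
#'
#' @param x numeric sample, n >= 5.
#' @return list with `statistic`, `p` and `method`; `p` is `NA` with
#'   `method = "degenerate"` for a constant sample.
#' @export
ks_normality <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, method = "degenerate"))
  }
  t <- nortest::lillie.test(x)
  list(statistic = unname(t$statistic), p = t$p.value,
       method = "lilliefors")
}

#' Percent change between paired state means
#'
#' `100 * (fatigue - nonfatigue) / nonfatigue`, rounded to `digits`
#' decimals (2 by default, the usual reporting precision). A zero baseline
#' yields `NA`.
#'
#' @param nonfatigue_mean,fatigue_mean state means.
#' @param digits decimals in the reported rate.
#' @return percent change (%).
#' @examples
#' percent_change(72.154, 86.692)  # +20.15
#' @export
percent_change <- function(nonfatigue_mean, fatigue_mean, digits = 2) {
  if (any(nonfatigue_mean == 0)) {
    out <- rep(NA_real_, length(nonfatigue_mean))
    ok <- nonfatigue_mean != 0
    out[ok] <- round(100 * (fatigue_mean[ok] - nonfatigue_mean[ok]) /
                       nonfatigue_mean[ok], digits)
    return(out)
  }
  round(100 * (fatigue_mean - nonfatigue_mean) / nonfatigue_mean, digits)
}

#' Significance stars
#'
#' `"**"` for p < 0.001, `"*"` for 0.001 <= p < 0.05, `"NS"` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", "NS")))
}

#' Gaussian kernel density estimate of a feature distribution
#'
#' Thin wrapper over [stats::density] on a grid spanning the data plus
#' three bandwidths, renormalized so the trapezoidal integral is exactly 1.
#'
#' @param values numeric sample, n >= 5, finite.
#' @param bandwidth_rule bandwidth selector passed to [stats::density]
#'   (`"nrd0"`, `"nrd"`, `"SJ"`, ...).
#' @return object of class `density_estimate`: `grid`, `density`,
#'   `bandwidth`; or, for a zero-variance sample, a point-mass marker
#'   (`type = "point_mass"`, `at = value`).
#' @export
estimate_pdf <- function(values, bandwidth_rule = "nrd0") {
  values <- as.numeric(values)
  if (length(values) < 5L || any(!is.finite(values))) {
    stop("need at least 5 finite values")
  }
  if (stats::sd(values) == 0) {
    return(structure(list(type = "point_mass", at = values[1L]),
                     class = "density_estimate"))
  }
  d <- stats::density(values, bw = bandwidth_rule, cut = 3, n = 512)
  integral <- pracma::trapz(d$x, d$y)
  structure(
    list(type = "kde", grid = d$x, density = d$y / integral,
         bandwidth = d$bw),
    class = "density_estimate"
  )
}

#' Paired nonfatigue-vs-fatigue cohort contrast
#'
#' For each feature column: state means and SDs, Spearman correlation of
#' the within-subject (nonfatigue, fatigue) pairs, a two-sided Mann-Whitney
#' U test between the two state groups, significance stars (`**` p < 0.001,
#' `*` p < 0.05, else NS) and the percent change of the fatigue mean
#' relative to the nonfatigue mean. Optionally the same contrast is
#' repeated within each gender. Supplementary Bonferroni and
#' Benjamini-Hochberg adjusted p-values are emitted as clearly separate
#' columns; the primary stars are based on the unadjusted p-values.
#'
#' @param features data frame with columns `subject_id`, `gender`, `state`
#'   (values `"nonfatigue"`/`"fatigue"`) and one numeric column per
#'   feature. One row per (subject, state); subjects missing either state
#'   have the affected features flagged (`spearman_rho` = NA) rather than
#'   dropped.
#' @param stratify_by_gender also compute per-gender contrasts.
#' @param mw_mode Mann-Whitney mode, see [mann_whitney_u].
#' @return data frame of class `group_comparison`, one row per feature (and
#'   per group when stratified, `group` in `all`, `male`, `female`) with
#'   columns `feature`, `group`, `n_nonfatigue`, `n_fatigue`,
#'   `nonfatigue_mean`, `nonfatigue_sd`, `fatigue_mean`, `fatigue_sd`,
#'   `spearman_rho`, `u_statistic`, `p_value`, `stars`, `percent_change`,
#'   `p_bonferroni`, `p_fdr`.
#' @export
compare_states <- function(features, stratify_by_gender = FALSE,
                           mw_mode = "auto") {
  required <- c("subject_id", "gender", "state")
  if (!all(required %in% names(features))) {
    stop("features must have subject_id, gender and state columns")
  }
  if (!all(features$state %in% c("nonfatigue", "fatigue"))) {
    stop("state must be 'nonfatigue' or 'fatigue'")
  }
  feat_cols <- setdiff(names(features), required)
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  if (length(feat_cols) == 0L) stop("no numeric feature columns found")
  groups <- "all"
  if (stratify_by_gender) groups <- c("all", "male", "female")

  one_group <- function(df, group) {
    rows <- lapply(feat_cols, function(fc) {
      nf <- df[df$state == "nonfatigue", c("subject_id", fc)]
      ft <- df[df$state == "fatigue", c("subject_id", fc)]
      nfv <- nf[[fc]][is.finite(nf[[fc]])]
      ftv <- ft[[fc]][is.finite(ft[[fc]])]
      if (length(nfv) < 1L || length(ftv) < 1L) {
        return(data.frame(
          feature = fc, group = group, n_nonfatigue = length(nfv),
          n_fatigue = length(ftv), nonfatigue_mean = NA_real_,
          nonfatigue_sd = NA_real_, fatigue_mean = NA_real_,
          fatigue_sd = NA_real_, spearman_rho = NA_real_,
          u_statistic = NA_real_, p_value = NA_real_,
          stars = NA_character_, percent_change = NA_real_))
      }
      paired <- merge(nf, ft, by = "subject_id",
                      suffixes = c("_nf", "_f"))
      px <- paired[[paste0(fc, "_nf")]]
      py <- paired[[paste0(fc, "_f")]]
      cc <- is.finite(px) & is.finite(py)
      rho <- if (sum(cc) >= 3 && stats::sd(px[cc]) > 0 &&
                 stats::sd(py[cc]) > 0) {
        spearman_rho(px[cc], py[cc])
      } else {
        NA_real_
      }
      mw <- tryCatch(mann_whitney_u(nfv, ftv, mode = mw_mode),
                     error = function(e) list(u = NA_real_, p = NA_real_))
      data.frame(
        feature = fc, group = group,
        n_nonfatigue = length(nfv), n_fatigue = length(ftv),
        nonfatigue_mean = mean(nfv), nonfatigue_sd = stats::sd(nfv),
        fatigue_mean = mean(ftv), fatigue_sd = stats::sd(ftv),
        spearman_rho = rho, u_statistic = mw$u, p_value = mw$p,
        stars = significance_stars(mw$p),
        percent_change = percent_change(mean(nfv), mean(ftv)))
    })
    do.call(rbind, rows)
  }

  out <- do.call(rbind, lapply(groups, function(g) {
    df <- if (g == "all") features else features[features$gender == g, ]
    if (nrow(df) == 0L) {
      data.frame(feature = feat_cols, group = g, n_nonfatigue = 0L,
                 n_fatigue = 0L, nonfatigue_mean = NA_real_,
                 nonfatigue_sd = NA_real_, fatigue_mean = NA_real_,
                 fatigue_sd = NA_real_, spearman_rho = NA_real_,
                 u_statistic = NA_real_, p_value = NA_real_,
                 stars = NA_character_, percent_change = NA_real_)
    } else {
      one_group(df, g)
    }
  }))
  # supplementary multiplicity adjustments, per group (not used for stars)
  out$p_bonferroni <- NA_real_
  out$p_fdr <- NA_real_
  for (g in unique(out$group)) {
    sel <- out$group == g
    out$p_bonferroni[sel] <- stats::p.adjust(out$p_value[sel], "bonferroni")
    out$p_fdr[sel] <- stats::p.adjust(out$p_value[sel], "BH")
  }
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}
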