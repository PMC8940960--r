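#' All HRV features of one RR series as a single row
#'
#' Runs the time-domain, spectral and nonlinear analyses on one (already
#' artifact-filtered) RR series and returns the full feature vector with
#' the conventional column names (`meanRR`, `meanHR`, `SDNN`, `RMSSD`,
#' `SDSD`, `PNN20`, `PNN50`, `CV`, `VLF_percent`, `LF_percent`,
#' `HF_percent`, `LF_norm`, `HF_norm`, `LF_HF`, `SD1`, `SD2`, `SD1_SD2`,
#' `SampleEn_RR`, `SampleEn_iHR`, `SampleEn_Peak`).
#'
#' @param rr [rr_series]
#' @param psd_method `"welch"` or `"ar"`.
#' @param resample_rate tachogram resampling rate, Hz.
#' @param segment_s,overlap Welch settings.
#' @param m,r_coef,tau sample-entropy settings.
#' @param vlf,lf,hf band edges, Hz.
#' @return one-row data frame. `SampleEn_Peak` is `NA` when the series
#'   carries no amplitudes; spectral columns are `NA` when the series is
#'   too short for spectral analysis.
#' @export
hrv_features <- function(rr, psd_method = "welch", resample_rate = 4,
                         segment_s = 120, overlap = 0.5,
                         m = 2, r_coef = 0.2, tau = 1,
                         vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                         hf = c(0.15, 0.4)) {
  td <- compute_time_domain(rr)
  sp <- tryCatch({
    u <- resample_tachogram(rr, rate = resample_rate)
    band_powers(estimate_psd(u, method = psd_method, segment_s = segment_s,
                             overlap = overlap),
                vlf = vlf, lf = lf, hf = hf)
  }, error = function(e) NULL)
  pc <- tryCatch(poincare_descriptors(rr), error = function(e) NULL)
  en <- tryCatch(entropy_panel(rr, m = m, r_coef = r_coef, tau = tau),
                 error = function(e) NULL)
  g <- function(obj, field) if (is.null(obj)) NA_real_ else obj[[field]]
  data.frame(
    meanRR = td$mean_rr, meanHR = td$mean_hr, SDNN = td$sdnn,
    RMSSD = td$rmssd, SDSD = td$sdsd, PNN20 = td$pnn20, PNN50 = td$pnn50,
    CV = td$cv,
    VLF_percent = g(sp, "vlf_percent"), LF_percent = g(sp, "lf_percent"),
    HF_percent = g(sp, "hf_percent"), LF_norm = g(sp, "lf_norm"),
    HF_norm = g(sp, "hf_norm"), LF_HF = g(sp, "lf_hf"),
    SD1 = g(pc, "sd1"), SD2 = g(pc, "sd2"), SD1_SD2 = g(pc, "ratio"),
    SampleEn_RR = if (is.null(en)) NA_real_ else en$rr$value,
    SampleEn_iHR = if (is.null(en)) NA_real_ else en$ihr$value,
    SampleEn_Peak = if (is.null(en) || is.null(en$peak)) NA_real_ else {
      en$peak$value
    }
  )
}

.feature_units <- c(
  meanRR = "ms", meanHR = "beats/min", SDNN = "ms", RMSSD = "ms",
  SDSD = "ms", PNN20 = "%", PNN50 = "%", CV = "-", VLF_percent = "%",
  LF_percent = "%", HF_percent = "%", LF_norm = "-", HF_norm = "-",
  LF_HF = "-", SD1 = "ms", SD2 = "ms", SD1_SD2 = "-", SampleEn_RR = "-",
  SampleEn_iHR = "-", SampleEn_Peak = "-",
  FS14_total = "score", FS14_physical = "score", FS14_mental = "score"
)

#' Pipeline run configuration
#'
#' Declarative description of one end-to-end run. Exactly one input mode is
#' active: `"synthetic"` (generate a cohort), `"rr_files"` (a manifest CSV
#' of RR text files) or `"ecg_files"` (a manifest CSV of ECG CSV traces).
#'
#' @param mode input mode.
#' @param output_dir where all outputs are written.
#' @param seed RNG seed, recorded in every output.
#' @param n_male,n_female,between_subject_sd synthetic-mode cohort shape.
#' @param manifest path of the input manifest CSV (`subject_id`, `gender`,
#'   `state`, `file`) for the file modes.
#' @param fs14 optional FS-14 CSV (`subject_id`, `state`, `item1..item14`).
#' @param ecg_fs sampling-rate override for ECG CSVs, Hz.
#' @param vlf,lf,hf analysis band edges, Hz.
#' @param psd_method,resample_rate,segment_s,overlap spectral settings.
#' @param m,r_coef,tau sample-entropy settings.
#' @param min_ms,max_ms,max_rel_jump artifact-filter thresholds.
#' @param write_inputs synthetic mode: also write the generated RR/FS-14
#'   files under `output_dir/cohort/`.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "rr_files", "ecg_files"),
                       output_dir = tempfile("hrvrun"), seed = 1,
                       n_male = 38, n_female = 27, between_subject_sd = 0.12,
                       manifest = NULL, fs14 = NULL, ecg_fs = NULL,
                       vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                       hf = c(0.15, 0.4),
                       psd_method = "welch", resample_rate = 4,
                       segment_s = 120, overlap = 0.5,
                       m = 2, r_coef = 0.2, tau = 1,
                       min_ms = 300, max_ms = 2000, max_rel_jump = 0.3,
                       write_inputs = FALSE) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the configuration without running anything. Returns a data frame
#' of findings (field, reason); an empty result means the configuration is
#' runnable.
#'
#' @param config [run_config]
#' @return data frame with columns `field` and `reason` (zero rows when
#'   valid).
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(field, reason) {
    findings[[length(findings) + 1L]] <<- data.frame(field = field,
                                                     reason = reason)
  }
  if (!inherits(config, "run_config")) {
    add("config", "not a run_config object")
    return(do.call(rbind, findings))
  }
  if (!config$mode %in% c("synthetic", "rr_files", "ecg_files")) {
    add("mode", "unknown input mode")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      is.na(config$seed) || config$seed < 0 || config$seed != round(config$seed)) {
    add("seed", "seed must be a single non-negative integer")
  }
  for (bn in c("vlf", "lf", "hf")) {
    b <- config[[bn]]
    if (!is.numeric(b) || length(b) != 2L || b[1] >= b[2] || b[1] < 0) {
      add(bn, "band must be an ascending non-negative frequency pair")
    }
  }
  if (is.numeric(config$vlf) && is.numeric(config$lf) &&
      length(config$vlf) == 2L && length(config$lf) == 2L &&
      config$lf[1] < config$vlf[2]) {
    add("vlf/lf", "VLF and LF bands overlap")
  }
  if (is.numeric(config$lf) && is.numeric(config$hf) &&
      length(config$lf) == 2L && length(config$hf) == 2L &&
      config$hf[1] < config$lf[2]) {
    add("lf/hf", "LF and HF bands overlap")
  }
  if (config$mode == "synthetic") {
    if (config$n_male + config$n_female < 2) {
      add("n_male/n_female", "need at least 2 subjects")
    }
  } else {
    if (is.null(config$manifest)) {
      add("manifest", "file modes require a manifest CSV")
    } else if (!file.exists(config$manifest)) {
      add("manifest", sprintf("manifest not found: %s", config$manifest))
    }
  }
  if (config$m < 1 || config$tau < 1) add("m/tau", "entropy embedding must be positive")
  if (config$r_coef <= 0 || config$r_coef >= 1) {
    add("r_coef", "entropy tolerance fraction must be in (0, 1)")
  }
  if (config$min_ms >= config$max_ms || config$min_ms <= 0) {
    add("min_ms/max_ms", "artifact interval range invalid")
  }
  if (config$max_rel_jump <= 0) add("max_rel_jump", "must be positive")
  if (!config$psd_method %in% c("welch", "ar")) {
    add("psd_method", "must be 'welch' or 'ar'")
  }
  out <- if (length(findings)) do.call(rbind, findings) else {
    data.frame(field = character(0), reason = character(0))
  }
  out
}

# Read a YAML config file into a run_config; unknown keys rejected.
#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config].
#' @param ... overrides applied on top of the file values.
#' @return [run_config]
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# ---- internal input loaders ------------------------------------------------

load_manifest_rr <- function(config) {
  man <- utils::read.csv(config$manifest)
  need <- c("subject_id", "gender", "state", "file")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns subject_id, gender, state, file")
  }
  base <- dirname(config$manifest)
  lapply(seq_len(nrow(man)), function(i) {
    path <- man$file[i]
    if (!file.exists(path)) path <- file.path(base, man$file[i])
    if (!file.exists(path)) stop("input file not found: ", man$file[i])
    rr <- if (config$mode == "rr_files") {
      read_rr(path)
    } else {
      ecg <- read_ecg_csv(path, fs = config$ecg_fs)
      rr_from_peaks(detect_r_peaks(bandpass_filter(ecg)))
    }
    list(subject_id = as.character(man$subject_id[i]),
         gender = as.character(man$gender[i]),
         state = as.character(man$state[i]), rr = rr)
  })
}

load_fs14_csv <- function(path) {
  d <- utils::read.csv(path)
  items <- paste0("item", 1:14)
  if (!all(c("subject_id", "state", items) %in% names(d))) {
    stop("FS-14 CSV must have subject_id, state and item1..item14 columns")
  }
  d$FS14_total <- NA_real_
  d$FS14_physical <- NA_real_
  d$FS14_mental <- NA_real_
  for (i in seq_len(nrow(d))) {
    rec <- score_fs14(as.integer(d[i, items]))
    d$FS14_total[i] <- rec$total
    d$FS14_physical[i] <- rec$physical
    d$FS14_mental[i] <- rec$mental
  }
  d[, c("subject_id", "state", "FS14_total", "FS14_physical", "FS14_mental")]
}

# Recompute group means from the feature table and verify they match the
# comparison table: every comparison number must be traceable to rows of
# the feature CSV.
check_consistency <- function(features, comparison) {
  for (i in seq_len(nrow(comparison))) {
    row <- comparison[i, ]
    df <- if (row$group == "all") features else {
      features[features$gender == row$group, ]
    }
    v <- df[df$state == "nonfatigue", row$feature]
    v <- v[is.finite(v)]
    if (length(v) && is.finite(row$nonfatigue_mean) &&
        abs(mean(v) - row$nonfatigue_mean) > 1e-8) {
      return(FALSE)
    }
  }
  TRUE
}

#' Run the full fatigue-analysis pipeline
#'
#' Orchestrates one reproducible run: input acquisition (synthetic cohort
#' generation, RR text files, or raw ECG CSVs), artifact filtering, feature
#' extraction (time domain, spectral, Poincare, sample entropy, FS-14
#' scores), and the paired cohort contrast. Writes, under
#' `config$output_dir`:
#'
#' * `features.csv` — one row per (subject, state) with all feature columns;
#' * `comparison_overall.csv` / `comparison_by_gender.csv` — group means,
#'   SDs, Spearman rho, Mann-Whitney p, stars, percent change;
#' * `percent_change.csv` — feature, unit, state means, change rate;
#' * `densities.csv` — per-(feature, gender, state) kernel density grids;
#' * `report.json` — counts, exclusions, warnings, config echo, file list.
#'
#' Subjects failing interval-quality control (more than 20% of intervals
#' removed in either state) are excluded and listed in the report, never
#' dropped silently. With identical config and seed, synthetic-mode runs
#' are bit-identical.
#'
#' @param config [run_config]
#' @return object of class `run_report` (the parsed report, including
#'   `features` and `comparison` data frames).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- validate_config(config)
  if (nrow(v) > 0L) {
    stop("invalid config: ",
         paste(sprintf("%s (%s)", v$field, v$reason), collapse = "; "))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  fs14_tab <- NULL

  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$n_male, config$n_female,
                              between_subject_sd = config$between_subject_sd,
                              seed = config$seed)
    if (isTRUE(config$write_inputs)) {
      write_cohort(cohort, file.path(config$output_dir, "cohort"))
    }
    records <- list()
    fs_rows <- list()
    for (s in cohort) {
      for (state in c("nonfatigue", "fatigue")) {
        records[[length(records) + 1L]] <- list(
          subject_id = s$subject_id, gender = s$gender, state = state,
          rr = s[[paste0("rr_", state)]])
        rec <- s[[paste0("fs14_", state)]]
        fs_rows[[length(fs_rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, state = state,
          FS14_total = rec$total, FS14_physical = rec$physical,
          FS14_mental = rec$mental)
      }
    }
    fs14_tab <- do.call(rbind, fs_rows)
  } else {
    records <- load_manifest_rr(config)
    if (!is.null(config$fs14)) fs14_tab <- load_fs14_csv(config$fs14)
  }

  # artifact filter + quality gate per record
  filtered <- list()
  removals <- list()
  failed_subjects <- character(0)
  for (rec in records) {
    fr <- artifact_filter(rec$rr, max_rel_jump = config$max_rel_jump,
                          min_ms = config$min_ms, max_ms = config$max_ms)
    removals[[length(removals) + 1L]] <- data.frame(
      subject_id = rec$subject_id, state = rec$state,
      n_removed = length(fr$removed),
      fraction_removed = fr$fraction_removed, status = fr$status)
    if (fr$status == "quality_failure" || is.null(fr$series)) {
      failed_subjects <- union(failed_subjects, rec$subject_id)
    } else {
      rec$rr <- fr$series
      filtered[[length(filtered) + 1L]] <- rec
    }
  }
  filtered <- Filter(function(r) !(r$subject_id %in% failed_subjects),
                     filtered)
  if (length(failed_subjects)) {
    warnings_log <- c(warnings_log, sprintf(
      "excluded %d subject(s) on interval quality: %s",
      length(failed_subjects), paste(failed_subjects, collapse = ", ")))
  }
  if (length(filtered) == 0L) stop("no records left after quality control")

  feats <- do.call(rbind, lapply(filtered, function(rec) {
    cbind(data.frame(subject_id = rec$subject_id, gender = rec$gender,
                     state = rec$state),
          hrv_features(rec$rr, psd_method = config$psd_method,
                       resample_rate = config$resample_rate,
                       segment_s = config$segment_s,
                       overlap = config$overlap, m = config$m,
                       r_coef = config$r_coef, tau = config$tau,
                       vlf = config$vlf, lf = config$lf, hf = config$hf))
  }))
  if (!is.null(fs14_tab)) {
    feats <- merge(feats, fs14_tab, by = c("subject_id", "state"),
                   all.x = TRUE, sort = FALSE)
    feats <- feats[order(feats$subject_id, feats$state == "fatigue"), ]
  }
  feat_path <- file.path(config$output_dir, "features.csv")
  utils::write.csv(feats, feat_path, row.names = FALSE)

  out_files <- "features.csv"
  comparison <- NULL
  has_both <- all(c("nonfatigue", "fatigue") %in% feats$state)
  min_n <- if (has_both) min(table(feats$state)) else 0
  if (!has_both) {
    warnings_log <- c(warnings_log,
                      "comparison skipped: need both states for pairing")
  } else {
    comparison <- compare_states(feats, stratify_by_gender = TRUE)
    if (min_n < 5) {
      warnings_log <- c(warnings_log,
                        "low n: comparison p-values are unreliable")
    }
    overall <- comparison[comparison$group == "all", ]
    utils::write.csv(overall,
                     file.path(config$output_dir, "comparison_overall.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison[comparison$group != "all", ],
                     file.path(config$output_dir, "comparison_by_gender.csv"),
                     row.names = FALSE)
    rates <- data.frame(
      feature = overall$feature,
      unit = unname(.feature_units[overall$feature]),
      nonfatigue = overall$nonfatigue_mean,
      fatigue = overall$fatigue_mean,
      rate_percent = overall$percent_change)
    utils::write.csv(rates,
                     file.path(config$output_dir, "percent_change.csv"),
                     row.names = FALSE)
    if (!check_consistency(feats, comparison)) {
      stop("internal consistency check failed: comparison not traceable to features")
    }
    # density summaries per gender x state
    dens_rows <- list()
    for (fc in unique(overall$feature)) {
      for (g in unique(feats$gender)) for (st in c("nonfatigue", "fatigue")) {
        vals <- feats[feats$gender == g & feats$state == st, fc]
        vals <- vals[is.finite(vals)]
        if (length(vals) >= 5 && stats::sd(vals) > 0) {
          de <- estimate_pdf(vals)
          dens_rows[[length(dens_rows) + 1L]] <- data.frame(
            feature = fc, gender = g, state = st, grid = de$grid,
            density = de$density)
        }
      }
    }
    if (length(dens_rows)) {
      utils::write.csv(do.call(rbind, dens_rows),
                       file.path(config$output_dir, "densities.csv"),
                       row.names = FALSE)
      out_files <- c(out_files, "densities.csv")
    }
    out_files <- c(out_files, "comparison_overall.csv",
                   "comparison_by_gender.csv", "percent_change.csv")
  }

  report <- list(
    package_version = as.character(utils::packageVersion("hrvfatigue")),
    seed = config$seed,
    mode = config$mode,
    n_records_in = length(records),
    n_records_retained = length(filtered),
    n_subjects_retained = length(unique(vapply(filtered, `[[`, "",
                                               "subject_id"))),
    excluded_subjects = failed_subjects,
    removals = do.call(rbind, removals),
    warnings = warnings_log,
    config = config[setdiff(names(config), "output_dir")],
    files = out_files
  )
  report_json <- report
  report_json$removals <- NULL
  jsonlite::write_json(report_json,
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  stopifnot(all(file.exists(file.path(config$output_dir, out_files))))
  structure(c(report, list(features = feats, comparison = comparison)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<run_report> mode %s, seed %s\n",
    "  records: %d in, %d retained (%d subjects)\n",
    "  warnings: %d\n"),
    x$mode, x$seed, x$n_records_in, x$n_records_retained,
    x$n_subjects_retained, length(x$warnings)))
  invisible(x)
}
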