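# hrvfatigue

Heart rate variability (HRV) analysis of occupational fatigue from
short-term ECG, for researchers and ergonomists contrasting a worker
cohort's rested ("nonfatigue") and post-work ("fatigue") states.

The package covers the full chain:

* **ECG processing** — zero-phase 0.5–40 Hz band-pass, Pan–Tompkins-style
  R-peak detection, RR-interval extraction, rule-based artifact
  filtering.
* **Time domain** — meanRR, meanHR = 60000/meanRR, SDNN, RMSSD, SDSD,
  CV = SDNN/meanRR, pNN20, pNN50 (strict `> x` ms rule over N − 1
  successive pairs; population-SD convention with a sample-SD switch).
* **Frequency domain** — cubic resampling of the tachogram at 4 Hz,
  Welch (120 s Hann segments, 50% overlap) or Yule–Walker AR spectra,
  band powers over VLF 0.003–0.04 Hz, LF 0.04–0.15 Hz, HF 0.15–0.4 Hz,
  relative powers, LFnorm = LF/(LF+HF), HFnorm = HF/(LF+HF), LF/HF.
* **Nonlinear** — Poincaré SD1/SD2 (SD1 = (√2/2)·SDSD;
  SD2 = √(2·SDNN² − SDSD²/2) on the lagged-pair ensemble) and sample
  entropy SampEn(m = 2, r = 0.2·SD, τ = 1) = ln(Φᵐ/Φᵐ⁺¹) with Chebyshev
  distance and self-matches excluded, over RR, instantaneous-HR and
  R-peak-amplitude series.
* **Cohort statistics** — FS-14 questionnaire scoring (8 physical + 6
  mental items), Lilliefors normality screen, Spearman correlation of
  paired states, exact-enumeration and normal-approximation Mann–Whitney
  U tests, `**`/`*`/`NS` significance stars (p < 0.001 / p < 0.05),
  percent-change tables, kernel density summaries by gender and state.
* **Synthetic cohort** — paired nonfatigue/fatigue RR tachograms
  (narrowband phase-diffusion modulations plus white noise, calibrated
  to group means of 845→698 ms meanRR, 67→45 ms SDNN, LF/HF 3.0→4.8),
  template ECG traces with ground-truth beat times, and calibrated FS-14
  responses — so the whole pipeline is testable with no field data.

## Worked example

```r
library(hrvfatigue)

p  <- fatigue_study_profiles()          # calibrated state profiles
rr <- generate_rr_tachogram(p$nonfatigue, seed = 42)
rr
#> <rr_series> 356 intervals spanning 300.1 s, mean RR 842.8 ms, with R-peak amplitudes

compute_time_domain(rr)
#> <time_domain_summary> n = 356
#>   meanRR 842.85 ms   meanHR 71.19 bpm   SDNN 67.07 ms
#>   RMSSD 39.36 ms    SDSD 39.36 ms      CV 0.0796
#>   pNN20 61.69%      pNN50 21.69%

band_powers(estimate_psd(resample_tachogram(rr)))
#> <spectral_summary> total 4226.1 ms^2
#>   VLF 1951.8 (46.2%)  LF 1670.2 (39.5%)  HF 604.0 (14.3%)
#>   LFnorm 0.734  HFnorm 0.266  LF/HF 2.765

poincare_descriptors(rr)
#> <poincare_summary> SD1 27.832 ms, SD2 90.761 ms, SD1/SD2 0.307 (355 points)

sample_entropy(rr$intervals)
#> <sampen_result> m=2 tau=1 r=13.43 : SampEn 1.5352 (n=356)
```

The single 5-minute record above already shows the calibrated
nonfatigue physiology: mean RR near 845 ms, SDNN near 67 ms, about 46%
of spectral power in VLF and an LF/HF ratio near 3.

An end-to-end paired cohort run:

```r
rep <- run_pipeline(run_config(mode = "synthetic", n_male = 10,
                               n_female = 8, seed = 42,
                               output_dir = "run42"))
cmp <- rep$comparison[rep$comparison$group == "all", ]
cmp[cmp$feature %in% c("meanRR", "SDNN", "LF_HF", "SampleEn_RR",
                       "FS14_total"),
    c("feature", "nonfatigue_mean", "fatigue_mean", "p_value", "stars",
      "percent_change")]
#>        feature nonfatigue_mean fatigue_mean   p_value stars percent_change
#> 1       meanRR         884.039      684.194 7.168e-05    **         -22.61
#> 3         SDNN          66.683       47.665 1.811e-05    **         -28.52
#> 14       LF_HF           3.514        5.017 2.369e-02     *          42.77
#> 18 SampleEn_RR           1.536        1.550 9.370e-01    NS           0.94
#> 21  FS14_total          22.111       49.167 3.004e-07    **         122.36
```

Fatigue shortens the mean RR interval and shrinks overall variability
(both `**`, p < 0.001), raises sympathovagal balance (LF/HF, `*`), and
more than doubles the self-reported fatigue score. With only 18
subjects the small sample-entropy shift is not yet significant — at the
full 65-subject design it is. The run directory also receives
`features.csv` (one row per subject and state), per-gender comparison
tables, a percent-change table, density grids and a JSON run report.

A thin command-line wrapper with `run`, `synthesize`, `features`,
`compare` and `validate` verbs lives at
`inst/scripts/hrv-pipeline.R`; configuration can come from a YAML file
(`read_config()`), with flags overriding.

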