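Package: hrvfatigue
Title: Heart Rate Variability Analysis of Occupational Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for assessing occupational fatigue from short-term
    (5-minute) electrocardiogram recordings via heart rate variability (HRV).
    Covers R-peak detection and RR-interval extraction from raw single-channel
    ECG, time-domain statistics (meanRR, meanHR, SDNN, RMSSD, SDSD, CV,
    pNN20, pNN50), Welch and autoregressive spectral band powers (VLF, LF, HF,
    normalized powers, LF/HF), Poincare plot descriptors (SD1, SD2), sample
    entropy of RR, instantaneous heart rate and R-peak amplitude series,
    FS-14 fatigue questionnaire scoring, and a nonparametric paired cohort
    contrast (Spearman correlation, Mann-Whitney U tests, significance stars,
    percent-change tables, kernel density summaries). Includes a calibrated
    synthetic-cohort generator producing paired nonfatigue/fatigue RR
    tachograms, template ECG traces and questionnaire responses so the whole
    pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    pracma,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
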