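---
title: "Methods: HRV-based fatigue contrast and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV-based fatigue contrast and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvfatigue)
```

## The problem

Occupational fatigue shifts the balance of the autonomic nervous system:
sympathetic drive rises, vagal (parasympathetic) drive falls. Heart rate
variability (HRV) — the beat-to-beat fluctuation of RR intervals in the
ECG — is the standard non-invasive window onto that balance. This package
implements the complete analysis chain for a paired field design: each
subject is measured in a rested ("nonfatigue") state and again after a
day's physical work ("fatigue"), HRV features are extracted from 5-minute
ECG epochs, fatigue is corroborated by the FS-14 questionnaire, and the
two states are contrasted nonparametrically across the cohort.

Because raw field recordings of this kind are rarely shareable, the
package ships a calibrated synthetic-cohort generator. It is first-class,
tested code: every downstream stage can be exercised end to end, with
known ground truth, without any external data.

## From ECG to RR intervals

`bandpass_filter()` applies a zero-phase Butterworth band (default
0.5–40 Hz; order-8 low-pass and order-2 high-pass sections run
forward–backward) to remove baseline wander and mains interference.
`detect_r_peaks()` is a derivative–square–integrate detector with an
adaptive threshold in the Pan–Tompkins tradition: QRS-band (5–20 Hz)
filtering, squared derivative, 150 ms moving integration, peak picking
above a fraction of the robust energy ceiling, a 200 ms refractory
period, amplitude gating against the candidate population (candidates
below 0.65 of the median band-passed excursion are rejected as
noise-triggered), and a search-back pass that re-admits the best rejected
candidate inside gaps longer than 1.6 times the running median
beat-to-beat spacing. Correctness is defined contractually: on noise-free
synthetic ECG the full round trip (RR series to ECG to detected RR
series) recovers every interval within one sample period, and at 10 dB
additive white noise recall and precision stay at or above 0.95. The
amplitude gate assumes reasonably stable R-wave amplitude (within roughly
±35% of the running median); traces with severe amplitude modulation
would need a gentler gate.

`artifact_filter()` removes implausible intervals (outside 300–2000 ms,
or more than 30% away from the previous accepted interval — conventional
short-term-HRV practice), recomputes beat times, reports removed indices
(1-based), and flags a record as a quality failure when more than 20% of
intervals are removed. The filter is idempotent.

## Feature definitions

Time domain (`compute_time_domain()`): meanRR, meanHR = 60000/meanRR,
SDNN, RMSSD, SDSD, CV = SDNN/meanRR (a fraction), pNN20 and pNN50 with a
strict "greater than" rule on the absolute successive difference, out of
N − 1 pairs. Standard deviations use the population (1/N) convention by
default with a `sd_type = "sample"` switch. SDSD is the standard
deviation of the successive differences; RMSSD and SDSD then obey
RMSSD² = SDSD² + (mean successive difference)², so RMSSD ≥ SDSD always,
with near-equality on stationary series.

Frequency domain: the tachogram is cubic-spline resampled at 4 Hz
(`resample_tachogram()`), each interval indexed at its terminating beat
time. `estimate_psd()` offers Welch (default: 120 s Hann segments, 50%
overlap, linear detrend — conventional for 5-min epochs) and a
Yule–Walker AR spectrum (order 16) rescaled to the variance of the
detrended series so the two are band-comparable. `band_powers()`
integrates VLF 0.003–0.04 Hz, LF 0.04–0.15 Hz and HF 0.15–0.4 Hz by
trapezoid with the density interpolated at the exact band edges (with
only a handful of spectral bins inside VLF, dropping the edge fractions
would lose a large share of the band mass). Relative powers are
percentages of total 0.003–0.4 Hz power. Normalized powers use the
LF + HF denominator, the convention under which LFnorm + HFnorm = 1
exactly; ULF is excluded throughout, as is standard for 5-minute records.
LF/HF with exactly zero HF power is reported as `NA`, never infinity.

Nonlinear: `poincare_descriptors()` computes SD1/SD2 as the standard
deviations of the projections of successive-interval pairs onto the
diagonals. The familiar closed forms SD1 = (√2/2)·SDSD and
SD2 = √(2·SDNN² − SDSD²/2) are used as an internal cross-check; note the
SD2 identity is exact only when its "SDNN" term is the variance of the
lagged-pair ensemble (the N − 1 leading and trailing intervals pooled).
With the whole-series SDNN the identity holds up to O(1/N) edge terms,
which is why the package asserts agreement between projection and closed
form at 1e−9 using the pair-ensemble convention.

`sample_entropy()` implements SampEn(m, r, N): embedding dimension m = 2,
delay τ = 1 and tolerance r = 0.2·SD by default, Chebyshev distance,
self-matches excluded, the same N − mτ templates at both orders, and
SampEn = ln(Φᵐ/Φᵐ⁺¹). τ is exposed but rarely changed. When no template
pair matches at order m + 1 the value is an `NA` marker so cohort tables
can carry it as missing. The implementation is pinned, to 12 decimal
digits, against an independent brute-force double-loop oracle on random
series up to n = 200. `entropy_panel()` applies shared parameters to the
RR series, the instantaneous heart rate (60000/RR) and the R-peak
amplitude series.

## Cohort statistics

`compare_states()` reproduces the reporting conventions of paired field
studies: state means ± SD per feature, Spearman correlation of the
within-subject (nonfatigue, fatigue) pairs (the nonparametric choice,
since most HRV features fail a normality screen), a two-sided
Mann–Whitney U test between states, significance stars (`**` for
p < 0.001, `*` for p < 0.05, `NS` otherwise) and the percent change of
the fatigue mean against the nonfatigue baseline. The normality screen
(`ks_normality()`) is the Lilliefors-corrected one-sample K–S test,
because location and scale are always estimated from the data here; the
report labels it as such. No multiple-testing correction is applied to
the primary stars, matching standard practice in this literature;
Bonferroni and Benjamini–Hochberg columns are emitted alongside, clearly
marked as supplementary.

`mann_whitney_u()` enumerates the full permutation distribution of U for
pooled sizes up to 20 (ties handled exactly) and otherwise uses the
normal approximation with tie and continuity corrections via
`stats::wilcox.test`. The two routes agree within 0.02 in p for groups of
8 or more without heavy ties, which the suite verifies.

The Spearman column correlates each feature across the two states within
subject. The choice of within-subject pairing is a design decision of
this package — it is the only pairing that uses the paired structure of
the design — and is documented rather than asserted as the only reading.

FS-14: 14 Likert items (1–5), 8 physical plus 6 mental. Which items form
which subscale is configuration (`score_fs14()` defaults to items 1–8
physical, 9–14 mental); totals are the contractual quantity.

## The synthetic cohort

`generate_rr_tachogram()` builds each tachogram as

> RR(t) = meanRR + VLF(t) + LF(t) + HF(t) + white noise,

evaluated at the running cumulative beat time, so the series is
irregularly sampled by construction, exactly as real tachograms are. Each
band term is a constant-envelope phase-diffusion oscillator: a cosine at
the band's center frequency (0.02 Hz for VLF, configurable 0.1/0.25 Hz
for LF/HF) whose phase performs a Brownian walk, spreading the line into
a narrow band (linewidths 0.003/0.01/0.02 Hz). Two properties motivated
this choice over filtered white noise. First, the realized power of a
constant-envelope oscillator equals its configured power in every time
window, so a single 300 s realization delivers its band powers to within
the accuracy of the spectral estimator itself; filtered-noise
realizations of VLF-narrow bands fluctuate by tens of percent over 5
minutes, which would make the generator's band-power contract
untestable. Second, slow cardiovascular rhythms (Mayer waves, paced
respiration) are themselves quasi-oscillatory. The surrogate remains
non-physiological: no integral-pulse-frequency modulation, no
respiratory–cardiac phase coupling, no circadian drift. Passing tests on
this generator therefore demonstrate correctness of the analysis chain,
not validity of any physiological model.

The per-beat white noise is broadband and leaks into the analysis bands
after resampling; the default study profiles
(`fatigue_study_profiles()`) account for this by solving the oscillator
powers for the target *measured* band composition, noise included (the
empirical leakage fractions of the noise variance are 0.045/0.158/0.342
into VLF/LF/HF at 4 Hz cubic resampling).

The default profiles emulate the study conditions: nonfatigue meanRR
845 ms, SDNN 67 ms, 46% VLF, LF:HF 3.0, white noise 2 ms; fatigue meanRR
698 ms, SDNN 45 ms, 43.5% VLF, LF:HF 4.8, white noise 12 ms. The larger
fatigued noise floor raises the relative irregularity of the
shrunken-variance fatigued series, reproducing the observed direction of
the sample-entropy shift. `generate_cohort()` (default 38 male + 27
female, the study's retained cohort size) jitters each subject's profile:
log-normal factors with log-SD 0.12 on meanRR and, independently per
band, log-SD 0.48 on the powers — variance-type quantities spread much
wider across subjects than the mean interval, and independent band
factors give the LF/HF ratio a realistic between-subject spread. Mild
gender modifiers (±2–3% on meanRR per state; fatigued modulation power
scaled 1.29 for males, 0.65 for females) mirror the usual direction of
gender differences in such cohorts; the underlying study reports
per-gender group means but no per-gender generative parameters, so these
constants are configuration, not fixed truth.

FS-14 responses are truncated-discretized normal per item with
state-dependent latent means solved numerically (once) so the expected
cohort totals are 21.5 (nonfatigue) and 49.4 (fatigue), with physical
and mental subscales moving from 12.6 to 34.2 and 9.0 to 15.2. The
implied total SDs (2.2 and 3.4) fall slightly below the field values
(2.4 and 3.9); means are the contractual quantity.

Ectopic-like artifacts are simulated as isolated interval halvings or
doublings at a configurable per-beat rate, exercising the artifact
filter; real ectopy (compensatory pauses, interpolated beats) is more
structured.

## Numerical choices and degenerate inputs

* Welch with few segments underestimates very-low-frequency power that
  behaves like a within-segment trend; the VLF oscillator is centered at
  0.02 Hz, comfortably above the detrending knee.
* Band integration interpolates the density at the exact band edges;
  with 120 s segments the VLF band spans only about 4.4 resolution bins
  and naive in-bin trapezoids would lose up to a bin of mass.
* Sample entropy of a constant series is 0 (the tolerance resolves
  against a machine-epsilon floor); "no matches at order m + 1" is a
  tagged `NA`; ties at exactly r count as matches (≤ r).
* `percent_change()` with a zero baseline, LF/HF with zero HF power,
  Spearman on a constant vector, and the KDE of a zero-variance sample
  all return tagged markers, never exceptions or infinities.
* The exact Mann–Whitney mode is limited to pooled n ≤ 20
  (C(20,10) ≈ 1.8e5 arrangements, enumerated vectorized).
* Seeds: every generator takes an explicit seed; the cohort generator
  derives per-subject seeds from the master seed, so cohorts are
  bit-identical across runs and platforms.

## Problem sizes

The test-suite and acceptance runs use 5-minute records (about 350
beats, 1200 resampled points), the 38 + 27 paired cohort for end-to-end
checks, and brute-force oracle comparisons up to n = 200; these sizes
were chosen as the smallest at which every contract (spectral recovery,
entropy oracle equivalence, cohort direction recovery) is meaningfully
exercised.

## Known limitations

* The detector is tuned for single-channel, upright-QRS traces; it does
  not classify ectopic morphology and relies on the interval-rule filter
  downstream.
* The spectral generator contract is calibrated at 300 s; much shorter
  records will show larger band-power errors simply because the
  estimator's resolution degrades.
* Group-level calibration of the synthetic cohort reproduces means,
  directions and approximate spreads, not the full joint distribution of
  real HRV features; nothing here validates physiological claims about
  autonomic regulation.
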