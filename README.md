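# npsampen

Short-term (1-minute) heart-rate-variability analysis built around
**nonparametric sample entropy (NPSampEn)**, a tolerance-free variant of
sample entropy, with an end-to-end pipeline for screening obstructive sleep
apnea (OSA) from overnight single-lead ECG or RR-interval recordings.

## Who this is for

Researchers analyzing beat-to-beat regularity on very short RR segments —
the 60–100 beats of one annotated minute — where classical sample entropy is
fragile: an ill-chosen tolerance `r` leaves it undefined or ranks signal
complexity inconsistently.

## The statistic

Classical sample entropy compares template vectors of length `m` and `m + 1`
under one fixed Chebyshev tolerance `r` (self-matches excluded):

    SampEn(m, r) = ln( Φ^m(r) / Φ^{m+1}(r) )

NPSampEn drops the tolerance parameter. Let *scope* be the ascending vector
of all unique values in the two distance matrices `d^m` and `d^{m+1}`
(length *nbin*). Evaluating both cumulative match-probability profiles at
every scope value and averaging the log-ratios gives

    NPSampEn(m) = (1/nbin) Σ_q ln( Φ^m(scope(q)) / Φ^{m+1}(scope(q)) )

The tolerance set comes from the segment itself, so the estimator is affine
invariant, always defined, nonnegative, and adapts to individual differences.

## What's in the package

- `npsampen()`, `sampen()`, plus the shared machinery
  (`template_distances()`, `build_scope()`, `cumulative_profiles()`)
- MIX(p) surrogate benchmark: `generate_mix()`, `entropy_length_sweep()`,
  `entropy_r_sweep()`, `summarize_sweep()`
- ECG → RR preprocessing: `detect_r_peaks()` (Pan-Tompkins),
  `correct_rr_local_median()`, `segment_minutes()`, `resample_2hz()`,
  `rr_features()`
- Burg AR(6) spectral indices: `burg_psd()`, `band_power()`,
  `frequency_indices()` (LF, HF, LF/HF)
- Screening/statistics: `screen_recordings()`, `fisher_discriminant()`,
  `svm_2fold()`, `confusion_metrics()`, `roc_auc()`, `anova_lsd()`,
  `pearson_corr()`, `assign_group()`
- Synthetic fixtures: `cohort_spec()`, `generate_cohort()`, `synth_rr()`,
  `synth_ecg()`; readers/writers for RR CSV, signal CSV and WFDB
  (formats 16/212)
- A CLI dispatcher at `inst/cli/npsampen-cli.R`
  (`simulate | sweep | entropy | pipeline | fixtures | screen`)

## Worked example

Synthesize a severe-OSA-like RR recording, extract per-minute features, and
compare the two entropies on a MIX(0.3) benchmark signal:

```r
library(npsampen)
set.seed(1)
rec   <- synth_rr("SOSA", cohort_spec(), duration_h = 0.1)
feats <- rr_features(rec$rr, hours = 0.1)
round(feats[1:3, c("minute", "n_beats", "sampen", "npsampen", "lf_hf")], 3)
#>   minute n_beats sampen npsampen lf_hf
#> 1      0      60  0.850    0.262 2.401
#> 2      1      59  0.965    0.271 4.411
#> 3      2      60  1.135    0.325 1.748

x <- generate_mix(0.3, 100, seed = 7)$values
npsampen(x, m = 2)
#> npsampen: 0.4750311
sampen(x, m = 2, r = 0.2)
#> sampen: 1.093133
```

Each row is one minute: both entropies are low (the apneic cycle makes the
tachogram regular) and LF/HF is high (sympathetic dominance). At cohort
scale these per-recording means separate normal from apneic recordings; see
`screen_recordings()` for the ANOVA/LSD, ROC/AUC, Pearson-vs-AHI and
Fisher-discriminant report.

From a shell, the same pipeline runs as:

```sh
Rscript inst/cli/npsampen-cli.R fixtures --n 2,1,2 --duration 0.5 --out cohort/
Rscript inst/cli/npsampen-cli.R pipeline --rr cohort/rr_n01.csv --hours 0.5 --out features.csv
```

## Notes

The published real-data results for this method were computed on the
PhysioNet apnea-ecg recordings, which are not bundled; `read_wfdb()` can
load them into the identical pipeline if downloaded separately. The
synthetic cohort is a deliberately clean fixture — see the methods vignette
(`vignettes/npsampen-methods.Rmd`) for what it does and does not emulate.
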