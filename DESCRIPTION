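Package: npsampen
Title: Nonparametric Sample Entropy for Short-Term Heart Rate Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for short-term (1-minute) heart rate variability analysis
    built around nonparametric sample entropy (NPSampEn), a tolerance-free
    variant of sample entropy that replaces the fixed similarity threshold r
    by the full set of unique template distances of the segment. Includes
    classical sample entropy, a MIX(p) surrogate-signal benchmark for
    comparing the two estimators on short series, an ECG-to-RR preprocessing
    pipeline (Pan-Tompkins QRS detection, local-median artifact correction,
    1-minute segmentation, 2 Hz spline resampling), Burg autoregressive
    spectral indices (LF, HF, LF/HF), a seeded synthetic cohort generator
    emulating normal and obstructive-sleep-apnea-like RR dynamics, and a
    screening/statistics layer (Fisher discriminant, nu-SVM with 2-fold
    cross-validation, ROC/AUC, one-way ANOVA with LSD post-hoc tests,
    Pearson correlation against the apnea-hypopnea index).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
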