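---
title: "Nonparametric sample entropy for 1-minute HRV segments: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric sample entropy for 1-minute HRV segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npsampen)
```

## The problem

Obstructive sleep apnea (OSA) leaves a signature in heart rate variability:
recurrent apneas drive a slow cyclic bradycardia–tachycardia oscillation and a
shift toward sympathetic dominance, so the RR-interval series of an apneic
sleeper is *more regular* (lower entropy) and has a *higher LF/HF ratio* than
that of a healthy sleeper. Screening conventions annotate overnight
recordings minute by minute, so the natural analysis unit is a 1-minute RR
segment — just 60–100 beats.

Classical sample entropy on such short segments is fragile. SampEn(m, r) is
the negative log of the conditional probability that two length-`m` templates
within tolerance `r` (Chebyshev distance, self-matches excluded) stay within
`r` at length `m + 1`:

$$\mathrm{SampEn} = \ln\frac{\Phi^m(r)}{\Phi^{m+1}(r)}$$

On 60–100 points an ill-chosen `r` leaves no template matches, making the
statistic undefined, and the usual SD-relative choice (`r` between 0.1 and
0.25 SD) reacts to the segment's gross variability rather than to the fine
structure of its template distances.

Nonparametric sample entropy (NPSampEn) removes the tolerance parameter.
Let *scope* be the sorted vector of all unique values occurring in the two
distance matrices $d^m$ and $d^{m+1}$, with length *nbin*. Evaluating the two
cumulative match-probability profiles at every scope value and averaging the
log-ratios gives

$$\mathrm{NPSampEn} = \frac{1}{nbin}\sum_{q=1}^{nbin}
  \ln\frac{\Phi^m(\mathrm{scope}(q))}{\Phi^{m+1}(\mathrm{scope}(q))}.$$

Because the tolerance set is derived from the segment itself, the estimator
adapts to individual differences, is invariant under affine rescaling of the
signal, and is defined for every admissible segment.

## Estimator details and numerical choices

**Embedding.** Both distance matrices are indexed over the common template
range $i, j = 1..N-m$, so $d^{m+1} \ge d^m$ entrywise; this single fact makes
both profiles ordered ($\Phi^m \ge \Phi^{m+1}$ pointwise) and both entropies
nonnegative. The default embedding dimension is `m = 2`, the standard choice
in the SampEn literature; it is an argument everywhere.

**Tolerance scaling.** SampEn's `r` is a multiple of the segment's
*population* SD (divisor `N`), the convention of the original SampEn
formulation. The pipeline default is `r = 0.2`; the MIX benchmark sweeps use
`r = 0.25` where they reproduce the tolerance study.

**Empty scope bins.** The smallest scope entry is the global minimum template
distance, which always originates in $d^m$ (since $d^{m+1}\ge d^m$); for
generic data $\Phi^{m+1}$ is zero there, and the log-ratio is undefined.
These bins are excluded from both the numerator and the divisor of the
average, and their count is reported in the result's diagnostics. The largest
scope bin always has $\Phi^{m+1}=1$, so at least one bin contributes and
NPSampEn is always defined. This is the minimal regularization of the
defining average; on constant or exactly periodic segments (where no bin is
empty) it changes nothing.

**Uniqueness.** Scope deduplication uses exact floating-point equality; the
estimator is therefore fully deterministic and matches a straight-line
reimplementation of the definition bit for bit, which is how the test suite
checks it (brute-force double-loop oracles, agreement to 1e-12, series up to
N = 60, m in 1..3).

**Degenerate SampEn.** When no template pair matches at the chosen tolerance
the statistic is returned as an `NA` value with a reason code rather than an
error, so batch sweeps record the failure instead of aborting — the failure
mode itself is one of the things the MIX benchmark measures.

## The MIX(p) benchmark

`generate_mix()` draws the classic complexity benchmark
$MIX(p)_j = (1-Z_j)X_j + Z_jY_j$ with $X_j = 2\sin(2\pi j/12)$,
$Z_j \sim \mathrm{Bernoulli}(p)$ i.i.d. per index and
$Y_j \sim \mathrm{U}(-3,3)$. The uniform law for $Y$ is the standard reading
of "random variables within [-3, 3]" in the MIX literature; indices run from
1. Sweeps (`entropy_length_sweep()`, `entropy_r_sweep()`) advance a single
RNG stream seeded once per sweep, so a sweep is reproducible from its seed
alone; replicate `NA`s (undefined SampEn cells) are recorded, never dropped.

Two behaviours matter and are asserted by the acceptance tests:

* **Consistency of NPSampEn.** Replicate-mean NPSampEn orders MIX(0) <
  MIX(0.3) < MIX(0.5) at every length on a coarse grid from 50 to 200 points,
  with no crossings, and drifts downward with length beyond ~100 points.
  The drift is gentle and not pointwise monotone: high-replicate runs show
  the true mean curve wiggling by a few thousandths between adjacent grid
  points (and the deterministic MIX(0) curve is quantized by the sine's
  12-sample period), so the tests assert strict ordering plus an
  endpoint-to-endpoint decrease within sampling error rather than
  step-by-step monotonicity.
* **Inconsistency of SampEn.** Mean SampEn of the stochastic MIX signals
  falls as `r` grows (strongly negative rank correlation), but on single
  realizations at N = 100 an ill-chosen `r` can rank MIX(0.3) *above*
  MIX(0.5) — a few percent of (realization, r) cells in our runs. The pure
  sine MIX(0) is a special case: all its template matches are exact, so its
  SampEn is 0 at small `r` and moves in quantized steps (both up and down) as
  `r` crosses the few distinct distance values; a monotone decrease in `r`
  is not a property of the estimator there, and the tests instead assert
  that the deterministic signal stays the least complex at every tolerance.

## Preprocessing pipeline

`detect_r_peaks()` is a standard Pan-Tompkins detector: zero-phase 5–15 Hz
Butterworth band-pass, five-point derivative, squaring, 150 ms
moving-window integration, adaptive dual thresholds with search-back when a
beat is overdue (1.66 times the running RR average), 200 ms refractory
period, and refinement of each fiducial mark to the local maximum of the raw
mean-removed waveform (the raw apex is a better time marker than the
band-passed one, whose shape the filter distorts).

`correct_rr_local_median()` replaces any interval deviating from its 5-beat
local median by more than 20% of that median, rebuilding beat times by
cumulative summation. Window and tolerance are conventional
artifact-rejection defaults and both are arguments.

`segment_minutes()` assigns each tachogram point (an interval stamped at its
closing beat) to the half-open minute `[60k, 60(k+1))`; minutes with fewer
than 30 points are flagged invalid — below half the physiologic 60–100
beats/min this indicates detector failure, not physiology — and excluded
downstream. `resample_2hz()` interpolates the tachogram with a natural cubic
spline onto the 0.5 s grid of the minute (exactly 120 samples), holding edge
values constant outside the observed beats; a linear mode exists for
sensitivity checks. A natural spline reproduces affine tachograms exactly and
avoids the end-interval overshoot of the default spline boundary conditions.

**What the entropy stage consumes.** The framework resamples before both the
spectral and the nonlinear analyses, so by default both entropies are
computed on the 120-sample resampled series; `entropy_on = "raw"` switches
the entropy stage to the raw per-minute intervals, since the short-segment
motivation (60–100 intervals per annotated minute) can also be read that
way. Results are reported per mode; the package default is the resampled
mode.

## Spectral indices

`burg_psd()` fits an AR(6) model by the Burg recursion (mean removed) and
evaluates the one-sided AR spectrum on a 1024-point grid over [0, 1] Hz (the
Nyquist band of the 2 Hz tachogram). Order 6 is the conventional choice for
segments this short, where a periodogram is unstable. LF is the trapezoidal
band integral over 0.04–0.15 Hz, HF over 0.15–0.4 Hz; band edges are
interpolated linearly. Absolute PSD normalization is conventional (RR in
seconds gives band powers in s²); it cancels in LF/HF, which is the index the
screening layer uses.

## Synthetic cohort generator

`generate_cohort()` emulates the study cohort — 20 normal, 14 mild-moderate,
26 severe recordings of 6 h each, mean RR 1.0 s — with a sum-of-sinusoids
RR model: a respiratory oscillation at 0.25 Hz, an LF component at 0.095 Hz,
white beat-to-beat noise, and (in the OSA groups) a slow apnea cycle (50 s /
45 s period) switched on per cycle block with the group's prevalence.
Severity lowers the respiratory amplitude and noise (raising regularity) and
raises the LF and cycle amplitudes — reproducing the directional contrast of
interest: entropy falls and LF/HF rises with severity. AHI labels are drawn
uniformly within each group's clinical band (<5, 5–30, ≥30 events/h).

Intervals are synthesized on a provisional uniform beat grid (spacing equal
to the mean RR) and cumulated into beat times; the phase error this
introduces is far below the modulation depths involved. Per-recording
individual differences are two independent lognormal jitters (SD 0.15 on the
log scale) on the structured amplitudes and on the noise SD — independent
because both entropies are affine invariant, so only the noise-to-structure
*ratio* distinguishes recordings. Effect sizes were calibrated once so that
the group contrast is unambiguous at cohort scale (ordering and screening
tests pass with margin across seeds) and then frozen; they are deliberately
cleaner than real apnea-ecg data. The generator is a test fixture, not a
physiological model: it has no respiration signal, no ectopy, no
arrhythmias, no sleep staging, and its apnea cycles are phase-coherent
sinusoids rather than event-locked decelerations. Passing tests therefore
demonstrate that the estimators and the screening layer recover a known
regularity contrast through the full pipeline — not that the published
real-data accuracies are reproduced; those require the original PhysioNet
recordings, which the optional WFDB loader can feed through the same
pipeline.

`synth_ecg()` places a fixed QRS-like template at known beat times with
baseline wander and white noise, retaining ground truth so the detector is
scored exactly (≥99% beat recovery at mild noise; RR within one sample
period).

## Screening and statistics layer

Recordings are aggregated as the arithmetic mean of each index over valid
minutes. The statistics follow the validation protocol of the study design:
one-way ANOVA with Fisher's LSD post-hoc (pairwise t on the pooled
within-group MSE with `N - k` df, unadjusted — the least conservative
post-hoc, so its p-values never exceed Bonferroni-adjusted ones), Pearson
correlation of each index with AHI, ROC/AUC in the Mann–Whitney formulation
(ties count one half), and two classifiers: Fisher's linear discriminant
(equal priors, pooled covariance — the decision cut sits at the midpoint of
the projected class means) and a nu-SVM with stratified 2-fold
cross-validation. Fisher is the default for single-index screening, trained
and evaluated on all recordings as in a descriptive discriminant analysis;
the report records which classifier produced the counts. ROC scores are
oriented by the training group means so that the apneic class scores higher
(entropy indices are flipped).

## Problem sizes and runtime

The shipped tests and the acceptance script use the full study-scale
conditions: MIX sweeps over lengths 50–200 (20 replicates per cell),
tolerance sweeps at N = 100, and the complete 60-recording, 6-hour cohort
(21,600 one-minute segments through entropy and spectral stages). The whole
suite runs in a few minutes on one core; per-segment work is O(N²) on 120
samples, dominated by the distance matrices, which are computed once per
segment and shared by both entropies.

## Known limitations

* NPSampEn's scope can contain tens of thousands of bins for a 120-sample
  segment; the implementation pools counts via sorted distances rather than
  materializing per-row CDF matrices, but cost remains O(N² log N) per
  segment.
* The Burg spectrum's absolute scale is conventional; only ratios (LF/HF)
  should be compared across implementations.
* The Pan-Tompkins detector is tuned for clean single-lead recordings with
  dominant positive R waves; inverted or very noisy leads need
  record-specific handling upstream.
* The WFDB reader covers formats 16 and 212 with single-file records only.
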