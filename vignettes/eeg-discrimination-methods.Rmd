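---
title: "Methods: an EEG discriminant framework for progression from aMCI to AD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an EEG discriminant framework for progression from aMCI to AD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegmci)
```

## The problem

Amnestic mild cognitive impairment (aMCI) is the memory-dominant prodrome of
Alzheimer's disease (AD). Over an 18-month horizon some patients progress to
AD (PMCI) while others remain stable (SMCI); separating the two groups from
resting-state EEG at the time of the initial diagnosis is the goal of this
package. Three EEG signatures of progression motivate the feature sets:

* **spectral slowing** — a shift of relative power from fast (alpha/beta)
  to slow (delta/theta) bands;
* **loss of complexity** — lower entropy and a smaller phase-space orbit of
  the signal;
* **disconnection** — weaker inter-channel phase coupling.

The pipeline is: preprocessing → feature extraction (spectral, nonlinear,
connectivity) → leakage-safe subject-level 10-fold cross-validated
classification, exercised end-to-end on a synthetic two-group cohort so that
every stage is testable without clinical data.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` produce 16-channel (10–20 montage)
recordings of 20 s at 500 Hz, 65 SMCI and 42 PMCI subjects by default. Each
channel is a sum of three parts:

1. **Band-limited oscillations.** For each band (delta 0.5–4, theta 4–8,
   alpha 8–13, beta 13–30, gamma 30–45 Hz), white noise is band-passed to
   the central part of the band and weighted by the group's relative band
   power (`band_power_profile`, sums to 1). The PMCI profile moves weight
   from alpha/beta to delta/theta, producing the slowing contrast.
2. **A shared narrowband alpha source** (8.5–12.5 Hz), received by every
   channel at a fixed per-channel phase offset and scaled by the group's
   `connectivity_strength`. The phase offsets are montage geometry — golden-
   angle spaced, identical across subjects — so pairwise phase differences
   stay away from 0 and π (where the phase lag index is blind) and
   connectivity features do not act as per-subject fingerprints.
3. **Broadband noise** restricted to 0.5–45 Hz, scaled by
   `complexity_noise`. The noise weight also widens the oscillators' bands
   (bandwidth factor `0.45 + 0.55 * complexity_noise`), so a low-complexity
   group has both less broadband power and more ordered, narrower spectral
   peaks. This one knob therefore drives the entropies, the in-band spectral
   entropy, and — because the noise adds total power and hence orbit size —
   the median phase-space centroid distance, all in the reported direction.

Amplitudes are in µV with a fixed, slightly posterior-dominant per-channel
gain. Absolute scale cancels in every ratio, entropy and connectivity
feature; only the phase-space statistic is amplitude-dependent, which is
deliberate (it is an orbit-size measure). `effect_scale` interpolates the
PMCI knobs between the SMCI values (0 = null cohort, used for calibration
tests) and the full contrast (1). Subject seeds are derived from the master
seed and the subject index, so cohorts regenerate bit-identically.

Default knob values (SMCI vs PMCI: connectivity 0.6 vs 0.25, noise 0.8 vs
0.25, band profiles as in `cohort_config()`) were chosen once to give a
clearly separable regime — clinical effect sizes for these contrasts are not
published, so the generator emulates directions, not magnitudes.
What the generator does **not** emulate: artifacts (blinks, EMG, line
transients), non-stationarity across the recording, volume-conduction
mixing of nearby channels, and individual alpha-frequency variability.
Passing tests therefore demonstrate the correctness and leakage-safety of
the machinery, not clinical-grade accuracy.

## Preprocessing

`preprocess()` applies, in order: average re-reference, zero-phase FIR
band-pass 0.1–70 Hz, zero-phase 50 Hz notch (2 Hz stop band), down-sampling
to 250 Hz. The notch follows the band-pass purely by narrative convention;
both are linear and zero-phase, so the order does not affect the output.

The filters are realised in the frequency domain: a real, even transfer
function with raised-cosine transition bands (low edge
`max(0.25·f, 0.05)` Hz, high edge 25% of the cutoff), applied to the
reflection-padded FFT of the signal. A time-domain windowed-sinc kernel for
a 0.1 Hz edge would need tens of thousands of taps — longer than a 20-s
record — whereas the frequency-domain form realises the same zero-phase
response at the spectral resolution the segment supports. Because the high
cutoff (70 Hz) is below the target Nyquist (125 Hz), the band-pass doubles
as the anti-aliasing filter and 500→250 Hz resampling is exact factor-2
decimation; non-integer rate ratios are rejected.

`segment_epochs()` cuts non-overlapping 2-s epochs (10 per 20-s segment,
1070 rows for the default 107-subject cohort), dropping any trailing
remainder. An optional amplitude threshold (`reject_threshold`, µV) drops
contaminated epochs — an automated stand-in for manual epoch screening, as
is `select_segment()`, which picks the contiguous 20-s window minimising
peak amplitude from longer recordings. ICA-based artifact removal is out of
scope (operator-dependent); synthetic data are generated artifact-light.

## Feature extraction

All features are computed per 2-s epoch (epoch mode) or once per 20-s
recording (subject mode; Welch windows 2 s instead of 1 s).

**Spectral (200 per epoch).** Welch PSD (Hamming windows, 50% overlap).
Five band-power ratios per channel (delta/alpha, theta/alpha,
delta/(alpha+beta), theta/(alpha+beta), (delta+theta)/(alpha+beta+gamma));
spectral entropy of the normalised in-band PSD per band and channel
(natural log, bounded by ln N bins); log10 left/right band-power asymmetry
for the eight homologous pairs. Bands are half-open `[low, high)` so shared
edges are counted once. Zero-power degenerate cases yield `NA` rather than
±Inf, and flow through selection as missing values.

**Nonlinear (528 per epoch).** Multiscale (1–10, non-overlapping block
means) permutation entropy (m = 3, delay 1, ties by order of occurrence),
approximate entropy (m = 2, r = 0.2·SD, self-matches included) and sample
entropy (self-matches excluded; zero matches at length m+1 give `NA`); for
the multiscale entropies the tolerance r is fixed from the scale-1 SD so
scales are comparable. Lempel–Ziv complexity binarizes at the signal mean
and reports the normalised LZ76 phrase count `c(n)·log2(n)/n`. The Hurst
exponent uses classical rescaled-range analysis over dyadic block sizes.
The phase-space statistic embeds the signal in three dimensions with the
lag at the first nonpositive autocorrelation crossing (1/e fallback, capped
so the embedding exists) and returns the median Euclidean distance of the
embedded points from their centroid. At scale 10 a 500-sample epoch leaves
50 samples — marginal for sample entropy, so per-scale failures are
recorded as `NA` without affecting other scales. The O(n²) entropy kernels
are compiled (Rcpp); independent brute-force R implementations live in the
test suite and must agree to 1e-10.

**Connectivity (2160 per epoch).** For each of six bands (the five analysis
bands plus "full" = 0.5–45 Hz, a definition this package fixes since no
numeric range is conventional): Pearson correlation on the band-filtered
signals, phase lag index (analytic-signal phases, 5% edge trim,
`|mean sign sin Δφ|`), and magnitude-squared coherence (Welch cross-spectra
averaged over in-band bins; at least two segments, since one segment makes
the estimator identically 1). Each symmetric 16×16 matrix is vectorized to
its 120-pair strict upper triangle in row-major channel order.

## Discrimination

Rows (epochs or subjects) are classified as SMCI/PMCI with PMCI positive.
The cross-validation is subject-level: folds partition *subjects*,
stratified by group, so epochs of one subject can never span training and
test — `audit_leakage()` verifies this mechanically. Within each training
fold only:

1. **Selection:** Welch t-test and Wilcoxon rank-sum test per feature;
   retained iff either p < 0.05 (the union rule is the more inclusive
   reading of using both tests; PCA absorbs the redundancy, and a
   both-tests rule is available). Constants are dropped; the Wilcoxon
   p-values use the tie-corrected normal approximation, which matches
   `wilcox.test(exact = FALSE)` to 1e-10.
2. **Imputation and standardization:** training-fold medians and z-scores.
3. **PCA** via SVD of the standardized training block, truncated at the
   smallest component count reaching 95% cumulative variance; component
   signs fixed by making the largest-magnitude loading positive.

Test rows are pushed through the stored parameters only. Eight classifiers
run with library defaults: SVM (radial, decision values as scores), CART
decision tree, naive Bayes, LDA, AdaBoost.M1 (50 depth-1 stumps — written
in-package, scores through a logistic link), 1-nearest-neighbour, random
forest, and logistic regression. Metrics per fold — ACC, SEN, SPE, PPV, F1
from the confusion counts, AUC by the rank (Mann–Whitney) formula with
average ranks for ties — are summarised as mean ± SD across folds, not
pooled. Degenerate ratios (zero denominators) are reported missing rather
than 0.

Subject-based mode extracts one feature vector from the whole 20-s signal
and reuses the same machinery on 107 rows; it is the described procedure,
not majority voting of epoch predictions.

`cohort_statistics()` reproduces demographic-table statistics from printed
summaries: pooled-variance two-sample t for continuous variables and
Pearson chi-square without continuity correction for counts — the pooled /
uncorrected forms are the ones that reproduce the published values.
`group_difference_map()` gives per-channel (or per-pair) Wilcoxon p-value
maps per feature family, with an optional top-n listing for connectivity.

## Numerical and design notes

* Null retention of the either-test selection rule is ~0.06 at α = 0.05,
  between α (perfectly correlated tests) and the union bound 2α − α²
  (independent tests) — the t and Wilcoxon p-values are strongly
  correlated, so the union bound is loose.
* LZ76 parses a constant binary string into two phrases (first symbol +
  copyable remainder), so the raw complexity of a constant signal is 2 by
  the same convention that parses `0101010101` into `0 | 1 | 01010101`.
* Cross-validated AUC on null cohorts is chance-level but noisy: fold AUCs
  share training data and are correlated, so the mean over 10 folds has an
  sd of several points even with 40 subjects. The calibration band
  [0.35, 0.65] reflects that.
* Problem sizes: the end-to-end calibration and effect-recovery runs in
  the tests and the acceptance script use 24 SMCI / 16 PMCI subjects —
  the same ~65:42 class ratio, and at least 10 subjects per class so
  10-fold subject-level CV is defined. The epoch-accounting check runs the
  full 107-subject default cohort.
* EDF I/O is a minimal 16-bit implementation (1-s records, per-channel
  physical calibration from the sample range); round-trip error is bounded
  by one quantization step.

## Known limitations

The generator's group contrasts are directional emulations, not fits to
clinical data; classifier performance on it says nothing quantitative about
clinical cohorts. Bad-channel interpolation, ICA cleaning and human epoch
screening are not modelled. The Hurst estimator is the classical R/S form
(no detrending); graph-theoretic connectivity summaries and weighted-PLI
variants are out of scope.
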