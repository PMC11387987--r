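---
title: "Short-term spectral features for MFC stride series: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term spectral features for MFC stride series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcspectra)
```

## The signal and its sampling

A minimum foot clearance (MFC) series assigns one scalar clearance height to
each stride of a treadmill walk, so it is uniformly sampled at one sample per
stride; frequency is measured in cycles/stride with Nyquist 0.5. A typical
baseline recording covers about 200 strides. Series are normalized per
subject before analysis — by default minmax to [0, 1] — to remove
between-subject clearance-height differences. Per-subject minmax (rather than
a cohort-wide map) is used because the normalization exists precisely to
cancel between-subject level differences; published normalized group means
(0.52–0.71) and SDs (0.09–0.14) are consistent with [0, 1]-ranged series.

## The short-term magnitude spectrum

MFC series are non-stationary: the oscillatory structure of stride-to-stride
fluctuation drifts over a session. The pipeline therefore analyses the series
in frames. The series is divided into `n_segments = 8` frames at 50% overlap;
the frame length is derived from the series length so the frames tile it,
`seg = floor(N / (1 + (n_segments − 1)(1 − overlap)))`, hop
`floor(seg(1 − overlap))` (44 and 22 strides for N = 200, last frame ending
at stride 198). Each frame is multiplied by a **symmetric** Hamming window —
the usual choice for spectral estimation of short segments, as opposed to the
periodic form used for spectral synthesis — zero-padded to `nfft = 256`
points and Fourier-transformed; the one-sided magnitudes (129 bins) are
averaged over the 8 frames.

Numerical conventions that matter:

* **No magnitude scaling.** Magnitudes are raw `|FFT|` values, with no `1/M`
  or window-energy compensation. The DC bin of a frame is then exactly the
  absolute windowed sum `|Σ w(n) x(n)|` (a window-weighted local mean scaled
  by `Σw ≈ 23.30` for 44-sample Hamming frames), which makes the calibrated
  group DC values (≈ 16.6 vs ≈ 11.5–12.0) directly interpretable as
  `Σw ×` group mean level.
* **No detrending.** The series mean is deliberately retained; the DC feature
  is part of the method.
* **Zero-padding, never truncation.** `nfft` must be at least the frame
  length. One consequence worth stating plainly: with 44-sample frames padded
  to 256 points, bins 1–2 lie deep inside the window transform's mainlobe
  (half-width 2/44 of the sampling rate against bin spacing 1/256), so the
  leading bins are strongly mutually correlated — for a constant series
  `S(1) ≈ 0.97 · S(0)`, not 0. The three leading features largely measure
  one thing (the windowed local mean and its stability) sampled three times.
* **Frequency axis.** Bin `k` is reported at `k/nfft` cycles/stride. Reported
  axis conventions for this kind of analysis are not always consistent;
  feature values depend only on bin indexing, not on the axis labeling.

Class separability per bin is summarized by the F-ratio of the per-subject
mean-spectrum magnitudes: an unweighted sum over classes of squared
class-mean deviations from the (unweighted) mean of class means, divided by
the sum over classes of the within-class mean squared deviation. The grand
mean is taken over class means, not pooled subjects; for balanced designs the
two coincide. It is computed on per-subject mean spectra (one sample per
subject), not per-frame spectra. Bins with zero within-class scatter get a
flagged undefined ratio rather than an infinity or a silent 0, keeping
downstream rankings explicit.

## Comparison feature families

* **Descriptive:** mean, median, sample SD, Q1, Q3, IQR
  (linear-interpolation quantiles).
* **Histogram + Poincaré (24 features):** the descriptive set plus g1
  skewness, g2 excess kurtosis, the midpoint of the fullest of 16 equal-width
  histogram bins (mode), min, max, quartile coefficient of dispersion; and,
  for lags 1–3 of the stride-to-stride scatter plot, SD1 (dispersion
  perpendicular to the identity line, short-term variability), SD2 (along
  it, long-term variability), SD1/SD2 and the ellipse area π·SD1·SD2. The
  original 24-feature set is not fully enumerated in the source literature;
  extending the Poincaré block across lags 1–3 is this package's documented
  reconstruction. Note the exact lag-1 identity is
  `SD1² + SD2² = Var(x[2:n]) + Var(x[1:(n−1)])`; the textbook `2·Var(x)`
  holds asymptotically.
* **Tone–entropy:** the percentage index `PI[i] = 100(x[i+1] − x[i])/x[i]`
  requires strictly positive values, so it is computed on the max-normalized
  series by default (minmax produces an exact zero). Tone is the PI mean;
  entropy is base-2 Shannon entropy over a 50-bin equal-width histogram of
  the PI values (empty bins skipped, degenerate series have entropy 0). The
  cited construction does not state the log base or binning; base 2 with 50
  bins is plausible against published entropy values (~2.6–2.7) but exact
  reproduction is impossible without the original data.
* **Wavelet multiscale (6 features):** Daubechies 12-tap (6 vanishing
  moments) decomposition with symmetric extension, up to 8 levels capped at
  `floor(log2 n)` (7 levels for n = 200, with a warning). Features are the
  log2 detail variances `v1..v5` and the least-squares slope of `v_l` vs
  level over all available levels — a multiscale exponent that is 0 for
  white variability. Which six features the cited work used is not stated;
  this composition is an explicit stand-in that captures the variance-across-
  scales idea.

## Screening, classifiers and cross-validation

Features are screened per column with the two-sided Mann-Whitney U test
(exact distribution when the combined sample is ≤ 20 without ties,
tie-corrected normal approximation otherwise) and the rank AUC (ties ½),
reported orientation-free as `max(auc, 1 − auc)` with the flip recorded.

The classifier layer is deliberately a set of contracts over standard
implementations (e1071 SVM, randomForest, rpart-based bagging and AdaBoost
stumps, nnet). Three protocol choices are worth justifying:

* **Positive class = improved.** With 14/19 subjects improved, a collapsed
  classifier that predicts everything positive scores ACC 73.68, SENS 100,
  SPEC 0, F1 84.85 — the degenerate pattern that appears repeatedly in
  small-cohort benchmarks and is reproduced exactly by `confusion_metrics()`.
* **Within-split standardization.** Features span 0.1–17 across families, so
  each CV iteration z-scores with training-split statistics only; the
  held-out subject never influences the scaling.
* **Aggregation.** Leave-one-sample-out pools its n single-subject
  predictions into one confusion matrix (per-iteration metrics are degenerate
  for a one-subject test set; for accuracy, pooling equals averaging).
  The repeated 4-per-class protocol and stratified 5-fold average
  per-iteration metrics and never recompute from pooled counts. Report AUCs
  are rank AUCs of decision scores — pooled for LOSO, fold-averaged
  otherwise.
* **ANN caveat.** The network contract records a learning-rate
  hyperparameter, but `nnet` fits by quasi-Newton optimization, so that value
  has no effect on the fit; it is carried for provenance.

The noise sweep interprets "x% noise" as Gaussian noise with SD equal to x%
of the series' own SD, added to the normalized **series** (not the extracted
features) of the held-out subject only; training features stay clean. Level 0
is the identity, so the level-0 sweep equals the clean LOSO report exactly.

## The synthetic cohort generator

No patient data are deposited, so the generator is a first-class module that
encodes the reported structure of the two classes:

```
x[i] = mu_s + A[i] sin(2π f i + phi[i]) + e[i]
```

with subject level `mu_s ~ N(mean_mu, mean_sd)` truncated to (0, 1), stride
scale `sigma_s ~ N(sd_mu, sd_sd)` truncated positive, oscillation frequency
`f = 0.03` cycles/stride (inside the discriminative low-frequency zone), and
white noise `e`. The amplitude multiplier follows an AR(1) process
(coefficient 0.95) and the phase a random walk, both with innovation scale
`0.3 (1 − osc_stability)`: stability 0.9 (unimproved) keeps the oscillation
sustained across analysis windows, stability 0.2 (improved) makes it wander,
which is what drives the across-frame spectral variance apart. Amplitude and
noise are normalized so the oscillation carries a fixed fraction
(`osc_var_frac`, default 0.5 — an even split, chosen once) of the stride
variance and the realized series SD matches `sigma_s` in expectation. Values
are clipped to (0, 1) rather than re-normalized so the generator stays
independent of `normalize_series()`; clip counts are recorded.

Class levels and spreads are the published Table-of-group-statistics values
(improved 0.5164 ± 0.1282 level, 0.1351 ± 0.0319 stride SD; unimproved
0.7148 ± 0.0537 and 0.0933 ± 0.0186). With `Σw = 23.30` these place the
group DC means at ≈ 16.65 and ≈ 12.0, against published feature values
16.63 ± 1.25 and 11.50 ± 2.23.

**What the generator does and does not show.** It reproduces the group
moments, the effect direction (higher DC magnitude and lower across-frame
spectral variance for unimproved subjects in ≈ 99% of replicate cohorts) and
nominal null calibration of the screening test. It does **not** reproduce two
features of the real data:

1. *The real feature-table spread.* The published improved-class DC SD
   (2.23) is tighter than what the published level spread implies under pure
   DC scaling (0.1282 × 23.30 ≈ 2.99). A generator pinned to the level
   moments cannot match both; this package pins the levels. The consequence
   is slightly more class overlap than the real data had: the expected
   DC-feature AUC is ≈ 0.93 (vs ≈ 0.98 reported) and the expected
   leave-one-sample-out accuracy of a linear margin on the three spectral
   features is ≈ 85–88% (vs ≥ 90% on the real cohort). Recovery checks
   pinned at AUC > 0.9 and accuracy ≥ 90% sit at or above what these study
   conditions support and can fail at a fixed seed; the package reports them
   as computed rather than adjusting the generator toward them.
2. *Monotone decay of discriminability with frequency.* In the real data the
   leading three bins were the significant ones and significance dropped
   beyond the fourth. The generator's single class-different oscillation at
   0.03 cycles/stride makes bins near the oscillation (≈ bins 5–20) *more*
   discriminative than DC. Conclusions about bin *ranking* therefore do not
   transfer from synthetic to real data; conclusions about the pipeline's
   mechanics (framing, windowing, screening calibration, CV bookkeeping,
   noise protocol) do.

## Problem sizes used in the shipped checks

Synthetic recovery checks use 50 subjects per class at 200 strides;
null-calibration uses 200 replicate cohorts; effect-direction checks use 100
replicate 14/5 cohorts; oracle-equivalence checks run the naive O(N²) DFT on
series up to 64 samples and full permutation enumeration up to 6-vs-6. These
sizes make every Monte-Carlo band explicit and keep a full run in the tens of
seconds on one core.

## Known limitations

* Labels are taken as given; detecting MFC events from toe-marker
  trajectories, the training protocol itself, and the clinical improvement
  threshold are all out of scope.
* The generator encodes only the reported moments plus one oscillation; the
  true within/between-subject covariance structure of patient MFC is
  unknown.
* The exact wavelet feature set and the tone-entropy binning of the cited
  comparison work are reconstructions, adequate for benchmarking the
  families against each other but not for reproducing their historical
  numbers.
* Real-data benchmark tables cannot be reproduced without the undeposited
  cohort; the package reproduces their data-independent degenerate rows
  exactly and their structure (metrics, protocols, grids).
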