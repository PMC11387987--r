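# mfcspectra

Short-term spectral features for minimum foot clearance (MFC) stride series.

## The problem

Minimum foot clearance — the lowest height of the swing foot above the ground
at mid-swing — is the gait variable most directly tied to tripping risk, and
stroke survivors often walk with low, highly variable MFC. Biofeedback
treadmill training can raise MFC, but it takes ten or more sessions to find
out whether a given patient responds. `mfcspectra` implements a signal-
processing pipeline that predicts the training outcome from the **baseline**
stride series alone: each subject contributes one MFC value per stride
(about 200 strides), and the question is whether stride-to-stride fluctuation
patterns in that short series separate the patients who will improve from
those who will not.

The package is aimed at gait-analysis and rehabilitation researchers who have
per-stride clearance series with a binary outcome label, and at anyone who
needs a worked, fully testable example of small-cohort feature screening and
cross-validation design.

## The method

The core feature set is the frame-averaged short-term Fourier magnitude
spectrum of the per-subject normalized series `x[1..N]`:

1. divide the series into 8 segments with 50% overlap
   (`seg = floor(N / (1 + 7/2))`, 44 strides for `N = 200`);
2. multiply each segment by a symmetric Hamming window `w`;
3. zero-pad to 256 points and take the one-sided FFT magnitude
   `|X_m(k)|`, k = 0..128, in cycles/stride (`k/256`);
4. average over the `L = 8` frames:
   `S(k) = (1/L) * sum_m |X_m(k)|`.

`S(0)` is the DC value — the frame-averaged absolute windowed sum
`|sum_n w(n) x(n)|`, a localized, window-weighted mean of the clearance
series. The first three components `S(0), S(1), S(2)` form the classifier
feature vector. Per-frequency class separability is ranked with the F-ratio

```
F(k) = sum_i (S̄_i(k) − S̄(k))²  /  sum_i (1/C_i) sum_j (S_ij(k) − S̄_i(k))²
```

(between-class spread of class means over averaged within-class scatter),
features are screened with the Mann-Whitney U test and the rank AUC, and
classifiers (SVM, random forest, AdaBoost stumps, bagged trees, single-layer
ANN) are benchmarked under three small-sample cross-validation protocols:
leave-one-sample-out, repeated 4-per-class training folds, and stratified
5-fold. A noise sweep recomputes the held-out subject's features from a
noise-contaminated series (Gaussian, SD = 0/10/20/30% of the series SD)
while training stays clean.

Comparison feature families from the earlier MFC literature are included:
descriptive statistics, a 24-feature histogram + Poincaré set, tone-entropy
of the percentage-index (per-stride percent change) series, and Daubechies-6
wavelet multiscale log-variances.

Because the patient data behind the published study are not deposited, the
package ships a seeded synthetic cohort generator calibrated to the published
normalized group statistics (improved: mean 0.5164 ± 0.1282, stride SD
0.1351 ± 0.0319, wandering low-frequency oscillation; unimproved: mean
0.7148 ± 0.0537, stride SD 0.0933 ± 0.0186, sustained oscillation), so every
stage of the pipeline is testable end to end.

## Worked example

```r
library(mfcspectra)

cohort <- generate_cohort(cohort_config(n_improved = 14, n_unimproved = 5,
                                        n_strides = 200, seed = 7))
cohort
#> <mfc_cohort> 19 subjects (improved: 14, unimproved: 5)

ft <- extract_features(cohort, "spectral")
head(screen_features(ft), 3)
#>   feature U           p auc flipped
#> 1 spec_k0 7 0.007223942 0.9    TRUE
#> 2 spec_k1 7 0.007223942 0.9    TRUE
#> 3 spec_k2 7 0.007223942 0.9    TRUE

cv_leave_one_sample_out(ft, classifier_spec("svm", kernel = "linear", C = 1),
                        seed = 7)
#> <eval_report> loso, svm classifier, 19 iterations (seed 7)
#> <metric_set> ACC 78.95 SENS 85.71 SPEC 60.00 F1 85.71 AUC 0.886
```

The screening table says each of the three leading spectral magnitudes
separates the groups well on this 19-subject cohort (AUC 0.9, p < 0.01;
`flipped` records that improved subjects have the *lower* DC magnitude, i.e.
lower and less windowed-mean-stable clearance). The LOSO report pools the 19
held-out predictions: 15/19 correct, sensitivity (improved detection) 85.71%
and specificity 60% — small-cohort results swing noticeably with the seed.

The same steps are available from a shell:

```sh
Rscript inst/cli/mfc-spectra.R simulate --out cohort.csv --seed 7
Rscript inst/cli/mfc-spectra.R evaluate --in cohort.csv --features spectral \
    --cv loso --classifier svm --kernel linear --C 1 --seed 7 --out report.csv
```

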