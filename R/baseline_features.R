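#' Descriptive statistics of a normalized MFC series
#'
#' Mean, median, sample standard deviation (n-1 denominator), first and third
#' quartiles (linear-interpolation quantiles, R type 7) and the interquartile
#' range — the classical whole-series summary used as the simplest comparison
#' feature family.
#'
#' @param s a normalized [mfc_series()] with at least 4 strides.
#' @return named numeric vector `mean, median, sd, q1, q3, iqr`.
#' @export
descriptive_features <- function(s) {
  stopifnot(inherits(s, "mfc_series"))
  if (!s$normalized)
    stop_validation("descriptive features are defined on normalized series")
  if (s$n < 4) stop_validation("need at least 4 strides")
  x <- s$values
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(mean = mean(x), median = median(x), sd = sd(x),
    q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}

poincare_block <- function(x, lag) {
  a <- x[(1 + lag):length(x)]
  b <- x[1:(length(x) - lag)]
  sd1 <- sd(a - b) / sqrt(2)
  sd2 <- sd(a + b) / sqrt(2)
  ratio <- if (sd2 > 0) sd1 / sd2 else 0
  out <- c(sd1, sd2, ratio, pi * sd1 * sd2)
  names(out) <- paste0(c("sd1", "sd2", "sd1_sd2_ratio", "ellipse_area"),
                       "_lag", lag)
  out
}

#' Histogram and Poincare feature family (24 features)
#'
#' The descriptive set plus skewness (g1), excess kurtosis (g2), the mode
#' (midpoint of the fullest of 16 equal-width histogram bins, lowest bin on
#' ties), minimum, maximum and the quartile coefficient of dispersion
#' `(Q3 - Q1) / (Q3 + Q1)`; and, from the lag-`l` Poincare scatter of the
#' series against itself (l = 1, 2, 3), the minor-axis dispersion
#' `SD1 = SD(x[i+l] - x[i]) / sqrt(2)` (short-term variability), major-axis
#' dispersion `SD2 = SD(x[i+l] + x[i]) / sqrt(2)` (long-term variability),
#' their ratio and the fitted ellipse area `pi * SD1 * SD2`. 12 statistical
#' features + 3 lags x 4 Poincare features = 24.
#'
#' @param s an [mfc_series()] with at least 4 strides.
#' @return named numeric vector of length 24.
#' @export
histogram_poincare_features <- function(s) {
  stopifnot(inherits(s, "mfc_series"))
  if (s$n < 4) stop_validation("need at least 4 strides")
  x <- s$values
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] + q[2] == 0)
    stop_degenerate("quartile coefficient of dispersion undefined: Q1 + Q3 = 0")
  stat <- c(mean = mean(x), median = median(x), sd = sd(x),
            q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
            skewness = e1071::skewness(x, type = 1),
            kurtosis = e1071::kurtosis(x, type = 1),
            mode = histogram_mode(x, n_bins = 16),
            min = min(x), max = max(x),
            qcd = (q[2] - q[1]) / (q[2] + q[1]))
  c(stat, poincare_block(x, 1), poincare_block(x, 2), poincare_block(x, 3))
}

# Midpoint of the fullest of n_bins equal-width histogram bins spanning the
# data range; constant series return their value.
histogram_mode <- function(x, n_bins = 16) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  top <- which.max(counts)
  (breaks[top] + breaks[top + 1]) / 2
}

#' Percentage-index series of stride-to-stride change
#'
#' `PI[i] = 100 * (x[i+1] - x[i]) / x[i]`: the percent change of each MFC
#' value relative to the previous stride. All source values must be strictly
#' positive — use the raw series or a max-normalized one (a minmax-normalized
#' series contains an exact 0).
#'
#' @param s an [mfc_series()].
#' @return an object of class `pi_series`: list with `values` (length
#'   `n - 1`) and `source_id`.
#' @export
percentage_index <- function(s) {
  stopifnot(inherits(s, "mfc_series"))
  x <- s$values
  zero <- which(x == 0)
  if (length(zero))
    stop_validation(sprintf(
      "series '%s': zero clearance at stride %d; percentage index undefined",
      s$subject_id, zero[1]))
  if (min(x) < 0)
    stop_validation(sprintf(
      "series '%s': negative values; percentage index needs a positive series",
      s$subject_id))
  structure(list(values = 100 * diff(x) / x[-length(x)],
                 source_id = s$subject_id),
            class = "pi_series")
}

#' Tone and entropy of a percentage-index series
#'
#' Tone is the arithmetic mean of the percentage-index values: negative tone
#' means clearance tends to drop from stride to stride relative to its
#' current level. Entropy is the Shannon entropy (base 2) of the PI values
#' over `n_bins` equal-width histogram bins spanning the observed range;
#' empty bins are skipped. A degenerate PI series (all values equal) has
#' entropy 0 by convention.
#'
#' @param pi a [percentage_index()] result.
#' @param n_bins histogram bin count for the entropy estimate.
#' @return list with `tone` and `entropy`.
#' @export
tone_entropy <- function(pi, n_bins = 50) {
  stopifnot(inherits(pi, "pi_series"))
  v <- pi$values
  if (length(v) < 2) stop_validation("PI series must have length >= 2")
  tone <- mean(v)
  rng <- range(v)
  if (rng[1] == rng[2]) return(list(tone = tone, entropy = 0))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  p <- counts[counts > 0] / sum(counts)
  list(tone = tone, entropy = -sum(p * log2(p)))
}

# Daubechies-6 (12-tap, 6 vanishing moments) analysis filter pair, standard
# published values: lowpass sums to sqrt(2) with unit energy; highpass is its
# quadrature mirror.
db6_dec_lo <- c(-0.00107730108530848, 0.00477725751094551,
                 0.000553842201161496, -0.0315820393174860,
                 0.0275228655303057, 0.0975016055873230,
                -0.129766867567262, -0.226264693965440,
                 0.315250351709198, 0.751133908021095,
                 0.494623890398453, 0.111540743350109)
db6_dec_hi <- rev(db6_dec_lo) * rep(c(-1, 1), 6)

# One analysis step of the discrete wavelet transform with symmetric
# (reflected, edge-repeated) signal extension and dyadic downsampling.
dwt_step <- function(x, lo = db6_dec_lo, hi = db6_dec_hi) {
  len <- length(lo)
  n <- length(x)
  if (n < len)
    stop_degenerate(sprintf(
      "series of length %d is shorter than the wavelet filter (%d taps)",
      n, len))
  ext <- c(rev(x[seq_len(len - 1)]), x, rev(x)[seq_len(len - 1)])
  n_out <- floor((n + len - 1) / 2)
  idx <- outer(seq_len(len), 2 * (seq_len(n_out) - 1), "+")
  segs <- matrix(ext[idx], nrow = len)
  list(approx = as.numeric(crossprod(segs, lo)),
       detail = as.numeric(crossprod(segs, hi)))
}

#' Wavelet multiscale feature family
#'
#' Decomposes the series with the 12-tap Daubechies wavelet with 6 vanishing
#' moments, up to 8 levels (capped at `floor(log2(n))` with a warning when
#' fewer than 8 are available). Level `l` details capture fluctuation at
#' scales around `2^l` strides; the log2 variance of the detail coefficients,
#' `v_l`, summarizes the energy at that scale, and the least-squares slope of
#' `v_l` against `l` over all available levels is a multiscale exponent: 0
#' for white (scale-free, uncorrelated) variability, positive when long-range
#' structure dominates. The emitted features are `v1..v5` and the slope (6
#' features).
#'
#' @param s an [mfc_series()] with at least 32 strides.
#' @return named numeric vector
#'   `wv_v1, ..., wv_v5, wv_slope`.
#' @export
wavelet_multiscale_features <- function(s) {
  stopifnot(inherits(s, "mfc_series"))
  max_level <- min(8L, floor(log2(s$n)))
  if (s$n < 32 || max_level < 5)
    stop_validation("need at least 32 strides for 5 decomposition levels")
  if (max_level < 8)
    warning(sprintf("series of length %d supports only %d of 8 levels",
                    s$n, max_level), call. = FALSE)
  v <- numeric(max_level)
  a <- s$values
  for (l in seq_len(max_level)) {
    step <- dwt_step(a)
    v[l] <- log2(var(step$detail))
    a <- step$approx
  }
  lev <- seq_len(max_level)
  slope <- sum((lev - mean(lev)) * (v - mean(v))) / sum((lev - mean(lev))^2)
  stats::setNames(c(v[1:5], slope), c(paste0("wv_v", 1:5), "wv_slope"))
}

#' Extract a feature family for every subject in a cohort
#'
#' Dispatches to the per-series extractors and assembles a
#' [feature_table()]. Raw series are normalized on the fly: per-subject
#' minmax for the `spectral`, `descriptive`, `histogram_poincare` and
#' `wavelet` families, and max-normalization for `tone_entropy` (whose
#' percentage-index series needs strictly positive values).
#'
#' @param cohort an [mfc_cohort()].
#' @param family feature family.
#' @param cfg an [stft_config()] (spectral family only).
#' @param n_spectral number of leading spectral bins (spectral family only).
#' @return a [feature_table()].
#' @export
extract_features <- function(cohort,
                             family = c("spectral", "descriptive",
                                        "histogram_poincare", "tone_entropy",
                                        "wavelet"),
                             cfg = stft_config(), n_spectral = 3) {
  stopifnot(inherits(cohort, "mfc_cohort"))
  family <- match.arg(family)
  rows <- lapply(cohort$series, function(s) series_features(s, family, cfg,
                                                            n_spectral))
  m <- do.call(rbind, rows)
  feature_table(m, cohort_ids(cohort), cohort_labels(cohort))
}

series_features <- function(s, family, cfg = stft_config(), n_spectral = 3) {
  norm_for <- function(method) {
    if (s$normalized) s else normalize_series(s, method)
  }
  switch(family,
         spectral = spectral_features(norm_for("minmax"), cfg, n_spectral),
         descriptive = descriptive_features(norm_for("minmax")),
         histogram_poincare = histogram_poincare_features(norm_for("minmax")),
         tone_entropy = {
           te <- tone_entropy(percentage_index(norm_for("max")))
           c(tone = te$tone, entropy = te$entropy)
         },
         wavelet = wavelet_multiscale_features(norm_for("minmax")))
}
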