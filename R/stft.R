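#' Short-term Fourier transform configuration
#'
#' The defaults mirror the analysis protocol for ~200-stride MFC series:
#' eight segments with 50% overlap, a symmetric Hamming window, and a
#' 256-point FFT giving `nfft/2 + 1 = 129` one-sided frequency bins (the 0th
#' bin is the DC component). The segment length is derived from the series
#' length at transform time (see [frame_series()]); `nfft` must be at least
#' the segment length, so frames are zero-padded, never truncated.
#'
#' @param n_segments number of frames the series is divided into.
#' @param overlap fractional overlap between consecutive frames, in \[0, 1).
#' @param window analysis window.
#' @param nfft FFT length (even).
#' @return an object of class `stft_config`.
#' @export
stft_config <- function(n_segments = 8, overlap = 0.5,
                        window = c("hamming", "hann", "rectangular"),
                        nfft = 256) {
  window <- match.arg(window)
  if (!is.numeric(n_segments) || n_segments < 1 || n_segments != round(n_segments))
    stop_config("n_segments must be a positive integer")
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1)
    stop_config("overlap must lie in [0, 1)")
  if (!is.numeric(nfft) || nfft < 2 || nfft %% 2 != 0)
    stop_config("nfft must be a positive even integer")
  structure(list(n_segments = as.integer(n_segments), overlap = overlap,
                 window = window, nfft = as.integer(nfft)),
            class = "stft_config")
}

#' @export
print.stft_config <- function(x, ...) {
  cat(sprintf("<stft_config> %d segments, %.0f%% overlap, %s window, nfft=%d\n",
              x$n_segments, 100 * x$overlap, x$window, x$nfft))
  invisible(x)
}

# Symmetric (periodogram-style) window coefficients of length m.
window_coefficients <- function(window, m) {
  if (m == 1) return(1)
  switch(window,
         hamming = as.numeric(signal::hamming(m)),
         hann = as.numeric(signal::hanning(m)),
         rectangular = rep(1, m))
}

#' Divide a series into overlapping frames
#'
#' The segment length is chosen so that `n_segments` frames at the requested
#' overlap tile (almost) the whole series:
#' `seg = floor(N / (1 + (n_segments - 1) * (1 - overlap)))` with hop
#' `floor(seg * (1 - overlap))`. For the defaults (8 segments, 50% overlap)
#' a 200-stride series gives seg 44, hop 22, frame starts 0, 22, ..., 154.
#' Trailing samples beyond the last frame are discarded.
#'
#' @param x numeric series.
#' @param cfg an [stft_config()].
#' @return list with `frames` (seg x n_segments matrix, one frame per
#'   column), `frame_starts` (0-based), `seg_length`, `hop`.
#' @export
frame_series <- function(x, cfg = stft_config()) {
  stopifnot(inherits(cfg, "stft_config"))
  n <- length(x)
  if (n < cfg$n_segments + 2)
    stop_degenerate(sprintf(
      "series of length %d is too short for %d segments", n, cfg$n_segments))
  seg <- floor(n / (1 + (cfg$n_segments - 1) * (1 - cfg$overlap)))
  hop <- max(1L, floor(seg * (1 - cfg$overlap)))
  if (seg < 2)
    stop_degenerate(sprintf(
      "series of length %d is too short for %d segments", n, cfg$n_segments))
  starts <- (seq_len(cfg$n_segments) - 1L) * hop
  if (max(starts) + seg > n)
    stop_degenerate(sprintf(
      "cannot place %d frames of length %d (hop %d) in %d samples",
      cfg$n_segments, seg, hop, n))
  frames <- vapply(starts, function(s0) x[(s0 + 1):(s0 + seg)],
                   numeric(seg))
  frames <- matrix(frames, nrow = seg)
  list(frames = frames, frame_starts = as.integer(starts),
       seg_length = as.integer(seg), hop = as.integer(hop))
}

#' Short-term magnitude spectrum of a series
#'
#' Each frame is multiplied elementwise by the symmetric analysis window,
#' zero-padded to `nfft` points, Fourier-transformed, and reduced to the
#' one-sided magnitude spectrum (bins `0..nfft/2`). Magnitudes are raw
#' absolute FFT coefficients: no scaling by frame length or window energy is
#' applied, so the DC bin of a frame equals `|sum(w * x)|`, the
#' window-weighted frame sum. The series' mean level is deliberately kept
#' (no detrending): the DC feature is part of the method.
#'
#' @param x numeric series (typically the values of a normalized
#'   [mfc_series()]).
#' @param cfg an [stft_config()].
#' @return an object of class `spectrogram`: list with `magnitudes`
#'   (n_frames x n_bins), `n_frames`, `n_bins`, `frame_starts`,
#'   `seg_length`, `window`, `config`.
#' @export
short_term_spectrum <- function(x, cfg = stft_config()) {
  fr <- frame_series(x, cfg)
  seg <- fr$seg_length
  if (cfg$nfft < seg)
    stop_config(sprintf(
      "nfft (%d) is smaller than the segment length (%d); truncation is not allowed",
      cfg$nfft, seg))
  w <- window_coefficients(cfg$window, seg)
  nbin <- cfg$nfft / 2 + 1
  pad <- rep(0, cfg$nfft - seg)
  mags <- t(apply(fr$frames, 2, function(frame) {
    Mod(fft(c(frame * w, pad)))[seq_len(nbin)]
  }))
  structure(list(magnitudes = mags,
                 n_frames = ncol(fr$frames),
                 n_bins = as.integer(nbin),
                 frame_starts = fr$frame_starts,
                 seg_length = seg,
                 window = w,
                 config = cfg),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins (seg %d, %s window)\n",
              x$n_frames, x$n_bins, x$seg_length, x$config$window))
  invisible(x)
}

#' Frame-averaged magnitude spectrum
#'
#' The per-bin arithmetic mean of the short-term magnitudes over all frames.
#' With the default 256-point FFT this is the 129-component mean magnitude
#' spectrum; bin `k` sits at frequency `k/nfft` cycles/stride.
#'
#' @param sg a [short_term_spectrum()] result.
#' @return an object of class `mean_spectrum`: list with `magnitudes`,
#'   `bin_frequencies`, `n_frames`, `config`.
#' @export
mean_magnitude_spectrum <- function(sg) {
  stopifnot(inherits(sg, "spectrogram"))
  if (!sg$n_frames) stop_degenerate("empty spectrogram")
  structure(list(magnitudes = colMeans(sg$magnitudes),
                 bin_frequencies = (seq_len(sg$n_bins) - 1) / sg$config$nfft,
                 n_frames = sg$n_frames,
                 config = sg$config),
            class = "mean_spectrum")
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat(sprintf("<mean_spectrum> %d bins (0 to %.3f cycles/stride), %d frames\n",
              length(x$magnitudes), max(x$bin_frequencies), x$n_frames))
  invisible(x)
}

#' @export
as.data.frame.mean_spectrum <- function(x, ...) {
  data.frame(bin = seq_along(x$magnitudes) - 1L,
             frequency_cycles_per_stride = x$bin_frequencies,
             magnitude = x$magnitudes)
}

#' Low-frequency spectral features of one subject
#'
#' The feature vector is the first `n_features` entries of the frame-averaged
#' magnitude spectrum, named `spec_k0`, `spec_k1`, ... . `spec_k0` is the DC
#' value: the frame-averaged absolute windowed sum, a localized
#' window-weighted mean of the clearance series. The series must be
#' normalized first.
#'
#' @param s a normalized [mfc_series()].
#' @param cfg an [stft_config()].
#' @param n_features number of leading spectral bins to keep (default 3).
#' @return named numeric vector of length `n_features`.
#' @export
spectral_features <- function(s, cfg = stft_config(), n_features = 3) {
  stopifnot(inherits(s, "mfc_series"))
  if (!s$normalized)
    stop_validation("spectral features are defined on normalized series")
  nbin <- cfg$nfft / 2 + 1
  if (n_features < 1 || n_features > nbin)
    stop_config(sprintf("n_features must lie in [1, %d]", nbin))
  ms <- mean_magnitude_spectrum(short_term_spectrum(s$values, cfg))
  stats::setNames(ms$magnitudes[seq_len(n_features)],
                  paste0("spec_k", seq_len(n_features) - 1L))
}

#' Across-frame spectral variance in the low-frequency zone
#'
#' The per-bin variance of the short-term magnitudes across frames, averaged
#' over all bins at or below `freq_max` cycles/stride. Subjects whose
#' low-frequency oscillation is stable in amplitude and phase show low values
#' (the dominant components persist from window to window); subjects with
#' wandering low-frequency content show high values.
#'
#' @param s a normalized [mfc_series()].
#' @param cfg an [stft_config()].
#' @param freq_max upper edge of the low-frequency zone, cycles/stride.
#' @return a single non-negative number.
#' @export
spectral_frame_variance <- function(s, cfg = stft_config(), freq_max = 0.2) {
  stopifnot(inherits(s, "mfc_series"))
  if (!s$normalized)
    stop_validation("spectral frame variance is defined on normalized series")
  sg <- short_term_spectrum(s$values, cfg)
  freqs <- (seq_len(sg$n_bins) - 1) / cfg$nfft
  keep <- freqs <= freq_max
  mean(apply(sg$magnitudes[, keep, drop = FALSE], 2, var))
}

#' Per-bin magnitude feature table for a whole cohort
#'
#' One row per subject, one column per frequency bin of the frame-averaged
#' magnitude spectrum (`spec_k0` ... `spec_k{nfft/2}`). This is the sample
#' matrix on which per-bin class separability (see [f_ratio_profile()]) and
#' feature screening operate.
#'
#' @param cohort an [mfc_cohort()] of normalized series.
#' @param cfg an [stft_config()].
#' @param n_bins number of leading bins to keep (default: all).
#' @return a [feature_table()].
#' @export
bin_magnitude_table <- function(cohort, cfg = stft_config(), n_bins = NULL) {
  stopifnot(inherits(cohort, "mfc_cohort"))
  nbin <- cfg$nfft / 2 + 1
  if (is.null(n_bins)) n_bins <- nbin
  if (n_bins < 1 || n_bins > nbin)
    stop_config(sprintf("n_bins must lie in [1, %d]", nbin))
  m <- t(vapply(cohort$series,
                function(s) spectral_features(s, cfg, n_features = n_bins),
                numeric(n_bins)))
  feature_table(m, cohort_ids(cohort), cohort_labels(cohort))
}
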