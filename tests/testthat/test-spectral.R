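test_that("framing follows the tiling formula", {
  fs <- frame_series(runif(200), stft_config())
  expect_equal(fs$seg_length, 44)
  expect_equal(fs$hop, 22)
  expect_equal(fs$frame_starts, seq(0, 154, by = 22))
  expect_equal(ncol(fs$frames), 8)

  # a single segment covers the whole series
  one <- frame_series(runif(44), stft_config(n_segments = 1))
  expect_equal(one$seg_length, 44)
  expect_equal(ncol(one$frames), 1)

  expect_error(frame_series(runif(9), stft_config(n_segments = 8)),
               class = "mfc_degenerate_error")
})

test_that("a constant series transforms to the zero-padded window spectrum", {
  cfg <- stft_config()
  sg <- short_term_spectrum(rep(1, 200), cfg)
  wsum <- sum_hamming(44)
  expect_equal(unname(sg$magnitudes[, 1]), rep(wsum, 8), tolerance = 1e-12)
  # every frame is the window itself, so the whole spectrum is the window's
  window_spectrum <- naive_dft_magnitudes(as.numeric(signal::hamming(44)), 256)
  for (fr in 1:8)
    expect_equal(unname(sg$magnitudes[fr, ]), window_spectrum,
                 tolerance = 1e-9)
  expect_equal(short_term_spectrum(rep(0, 100), cfg)$magnitudes,
               matrix(0, 8, 129), ignore_attr = TRUE)
})

test_that("a pure cosine concentrates at its own frequency bin", {
  n <- 0:255
  x <- cos(2 * pi * 8 * n / 256)
  cfg <- stft_config(n_segments = 1, window = "rectangular", nfft = 256)
  ms <- mean_magnitude_spectrum(short_term_spectrum(x, cfg))
  expect_equal(which.max(ms$magnitudes[-1]), 8)  # bins 1..128
  expect_equal(ms$magnitudes[9], 128, tolerance = 1e-9)
})

test_that("STFT magnitudes match a naive DFT and are one-sided symmetric", {
  for (case in list(list(n = 17, win = "rectangular", nfft = 32),
                    list(n = 40, win = "hamming", nfft = 64),
                    list(n = 64, win = "hann", nfft = 64),
                    list(n = 33, win = "hamming", nfft = 48))) {
    x <- with_test_seed(case$n, rnorm(case$n))
    cfg <- stft_config(n_segments = 1, window = case$win, nfft = case$nfft)
    sg <- short_term_spectrum(x, cfg)
    seg <- sg$seg_length
    windowed <- x[seq_len(seg)] * sg$window
    oracle <- naive_dft_magnitudes(windowed, case$nfft)
    expect_equal(unname(sg$magnitudes[1, ]), oracle, tolerance = 1e-9)
    # full-spectrum symmetry for real input: bin nfft-k mirrors bin k
    full <- Mod(fft(c(windowed, rep(0, case$nfft - seg))))
    ks <- seq_len(case$nfft / 2 - 1)
    expect_equal(full[case$nfft - ks + 1], full[ks + 1], tolerance = 1e-9)
  }
})

test_that("the DC identity holds per frame on random series", {
  cfg <- stft_config()
  for (seed in 1:25) {
    x <- with_test_seed(seed, runif(with_test_seed(seed + 1000,
                                                   sample(150:260, 1))))
    sg <- short_term_spectrum(x, cfg)
    fr <- frame_series(x, cfg)
    dc_oracle <- abs(colSums(fr$frames * sg$window))
    expect_equal(unname(sg$magnitudes[, 1]), dc_oracle,
                 tolerance = 1e-9)
  }
})

test_that("the mean spectrum is the per-bin frame average with 129 bins", {
  x <- with_test_seed(3, runif(200))
  sg <- short_term_spectrum(x, stft_config())
  ms <- mean_magnitude_spectrum(sg)
  expect_length(ms$magnitudes, 129)
  expect_equal(ms$magnitudes, colMeans(sg$magnitudes))
  expect_equal(ms$bin_frequencies, (0:128) / 256)

  # single frame: mean spectrum is that frame
  one <- short_term_spectrum(x[1:44], stft_config(n_segments = 1))
  expect_equal(mean_magnitude_spectrum(one)$magnitudes,
               unname(one$magnitudes[1, ]))

  # linearity: frames v and 3v average to 2v
  fake <- one
  fake$magnitudes <- rbind(one$magnitudes[1, ], 3 * one$magnitudes[1, ])
  fake$n_frames <- 2L
  expect_equal(mean_magnitude_spectrum(fake)$magnitudes,
               2 * unname(one$magnitudes[1, ]))
})

test_that("spectral features are the leading mean-spectrum bins and scale linearly", {
  s <- norm_series(rep(0.7, 200))
  f <- spectral_features(s)
  expect_named(f, c("spec_k0", "spec_k1", "spec_k2"))
  expect_equal(unname(f["spec_k0"]), 0.7 * sum_hamming(44), tolerance = 1e-9)
  # with zero-padding, bins 1-2 sample the window transform inside its
  # mainlobe: for a constant they equal 0.7 * |W(k/256)|, not zero
  window_spectrum <- naive_dft_magnitudes(as.numeric(signal::hamming(44)), 256)
  expect_equal(unname(f[2:3]), 0.7 * window_spectrum[2:3], tolerance = 1e-9)

  x <- with_test_seed(8, runif(200, 0.05, 0.45))
  f1 <- spectral_features(norm_series(x), n_features = 10)
  f2 <- spectral_features(norm_series(2 * x), n_features = 10)
  expect_equal(f2, 2 * f1, tolerance = 1e-9)

  expect_error(spectral_features(mfc_series(1:200 / 1)),
               class = "mfc_validation_error")
  expect_error(spectral_features(s, n_features = 200),
               class = "mfc_config_error")
})

test_that("the F-ratio reproduces the hand-computed two-class case", {
  m <- matrix(c(1, 3, 3, 5), ncol = 1, dimnames = list(NULL, "bin"))
  prof <- f_ratio_profile(m, c("improved", "improved",
                               "unimproved", "unimproved"))
  expect_equal(unname(prof$f_values), 1)
  expect_false(prof$undefined)
})

test_that("the F-ratio is zero for identical classes and invariant to shift/scale", {
  x <- with_test_seed(5, rnorm(12))
  m <- matrix(c(x, x), ncol = 2)
  colnames(m) <- c("b1", "b2")
  labs <- rep(c("improved", "unimproved"), each = 6)
  # both classes hold identical samples: numerator 0, denominator > 0
  m0 <- matrix(c(x[1:6], x[1:6]), ncol = 1, dimnames = list(NULL, "b"))
  prof0 <- f_ratio_profile(m0, rep(c("improved", "unimproved"), each = 6))
  expect_equal(unname(prof0$f_values), 0)

  prof <- f_ratio_profile(m, labs)
  shift <- f_ratio_profile(m + 7.5, labs)
  scaled <- f_ratio_profile(m * 3.2, labs)
  expect_equal(prof$f_values, shift$f_values, tolerance = 1e-9)
  expect_equal(prof$f_values, scaled$f_values, tolerance = 1e-9)
})

test_that("zero within-class variance is flagged undefined, not zero or infinite", {
  m <- matrix(c(1, 1, 2, 2), ncol = 1, dimnames = list(NULL, "b"))
  prof <- f_ratio_profile(m, rep(c("improved", "unimproved"), each = 2))
  expect_true(prof$undefined)
  expect_true(is.na(prof$f_values))
  expect_error(f_ratio_profile(m, c("improved", rep("unimproved", 3))),
               class = "mfc_validation_error")
})

test_that("class separation lifts the F-ratio profile above a null cohort's", {
  effect <- generate_cohort(cohort_config(50, 50, seed = 21))
  null_cfg <- cohort_config(
    50, 50, seed = 22,
    params = list(improved = default_class_params("improved"),
                  unimproved = default_class_params("improved")))
  null <- generate_cohort(null_cfg)
  f_eff <- f_ratio_profile(bin_magnitude_table(effect))$f_values
  f_null <- f_ratio_profile(bin_magnitude_table(null))$f_values
  expect_gt(median(f_eff, na.rm = TRUE), median(f_null, na.rm = TRUE))
})

test_that("unimproved-like cohorts hit the calibrated DC group mean", {
  cohort <- generate_cohort(cohort_config(2, 50, seed = 1))
  ft <- extract_features(cohort, "spectral")
  k0 <- ft$matrix[ft$labels == "unimproved", "spec_k0"]
  # group mean within 2 standard errors of the published 16.6300 +/- 1.2512
  expect_lt(abs(mean(k0) - 16.63), 2 * 1.2512 / sqrt(50))
})
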