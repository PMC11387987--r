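#' Add white Gaussian measurement noise to a normalized series
#'
#' The noise level is expressed relative to the series' own variability:
#' the added noise is i.i.d. Gaussian with standard deviation
#' `percent/100 * SD(x)`. A level of 0 returns the series unchanged. The
#' contaminated series keeps its `normalized` flag although individual values
#' may leave \[0, 1\] slightly — the contamination emulates measurement error
#' on already-normalized test data and is not re-normalized.
#'
#' @param s a normalized [mfc_series()].
#' @param percent noise level as a percentage of the series SD (>= 0).
#' @param seed optional seed for the noise draw; when `NULL` the current RNG
#'   stream is consumed.
#' @return an `mfc_series` with contaminated values.
#' @export
add_noise <- function(s, percent, seed = NULL) {
  stopifnot(inherits(s, "mfc_series"))
  if (!s$normalized)
    stop_validation("noise contamination is defined on normalized series")
  if (!is.numeric(percent) || length(percent) != 1 || percent < 0)
    stop_validation("percent must be a single non-negative number")
  if (percent == 0) return(s)
  draw <- function() rnorm(s$n, 0, percent / 100 * sd(s$values))
  eps <- if (is.null(seed)) draw() else with_seed(seed, draw())
  new_mfc_series(s$values + eps, s$subject_id, s$label, normalized = TRUE,
                 check_range = FALSE)
}

#' Noise-robustness sweep under leave-one-sample-out evaluation
#'
#' For each noise level, the leave-one-sample-out protocol is run with
#' training features computed from the clean series while the held-out
#' subject's features are recomputed from its noise-contaminated series —
#' training on clean data, testing on corrupted data. Level 0 reproduces the
#' clean LOSO report exactly.
#'
#' @param cohort an [mfc_cohort()] of normalized, labeled series.
#' @param family feature family passed to [extract_features()].
#' @param spec a [classifier_spec()].
#' @param levels noise levels in percent of the series SD.
#' @param cfg an [stft_config()].
#' @param n_spectral number of spectral features (spectral family).
#' @param seed top-level seed; noise draws and classifier seeds derive
#'   from it.
#' @return named list of [eval_report()]s, one per level, each carrying its
#'   level in `noise_percent`.
#' @export
noise_sweep <- function(cohort, family = "spectral",
                        spec = classifier_spec("svm"),
                        levels = c(0, 10, 20, 30),
                        cfg = stft_config(), n_spectral = 3, seed = 1) {
  stopifnot(inherits(cohort, "mfc_cohort"))
  if (any(levels < 0)) stop_validation("noise levels must be non-negative")
  cohort <- normalize_cohort(cohort)
  clean <- extract_features(cohort, family, cfg, n_spectral)
  seeds <- derive_seeds(seed, length(levels))
  reports <- lapply(seq_along(levels), function(li) {
    lev <- levels[li]
    t_test <- if (lev == 0) clean else {
      noise_seeds <- derive_seeds(seeds[li], length(cohort$series))
      noised <- mfc_cohort(lapply(seq_along(cohort$series), function(i) {
        add_noise(cohort$series[[i]], lev, noise_seeds[i])
      }))
      extract_features(noised, family, cfg, n_spectral)
    }
    res <- loso_engine(clean, t_test, spec, seed)
    eval_report("loso", spec, res$metrics,
                n_repeats = nrow(clean$matrix), seed = seed,
                details = res$predictions, feature_family = family,
                noise_percent = lev)
  })
  names(reports) <- paste0("noise_", levels)
  reports
}
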