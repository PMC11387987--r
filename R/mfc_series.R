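#' A single subject's minimum foot clearance stride series
#'
#' Minimum foot clearance (MFC) is the minimum vertical distance between the
#' swing foot and the walking surface at mid-swing; each stride contributes
#' exactly one MFC value, so the series is indexed in strides and treated as
#' uniformly sampled at one sample per stride (frequencies are in
#' cycles/stride, Nyquist 0.5).
#'
#' Raw clearance heights must be strictly positive. A normalized series
#' (see [normalize_series()]) is unitless and lies in \[0, 1\].
#'
#' @param values numeric vector of clearance heights, ordered by stride.
#' @param subject_id subject identifier.
#' @param label outcome label, one of `"improved"`, `"unimproved"`, or `NA`
#'   when unknown.
#' @param normalized logical; `TRUE` if `values` are already normalized.
#' @return an object of class `mfc_series` with fields `values`,
#'   `subject_id`, `n`, `label`, `normalized`.
#' @examples
#' s <- mfc_series(c(12.1, 14.3, 11.8, 13.0), subject_id = "s1",
#'                 label = "improved")
#' normalize_series(s)
#' @export
mfc_series <- function(values, subject_id = "subject", label = NA_character_,
                       normalized = FALSE) {
  s <- new_mfc_series(values, subject_id, label, normalized)
  validate_mfc_series(s)
  s
}

# Low-level constructor. `check_range = FALSE` is used internally for
# noise-contaminated normalized series, which may leave [0, 1] slightly.
new_mfc_series <- function(values, subject_id, label, normalized,
                           check_range = TRUE) {
  structure(
    list(values = as.numeric(values),
         subject_id = as.character(subject_id),
         n = length(values),
         label = as.character(label),
         normalized = isTRUE(normalized),
         check_range = isTRUE(check_range)),
    class = "mfc_series")
}

validate_mfc_series <- function(s) {
  if (s$n < 2)
    stop_validation(sprintf("series '%s': need at least 2 strides, got %d",
                            s$subject_id, s$n))
  if (!all(is.finite(s$values)))
    stop_validation(sprintf("series '%s': non-finite clearance values",
                            s$subject_id))
  if (!is.na(s$label) && !s$label %in% mfc_labels())
    stop_validation(sprintf("series '%s': label must be one of %s",
                            s$subject_id,
                            paste(mfc_labels(), collapse = ", ")))
  if (s$normalized) {
    if (s$check_range && (min(s$values) < 0 || max(s$values) > 1))
      stop_validation(sprintf(
        "series '%s': normalized values must lie in [0, 1]", s$subject_id))
  } else if (min(s$values) <= 0) {
    stop_validation(sprintf(
      "series '%s': raw clearance heights must be strictly positive",
      s$subject_id))
  }
  invisible(s)
}

#' @export
print.mfc_series <- function(x, ...) {
  cat(sprintf("<mfc_series> %s: %d strides, %s, label=%s\n",
              x$subject_id, x$n,
              if (x$normalized) "normalized" else "raw",
              if (is.na(x$label)) "unknown" else x$label))
  invisible(x)
}

#' Normalize an MFC series
#'
#' Per-subject normalization reduces the influence of between-subject
#' clearance-height differences before spectral analysis. `minmax` maps the
#' series affinely onto \[0, 1\]; `max` divides by the series maximum,
#' preserving zero and keeping all values strictly positive (useful upstream
#' of the percentage-index series, which divides by the previous stride);
#' `none` returns the series unchanged.
#'
#' @param s an [mfc_series()], not yet normalized.
#' @param method normalization method.
#' @return a normalized `mfc_series` (for `method = "none"`, `s` itself).
#' @export
normalize_series <- function(s, method = c("minmax", "max", "none")) {
  stopifnot(inherits(s, "mfc_series"))
  method <- match.arg(method)
  if (method == "none") return(s)
  if (s$normalized)
    stop_validation(sprintf("series '%s' is already normalized", s$subject_id))
  x <- s$values
  if (method == "minmax") {
    rng <- range(x)
    if (rng[1] == rng[2])
      stop_degenerate(sprintf(
        "series '%s': constant series cannot be minmax-normalized",
        s$subject_id))
    x <- (x - rng[1]) / (rng[2] - rng[1])
  } else {
    x <- x / max(x)
  }
  mfc_series(x, s$subject_id, s$label, normalized = TRUE)
}

#' A labeled cohort of MFC series
#'
#' @param series list of [mfc_series()] objects with unique subject ids.
#' @return an object of class `mfc_cohort` with fields `series` and
#'   `class_counts`.
#' @export
mfc_cohort <- function(series) {
  if (!length(series) || !all(vapply(series, inherits, TRUE, "mfc_series")))
    stop_validation("a cohort needs a non-empty list of mfc_series objects")
  ids <- vapply(series, `[[`, "", "subject_id")
  if (anyDuplicated(ids))
    stop_validation(sprintf("duplicate subject ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(series) <- ids
  labs <- vapply(series, `[[`, "", "label")
  counts <- table(factor(labs[!is.na(labs)], levels = mfc_labels()))
  structure(list(series = series,
                 class_counts = stats::setNames(as.integer(counts),
                                                names(counts))),
            class = "mfc_cohort")
}

#' @export
print.mfc_cohort <- function(x, ...) {
  cat(sprintf("<mfc_cohort> %d subjects (improved: %d, unimproved: %d)\n",
              length(x$series), x$class_counts[["improved"]],
              x$class_counts[["unimproved"]]))
  invisible(x)
}

#' @export
length.mfc_cohort <- function(x) length(x$series)

cohort_labels <- function(cohort) {
  vapply(cohort$series, `[[`, "", "label")
}

cohort_ids <- function(cohort) {
  vapply(cohort$series, `[[`, "", "subject_id")
}

#' Read a cohort from a tidy stride table
#'
#' Expects a long-format delimited file with one row per stride and columns
#' `subject_id`, `stride_index`, `mfc_value`, plus optional `label`
#' (`improved`/`unimproved`, constant within subject) and optional logical
#' `normalized`. Stride indices must be 1-based and consecutive within each
#' subject; gaps or duplicates are rejected rather than imputed.
#'
#' @param path path to a CSV (default) or TSV file.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.tab` means tab, otherwise comma).
#' @return an [mfc_cohort()].
#' @export
read_cohort <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "stride_index", "mfc_value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  if (!is.numeric(df$mfc_value))
    stop_validation("mfc_value must be numeric")
  has_label <- "label" %in% names(df)
  has_norm <- "normalized" %in% names(df)
  series <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$stride_index), , drop = FALSE]
    idx <- d$stride_index
    if (anyDuplicated(idx))
      stop_validation(sprintf("subject '%s': duplicate stride_index",
                              d$subject_id[1]))
    if (idx[1] != 1 || !all(diff(idx) == 1))
      stop_validation(sprintf(
        "subject '%s': stride_index must be consecutive starting at 1",
        d$subject_id[1]))
    lab <- NA_character_
    if (has_label) {
      labs <- unique(stats::na.omit(as.character(d$label)))
      labs <- labs[labs != ""]
      if (length(labs) > 1)
        stop_validation(sprintf("subject '%s': conflicting labels",
                                d$subject_id[1]))
      if (length(labs) == 1) lab <- labs
    }
    norm <- if (has_norm) isTRUE(as.logical(d$normalized[1])) else FALSE
    mfc_series(d$mfc_value, d$subject_id[1], lab, normalized = norm)
  })
  # preserve file order of first appearance rather than split()'s sorting
  first <- !duplicated(df$subject_id)
  mfc_cohort(series[as.character(df$subject_id[first])])
}

#' Write a cohort as a tidy stride table
#'
#' Inverse of [read_cohort()]: long CSV with columns `subject_id`,
#' `stride_index`, `mfc_value`, `label`, `normalized`.
#'
#' @param cohort an [mfc_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mfc_cohort"))
  rows <- lapply(cohort$series, function(s) {
    data.frame(subject_id = s$subject_id,
               stride_index = seq_len(s$n),
               mfc_value = s$values,
               label = s$label,
               normalized = s$normalized,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop_io(conditionMessage(e)))
  invisible(path)
}

#' Normalize every series in a cohort
#'
#' @param cohort an [mfc_cohort()].
#' @inheritParams normalize_series
#' @return an `mfc_cohort` of normalized series; series already normalized
#'   are passed through untouched.
#' @export
normalize_cohort <- function(cohort, method = c("minmax", "max", "none")) {
  method <- match.arg(method)
  mfc_cohort(lapply(cohort$series, function(s) {
    if (s$normalized || method == "none") s else normalize_series(s, method)
  }))
}
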