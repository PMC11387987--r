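#' Per-bin F-ratio class-separability profile
#'
#' For each frequency bin `k` the F-ratio compares the spread of the class
#' mean magnitudes around the grand mean with the averaged within-class
#' scatter:
#' \deqn{F(k) = \frac{\sum_i (\bar S_i(k) - \bar S(k))^2}
#'                  {\sum_i \frac{1}{C_i}\sum_j (S_{ij}(k) - \bar S_i(k))^2}}
#' where \eqn{S_{ij}(k)} is the magnitude of subject `j` of class `i` at bin
#' `k`, \eqn{\bar S_i(k)} the class mean and \eqn{\bar S(k)} the unweighted
#' mean of the class means. The numerator is an unweighted sum over class
#' means; the denominator averages squared deviations within each class, then
#' sums over classes. Bins whose within-class scatter is exactly zero have an
#' undefined ratio and are flagged rather than silently set to 0 or infinity.
#'
#' A large F(k) marks a bin at which the class means are well separated
#' relative to the within-class variability, i.e. a discriminative frequency.
#'
#' @param t a [feature_table()] of per-bin magnitudes (see
#'   [bin_magnitude_table()]), or a plain numeric matrix.
#' @param labels per-sample class labels; taken from `t` when it is a
#'   feature table.
#' @return an object of class `f_ratio_profile`: list with `f_values`
#'   (`NA` where undefined), `undefined` (logical flag per bin),
#'   `class_means`, `grand_means`, `class_sizes`, `n_classes`,
#'   `feature_names`.
#' @export
f_ratio_profile <- function(t, labels = NULL) {
  if (inherits(t, "feature_table")) {
    m <- t$matrix
    if (is.null(labels)) labels <- t$labels
  } else {
    m <- as.matrix(t)
  }
  if (is.null(labels) || length(labels) != nrow(m))
    stop_validation("labels must be supplied, one per sample")
  if (any(is.na(labels)))
    stop_validation("all samples must be labeled for the F-ratio")
  classes <- unique(labels)
  if (length(classes) < 2)
    stop_validation("the F-ratio needs at least 2 classes")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop_validation(sprintf(
      "every class needs at least 2 samples (got %s)",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))

  class_means <- matrix(vapply(classes,
                               function(cl) colMeans(m[labels == cl, , drop = FALSE]),
                               numeric(ncol(m))),
                        nrow = length(classes), ncol = ncol(m), byrow = TRUE,
                        dimnames = list(classes, colnames(m)))
  grand <- colMeans(class_means)  # unweighted over classes
  numer <- colSums(sweep(class_means, 2, grand)^2)
  denom <- rep(0, ncol(m))
  for (cl in classes) {
    dev <- sweep(m[labels == cl, , drop = FALSE], 2, class_means[cl, ])
    denom <- denom + colSums(dev^2) / sum(labels == cl)
  }
  undefined <- denom == 0
  f <- ifelse(undefined, NA_real_, numer / denom)
  structure(list(f_values = f,
                 undefined = undefined,
                 class_means = class_means,
                 grand_means = grand,
                 class_sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 n_classes = length(classes),
                 feature_names = colnames(m)),
            class = "f_ratio_profile")
}

#' @export
print.f_ratio_profile <- function(x, ...) {
  cat(sprintf("<f_ratio_profile> %d bins, %d classes (%s)%s\n",
              length(x$f_values), x$n_classes,
              paste(sprintf("%s=%d", names(x$class_sizes), x$class_sizes),
                    collapse = ", "),
              if (any(x$undefined))
                sprintf("; %d undefined bins", sum(x$undefined)) else ""))
  invisible(x)
}

#' @export
as.data.frame.f_ratio_profile <- function(x, ...) {
  nfft <- 2L * (length(x$f_values) - 1L)
  data.frame(bin = seq_along(x$f_values) - 1L,
             frequency_cycles_per_stride = (seq_along(x$f_values) - 1L) / nfft,
             f_ratio = x$f_values,
             undefined = x$undefined)
}
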