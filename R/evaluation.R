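#' Mann-Whitney U test for a two-group feature comparison
#'
#' Rank-based two-sided test of whether one group's feature values tend to
#' exceed the other's. The reported `U` is the smaller of the two one-sided
#' statistics. The p-value comes from the exact rank-sum distribution when
#' the combined sample size is at most 20 and there are no ties, and from the
#' tie-corrected normal approximation (with continuity correction) otherwise.
#'
#' @param a,b numeric samples (each non-empty).
#' @return list with `U` (smaller statistic), `U_a`, `U_b`, `p` (two-sided)
#'   and `exact` (logical).
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop_validation("both samples must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop_validation("samples must be finite")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- (na + nb) <= 20 && !has_ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  list(U = min(u_a, u_b), U_a = u_a, U_b = u_b, p = p, exact = exact)
}

#' Rank-based AUC of a single feature
#'
#' The probability that a randomly chosen positive-class subject outranks a
#' randomly chosen negative-class subject, with ties counting one half —
#' algebraically `U_pos / (n_pos * n_neg)`. For screening the orientation is
#' irrelevant, so the reported `auc` is `max(auc, 1 - auc)` with the flip
#' recorded in `flipped`; `auc_raw` preserves the direction.
#'
#' @param values feature value per subject.
#' @param labels outcome labels.
#' @param positive the positive class (default `improved`).
#' @return list with `auc` (oriented, >= 0.5), `auc_raw`, `flipped`.
#' @export
single_feature_auc <- function(values, labels, positive = "improved") {
  labels <- as.character(labels)
  pos <- labels == positive
  neg <- !pos & !is.na(labels)
  if (!any(pos) || !any(neg))
    stop_validation("both classes must be present to compute an AUC")
  v <- values[pos | neg]
  p <- pos[pos | neg]
  r <- rank(v)
  u_pos <- sum(r[p]) - sum(p) * (sum(p) + 1) / 2
  auc_raw <- u_pos / (sum(p) * sum(!p))
  list(auc = max(auc_raw, 1 - auc_raw), auc_raw = auc_raw,
       flipped = auc_raw < 0.5)
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity, specificity and F1 (all in percent) from paired
#' true/predicted label vectors, with `improved` as the positive class by
#' default. A metric whose denominator is zero is reported as 0 and its name
#' recorded in `undefined` rather than silently dropped.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive positive class label.
#' @return an object of class `metric_set`: list with `acc`, `sens`, `spec`,
#'   `f1` (percent), `auc` (`NA` here; filled by the CV drivers from decision
#'   scores), `confusion` (`tp`, `fp`, `tn`, `fn`) and `undefined`.
#' @examples
#' # an all-positive classifier on a 14 improved / 5 unimproved cohort
#' truth <- rep(c("improved", "unimproved"), c(14, 5))
#' confusion_metrics(truth, rep("improved", 19))
#' @export
confusion_metrics <- function(y_true, y_pred, positive = "improved") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop_validation("label vectors must have equal length")
  bad <- !c(y_true, y_pred) %in% mfc_labels()
  if (any(bad))
    stop_validation("labels must be 'improved' or 'unimproved'")
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  ratio <- function(num, den, name, env) {
    if (den == 0) {
      env$undefined <- c(env$undefined, name)
      return(0)
    }
    100 * num / den
  }
  env <- new.env(); env$undefined <- character(0)
  ms <- list(acc = ratio(tp + tn, tp + fp + tn + fn, "acc", env),
             sens = ratio(tp, tp + fn, "sens", env),
             spec = ratio(tn, tn + fp, "spec", env),
             f1 = ratio(2 * tp, 2 * tp + fp + fn, "f1", env),
             auc = NA_real_,
             confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
             undefined = env$undefined)
  structure(ms, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> ACC %.2f SENS %.2f SPEC %.2f F1 %.2f AUC %s%s\n",
              x$acc, x$sens, x$spec, x$f1,
              if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc),
              if (length(x$undefined))
                sprintf(" [undefined: %s]",
                        paste(x$undefined, collapse = ", ")) else ""))
  invisible(x)
}

#' Screen features by Mann-Whitney significance and rank AUC
#'
#' Runs [mann_whitney_u()] and [single_feature_auc()] on every column of a
#' labeled feature table, comparing the improved and unimproved groups.
#'
#' @param t a [feature_table()] with both classes labeled.
#' @return data frame with columns `feature`, `U`, `p`, `auc`, `flipped`,
#'   ordered as in the table.
#' @export
screen_features <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  lab <- t$labels
  a_idx <- which(lab == "improved")
  b_idx <- which(lab == "unimproved")
  if (!length(a_idx) || !length(b_idx))
    stop_validation("screening needs labeled subjects from both classes")
  rows <- lapply(t$feature_names, function(f) {
    v <- t$matrix[, f]
    mw <- mann_whitney_u(v[a_idx], v[b_idx])
    auc <- single_feature_auc(v[c(a_idx, b_idx)],
                              lab[c(a_idx, b_idx)])
    data.frame(feature = f, U = mw$U, p = mw$p, auc = auc$auc,
               flipped = auc$flipped, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
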