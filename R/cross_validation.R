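#' Aggregated cross-validation report
#'
#' Created by the CV drivers ([cv_leave_one_sample_out()],
#' [cv_leave_one_fold_out()], [cv_stratified_kfold()], [noise_sweep()]).
#' For repeated/fold schemes every metric is the mean of the per-iteration
#' metrics, never recomputed from pooled confusion counts; leave-one-sample-out
#' pools its single held-out predictions into one confusion matrix instead,
#' since per-iteration metrics are degenerate for a one-subject test set.
#'
#' @param scheme CV scheme identifier.
#' @param spec the [classifier_spec()] evaluated.
#' @param metrics a [confusion_metrics()] `metric_set` (aggregated).
#' @param n_repeats number of iterations averaged (or pooled).
#' @param seed the seed the driver consumed.
#' @param details per-iteration data (scheme-specific).
#' @param feature_family optional tag of the feature family evaluated.
#' @param noise_percent optional test-noise level (percent of series SD).
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(scheme, spec, metrics, n_repeats, seed,
                        details = NULL, feature_family = NA_character_,
                        noise_percent = NA_real_) {
  structure(list(scheme = scheme, classifier = spec, metrics = metrics,
                 n_repeats = n_repeats, seed = seed, details = details,
                 feature_family = feature_family,
                 noise_percent = noise_percent),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %s classifier, %d iterations (seed %s)\n",
              x$scheme, x$classifier$kind, x$n_repeats, format(x$seed)))
  print(x$metrics)
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(classifier = x$classifier$kind,
             cv_scheme = x$scheme,
             feature_family = x$feature_family,
             noise_percent = x$noise_percent,
             acc = x$metrics$acc, sens = x$metrics$sens,
             spec = x$metrics$spec, f1 = x$metrics$f1,
             auc = x$metrics$auc,
             n_repeats = x$n_repeats, seed = x$seed,
             stringsAsFactors = FALSE)
}

check_cv_table <- function(t, min_per_class = 2) {
  stopifnot(inherits(t, "feature_table"))
  if (any(is.na(t$labels)))
    stop_validation("cross-validation needs every subject labeled")
  counts <- table(factor(t$labels, levels = mfc_labels()))
  if (any(counts < min_per_class))
    stop_validation(sprintf("need at least %d subjects per class",
                            min_per_class))
  invisible(counts)
}

# Pooled AUC of decision scores against true labels; NA when degenerate.
score_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2 || any(!is.finite(scores))) return(NA_real_)
  single_feature_auc(scores, labels)$auc_raw
}

# Shared leave-one-sample-out engine. Training features always come from
# `t_train`; the held-out subject's feature row is taken from `t_test`,
# which allows noise_sweep() to substitute features recomputed from a
# contaminated series while training stays clean. With t_test == t_train this
# is plain LOSO.
loso_engine <- function(t_train, t_test, spec, seed) {
  n <- nrow(t_train$matrix)
  seeds <- derive_seeds(seed, n)
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    sc <- scale_train_test(t_train$matrix[-i, , drop = FALSE],
                           t_test$matrix[i, , drop = FALSE])
    fit <- fit_classifier(sc$train, t_train$labels[-i], spec, seeds[i])
    out <- predict_classifier(fit, sc$test)
    pred[i] <- out$label; score[i] <- out$score
  }
  ms <- confusion_metrics(t_train$labels, pred)
  ms$auc <- score_auc(score, t_train$labels)
  list(metrics = ms,
       predictions = data.frame(subject_id = t_train$subject_ids,
                                label = t_train$labels,
                                predicted = pred, score = score,
                                stringsAsFactors = FALSE))
}

#' Leave-one-sample-out cross-validation
#'
#' Each subject is held out once; the classifier is trained on the remaining
#' subjects (features z-scored with training-split statistics) and predicts
#' the held-out subject. The `n` held-out predictions are pooled into a
#' single confusion matrix, and the report AUC is the rank AUC of the pooled
#' decision scores.
#'
#' @param t a [feature_table()] with at least 2 subjects per class.
#' @param spec a [classifier_spec()].
#' @param seed seed controlling classifier randomness.
#' @return an [eval_report()]; `details` holds the per-subject predictions.
#' @export
cv_leave_one_sample_out <- function(t, spec = classifier_spec("svm"),
                                    seed = 1) {
  check_cv_table(t)
  res <- loso_engine(t, t, spec, seed)
  eval_report("loso", spec, res$metrics, n_repeats = nrow(t$matrix),
              seed = seed, details = res$predictions)
}

# Metrics for one train/test split; AUC from test-set decision scores.
split_metrics <- function(t, train_idx, spec, fit_seed) {
  test_idx <- setdiff(seq_len(nrow(t$matrix)), train_idx)
  sc <- scale_train_test(t$matrix[train_idx, , drop = FALSE],
                         t$matrix[test_idx, , drop = FALSE])
  fit <- fit_classifier(sc$train, t$labels[train_idx], spec, fit_seed)
  out <- predict_classifier(fit, sc$test)
  ms <- confusion_metrics(t$labels[test_idx], out$label)
  ms$auc <- score_auc(out$score, t$labels[test_idx])
  ms
}

mean_metric_sets <- function(sets) {
  pick <- function(f) vapply(sets, `[[`, 0, f)
  aucs <- pick("auc")
  ms <- list(acc = mean(pick("acc")), sens = mean(pick("sens")),
             spec = mean(pick("spec")), f1 = mean(pick("f1")),
             auc = if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE),
             confusion = Reduce(`+`, lapply(sets, `[[`, "confusion")),
             undefined = sort(unique(unlist(lapply(sets, `[[`, "undefined")))))
  structure(ms, class = "metric_set")
}

#' Leave-one-fold-out cross-validation (small random training folds)
#'
#' Repeatedly draws `n_per_class` random subjects from each class as the
#' training set and tests on all remaining subjects; metrics are computed per
#' repeat and averaged over `n_repeats` repeats. This deliberately inverts
#' the usual proportions — with very small cohorts it probes how little
#' training data the classifier can cope with.
#'
#' @param t a [feature_table()].
#' @param spec a [classifier_spec()].
#' @param n_per_class training subjects drawn per class (default 4).
#' @param n_repeats number of random draws (default 50).
#' @param seed seed controlling draws and classifier randomness.
#' @return an [eval_report()]; `details` holds per-repeat metrics.
#' @export
cv_leave_one_fold_out <- function(t, spec = classifier_spec("svm"),
                                  n_per_class = 4, n_repeats = 50, seed = 1) {
  counts <- check_cv_table(t)
  if (any(counts <= n_per_class))
    stop_validation(sprintf(
      "every class must have more than n_per_class = %d subjects", n_per_class))
  seeds <- derive_seeds(seed, 2 * n_repeats)
  per_repeat <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    train_idx <- with_seed(seeds[r], {
      unlist(lapply(mfc_labels(), function(cl) {
        sample(which(t$labels == cl), n_per_class)
      }))
    })
    per_repeat[[r]] <- split_metrics(t, train_idx, spec, seeds[n_repeats + r])
  }
  details <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    m <- per_repeat[[r]]
    data.frame(repeat_index = r, acc = m$acc, sens = m$sens, spec = m$spec,
               f1 = m$f1, auc = m$auc)
  }))
  eval_report("lofo", spec, mean_metric_sets(per_repeat),
              n_repeats = n_repeats, seed = seed, details = details)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' The subjects are partitioned into `k` folds preserving the class
#' proportions (within-class round-robin after a seeded shuffle); each fold
#' is tested once against a model trained on the others, and per-fold metrics
#' are averaged. For a 14/5 cohort with `k = 5`, every fold contains exactly
#' one unimproved subject.
#'
#' @param t a [feature_table()].
#' @param spec a [classifier_spec()].
#' @param k number of folds (default 5).
#' @param seed seed controlling the shuffle and classifier randomness.
#' @return an [eval_report()]; `details` holds per-fold metrics and the fold
#'   assignment.
#' @export
cv_stratified_kfold <- function(t, spec = classifier_spec("svm"), k = 5,
                                seed = 1) {
  counts <- check_cv_table(t)
  if (k < 2) stop_config("k must be at least 2")
  if (k > min(counts))
    warning(sprintf(
      "k = %d exceeds the minority class size (%d); some folds will lack %s",
      k, min(counts), "a minority subject"), call. = FALSE)
  seeds <- derive_seeds(seed, k + 1)
  fold <- stratified_folds(t$labels, k, seeds[1])
  per_fold <- lapply(seq_len(k), function(f) {
    split_metrics(t, which(fold != f), spec, seeds[1 + f])
  })
  details <- do.call(rbind, lapply(seq_len(k), function(f) {
    m <- per_fold[[f]]
    data.frame(fold = f, acc = m$acc, sens = m$sens, spec = m$spec,
               f1 = m$f1, auc = m$auc)
  }))
  rep <- eval_report("stratified5", spec, mean_metric_sets(per_fold),
                     n_repeats = k, seed = seed, details = details)
  rep$fold_assignment <- fold
  rep
}
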