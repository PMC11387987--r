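#' Classifier specification
#'
#' A declarative description of one of the five benchmarked classifier
#' families and its hyperparameters. Hyperparameters are validated against
#' the benchmark grids unless `override = TRUE`:
#'
#' * `svm`: `kernel` in linear / rbf / polynomial (degree 3),
#'   `C` in 0.01, 0.1, 1, 10, 100.
#' * `random_forest`, `bagged_trees`: `min_leaf` in 1, 5, 10; `n_trees`
#'   in 5..100.
#' * `adaboost`: depth-1 stumps, `learning_rate` in 0.001, 0.01, 0.1,
#'   `n_learners` in 15, 20, 25, 30.
#' * `ann`: one hidden layer with `hidden_nodes` in 10, 20, 50,
#'   `learning_rate` in 0.1, 0.01, 0.001, 1000 epochs, ridge penalty 0.01.
#'   The hidden layer is trained by quasi-Newton optimization, for which the
#'   nominal learning rate has no effect; it is recorded for provenance only.
#'
#' @param kind classifier family.
#' @param kernel,C SVM options.
#' @param min_leaf,n_trees tree-ensemble options.
#' @param learning_rate,n_learners boosting / ANN options.
#' @param hidden_nodes,epochs,ridge ANN options.
#' @param override allow hyperparameters outside the declared grids.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "random_forest", "adaboost",
                                     "bagged_trees", "ann"),
                            kernel = "linear", C = 1,
                            min_leaf = 1, n_trees = 50,
                            learning_rate = NULL, n_learners = 30,
                            hidden_nodes = 10, epochs = 1000, ridge = 0.01,
                            override = FALSE) {
  kind <- match.arg(kind)
  chk <- function(ok, what) {
    if (!ok && !override)
      stop_config(sprintf("%s outside the declared grid (use override = TRUE)",
                          what))
  }
  hp <- switch(kind,
    svm = {
      chk(kernel %in% c("linear", "rbf", "polynomial"), "kernel")
      chk(C %in% c(0.01, 0.1, 1, 10, 100), "C")
      list(kernel = kernel, C = C)
    },
    random_forest = ,
    bagged_trees = {
      chk(min_leaf %in% c(1, 5, 10), "min_leaf")
      chk(n_trees >= 5 && n_trees <= 100, "n_trees")
      list(min_leaf = min_leaf, n_trees = as.integer(n_trees))
    },
    adaboost = {
      if (is.null(learning_rate)) learning_rate <- 0.1
      chk(learning_rate %in% c(0.001, 0.01, 0.1), "learning_rate")
      chk(n_learners %in% c(15, 20, 25, 30), "n_learners")
      list(learning_rate = learning_rate, n_learners = as.integer(n_learners))
    },
    ann = {
      if (is.null(learning_rate)) learning_rate <- 0.01
      chk(hidden_nodes %in% c(10, 20, 50), "hidden_nodes")
      chk(learning_rate %in% c(0.1, 0.01, 0.001), "learning_rate")
      list(hidden_nodes = as.integer(hidden_nodes),
           learning_rate = learning_rate,
           epochs = as.integer(epochs), ridge = ridge)
    })
  structure(c(list(kind = kind), hp), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- x[setdiff(names(x), "kind")]
  cat(sprintf("<classifier_spec> %s (%s)\n", x$kind,
              paste(sprintf("%s=%s", names(hp), unlist(hp)), collapse = ", ")))
  invisible(x)
}

#' Fit a classifier to a labeled feature matrix
#'
#' Thin, seed-controlled wrappers around the standard implementations
#' (e1071 for the SVM, randomForest, rpart-based bagging and depth-1-stump
#' AdaBoost, nnet for the single-hidden-layer network). If the training data
#' contain only one class, a constant classifier predicting that class is
#' returned with a warning (this arises in extreme cross-validation splits
#' and keeps the iteration rather than dropping it).
#'
#' @param x numeric feature matrix (rows = subjects); callers are expected to
#'   have standardized columns with training-split statistics.
#' @param y outcome labels (`improved` / `unimproved`).
#' @param spec a [classifier_spec()].
#' @param seed integer seed consumed by randomized learners.
#' @return an object of class `mfc_classifier`; use [predict_classifier()].
#' @export
fit_classifier <- function(x, y, spec = classifier_spec("svm"), seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = mfc_labels())
  if (any(is.na(y))) stop_validation("training labels must be known")
  if (nlevels(droplevels(y)) < 2) {
    only <- as.character(unique(y))[1]
    warning(sprintf("training split contains a single class ('%s'); %s",
                    only, "fitting a constant classifier"), call. = FALSE)
    return(structure(list(kind = "constant", level = only, spec = spec),
                     class = "mfc_classifier"))
  }
  model <- with_seed(seed, switch(spec$kind,
    svm = e1071::svm(x, y,
                     kernel = switch(spec$kernel, linear = "linear",
                                     rbf = "radial", polynomial = "polynomial"),
                     degree = 3, cost = spec$C, scale = FALSE,
                     probability = FALSE),
    random_forest = randomForest::randomForest(x, y, ntree = spec$n_trees,
                                               nodesize = spec$min_leaf),
    bagged_trees = fit_bagged_trees(x, y, spec),
    adaboost = fit_adaboost_stumps(x, y, spec),
    ann = nnet::nnet(x, stats::model.matrix(~ y - 1)[, 1, drop = FALSE],
                     size = spec$hidden_nodes, decay = spec$ridge,
                     maxit = spec$epochs, entropy = TRUE, trace = FALSE)))
  structure(list(kind = spec$kind, model = model, spec = spec),
            class = "mfc_classifier")
}

#' Predict labels and positive-class scores
#'
#' @param object an `mfc_classifier` from [fit_classifier()].
#' @param newdata numeric feature matrix.
#' @return list with `label` (character) and `score` (numeric; larger means
#'   more `improved`-like).
#' @export
predict_classifier <- function(object, newdata) {
  stopifnot(inherits(object, "mfc_classifier"))
  newdata <- as.matrix(newdata)
  pos <- mfc_labels()[1]
  if (object$kind == "constant") {
    score <- rep(if (object$level == pos) 1 else -1, nrow(newdata))
    return(list(label = rep(object$level, nrow(newdata)), score = score))
  }
  m <- object$model
  switch(object$kind,
    svm = {
      pr <- predict(m, newdata, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 labels the decision column "<level1>/<level2>"; orient so that
      # a positive value favours the improved class.
      sgn <- if (grepl(paste0("^", pos, "/"), colnames(dv)[1])) 1 else -1
      list(label = as.character(pr), score = sgn * as.numeric(dv[, 1]))
    },
    random_forest = {
      p <- predict(m, newdata, type = "prob")[, pos]
      list(label = as.character(predict(m, newdata, type = "response")),
           score = as.numeric(p))
    },
    bagged_trees = predict_bagged_trees(m, newdata),
    adaboost = predict_adaboost_stumps(m, newdata),
    ann = {
      p <- as.numeric(predict(m, newdata))  # P(improved): first model column
      list(label = ifelse(p >= 0.5, pos, mfc_labels()[2]), score = p)
    })
}

# --- bagged decision trees -------------------------------------------------
# Bootstrap-aggregated full-depth rpart trees (bagging). rpart's defaults are
# tuned for larger samples, so splitting is opened up (minsplit = 2, cp = 0)
# and only the requested minimum leaf size is enforced.

fit_bagged_trees <- function(x, y, spec) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  ctrl <- rpart::rpart.control(minsplit = 2, minbucket = spec$min_leaf,
                               cp = 0, xval = 0)
  trees <- lapply(seq_len(spec$n_trees), function(b) {
    idx <- sample.int(nrow(df), replace = TRUE)
    rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class",
                 control = ctrl)
  })
  list(trees = trees)
}

predict_bagged_trees <- function(m, newdata) {
  df <- as.data.frame(newdata)
  pos <- mfc_labels()[1]
  probs <- vapply(m$trees,
                  function(tr) predict(tr, df, type = "prob")[, pos],
                  numeric(nrow(df)))
  p <- rowMeans(matrix(probs, nrow = nrow(df)))
  list(label = ifelse(p >= 0.5, pos, mfc_labels()[2]), score = p)
}

# --- AdaBoost with decision stumps -----------------------------------------
# Discrete AdaBoost: depth-1 rpart stumps on reweighted samples; the stage
# weight is shrunk by the learning rate. Training stops early if a stump is
# perfect (residual error 0) or no better than chance.

fit_adaboost_stumps <- function(x, y, spec) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  ysgn <- ifelse(y == mfc_labels()[1], 1, -1)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, minbucket = 1,
                               cp = 0, xval = 0)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(spec$n_learners)) {
    tr <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = ctrl)
    h <- ifelse(predict(tr, df, type = "class") == mfc_labels()[1], 1, -1)
    err <- sum(w[h != ysgn])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- spec$learning_rate * 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ysgn * h)
    w <- w / sum(w)
    if (sum(h != ysgn) == 0) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost_stumps <- function(m, newdata) {
  df <- as.data.frame(newdata)
  pos <- mfc_labels()[1]
  if (!length(m$stumps))
    return(list(label = rep(pos, nrow(df)), score = rep(0, nrow(df))))
  hs <- vapply(m$stumps,
               function(tr) ifelse(predict(tr, df, type = "class") == pos,
                                   1, -1),
               numeric(nrow(df)))
  score <- as.numeric(matrix(hs, nrow = nrow(df)) %*% m$alphas)
  list(label = ifelse(score >= 0, pos, mfc_labels()[2]), score = score)
}
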