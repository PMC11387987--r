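#' Subjects-by-features matrix with outcome labels
#'
#' The carrier object between feature extraction and screening /
#' cross-validation. No missing entries are allowed.
#'
#' @param matrix numeric matrix, one row per subject, one column per feature.
#' @param subject_ids character vector of row identifiers.
#' @param labels per-subject outcome labels (`improved`/`unimproved`/`NA`).
#' @param feature_names optional column names (defaults to `colnames(matrix)`).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(matrix, subject_ids, labels,
                          feature_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (!nrow(matrix) || !ncol(matrix))
    stop_validation("feature table must have at least one row and one column")
  if (is.null(feature_names)) stop_validation("feature names are required")
  if (length(subject_ids) != nrow(matrix))
    stop_validation("subject_ids length does not match matrix rows")
  if (length(feature_names) != ncol(matrix))
    stop_validation("feature_names length does not match matrix columns")
  if (length(labels) != nrow(matrix))
    stop_validation("labels length does not match matrix rows")
  if (anyDuplicated(subject_ids))
    stop_validation("duplicate subject ids in feature table")
  if (any(!is.finite(matrix)))
    stop_validation("feature table contains missing or non-finite entries")
  labels <- as.character(labels)
  bad <- !is.na(labels) & !labels %in% mfc_labels()
  if (any(bad))
    stop_validation("labels must be 'improved', 'unimproved', or NA")
  dimnames(matrix) <- list(as.character(subject_ids), feature_names)
  structure(list(matrix = matrix,
                 subject_ids = as.character(subject_ids),
                 feature_names = feature_names,
                 labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features [%s%s]\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(head(x$feature_names, 4), collapse = ", "),
              if (ncol(x$matrix) > 4) ", ..." else ""))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(subject_id = x$subject_ids, label = x$labels, x$matrix,
             row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write a feature table as tidy CSV
#'
#' Columns are `subject_id`, `label`, then one column per feature. Values are
#' written with 15 significant digits so a write/read round trip is identical
#' to within 1e-12 relative.
#'
#' @param t a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path) {
  stopifnot(inherits(t, "feature_table"))
  df <- as.data.frame(t)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
  tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop_io(conditionMessage(e)))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path path to the CSV file.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "label")
  if (!all(need %in% names(df)))
    stop_format("feature table file must have subject_id and label columns")
  feats <- setdiff(names(df), need)
  if (!length(feats)) stop_format("feature table file has no feature columns")
  m <- as.matrix(df[feats])
  storage.mode(m) <- "double"
  lab <- as.character(df$label)
  lab[lab %in% c("", "NA")] <- NA_character_
  feature_table(m, df$subject_id, lab, feats)
}

# z-score columns using reference (training-split) statistics; constant
# columns are centred but left unscaled.
scale_train_test <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}
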