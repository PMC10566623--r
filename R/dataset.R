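# Data model for tabular decoding problems: construction, delimited-table
# I/O, train/test splitting, covariate-of-no-interest residualization.

#' Construct a decoding dataset
#'
#' A `fvs_dataset` holds a numeric feature matrix `X` (n samples x m
#' features), a target vector `y` (numeric for regression, factor for
#' classification), optional covariates of no interest (e.g. total
#' intracranial volume), and the task type.
#'
#' @param X numeric matrix, samples in rows; column names become feature
#'   names if `feature_names` is missing.
#' @param y target vector of length `nrow(X)`.
#' @param task `"regression"` or `"classification"`.
#' @param feature_names character vector of unique feature names.
#' @param covariates optional numeric matrix (n x c) of nuisance covariates.
#' @return an object of class `fvs_dataset`.
#' @export
new_dataset <- function(X, y, task = c("regression", "classification"),
                        feature_names = colnames(X), covariates = NULL) {
  task <- match.arg(task)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(X))
    stopf("feature_names length (%d) != ncol(X) (%d)", length(feature_names), ncol(X))
  if (anyDuplicated(feature_names))
    stopf("duplicate feature names: %s",
          paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  if (length(y) != nrow(X))
    stopf("y length (%d) != nrow(X) (%d)", length(y), nrow(X))
  if (anyNA(X)) stopf("X contains missing values")
  if (anyNA(y)) stopf("y contains missing values")
  if (task == "classification") {
    y <- factor(y)
    if (nlevels(y) < 2) stopf("classification target needs >= 2 distinct labels")
  } else {
    if (!is.numeric(y)) stopf("regression target must be numeric")
    y <- as.numeric(y)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != nrow(X)) stopf("covariates rows != n")
    if (anyNA(covariates)) stopf("covariates contain missing values")
  }
  colnames(X) <- feature_names
  structure(list(X = X, y = y, feature_names = feature_names,
                 covariates = covariates, task = task),
            class = "fvs_dataset")
}

#' @exportS3Method base::print
print.fvs_dataset <- function(x, ...) {
  cat(sprintf("<fvs_dataset> %d samples x %d features, task = %s\n",
              nrow(x$X), ncol(x$X), x$task))
  if (x$task == "classification")
    cat("  classes:", paste(sprintf("%s (%d)", levels(x$y), tabulate(x$y)),
                            collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a dataset as a JSON-ready list
#'
#' @param dataset an [new_dataset()] object.
#' @return list with n, m, task and (classification) per-class counts.
#' @export
dataset_summary <- function(dataset) {
  out <- list(n = nrow(dataset$X), m = ncol(dataset$X), task = dataset$task)
  if (dataset$task == "classification")
    out$class_counts <- as.list(stats::setNames(tabulate(dataset$y), levels(dataset$y)))
  out
}

#' Load a delimited feature table
#'
#' Reads a CSV/TSV file with a header row. All numeric columns other than
#' the target, the covariates and non-numeric columns (e.g. subject IDs,
#' skipped with a warning) become features, in file order. Missing values
#' in feature, target or covariate columns are fatal unless `drop_na =
#' TRUE`, in which case offending rows are dropped; values are never
#' silently imputed.
#'
#' @param path path to a delimited text file (delimiter sniffed by
#'   [data.table::fread()]; decimal point `"."`).
#' @param target_column name of the target column.
#' @param covariate_columns character vector of covariate column names.
#' @param task `"regression"` or `"classification"`.
#' @param drop_na drop rows with missing entries instead of failing.
#' @return an `fvs_dataset`.
#' @export
load_table <- function(path, target_column,
                       covariate_columns = character(),
                       task = c("regression", "classification"),
                       drop_na = FALSE) {
  task <- match.arg(task)
  if (!file.exists(path)) stopf("input file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  nm <- names(dt)
  if (anyDuplicated(nm))
    stopf("duplicate header names in %s: %s", path,
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!target_column %in% nm)
    stopf("target column '%s' not found in %s", target_column, path)
  missing_cov <- setdiff(covariate_columns, nm)
  if (length(missing_cov))
    stopf("covariate column(s) not found: %s", paste(missing_cov, collapse = ", "))

  special <- c(target_column, covariate_columns)
  feat_cols <- setdiff(nm, special)
  numeric_ok <- vapply(dt[feat_cols], is.numeric, logical(1))
  if (any(!numeric_ok)) {
    skipped <- feat_cols[!numeric_ok]
    # distinguish genuinely non-numeric columns (ignored, e.g. IDs) from
    # numeric-looking columns broken by a stray cell
    for (cn in skipped) {
      v <- dt[[cn]]
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) && length(bad) < length(v) / 2)
        stopf("non-numeric value in feature column '%s' (e.g. row %d: '%s')",
              cn, bad[1], v[bad[1]])
    }
    warning(sprintf("ignoring non-numeric column(s): %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
    feat_cols <- feat_cols[numeric_ok]
  }
  if (!length(feat_cols)) stopf("no numeric feature columns in %s", path)

  X <- as.matrix(dt[feat_cols])
  y <- dt[[target_column]]
  C <- if (length(covariate_columns)) as.matrix(dt[covariate_columns]) else NULL
  if (!is.null(C) && !is.numeric(C)) stopf("covariate columns must be numeric")

  na_row <- rowSums(is.na(X)) > 0 | is.na(y)
  if (!is.null(C)) na_row <- na_row | rowSums(is.na(C)) > 0
  if (any(na_row)) {
    if (!drop_na) {
      j <- which(is.na(X), arr.ind = TRUE)
      where <- if (nrow(j)) sprintf("feature column '%s', row %d",
                                    feat_cols[j[1, 2]], j[1, 1])
               else sprintf("target/covariate, row %d", which(na_row)[1])
      stopf("missing values in %s (%d affected row(s)); use drop_na = TRUE to drop them",
            where, sum(na_row))
    }
    keep <- !na_row
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    if (!is.null(C)) C <- C[keep, , drop = FALSE]
    message(sprintf("dropped %d row(s) with missing values", sum(na_row)))
  }
  if (task == "regression" && !is.numeric(y))
    stopf("regression target '%s' is not numeric", target_column)
  new_dataset(X, y, task = task, feature_names = feat_cols, covariates = C)
}

#' Write a dataset back to a delimited table
#'
#' Inverse of [load_table()]: emits features, covariates and the target with
#' full double precision, so a load/write round trip preserves numeric
#' content.
#'
#' @param dataset an `fvs_dataset`.
#' @param path output file path; `.tsv` extension selects tab separation.
#' @param target_column name for the target column.
#' @return `path`, invisibly.
#' @export
write_table <- function(dataset, path, target_column = "target") {
  df <- as.data.frame(dataset$X)
  if (!is.null(dataset$covariates))
    df <- cbind(df, as.data.frame(dataset$covariates))
  df[[target_column]] <- if (dataset$task == "classification")
    as.character(dataset$y) else dataset$y
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Split configuration
#'
#' @param train_fraction fraction of samples in the training set (default
#'   0.7, the conventional 70/30 split).
#' @param cv_folds folds for hyperparameter tuning (default 5).
#' @param seed integer seed.
#' @param stratified preserve class proportions (classification only).
#' @return a `split_config` list.
#' @export
split_config <- function(train_fraction = 0.7, cv_folds = 5L, seed = 1L,
                         stratified = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_config")
}

#' Draw a reproducible train/test split
#'
#' @param dataset an `fvs_dataset`.
#' @param config a [split_config()].
#' @return list with integer vectors `train_idx`, `test_idx` (disjoint,
#'   exhaustive). Stratified splits preserve class proportions within one
#'   sample per class.
#' @export
make_split <- function(dataset, config = split_config()) {
  n <- nrow(dataset$X)
  if (n < 2 * config$cv_folds)
    stopf("need n >= 2*cv_folds (= %d), got n = %d", 2 * config$cv_folds, n)
  n_train <- round(config$train_fraction * n)
  if (config$stratified) {
    if (dataset$task != "classification")
      stopf("stratified splitting requires a classification task")
    cls <- split(seq_len(n), dataset$y)
    small <- names(cls)[vapply(cls, length, 0L) < config$cv_folds]
    if (length(small))
      stopf("class(es) with fewer than cv_folds members under stratification: %s",
            paste(small, collapse = ", "))
    train_idx <- integer(0)
    with_seed(config$seed, {
      for (idx in cls) {
        k <- round(config$train_fraction * length(idx))
        train_idx <- c(train_idx, sample(idx, k))
      }
    })
    # stratified rounding can drift from the global count by a sample or two;
    # per-class proportions are the contract here
    train_idx <- sort(train_idx)
  } else {
    train_idx <- with_seed(config$seed, sort(sample.int(n, n_train)))
  }
  structure(list(train_idx = train_idx,
                 test_idx = setdiff(seq_len(n), train_idx)),
            class = "fvs_split")
}

#' Regress covariates of no interest out of every feature
#'
#' Replaces each feature column by its residual from an ordinary least
#' squares fit (with intercept) of that feature on the covariates. The
#' coefficients are estimated on the training rows only and applied to all
#' rows, so no information from the test rows leaks into the adjustment.
#' The returned dataset has no covariates.
#'
#' @param dataset an `fvs_dataset` with covariates.
#' @param split a [make_split()] result; covariate coefficients are fit on
#'   `split$train_idx`. Defaults to all rows (no held-out set).
#' @return an `fvs_dataset` of residualized features.
#' @export
residualize_covariates <- function(dataset, split = NULL) {
  if (is.null(dataset$covariates)) stopf("dataset has no covariates")
  n <- nrow(dataset$X)
  tr <- if (is.null(split)) seq_len(n) else split$train_idx
  C <- cbind(`(Intercept)` = 1, dataset$covariates)
  qrC <- qr(C[tr, , drop = FALSE])
  if (qrC$rank < ncol(C))
    stopf("rank-deficient covariate matrix (rank %d < %d columns)",
          qrC$rank, ncol(C))
  beta <- qr.coef(qrC, dataset$X[tr, , drop = FALSE])
  R <- dataset$X - C %*% beta
  new_dataset(R, dataset$y, task = dataset$task,
              feature_names = dataset$feature_names, covariates = NULL)
}

# restrict a dataset to named feature columns (order preserved as given)
select_features <- function(dataset, features) {
  miss <- setdiff(features, dataset$feature_names)
  if (length(miss)) stopf("unknown feature(s): %s", paste(miss, collapse = ", "))
  new_dataset(dataset$X[, features, drop = FALSE], dataset$y,
              task = dataset$task, feature_names = features,
              covariates = dataset$covariates)
}
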