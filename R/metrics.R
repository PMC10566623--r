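# Scoring functions shared by every pipeline stage.

#' Regression metrics
#'
#' Mean squared error, mean absolute error and the Spearman rank
#' correlation (average ranks on ties) between predictions and truth.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return list with `mse`, `mae`, `spearman_rho`, `spearman_p`. Spearman
#'   quantities are `NA` (with a warning) when either vector is constant.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  if (length(y_true) < 2) stopf("need at least 2 observations")
  err <- y_true - y_pred
  mse <- mean(err^2)
  mae <- mean(abs(err))
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    rho <- NA_real_; pval <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(y_true, y_pred, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    pval <- ct$p.value
  }
  list(mse = mse, mae = mae, spearman_rho = rho, spearman_p = pval)
}

# Mann-Whitney formulation of the ROC AUC: probability that a random
# positive scores above a random negative (ties count 1/2).
binary_auc <- function(labels_pos, score) {
  n1 <- sum(labels_pos); n0 <- sum(!labels_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[labels_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics
#'
#' Accuracy, precision, recall, F1, ROC AUC and the confusion matrix.
#' Binary problems use a single positive class (by default the
#' lexicographically larger label); multiclass problems report
#' macro-averaged precision/recall/F1 and one-vs-rest macro AUC.
#' Zero-denominator precision/recall are reported as 0 with a warning.
#'
#' @param y_true true labels (factor or vector).
#' @param y_pred predicted labels over the same label set.
#' @param y_score optional score matrix (columns = sorted class labels) or,
#'   for binary problems, a vector of positive-class scores; required for
#'   AUC.
#' @param positive positive-class label for binary problems.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `per_class_recall`, and `confusion` (K x K counts, rows = truth).
#' @export
classification_metrics <- function(y_true, y_pred, y_score = NULL,
                                   positive = NULL) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  lev <- sort(unique(as.character(y_true)))
  y_true <- factor(as.character(y_true), levels = lev)
  bad <- setdiff(unique(as.character(y_pred)), lev)
  if (length(bad))
    stopf("predicted class(es) absent from true label set: %s",
          paste(bad, collapse = ", "))
  y_pred <- factor(as.character(y_pred), levels = lev)
  K <- length(lev)
  confusion <- table(truth = y_true, predicted = y_pred)
  confusion <- matrix(as.integer(confusion), K, K,
                      dimnames = list(truth = lev, predicted = lev))
  accuracy <- sum(diag(confusion)) / sum(confusion)
  per_class_recall <- diag(confusion) / pmax(rowSums(confusion), 1L)

  prf <- function(tp, fp, fn) {
    if (tp + fp == 0 || tp + fn == 0)
      warning("zero denominator in precision/recall; reporting 0", call. = FALSE)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }

  if (K == 2) {
    positive <- positive %||% lev[2]  # lexicographically larger label
    if (!positive %in% lev) stopf("positive class '%s' not a label", positive)
    pos <- y_true == positive
    tp <- sum(pos & y_pred == positive)
    fp <- sum(!pos & y_pred == positive)
    fn <- sum(pos & y_pred != positive)
    v <- prf(tp, fp, fn)
    auc <- NA_real_
    if (!is.null(y_score)) {
      s <- if (is.matrix(y_score)) y_score[, match(positive, lev)] else y_score
      auc <- binary_auc(pos, s)
    }
  } else {
    per <- vapply(seq_len(K), function(k) {
      tp <- confusion[k, k]
      fp <- sum(confusion[-k, k])
      fn <- sum(confusion[k, -k])
      prf(tp, fp, fn)
    }, numeric(3))
    v <- rowMeans(per)  # macro average
    auc <- NA_real_
    if (!is.null(y_score) && is.matrix(y_score)) {
      aucs <- vapply(seq_len(K), function(k)
        binary_auc(y_true == lev[k], y_score[, k]), 0)
      auc <- mean(aucs, na.rm = TRUE)
    }
  }
  list(accuracy = accuracy, precision = v[1], recall = v[2], f1 = v[3],
       auc = auc, per_class_recall = per_class_recall, confusion = confusion)
}

# single-number criterion used by tuning/ranking/FVS
score_predictions <- function(y_true, pred, criterion) {
  switch(criterion,
    mse = mean((y_true - pred$value)^2),
    mae = mean(abs(y_true - pred$value)),
    accuracy = mean(as.character(y_true) == as.character(pred$class)),
    auc = {
      lev <- levels(factor(y_true))
      if (length(lev) != 2) stopf("auc criterion requires a binary target")
      binary_auc(factor(y_true, levels = lev) == lev[2], pred$prob[, 2])
    },
    stopf("unknown criterion '%s'", criterion))
}

# metric map for evaluate_fitted / metrics.json
full_metrics <- function(y_true, pred, task) {
  if (task == "regression") regression_metrics(y_true, pred$value)
  else classification_metrics(y_true, pred$class, y_score = pred$prob)
}
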