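# Stage 1: fit every zoo model with nested tuning on the train split,
# evaluate on the held-out test split, and rank by the primary metric.

#' Evaluate a fitted model on held-out data
#'
#' @param model a [fit_model()] result.
#' @param X_test,y_test held-out rows.
#' @return metric map: regression `mse`, `mae`, `spearman_rho`,
#'   `spearman_p`; classification `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`, `per_class_recall`, `confusion`.
#' @export
evaluate_fitted <- function(model, X_test, y_test) {
  pred <- predict(model, X_test)
  n_pred <- if (model$task == "regression") length(pred$value) else length(pred$class)
  if (n_pred != length(y_test)) stopf("prediction/target length mismatch")
  full_metrics(y_test, pred, model$task)
}

#' Rank all zoo models on one train/test split
#'
#' For each registry model: tune hyperparameters by cross-validation on the
#' training rows, refit the best configuration on all training rows,
#' predict the test rows, and compute the full metric map. Rows are sorted
#' by the primary metric (MSE ascending for regression, accuracy descending
#' for classification); the top row is the recommended model. A model that
#' fails entirely is omitted with a logged error.
#'
#' @param dataset an `fvs_dataset` (already residualized if covariates are
#'   to be controlled).
#' @param split a [make_split()] result.
#' @param seed master seed.
#' @param cv_folds tuning folds (default 5).
#' @param models optional character subset of registry names.
#' @param config registry overrides forwarded to [registry()].
#' @param verbose print per-model progress.
#' @return a `data.frame` ranking table with one row per completed model:
#'   name, primary and secondary metrics, tuned parameters (string),
#'   `n_features`, and elapsed CPU seconds; attribute `"best_model"` holds
#'   the top name.
#' @export
rank_models <- function(dataset, split, seed = 1L, cv_folds = 5L,
                        models = NULL, config = NULL, verbose = FALSE) {
  specs <- registry(dataset$task, config = config)
  if (!is.null(models)) {
    miss <- setdiff(models, names(specs))
    if (length(miss)) stopf("unknown model(s): %s", paste(miss, collapse = ", "))
    specs <- specs[models]
  }
  Xtr <- dataset$X[split$train_idx, , drop = FALSE]
  ytr <- dataset$y[split$train_idx]
  Xte <- dataset$X[split$test_idx, , drop = FALSE]
  yte <- dataset$y[split$test_idx]
  primary <- if (dataset$task == "regression") "mse" else "accuracy"

  rows <- list()
  for (nm in names(specs)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      tr <- tune(specs[[nm]], Xtr, ytr, cv_folds = cv_folds,
                 seed = derive_seed(seed, "tune", nm))
      m <- fit_model(specs[[nm]], tr$best_params, Xtr, ytr,
                     seed = derive_seed(seed, "refit", nm))
      met <- evaluate_fitted(m, Xte, yte)
      list(tuned = tr, metrics = met)
    }, error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      message(sprintf("rank_models: model '%s' failed (%s); omitted",
                      nm, conditionMessage(res)))
      next
    }
    met <- res$metrics
    row <- if (dataset$task == "regression") {
      data.frame(model = nm, mse = met$mse, mae = met$mae,
                 spearman_rho = met$spearman_rho,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(model = nm, accuracy = met$accuracy,
                 precision = met$precision, recall = met$recall,
                 f1 = met$f1, auc = met$auc, stringsAsFactors = FALSE)
    }
    row$cv_score <- res$tuned$best_cv_score
    row$params <- paste(sprintf("%s=%s", names(res$tuned$best_params),
                                vapply(res$tuned$best_params, format, "")),
                        collapse = ";")
    row$n_features <- ncol(dataset$X)
    row$cpu_seconds <- elapsed
    rows[[nm]] <- row
    fvs_log(verbose, "rank_models: %s %s = %.4f (%.1fs)", nm, primary,
            row[[primary]], elapsed)
  }
  if (!length(rows)) stopf("rank_models: every model failed")
  tab <- do.call(rbind, rows)
  ord <- order(tab[[primary]],
               decreasing = dataset$task == "classification")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "best_model") <- tab$model[1]
  attr(tab, "primary_metric") <- primary
  tab
}
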