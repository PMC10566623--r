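# Shared fixtures and independent oracles used across test files.

# tiny deterministic regression dataset with a known linear signal
toy_regression <- function(n = 60, m = 6, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("f", 1:m)))
  y <- 2 * X[, 1] - X[, 3] + rnorm(n, sd = 0.3)
  new_dataset(X, y, task = "regression")
}

toy_classification <- function(n = 80, m = 5, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("f", 1:m)))
  y <- factor(ifelse(X[, 2] + 0.5 * X[, 4] + rnorm(n, sd = 0.5) > 0, "b", "a"))
  new_dataset(X, y, task = "classification")
}

# independent ridge solver (standardize columns, center target, solve the
# regularized normal equations); mirrors the documented model contract but
# shares no code with the package
oracle_ridge_fit <- function(X, y, lambda) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  b <- solve(crossprod(Xs) + diag(lambda, ncol(X)), crossprod(Xs, y - mean(y)))
  list(predict = function(Xn) {
    Xn <- sweep(sweep(Xn, 2, ctr), 2, scl, "/")
    as.numeric(Xn %*% b + mean(y))
  })
}

# single-candidate ridge pipeline used by the greedy-equivalence oracles:
# CV-tune over an alpha grid on the given folds, refit, score test MSE
oracle_ridge_score <- function(X, y, cols, train_idx, test_idx, folds,
                               alphas) {
  Xtr <- X[train_idx, cols, drop = FALSE]; ytr <- y[train_idx]
  cv <- vapply(alphas, function(a) {
    mean(vapply(seq_len(max(folds)), function(f) {
      fit <- oracle_ridge_fit(Xtr[folds != f, , drop = FALSE], ytr[folds != f], a)
      mean((fit$predict(Xtr[folds == f, , drop = FALSE]) - ytr[folds == f])^2)
    }, 0))
  }, 0)
  best <- alphas[which.min(cv)]
  fit <- oracle_ridge_fit(Xtr, ytr, best)
  mean((fit$predict(X[test_idx, cols, drop = FALSE]) - y[test_idx])^2)
}

write_temp_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  sep <- if (ext == ".tsv") "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
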