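test_that("load_table builds the expected dataset from CSV and TSV", {
  df <- data.frame(id = c("s1", "s2", "s3", "s4"),
                   f1 = c(1.5, 2.5, 3.5, 4.5),
                   f2 = c(0.1, 0.2, 0.3, 0.4),
                   age = c(22, 26, 31, 36))
  csv <- write_temp_csv(df)
  ds <- suppressWarnings(load_table(csv, "age", task = "regression"))
  expect_equal(nrow(ds$X), 4)
  expect_equal(ncol(ds$X), 2)
  expect_equal(ds$feature_names, c("f1", "f2"))
  expect_equal(ds$y, df$age)
  expect_warning(load_table(csv, "age", task = "regression"),
                 "non-numeric column")

  tsv <- write_temp_csv(df, ext = ".tsv")
  ds2 <- suppressWarnings(load_table(tsv, "age", task = "regression"))
  expect_identical(ds$X, ds2$X)
  expect_identical(ds$y, ds2$y)
})

test_that("load_table rejects missing and malformed input", {
  df <- data.frame(f1 = c(1, 2, 3, 4), f2 = c(1, NA, 3, 4), age = 1:4)
  csv <- write_temp_csv(df)
  expect_error(load_table(csv, "age", task = "regression"), "f2")
  # drop_na drops the offending row instead
  ds <- suppressMessages(load_table(csv, "age", task = "regression",
                                    drop_na = TRUE))
  expect_equal(nrow(ds$X), 3)

  expect_error(load_table(csv, "height", task = "regression"),
               "target column 'height' not found")
  expect_error(load_table(tempfile(), "age", task = "regression"),
               "not found")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("f1,f1,age", "1,2,3"), dup)
  expect_error(load_table(dup, "age", task = "regression"), "duplicate")

  badcell <- tempfile(fileext = ".csv")
  writeLines(c("f1,f2,age", "1,2,30", "2,oops,40", "3,4,50", "4,5,60"), badcell)
  expect_error(load_table(badcell, "age", task = "regression"),
               "non-numeric value in feature column 'f2'")
})

test_that("write_table/load_table round trip preserves numeric content", {
  ds <- simulate_dataset(sim_config(n = 30, m = 8, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_table(ds, path, target_column = "y")
  back <- load_table(path, "y", covariate_columns = "TIV",
                     task = "regression")
  expect_equal(unname(back$X), unname(ds$X), tolerance = 1e-12)
  expect_equal(back$y, ds$y, tolerance = 1e-12)
  expect_equal(unname(back$covariates), unname(ds$covariates),
               tolerance = 1e-12)
})

test_that("make_split honors sizes, determinism and the bijection contract", {
  ds <- toy_regression(n = 10)
  sp <- make_split(ds, split_config(train_fraction = 0.7, seed = 1))
  expect_length(sp$train_idx, 7)
  expect_length(sp$test_idx, 3)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp2 <- make_split(ds, split_config(train_fraction = 0.7, seed = 1))
  expect_identical(sp, sp2)

  # property: for several n and seeds, train+test is a permutation of 1..n
  for (n in c(11, 37, 100)) {
    dsn <- toy_regression(n = n)
    for (seed in 1:3) {
      s <- make_split(dsn, split_config(seed = seed))
      expect_identical(sort(c(s$train_idx, s$test_idx)), seq_len(n))
    }
  }
})

test_that("stratified splits preserve class proportions within one sample", {
  set.seed(3)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("x", "y"), times = c(40, 60)))
  ds <- new_dataset(X, y, task = "classification")
  sp <- make_split(ds, split_config(train_fraction = 0.7, seed = 5,
                                    stratified = TRUE))
  counts <- table(ds$y[sp$train_idx])
  expect_lte(abs(counts[["x"]] - 28), 1)
  expect_lte(abs(counts[["y"]] - 42), 1)

  # a class smaller than cv_folds is fatal under stratification
  y2 <- factor(c(rep("x", 3), rep("y", 97)))
  ds2 <- new_dataset(X, y2, task = "classification")
  expect_error(make_split(ds2, split_config(stratified = TRUE)),
               "fewer than cv_folds")
})

test_that("residualize_covariates matches OLS and is leakage-safe", {
  # exact linear dependence: residual is numerically zero
  set.seed(7)
  tiv <- rnorm(50, 1500, 100)
  X <- cbind(f1 = 2 * tiv, f2 = rnorm(50))
  ds <- new_dataset(X, rnorm(50), task = "regression",
                    covariates = cbind(TIV = tiv))
  r <- residualize_covariates(ds)
  expect_lt(max(abs(r$X[, "f1"])), 1e-8)

  # orthogonal covariate leaves the feature unchanged up to centering
  f <- rnorm(50)
  cov_orth <- residuals(lm(rnorm(50) ~ f))   # zero sample covariance with f
  ds2 <- new_dataset(cbind(f = f), rnorm(50), task = "regression",
                     covariates = cbind(C = cov_orth))
  r2 <- residualize_covariates(ds2)
  expect_equal(r2$X[, "f"], f - mean(f) - mean(cov_orth) * coef(lm(f ~ cov_orth))[2],
               tolerance = 1e-10, ignore_attr = TRUE)

  # 3-sample toy against hand-solved normal equations:
  # f = (1,2,3) on TIV = (1,1,2): slope = cov/var = (1/3)/(2/9) = 1.5,
  # intercept = 2 - 1.5 * 4/3 = 0; fitted = (1.5, 1.5, 3),
  # residuals = (-0.5, 0.5, 0)
  ds3 <- new_dataset(cbind(f = c(1, 2, 3)), c(0, 0, 0), task = "regression",
                     covariates = cbind(TIV = c(1, 1, 2)))
  r3 <- residualize_covariates(ds3)
  expect_equal(unname(r3$X[, "f"]), c(-0.5, 0.5, 0), tolerance = 1e-10)

  # idempotence given the same split
  ds4 <- simulate_dataset(sim_config(n = 60, m = 5, seed = 2))
  sp <- make_split(ds4, split_config(seed = 1))
  once <- residualize_covariates(ds4, sp)
  # re-attach the covariate to apply the operation again
  again <- residualize_covariates(
    new_dataset(once$X, once$y, task = "regression",
                covariates = ds4$covariates), sp)
  expect_lt(max(abs(again$X - once$X)), 1e-8)

  # rank-deficient covariates are fatal
  ds5 <- new_dataset(cbind(f = rnorm(20)), rnorm(20), task = "regression",
                     covariates = cbind(a = 1:20, b = 2 * (1:20)))
  expect_error(residualize_covariates(ds5), "rank-deficient")
})

test_that("dataset invariants are enforced at construction", {
  X <- matrix(1:12, 4, 3)
  expect_error(new_dataset(X, 1:3, task = "regression"), "y length")
  expect_error(new_dataset(X, 1:4, feature_names = c("a", "a", "b"),
                           task = "regression"), "duplicate")
  expect_error(new_dataset(X, factor(rep("only", 4)),
                           task = "classification"), "2 distinct")
  Xna <- X; Xna[2, 2] <- NA
  expect_error(new_dataset(Xna, 1:4, task = "regression"), "missing")
  s <- dataset_summary(toy_classification())
  expect_equal(s$task, "classification")
  expect_named(s$class_counts, c("a", "b"))
})
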