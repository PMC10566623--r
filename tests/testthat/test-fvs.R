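# Forward-selection engine: greedy rule, stopping rule, candidate scoring
# purity, worker-queue partitioning, parallel determinism.

ridge_grid <- list(alpha = c(0.01, 1, 100))

test_that("an exact-copy feature is selected first", {
  set.seed(20)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 3]                       # f3 duplicates the target
  ds <- new_dataset(X, y, task = "regression")
  tr <- forward_select(ds, fvs_config("ridge", n_selected_features = 1,
                                      master_seed = 1,
                                      param_space = ridge_grid))
  expect_identical(selected_features(tr)[1], "f3")
  expect_lt(tr$score[1], 1e-4)

  # brute force: f3 uniquely minimizes single-feature test MSE
  split <- make_split(ds, split_config(seed = derive_seed(1, "split", 1L)))
  folds <- make_cv_folds(length(split$train_idx), 5,
                         derive_seed(1, "folds", 1L))
  scores <- vapply(colnames(X), function(f)
    oracle_ridge_score(X, y, f, split$train_idx, split$test_idx, folds,
                       ridge_grid$alpha), 0)
  expect_identical(names(which.min(scores)), "f3")
})

test_that("the cap stops selection with stop_reason cap_reached", {
  ds <- simulate_dataset(sim_config(n = 100, m = 6, k = 4, effect = 3,
                                    seed = 21))
  tr <- forward_select(ds, fvs_config("ridge", n_selected_features = 2,
                                      master_seed = 2,
                                      param_space = ridge_grid))
  expect_lte(nrow(tr), 2)
  expect_identical(attr(tr, "stop_reason"), "cap_reached")
  expect_error(fvs_config("ridge", n_selected_features = 0), ">= 1")
})

test_that("pure-noise features stop selection; stopping is oracle-verified", {
  set.seed(22)
  n <- 80; m <- 6
  X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("f", 1:m)))
  y <- rnorm(n)
  ds <- new_dataset(X, y, task = "regression")
  cfg <- fvs_config("ridge", improvement_tol = 0, master_seed = 5,
                    resplit_each_iteration = FALSE,
                    param_space = ridge_grid)
  tr <- forward_select(ds, cfg)
  expect_identical(attr(tr, "stop_reason"), "no_improvement")
  expect_lt(nrow(tr), m)

  # at the stopping iteration, no remaining candidate beats the baseline:
  # rescore every candidate with the package's own scorer at the same seeds
  t_stop <- nrow(tr) + 1L
  sel <- selected_features(tr)
  split <- make_split(ds, split_config(seed = derive_seed(5, "split", 1L)))
  folds <- make_cv_folds(length(split$train_idx), 5,
                         derive_seed(5, "folds", 1L))  # fixed-split mode
  spec <- model_spec("ridge", "regression", ridge_grid, "grid")
  baseline <- score_candidate(ds, sel[-length(sel)], sel[length(sel)], spec,
                              split, seed = derive_seed(5, "base", t_stop),
                              folds = folds)$score
  for (f in setdiff(colnames(X), sel)) {
    j <- match(f, colnames(X))
    sc <- score_candidate(ds, sel, f, spec, split,
                          seed = derive_seed(5, "cand", t_stop, j),
                          folds = folds)$score
    expect_gte(sc, baseline)
  }
})

test_that("score_candidate is a pure, order-invariant function", {
  ds <- toy_regression(n = 60, m = 5)
  spec <- model_spec("ridge", "regression", ridge_grid, "grid")
  split <- make_split(ds, split_config(seed = 3))
  a <- score_candidate(ds, c("f1", "f4"), "f2", spec, split, seed = 9)
  b <- score_candidate(ds, c("f4", "f1"), "f2", spec, split, seed = 9)
  expect_identical(a$score, b$score)
  expect_identical(a$params, b$params)
  expect_error(score_candidate(ds, c("f1"), "f1", spec, split, seed = 9),
               "already selected")

  # matches an independently coded split -> tune -> refit -> score pipeline
  folds <- make_cv_folds(length(split$train_idx), 5, derive_seed(9, "folds"))
  got <- score_candidate(ds, c("f1", "f4"), "f2", spec, split, seed = 9,
                         folds = folds)
  want <- oracle_ridge_score(ds$X, ds$y, c("f1", "f2", "f4"),
                             split$train_idx, split$test_idx, folds,
                             ridge_grid$alpha)
  expect_equal(got$score, want, tolerance = 1e-10)
})

test_that("partition_candidates balances disjoint exhaustive queues", {
  p <- partition_candidates(paste0("f", 1:10), 3, seed = 1)
  expect_length(p, 3)
  expect_setequal(sort(vapply(p, length, 0L)), c(3, 3, 4))
  expect_setequal(unlist(p), paste0("f", 1:10))
  expect_identical(partition_candidates(letters[1:4], 1, seed = 2)[[1]],
                   with_one <- partition_candidates(letters[1:4], 1, seed = 2)[[1]])
  expect_length(partition_candidates(character(0), 4, seed = 1), 0)
  # reproducible given seed
  expect_identical(partition_candidates(letters, 5, seed = 3),
                   partition_candidates(letters, 5, seed = 3))
})

test_that("traces are identical for any worker count", {
  ds <- simulate_dataset(sim_config(n = 80, m = 8, k = 2, effect = 2,
                                    seed = 23))
  t1 <- forward_select(ds, fvs_config("ridge", n_selected_features = 4,
                                      master_seed = 7, n_workers = 1,
                                      param_space = ridge_grid))
  t2 <- forward_select(ds, fvs_config("ridge", n_selected_features = 4,
                                      master_seed = 7, n_workers = 2,
                                      param_space = ridge_grid))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(selected_features(t1), selected_features(t2))
})

test_that("scores improve monotonically within iterations (fixed split)", {
  ds <- simulate_dataset(sim_config(n = 120, m = 10, k = 3, effect = 2,
                                    seed = 24))
  tr <- forward_select(ds, fvs_config("ridge", master_seed = 3,
                                      resplit_each_iteration = FALSE,
                                      param_space = ridge_grid))
  # fixed split: every accepted step strictly beats its baseline, and the
  # recorded score sequence itself is monotone for a loss criterion
  expect_true(all(tr$score < tr$baseline))
  expect_true(all(diff(tr$score) < 0) || nrow(tr) <= 1)
})

test_that("tune_every reuses parameters between retunes", {
  ds <- simulate_dataset(sim_config(n = 100, m = 8, k = 3, effect = 2,
                                    seed = 26))
  tr <- forward_select(ds, fvs_config("ridge", n_selected_features = 4,
                                      master_seed = 6, tune_every = 3L,
                                      param_space = ridge_grid))
  expect_gte(nrow(tr), 2)
  # iterations 2 and 3 reuse iteration 1's tuned parameters
  expect_identical(tr$params[2], tr$params[1])
})

test_that("classification selection supports accuracy and auc criteria", {
  ds <- simulate_dataset(sim_config(n = 120, m = 8, k = 2, effect = 3,
                                    task = "classification", seed = 25))
  nb_grid <- list(smoothing = c(1e-9, 1e-3))
  tacc <- forward_select(ds, fvs_config("naive_bayes",
                                        n_selected_features = 3,
                                        master_seed = 4,
                                        param_space = nb_grid))
  expect_identical(attr(tacc, "criterion"), "accuracy")
  expect_gte(nrow(tacc), 1)
  tauc <- forward_select(ds, fvs_config("naive_bayes",
                                        n_selected_features = 3,
                                        master_seed = 4, criterion = "auc",
                                        param_space = nb_grid))
  expect_identical(attr(tauc, "criterion"), "auc")
  expect_true(all(tauc$score <= 1))
})
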