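# Oracle checks for the estimator backends that are implemented in this
# package (closed-form ridge, LARS, the CART engine, boosting, naive
# Bayes); glmnet-backed families are covered through the zoo smoke tests.

test_that("ridge matches the regularized normal equations", {
  ds <- toy_regression(n = 50, seed = 2)
  for (lambda in c(0.1, 10)) {
    m <- fit_model("ridge", list(alpha = lambda), ds$X, ds$y,
                   task = "regression")
    o <- oracle_ridge_fit(ds$X, ds$y, lambda)
    expect_equal(predict(m, ds$X)$value, o$predict(ds$X), tolerance = 1e-10)
  }
})

test_that("LassoLAR coefficients agree with glmnet along the path", {
  set.seed(4)
  X <- matrix(rnorm(120 * 8), 120, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- X[, 1] - 2 * X[, 4] + 0.5 * X[, 6] + rnorm(120, sd = 0.4)
  for (alpha in c(0.3, 0.05, 0.005)) {
    m <- fit_model("lassolar", list(alpha = alpha), X, y, task = "regression")
    g <- glmnet::glmnet(X, y, alpha = 1, lambda = alpha, standardize = TRUE)
    expect_equal(m$fit$beta, as.numeric(coef(g))[-1], tolerance = 2e-3)
  }
})

test_that("LAR respects the nonzero-coefficient budget and reaches OLS", {
  set.seed(5)
  X <- matrix(rnorm(100 * 6), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 3 * X[, 2] - X[, 5] + rnorm(100, sd = 0.2)
  m1 <- fit_model("lar", list(n_nonzero_coefs = 1), X, y, task = "regression")
  expect_equal(sum(m1$fit$beta != 0), 1)
  expect_equal(which.max(abs(m1$fit$beta)), 2L)  # strongest predictor first

  mfull <- fit_model("lar", list(n_nonzero_coefs = 6), X, y,
                     task = "regression")
  ols <- lm(y ~ X)
  expect_equal(mfull$fit$beta, unname(coef(ols))[-1], tolerance = 1e-6)
})

test_that("CART finds the exhaustive best split on a tiny dataset", {
  # one clean threshold on f2 at 0.5 separates the classes
  X <- cbind(f1 = c(0.1, 0.9, 0.4, 0.6, 0.2, 0.8),
             f2 = c(0, 0, 0, 1, 1, 1))
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  m <- fit_model("decision_tree", list(max_depth = 1), X, y,
                 task = "classification")
  expect_equal(m$fit$tree$feature[1], 1L)        # 0-based: f2
  expect_equal(m$fit$tree$threshold[1], 0.5)
  expect_equal(as.character(predict(m, X)$class), as.character(y))

  # regression: leaf values are subset means
  yr <- c(1, 1, 1, 5, 5, 5)
  mr <- fit_model("decision_tree", list(max_depth = 1), X, yr,
                  task = "regression")
  expect_setequal(unique(predict(mr, X)$value), c(1, 5))
})

test_that("tree hyperparameters constrain growth", {
  set.seed(6)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- X[, 1] + rnorm(200, sd = 0.1)
  deep <- fit_model("decision_tree", list(max_depth = 0), X, y,
                    task = "regression")
  stump <- fit_model("decision_tree", list(max_depth = 1), X, y,
                     task = "regression")
  expect_lte(length(unique(cpp_leaves <- predict(stump, X)$value)), 2)
  expect_gt(length(unique(predict(deep, X)$value)), 10)
  big_leaf <- fit_model("decision_tree", list(min_samples_leaf = 50), X, y,
                        task = "regression")
  # every leaf must hold >= 50 of the 200 samples: at most 4 leaves
  expect_lte(length(unique(predict(big_leaf, X)$value)), 4)
})

test_that("forests are seed-deterministic and average out tree noise", {
  ds <- toy_regression(n = 150, m = 4, seed = 9)
  m1 <- fit_model("random_forest", list(n_trees = 30), ds$X, ds$y,
                  task = "regression", seed = 7)
  m2 <- fit_model("random_forest", list(n_trees = 30), ds$X, ds$y,
                  task = "regression", seed = 7)
  expect_identical(predict(m1, ds$X)$value, predict(m2, ds$X)$value)

  m3 <- fit_model("random_forest", list(n_trees = 30), ds$X, ds$y,
                  task = "regression", seed = 8)
  expect_false(identical(predict(m1, ds$X)$value, predict(m3, ds$X)$value))

  # impurity importance concentrates on the true drivers (f1, f3)
  imp <- m1$fit$importance
  expect_true(all(order(imp, decreasing = TRUE)[1:2] %in% c(1, 3)))
})

test_that("gradient boosting reduces training loss over stages", {
  # regression boosting backs the classification registry families; build
  # the spec directly since the regression registry does not list it
  ds <- toy_regression(n = 120, m = 4, seed = 10)
  gb_spec <- model_spec("gb", "regression", list(n_stages = c(5L, 80L)),
                        "grid", estimator_family = "gradient_boosting")
  short <- fit_model(gb_spec, list(n_stages = 5), ds$X, ds$y, seed = 1)
  long <- fit_model(gb_spec, list(n_stages = 80), ds$X, ds$y, seed = 1)
  mse_s <- mean((predict(short, ds$X)$value - ds$y)^2)
  mse_l <- mean((predict(long, ds$X)$value - ds$y)^2)
  expect_lt(mse_l, mse_s)

  # absolute loss variant trains too
  mabs <- fit_model(gb_spec, list(n_stages = 30, loss = "absolute"),
                    ds$X, ds$y, seed = 1)
  expect_lt(mean(abs(predict(mabs, ds$X)$value - ds$y)), mean(abs(ds$y - median(ds$y))))
})

test_that("naive Bayes posterior matches a hand computation", {
  # one feature, two classes with known means/variances
  X <- cbind(f = c(0, 0.2, -0.2, 4, 4.2, 3.8))
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  m <- fit_model("naive_bayes", list(smoothing = 0), X, y,
                 task = "classification")
  mu <- c(0, 4); v <- rep(mean(c(0.2^2 + 0.2^2) * 1 / 3), 2) # population var
  x0 <- 1
  ll <- dnorm(x0, mu, sqrt(v), log = TRUE) + log(0.5)
  post <- exp(ll) / sum(exp(ll))
  p <- predict(m, cbind(f = x0))
  expect_equal(as.numeric(p$prob), post, tolerance = 1e-8)
})

test_that("kernel machines interpolate in the low-regularization limit", {
  set.seed(12)
  X <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- sin(3 * X[, 1])
  m <- fit_model("kernel_ridge",
                 list(kernel = "gaussian", alpha = 1e-8, gamma = 1),
                 X, y, task = "regression")
  expect_lt(mean((predict(m, X)$value - y)^2), 1e-8)
  # gp with noise behaves like smoothed kernel ridge
  g <- fit_model("gaussian_process",
                 list(kernel = "gaussian", length_scale = 1, noise = 0.01),
                 X, y, task = "regression")
  expect_lt(mean((predict(g, X)$value - y)^2), 1e-2)
})
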