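# Model zoo: registry of estimator families, default hyperparameter
# spaces, search-strategy assignment, and the fit/predict dispatch.
#
# Search-strategy convention: exhaustive grid search for families with a
# small parameter space (shrinkage-penalised linear models, kernel ridge,
# Gaussian process, logistic elastic-net, naive Bayes); random search for
# the many-parameter families (trees, forests, boosting, SGD).

.shrinkage_grid <- 10^seq(-4, 4)                 # 9 log-spaced points
.lambda_grid <- 10^seq(-3, 1)                    # glmnet-style penalties
.tree_depths <- c(2L, 4L, 8L, 16L, 0L)           # 0 = unlimited
.tree_counts <- c(50L, 100L, 250L, 500L)

.tree_space <- function(task) {
  sp <- list(
    max_depth = .tree_depths,
    min_samples_split = c(2L, 5L, 10L, 20L),
    min_samples_leaf = c(1L, 2L, 5L, 10L),
    splitter = c("best", "random"),
    max_features = list("all", "sqrt", "log2", 0.5))
  sp$criterion <- if (task == "classification") c("gini", "entropy")
                  else "variance"
  sp
}

.boost_space <- function(task) {
  list(loss = if (task == "regression") c("squared", "absolute") else "deviance",
       criterion = "variance",
       n_stages = c(50L, 100L, 200L),
       learning_rate = c(0.05, 0.1, 0.2),
       max_depth = c(2L, 3L, 4L),
       min_samples_leaf = c(1L, 5L))
}

.zoo_table <- function() {
  reg <- list(
    ridge = list(strategy = "grid",
                 space = list(alpha = .shrinkage_grid)),
    lasso = list(strategy = "grid",
                 space = list(alpha = .lambda_grid)),
    kernel_ridge = list(strategy = "grid",
                        space = list(kernel = c("linear", "laplacian",
                                                "gaussian", "sigmoid"),
                                     alpha = 10^seq(-2, 2),
                                     gamma = c(0.01, 0.1, 1))),
    multitask_lasso = list(strategy = "grid",
                           space = list(alpha = .lambda_grid)),
    lar = list(strategy = "grid",
               space = list(n_nonzero_coefs = c(1L, 2L, 4L, 8L, 16L, 32L,
                                                64L, 128L, 246L))),
    lassolar = list(strategy = "grid",
                    space = list(alpha = .lambda_grid)),
    elastic_net = list(strategy = "grid",
                       space = list(alpha = .lambda_grid,
                                    l1_ratio = c(0.1, 0.3, 0.5, 0.7, 0.9))),
    sgd_regressor = list(strategy = "random",
                         space = list(loss = c("squared", "huber"),
                                      penalty = c("l2", "l1", "elasticnet"),
                                      alpha = 10^seq(-5, -1),
                                      learning_rate = c("constant", "invscaling"),
                                      eta0 = c(0.001, 0.01, 0.1))),
    decision_tree = list(strategy = "random",
                         space = .tree_space("regression")),
    random_forest = list(strategy = "random",
                         space = c(.tree_space("regression")[
                                     c("max_depth", "min_samples_split",
                                       "min_samples_leaf", "max_features",
                                       "criterion")],
                                   list(n_trees = .tree_counts))),
    gaussian_process = list(strategy = "grid",
                            space = list(kernel = c("gaussian", "laplacian"),
                                         length_scale = c(0.1, 1, 10),
                                         noise = c(0.01, 0.1, 1))))
  clf_tree <- .tree_space("classification")
  clf <- list(
    decision_tree = list(strategy = "random", space = clf_tree),
    random_forest = list(strategy = "random",
                         space = c(clf_tree[c("max_depth", "min_samples_split",
                                              "min_samples_leaf", "max_features",
                                              "criterion")],
                                   list(n_trees = .tree_counts))),
    gradient_boosting = list(strategy = "random",
                             space = .boost_space("classification")),
    extreme_gradient_boosting = list(strategy = "random",
                                     space = c(.boost_space("classification"),
                                               list(n_parallel_trees = c(1L, 2L, 4L)))),
    extremely_randomized_trees = list(strategy = "random",
                                      space = c(clf_tree[c("max_depth",
                                                           "min_samples_split",
                                                           "min_samples_leaf",
                                                           "max_features",
                                                           "criterion")],
                                                list(n_trees = .tree_counts))),
    logistic_l1 = list(strategy = "grid",
                       space = list(l1_ratio = c(0, 0.25, 0.5, 0.75, 1),
                                    alpha = 10^seq(-3, 1))),
    naive_bayes = list(strategy = "grid",
                       space = list(smoothing = 10^seq(-10, -2))))
  list(regression = reg, classification = clf)
}

#' Build a model specification
#'
#' @param name unique model key within a task.
#' @param task `"regression"` or `"classification"`.
#' @param param_space named list; each entry a vector/list of candidate
#'   values (grid strategy requires finite lists).
#' @param search_strategy `"grid"` or `"random"`.
#' @param n_random_draws configurations sampled per tuning call under the
#'   random strategy.
#' @param estimator_family internal estimator key (defaults to `name`).
#' @return a `model_spec` object.
#' @export
model_spec <- function(name, task, param_space, search_strategy = "grid",
                       n_random_draws = 50L, estimator_family = name) {
  stopifnot(search_strategy %in% c("grid", "random"),
            task %in% c("regression", "classification"))
  if (search_strategy == "grid") {
    sizes <- vapply(param_space, length, 0L)
    if (prod(sizes) > 10000)
      stopf("grid for '%s' has %d combinations (> 10000)", name, prod(sizes))
  }
  structure(list(name = name, task = task, param_space = param_space,
                 search_strategy = search_strategy,
                 n_random_draws = as.integer(n_random_draws),
                 estimator_family = estimator_family),
            class = "model_spec")
}

#' Model registry
#'
#' Returns the default zoo: 11 regression families (ridge, lasso, kernel
#' ridge, multitask lasso, LAR, LassoLAR, elastic net, SGD regressor,
#' decision tree, random forest, Gaussian process) or 7 classification
#' families (decision tree, random forest, gradient boosting, extreme
#' gradient boosting, extremely randomized trees, elastic-net logistic
#' regression, naive Bayes). The registry is extensible: `config` may
#' override any model's `param_space`, `search_strategy` or
#' `n_random_draws`, or add new entries backed by an existing
#' `estimator_family`.
#'
#' @param task `"regression"` or `"classification"`.
#' @param config optional named list (or path to a JSON file) of overrides,
#'   e.g. `list(ridge = list(param_space = list(alpha = c(0.1, 1))))`.
#' @return named list of [model_spec()] objects.
#' @export
registry <- function(task = c("regression", "classification"), config = NULL) {
  task <- match.arg(task)
  tab <- .zoo_table()[[task]]
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  specs <- lapply(names(tab), function(nm)
    model_spec(nm, task, tab[[nm]]$space, tab[[nm]]$strategy))
  names(specs) <- names(tab)
  for (nm in names(config %||% list())) {
    ov <- config[[nm]]
    base <- if (nm %in% names(specs)) specs[[nm]] else NULL
    fam <- ov$estimator_family %||% (base$estimator_family %||% nm)
    if (!fam %in% names(.zoo_table()[[task]]))
      stopf("unknown estimator_family '%s' for registry entry '%s'", fam, nm)
    specs[[nm]] <- model_spec(
      nm, task,
      param_space = ov$param_space %||% base$param_space,
      search_strategy = ov$search_strategy %||% base$search_strategy,
      n_random_draws = ov$n_random_draws %||% base$n_random_draws %||% 50L,
      estimator_family = fam)
  }
  specs
}

#' Default hyperparameter space of a zoo model
#'
#' @param name model key, e.g. `"kernel_ridge"`.
#' @param task `"regression"` or `"classification"`.
#' @return named list of candidate values per tuned parameter.
#' @export
default_param_space <- function(name, task = c("regression", "classification")) {
  task <- match.arg(task)
  tab <- .zoo_table()[[task]]
  if (!name %in% names(tab))
    stopf("unknown model '%s' for task %s", name, task)
  tab[[name]]$space
}

# ---- fit / predict dispatch ----------------------------------------------

.fit_dispatch <- list(
  ridge = function(X, y, p, s, cl) fit_ridge(X, y, p, s),
  lasso = function(X, y, p, s, cl) fit_lasso(X, y, p, s),
  elastic_net = function(X, y, p, s, cl) fit_elastic_net(X, y, p, s),
  multitask_lasso = function(X, y, p, s, cl) fit_multitask_lasso(X, y, p, s),
  lar = function(X, y, p, s, cl) fit_lar(X, y, p, s),
  lassolar = function(X, y, p, s, cl) fit_lassolar(X, y, p, s),
  sgd_regressor = function(X, y, p, s, cl) fit_sgd(X, y, p, s),
  kernel_ridge = function(X, y, p, s, cl) fit_kernel_ridge(X, y, p, s),
  gaussian_process = function(X, y, p, s, cl) fit_gaussian_process(X, y, p, s),
  decision_tree = function(X, y, p, s, cl) fit_decision_tree(X, y, p, s, cl),
  random_forest = function(X, y, p, s, cl) fit_random_forest(X, y, p, s, cl),
  extremely_randomized_trees = function(X, y, p, s, cl) fit_extra_trees(X, y, p, s, cl),
  gradient_boosting = function(X, y, p, s, cl) fit_gboost(X, y, p, s, cl),
  extreme_gradient_boosting = function(X, y, p, s, cl)
    fit_gboost(X, y, p, s, cl, extreme = TRUE),
  logistic_l1 = function(X, y, p, s, cl) fit_logistic_l1(X, y, p, s, cl),
  naive_bayes = function(X, y, p, s, cl) fit_naive_bayes(X, y, p, s, cl))

.predict_dispatch <- list(
  ridge = predict_ridge, glmnet_reg = predict_glmnet_reg,
  glmnet_mtl = predict_glmnet_mtl, lars = predict_lars, sgd = predict_sgd,
  kernel_machine = predict_kernel_machine, cart = predict_cart,
  forest = predict_forest, gboost = predict_gboost,
  gboost_ovr = predict_gboost_ovr, logistic_l1 = predict_logistic_l1,
  naive_bayes = predict_naive_bayes)

#' Fit one zoo model with a fixed hyperparameter assignment
#'
#' @param spec a [model_spec()] (or a model name resolvable in the default
#'   registry for `task`).
#' @param params named list of hyperparameter values.
#' @param X numeric training matrix.
#' @param y training target.
#' @param seed integer seed for stochastic estimators.
#' @param task needed only when `spec` is given by name.
#' @return a `fvs_model` with a `predict()` method. Regression predictions
#'   are numeric vectors wrapped as `list(value = ...)`; classification
#'   predictions carry `class` labels and a per-class `prob` matrix.
#' @export
fit_model <- function(spec, params, X, y, seed = 1L, task = NULL) {
  if (is.character(spec)) {
    stopifnot(!is.null(task))
    spec <- registry(task)[[spec]] %||% stopf("unknown model '%s'", spec)
  }
  classes <- if (spec$task == "classification")
    levels(factor(y)) else NULL
  X <- as.matrix(X)
  fn <- .fit_dispatch[[spec$estimator_family]] %||%
    stopf("no estimator for family '%s'", spec$estimator_family)
  fit <- fn(X, y, params, as.integer(seed), classes)
  structure(list(spec = spec, params = params, fit = fit,
                 task = spec$task, classes = classes,
                 feature_names = colnames(X), n_features = ncol(X)),
            class = "fvs_model")
}

#' @export
predict.fvs_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  raw <- .predict_dispatch[[object$fit$kind]](object$fit, newdata)
  if (object$task == "regression") {
    stopifnot(length(raw) == nrow(newdata))
    return(list(value = raw))
  }
  prob <- raw
  cls <- object$classes[max.col(prob, ties.method = "first")]
  stopifnot(length(cls) == nrow(newdata))
  list(class = factor(cls, levels = object$classes), prob = prob)
}

# impurity importance if the estimator provides one (forests, trees)
model_importance <- function(model) model$fit$importance %||% NULL
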