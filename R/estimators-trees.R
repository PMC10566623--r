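# Tree-based estimators on top of the internal CART engine (src/cart.cpp):
# single decision trees, random forests, extremely randomized trees, and
# gradient boosting (plain and the "extreme" variant with parallel trees
# per boosting stage).

.crit_code <- function(criterion, task) {
  if (task == "regression") return(0L)           # variance
  switch(criterion %||% "gini", gini = 1L, entropy = 2L,
         stopf("unknown split criterion '%s'", criterion))
}

.splitter_code <- function(splitter) {
  switch(splitter %||% "best", best = 0L, random = 1L,
         stopf("unknown splitter '%s'", splitter))
}

# max_features spec: "all", "sqrt", "log2", a fraction in (0,1), or a count
resolve_max_features <- function(mf, p) {
  if (is.null(mf) || identical(mf, "all")) return(0L)
  if (identical(mf, "sqrt")) return(max(1L, as.integer(ceiling(sqrt(p)))))
  if (identical(mf, "log2")) return(max(1L, as.integer(ceiling(log2(p)))))
  mf <- as.numeric(mf)
  if (mf <= 0) return(0L)
  if (mf < 1) return(max(1L, as.integer(round(mf * p))))
  as.integer(min(mf, p))
}

.tree_args <- function(params, p, task) {
  list(criterion = .crit_code(params$criterion, task),
       max_depth = as.integer(params$max_depth %||% 0L),
       min_split = as.integer(params$min_samples_split %||% 2L),
       min_leaf = as.integer(params$min_samples_leaf %||% 1L),
       max_features = resolve_max_features(params$max_features, p))
}

.class_codes <- function(y, classes) {
  as.numeric(match(as.character(y), classes) - 1L)
}

fit_decision_tree <- function(X, y, params, seed, classes = NULL) {
  task <- if (is.null(classes)) "regression" else "classification"
  a <- .tree_args(params, ncol(X), task)
  yv <- if (is.null(classes)) as.numeric(y) else .class_codes(y, classes)
  tree <- cpp_cart_fit(X, yv, length(classes %||% character(0)),
                       a$criterion, a$max_depth, a$min_split, a$min_leaf,
                       a$max_features, .splitter_code(params$splitter), seed)
  list(kind = "cart", tree = tree, classes = classes,
       importance = .norm_importance(tree$importance))
}

predict_cart <- function(fit, X) {
  out <- cpp_cart_predict(fit$tree, X)
  if (is.null(fit$classes)) as.numeric(out[, 1])
  else { colnames(out) <- fit$classes; out }
}

.norm_importance <- function(imp) {
  s <- sum(imp)
  if (s > 0) imp / s else imp
}

.forest_fit <- function(X, y, params, seed, classes, splitter, bootstrap,
                        default_mtry, keep_inbag = FALSE) {
  task <- if (is.null(classes)) "regression" else "classification"
  a <- .tree_args(params, ncol(X), task)
  if (is.null(params$max_features))
    a$max_features <- resolve_max_features(default_mtry, ncol(X))
  yv <- if (is.null(classes)) as.numeric(y) else .class_codes(y, classes)
  f <- cpp_forest_fit(X, yv, length(classes %||% character(0)),
                      as.integer(params$n_trees %||% 100L),
                      a$criterion, a$max_depth, a$min_split, a$min_leaf,
                      a$max_features, .splitter_code(splitter), bootstrap,
                      seed, keep_inbag)
  list(kind = "forest", forest = f, classes = classes,
       importance = .norm_importance(f$importance))
}

# Breiman-style forest: bootstrap rows, random feature subset per split
fit_random_forest <- function(X, y, params, seed, classes = NULL) {
  mtry_default <- if (is.null(classes)) 1 / 3 else "sqrt"
  .forest_fit(X, y, params, seed, classes, splitter = "best",
              bootstrap = TRUE, default_mtry = mtry_default,
              keep_inbag = isTRUE(params$keep_inbag))
}

# extra trees: no bootstrap, random split thresholds
fit_extra_trees <- function(X, y, params, seed, classes = NULL) {
  mtry_default <- if (is.null(classes)) 1 / 3 else "sqrt"
  .forest_fit(X, y, params, seed, classes, splitter = "random",
              bootstrap = FALSE, default_mtry = mtry_default)
}

predict_forest <- function(fit, X) {
  out <- cpp_forest_predict(fit$forest$trees, X,
                            length(fit$classes %||% character(0)))
  if (is.null(fit$classes)) as.numeric(out[, 1])
  else { colnames(out) <- fit$classes; out }
}

# ---- gradient boosting ---------------------------------------------------

# One gradient tree: fit a variance-criterion regression tree to the
# gradient g, then recompute leaf values as sum(g)/sum(h) over the training
# rows in each leaf (h = 1 recovers leaf means; h = p(1-p) gives the Newton
# step for binomial deviance). `median_of` switches to leaf medians for the
# absolute-error loss line search.
fit_gradient_tree <- function(X, g, h, a, seed, median_of = NULL) {
  tree <- cpp_cart_fit(X, g, 0L, 0L, a$max_depth, a$min_split, a$min_leaf,
                       a$max_features, 0L, seed)
  leaves <- cpp_cart_apply(tree, X)
  ids <- sort(unique(leaves))
  leafval <- vapply(ids, function(l) {
    rows <- leaves == l
    if (!is.null(median_of)) stats::median(median_of[rows])
    else sum(g[rows]) / max(sum(h[rows]), 1e-12)
  }, 0)
  list(tree = tree, leaf_ids = ids, leafval = leafval)
}

predict_gradient_tree <- function(gt, X) {
  leaves <- cpp_cart_apply(gt$tree, X)
  gt$leafval[match(leaves, gt$leaf_ids)]
}

# Boosting stage with optional parallel trees: each parallel tree is grown
# on its own bootstrap resample of the stage gradients and their
# predictions averaged (the "extreme" gradient boosting parallel-tree
# option, a boosted random forest).
fit_boost_stage <- function(X, g, h, a, n_parallel, seed, median_of = NULL) {
  if (n_parallel <= 1)
    return(list(fit_gradient_tree(X, g, h, a, seed, median_of)))
  n <- nrow(X)
  lapply(seq_len(n_parallel), function(t) {
    rows <- with_seed(derive_seed(seed, "ptree", t), sample.int(n, n, replace = TRUE))
    gt <- fit_gradient_tree(X[rows, , drop = FALSE], g[rows], h[rows],
                            a, derive_seed(seed, "pfit", t),
                            if (is.null(median_of)) NULL else median_of[rows])
    gt
  })
}

predict_boost_stage <- function(stage, X) {
  preds <- lapply(stage, function(gt) predict_gradient_tree(gt, X))
  rowMeans(do.call(cbind, preds))
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

# shared boosting loop; `extreme` adds the parallel-tree count parameter
fit_gboost <- function(X, y, params, seed, classes = NULL, extreme = FALSE) {
  task <- if (is.null(classes)) "regression" else "classification"
  # stage trees are always variance-criterion regression trees on gradients
  a <- .tree_args(params[setdiff(names(params), "criterion")], ncol(X),
                  "regression")
  if (is.null(params$max_depth)) a$max_depth <- 3L
  n_stages <- as.integer(params$n_stages %||% 100L)
  lr <- params$learning_rate %||% 0.1
  np <- if (extreme) as.integer(params$n_parallel_trees %||% 1L) else 1L
  n <- nrow(X)

  if (task == "regression") {
    loss <- params$loss %||% "squared"
    F0 <- if (loss == "absolute") stats::median(y) else mean(y)
    Fc <- rep(F0, n)
    stages <- vector("list", n_stages)
    for (s in seq_len(n_stages)) {
      r <- y - Fc
      g <- if (loss == "absolute") sign(r) else r
      med <- if (loss == "absolute") r else NULL
      st <- fit_boost_stage(X, g, rep(1, n), a, np,
                            derive_seed(seed, "stage", s), med)
      stages[[s]] <- st
      Fc <- Fc + lr * predict_boost_stage(st, X)
    }
    return(list(kind = "gboost", task = task, F0 = F0, lr = lr,
                stages = stages, classes = NULL))
  }

  K <- length(classes)
  yc <- match(as.character(y), classes)
  if (K == 2) {
    y01 <- as.numeric(yc == 2)
    pbar <- min(max(mean(y01), 1e-6), 1 - 1e-6)
    F0 <- log(pbar / (1 - pbar))
    Fc <- rep(F0, n)
    stages <- vector("list", n_stages)
    for (s in seq_len(n_stages)) {
      p <- sigmoid(Fc)
      st <- fit_boost_stage(X, y01 - p, p * (1 - p), a, np,
                            derive_seed(seed, "stage", s))
      stages[[s]] <- st
      Fc <- Fc + lr * predict_boost_stage(st, X)
    }
    return(list(kind = "gboost", task = task, F0 = F0, lr = lr,
                stages = stages, classes = classes))
  }
  # multiclass: one-vs-rest binomial boosters, probabilities renormalized
  boosters <- lapply(seq_len(K), function(k) {
    yk <- factor(ifelse(yc == k, "pos", "neg"), levels = c("neg", "pos"))
    fit_gboost(X, yk, params, derive_seed(seed, "ovr", k),
               classes = c("neg", "pos"), extreme = extreme)
  })
  list(kind = "gboost_ovr", task = task, boosters = boosters,
       classes = classes)
}

predict_gboost <- function(fit, X) {
  Fc <- rep(fit$F0, nrow(X))
  for (st in fit$stages) Fc <- Fc + fit$lr * predict_boost_stage(st, X)
  if (fit$task == "regression") return(as.numeric(Fc))
  p <- sigmoid(Fc)
  prob <- cbind(1 - p, p)
  colnames(prob) <- fit$classes
  prob
}

predict_gboost_ovr <- function(fit, X) {
  scores <- vapply(fit$boosters,
                   function(b) predict_gboost(b, X)[, "pos"],
                   numeric(nrow(X)))
  prob <- scores / pmax(rowSums(scores), 1e-12)
  colnames(prob) <- fit$classes
  prob
}

# ---- permutation importance (out-of-bag) ---------------------------------

# OOB permutation importance for a bootstrap forest fit with keep_inbag:
# per tree, score its out-of-bag rows before and after permuting one
# feature; the mean drop across trees is the importance.
rf_permutation_importance <- function(fit, X, y, seed = 1L) {
  if (is.null(fit$forest$inbag)) stopf("forest was fit without keep_inbag")
  inbag <- fit$forest$inbag
  trees <- fit$forest$trees
  K <- length(fit$classes %||% character(0))
  p <- ncol(X)
  imp <- numeric(p)
  yv <- if (K > 0) match(as.character(y), fit$classes) else as.numeric(y)
  score <- function(pred, truth) {
    if (K > 0) mean(max.col(pred, ties.method = "first") == truth)
    else -mean((pred[, 1] - truth)^2)
  }
  for (t in seq_along(trees)) {
    oob <- which(inbag[, t] == 0)
    if (length(oob) < 2) next
    Xo <- X[oob, , drop = FALSE]
    base <- score(cpp_cart_predict(trees[[t]], Xo), yv[oob])
    for (j in seq_len(p)) {
      Xp <- Xo
      Xp[, j] <- with_seed(derive_seed(seed, t, j),
                           sample(Xp[, j]))
      imp[j] <- imp[j] + (base - score(cpp_cart_predict(trees[[t]], Xp), yv[oob]))
    }
  }
  imp / length(trees)
}
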