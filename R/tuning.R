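# Hyperparameter optimization: grid or random search with k-fold
# cross-validation on the training rows.

#' Assign cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment; stratified by class
#' when requested. Shared fold vectors let callers pair tuning calls
#' across candidates.
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param seed integer seed.
#' @param y optional class labels for stratification.
#' @param stratified preserve class balance across folds.
#' @return integer vector of fold ids in `1..k`, length `n`.
#' @export
make_cv_folds <- function(n, k, seed, y = NULL, stratified = FALSE) {
  if (n < k) stopf("need n >= cv_folds, got n = %d, k = %d", n, k)
  if (stratified && !is.null(y)) {
    folds <- integer(n)
    with_seed(seed, {
      for (idx in split(seq_len(n), y)) {
        idx <- sample(idx)
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    folds
  } else {
    ord <- with_seed(seed, sample.int(n))
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  }
}

# deterministic enumeration of a finite grid: last parameter varies fastest
expand_param_grid <- function(param_space) {
  if (!length(param_space)) return(list(list()))
  sizes <- vapply(param_space, length, 0L)
  if (any(sizes == 0)) stopf("empty parameter dimension")
  idx <- expand.grid(rev(lapply(sizes, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(sizes)), drop = FALSE]
  names(idx) <- names(param_space)
  lapply(seq_len(nrow(idx)), function(r) {
    cfg <- lapply(names(param_space), function(p)
      param_space[[p]][[idx[r, p]]])
    names(cfg) <- names(param_space)
    cfg
  })
}

#' Draw random hyperparameter configurations
#'
#' Each draw picks one value per parameter independently and uniformly from
#' its candidate list (or uniformly within a `range(lo, hi)` bound);
#' duplicates are allowed.
#'
#' @param param_space named list: each entry a vector/list of candidate
#'   values, or a length-2 numeric `c(lo, hi)` wrapped in
#'   `structure(..., sampling = "uniform")` for a continuous bound.
#' @param n_draws number of configurations.
#' @param seed integer seed; fixed seed gives an identical list.
#' @return list of named parameter assignments.
#' @export
draw_random_configs <- function(param_space, n_draws, seed) {
  if (!length(param_space)) stopf("empty parameter space")
  if (n_draws < 1) stopf("n_draws must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      cfg <- lapply(param_space, function(vals) {
        if (identical(attr(vals, "sampling"), "uniform")) {
          stats::runif(1, vals[1], vals[2])
        } else {
          vals[[sample.int(length(vals), 1)]]
        }
      })
      names(cfg) <- names(param_space)
      cfg
    })
  })
}

#' Tune one model by cross-validated grid or random search
#'
#' Enumerates configurations (exhaustively for the grid strategy, by
#' [draw_random_configs()] for the random strategy), scores each by k-fold
#' cross-validation on `X_train`, and returns the optimizer. Folds are
#' fixed across configurations within one call, so comparisons are paired.
#' A configuration that fails on any fold is scored as worst-possible and
#' logged, never fatal; only all configurations failing aborts.
#'
#' @param spec a [model_spec()].
#' @param X_train,y_train training rows.
#' @param cv_folds folds (default 5).
#' @param seed integer; drives fold assignment, random draws and stochastic
#'   fits. Ties are broken by the first-encountered configuration in the
#'   deterministic enumeration order.
#' @param criterion `"mse"` (regression default), `"mae"`, `"accuracy"`
#'   (classification default) or `"auc"`.
#' @param folds optional precomputed integer fold ids (overrides `seed` for
#'   fold assignment; used to pair tuning calls across candidates).
#' @return list with `best_params`, `best_cv_score`, `n_configs_evaluated`,
#'   `per_config_scores` (data.frame of parameters and mean CV score).
#' @export
tune <- function(spec, X_train, y_train, cv_folds = 5L, seed = 1L,
                 criterion = NULL, folds = NULL) {
  criterion <- criterion %||%
    (if (spec$task == "regression") "mse" else "accuracy")
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (is.null(folds))
    folds <- make_cv_folds(n, cv_folds, derive_seed(seed, "folds"),
                           y = y_train,
                           stratified = spec$task == "classification")
  k <- max(folds)
  configs <- if (spec$search_strategy == "grid") {
    expand_param_grid(spec$param_space)
  } else {
    draw_random_configs(spec$param_space, spec$n_random_draws,
                        derive_seed(seed, "draws"))
  }

  score_config <- function(cfg, ci) {
    fold_scores <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      res <- tryCatch({
        m <- fit_model(spec, cfg, X_train[tr, , drop = FALSE], y_train[tr],
                       seed = derive_seed(seed, "fit", ci, f))
        pred <- predict(m, X_train[!tr, , drop = FALSE])
        score_predictions(y_train[!tr], pred, criterion)
      }, error = function(e) e)
      if (inherits(res, "condition") || is.na(res)) {
        message(sprintf("tune[%s]: config %d failed on fold %d (%s); scored as worst",
                        spec$name, ci, f,
                        if (inherits(res, "condition")) conditionMessage(res) else "NA score"))
        return(worst_score(criterion))
      }
      fold_scores[f] <- res
    }
    mean(fold_scores)
  }

  scores <- vapply(seq_along(configs),
                   function(ci) score_config(configs[[ci]], ci), 0)
  if (all(!is.finite(scores)))
    stopf("tune[%s]: every configuration failed", spec$name)
  best_i <- if (is_loss_criterion(criterion)) which.min(scores) else which.max(scores)

  per_config <- data.frame(
    config = seq_along(configs),
    score = scores,
    params = vapply(configs, function(cfg)
      paste(sprintf("%s=%s", names(cfg), vapply(cfg, format, "")),
            collapse = ";"), ""),
    stringsAsFactors = FALSE)

  list(best_params = configs[[best_i]],
       best_cv_score = scores[best_i],
       n_configs_evaluated = length(configs),
       per_config_scores = per_config,
       criterion = criterion,
       folds = folds)
}
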