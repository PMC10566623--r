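# Stage 2: greedy forward variable selection. Each iteration draws (or
# reuses) a 70/30 split, scores every remaining candidate feature by
# CV-tuning + refit + held-out evaluation on the columns selected-so-far
# plus the candidate, and appends the best candidate if it improves on the
# selected set alone by more than the tolerance.

#' Forward-selection configuration
#'
#' @param model_name zoo model key driving the selection.
#' @param n_selected_features cap on selected features (default `Inf`,
#'   i.e. all available features).
#' @param improvement_tol minimum improvement to continue (default 0: any
#'   strict improvement).
#' @param resplit_each_iteration draw a fresh 70/30 split per iteration
#'   (default TRUE, the canonical mode); FALSE fixes one split, which
#'   makes the whole trace comparable on a single held-out set.
#' @param master_seed integer; every split, fold assignment and stochastic
#'   fit derives its seed from this.
#' @param n_workers parallel workers for candidate evaluation. Results are
#'   identical for any worker count: per-candidate seeds derive from
#'   (master_seed, iteration, feature index), never from worker identity.
#' @param cv_folds tuning folds (default 5).
#' @param criterion `"mse"` (regression) or `"accuracy"`/`"auc"`
#'   (classification); default by task.
#' @param train_fraction per-iteration train fraction (default 0.7).
#' @param tune_every retune hyperparameters every k-th iteration (default
#'   1 = every iteration, the canonical cadence); between retunes the last tuned
#'   assignment is reused.
#' @param param_space optional override of the model's tuning space.
#' @param keep_candidate_scores keep the per-candidate score table of every
#'   iteration in the trace.
#' @return an `fvs_config` list.
#' @export
fvs_config <- function(model_name, n_selected_features = Inf,
                       improvement_tol = 0, resplit_each_iteration = TRUE,
                       master_seed = 1L, n_workers = 1L, cv_folds = 5L,
                       criterion = NULL, train_fraction = 0.7,
                       tune_every = 1L, param_space = NULL,
                       keep_candidate_scores = FALSE) {
  if (n_selected_features < 1) stopf("n_selected_features must be >= 1")
  stopifnot(improvement_tol >= 0, n_workers >= 1, tune_every >= 1)
  structure(list(model_name = model_name,
                 n_selected_features = n_selected_features,
                 improvement_tol = improvement_tol,
                 resplit_each_iteration = isTRUE(resplit_each_iteration),
                 master_seed = as.integer(master_seed),
                 n_workers = as.integer(n_workers),
                 cv_folds = as.integer(cv_folds),
                 criterion = criterion,
                 train_fraction = train_fraction,
                 tune_every = as.integer(tune_every),
                 param_space = param_space,
                 keep_candidate_scores = isTRUE(keep_candidate_scores)),
            class = "fvs_config")
}

#' Partition candidates into worker queues
#'
#' Shuffles the candidates with a seeded RNG and deals them round-robin
#' into `n_workers` disjoint subsets whose sizes differ by at most one.
#'
#' @param candidates vector of candidate identifiers.
#' @param n_workers number of queues.
#' @param seed integer seed.
#' @return list of disjoint subsets whose union is `candidates`.
#' @export
partition_candidates <- function(candidates, n_workers, seed = 1L) {
  if (n_workers < 1) stopf("n_workers must be >= 1")
  if (!length(candidates)) return(list())
  shuffled <- with_seed(seed, sample(candidates))
  k <- min(n_workers, length(shuffled))
  lapply(seq_len(k), function(w) shuffled[seq(w, length(shuffled), by = k)])
}

#' Score one candidate feature given a selected set
#'
#' Pure function of (dataset, selected, candidate, split, seed): tunes the
#' model by cross-validation on the training rows restricted to the columns
#' `selected + candidate`, refits the best configuration on all training
#' rows, and scores the test rows. Column order is canonicalized to dataset
#' order, so the result does not depend on the order of `selected`.
#'
#' @param dataset an `fvs_dataset`.
#' @param selected character vector of already-selected feature names.
#' @param candidate feature name not in `selected`.
#' @param spec a [model_spec()].
#' @param split a [make_split()] result.
#' @param seed integer seed for draws and stochastic fits.
#' @param cv_folds tuning folds.
#' @param criterion scoring criterion (see [fvs_config()]).
#' @param folds optional precomputed fold ids shared across candidates.
#' @param params optional fixed hyperparameters (skips tuning).
#' @return list with `score`, `params`, `cv_score`.
#' @export
score_candidate <- function(dataset, selected, candidate, spec, split,
                            seed = 1L, cv_folds = 5L, criterion = NULL,
                            folds = NULL, params = NULL) {
  if (candidate %in% selected) stopf("candidate already selected")
  criterion <- criterion %||%
    (if (dataset$task == "regression") "mse" else "accuracy")
  cols <- dataset$feature_names[dataset$feature_names %in% c(selected, candidate)]
  Xtr <- dataset$X[split$train_idx, cols, drop = FALSE]
  ytr <- dataset$y[split$train_idx]
  Xte <- dataset$X[split$test_idx, cols, drop = FALSE]
  yte <- dataset$y[split$test_idx]
  if (is.null(params)) {
    tr <- tune(spec, Xtr, ytr, cv_folds = cv_folds, seed = seed,
               criterion = criterion, folds = folds)
    params <- tr$best_params
    cv_score <- tr$best_cv_score
  } else {
    cv_score <- NA_real_
  }
  m <- fit_model(spec, params, Xtr, ytr, seed = derive_seed(seed, "refit"))
  pred <- predict(m, Xte)
  list(score = score_predictions(yte, pred, criterion),
       params = params, cv_score = cv_score)
}

#' Greedy forward variable selection
#'
#' @param dataset an `fvs_dataset` (residualize covariates first if
#'   needed).
#' @param config an [fvs_config()].
#' @param verbose log each iteration (chosen feature and score).
#' @return an `fvs_trace`: data.frame with one row per accepted feature
#'   (iteration, feature, score after inclusion, baseline score of the set
#'   without it, tuned parameters); attributes `selected` (character
#'   vector, in order), `stop_reason` (`"no_improvement"` or
#'   `"cap_reached"`), `criterion`, `model_name`, and optionally
#'   `candidate_scores`.
#' @export
forward_select <- function(dataset, config, verbose = FALSE) {
  spec <- registry(dataset$task)[[config$model_name]]
  if (is.null(spec))
    stopf("model '%s' not in the %s registry", config$model_name, dataset$task)
  if (!is.null(config$param_space))
    spec <- model_spec(spec$name, spec$task, config$param_space,
                       spec$search_strategy, spec$n_random_draws,
                       spec$estimator_family)
  if (nrow(dataset$X) < 10) stopf("need at least 10 samples")
  m <- ncol(dataset$X)
  cap <- min(config$n_selected_features, m)
  criterion <- config$criterion %||%
    (if (dataset$task == "regression") "mse" else "accuracy")
  stratified <- dataset$task == "classification"

  selected <- character(0)
  last_params <- NULL
  steps <- list()
  cand_tables <- list()
  stop_reason <- "cap_reached"

  fixed_split <- make_split(dataset, split_config(
    train_fraction = config$train_fraction, cv_folds = config$cv_folds,
    seed = derive_seed(config$master_seed, "split", 1L),
    stratified = stratified))

  for (t in seq_len(cap)) {
    split <- if (config$resplit_each_iteration && t > 1) {
      make_split(dataset, split_config(
        train_fraction = config$train_fraction, cv_folds = config$cv_folds,
        seed = derive_seed(config$master_seed, "split", t),
        stratified = stratified))
    } else fixed_split

    # with a fixed split the CV folds are fixed too, so the baseline
    # recomputation of the selected set reproduces the previous step's
    # score exactly and the recorded trace is strictly monotone
    fold_iter <- if (config$resplit_each_iteration) t else 1L
    folds <- make_cv_folds(length(split$train_idx), config$cv_folds,
                           derive_seed(config$master_seed, "folds", fold_iter),
                           y = dataset$y[split$train_idx],
                           stratified = stratified)
    retune <- ((t - 1L) %% config$tune_every) == 0L || is.null(last_params)

    # baseline: score of the selected set alone on this iteration's split;
    # the empty set scores worst-possible so the first feature is always
    # accepted
    baseline <- if (!length(selected)) {
      worst_score(criterion)
    } else {
      score_candidate(dataset, selected[-length(selected)],
                      selected[length(selected)], spec, split,
                      seed = derive_seed(config$master_seed, "base", t),
                      cv_folds = config$cv_folds, criterion = criterion,
                      folds = folds,
                      params = if (retune) NULL else last_params)$score
    }

    candidates <- setdiff(dataset$feature_names, selected)
    queues <- partition_candidates(candidates, config$n_workers,
                                   derive_seed(config$master_seed, "part", t))
    eval_queue <- function(queue) {
      lapply(queue, function(f) {
        j <- match(f, dataset$feature_names)
        res <- tryCatch(
          score_candidate(dataset, selected, f, spec, split,
                          seed = derive_seed(config$master_seed, "cand", t, j),
                          cv_folds = config$cv_folds, criterion = criterion,
                          folds = folds,
                          params = if (retune) NULL else last_params),
          error = function(e) {
            message(sprintf("forward_select: candidate '%s' failed (%s); scored as worst",
                            f, conditionMessage(e)))
            list(score = worst_score(criterion), params = NULL,
                 cv_score = NA_real_)
          })
        list(feature = f, idx = j, score = res$score, params = res$params)
      })
    }
    results <- if (config$n_workers > 1) {
      unlist(parallel::mclapply(queues, eval_queue,
                                mc.cores = config$n_workers),
             recursive = FALSE)
    } else {
      unlist(lapply(queues, eval_queue), recursive = FALSE)
    }
    idx <- vapply(results, `[[`, 0L, "idx")
    ord <- order(idx)                   # tie-break: lowest feature index
    results <- results[ord]
    scores <- vapply(results, `[[`, 0, "score")

    best_i <- if (is_loss_criterion(criterion)) which.min(scores) else which.max(scores)
    best <- results[[best_i]]
    if (config$keep_candidate_scores)
      cand_tables[[t]] <- data.frame(
        iteration = t,
        feature = vapply(results, `[[`, "", "feature"),
        score = scores, stringsAsFactors = FALSE)

    if (!better(best$score, baseline, criterion, config$improvement_tol)) {
      stop_reason <- "no_improvement"
      fvs_log(verbose, "fvs iter %d: no candidate improves on %.6g; stop",
              t, baseline)
      break
    }
    selected <- c(selected, best$feature)
    if (!is.null(best$params)) last_params <- best$params
    steps[[t]] <- data.frame(
      iteration = t, feature = best$feature, score = best$score,
      baseline = baseline,
      params = if (is.null(best$params)) "" else
        paste(sprintf("%s=%s", names(best$params),
                      vapply(best$params, format, "")), collapse = ";"),
      stringsAsFactors = FALSE)
    fvs_log(verbose, "fvs iter %d: + %s (%s = %.6g)", t, best$feature,
            criterion, best$score)
  }

  trace <- if (length(steps)) do.call(rbind, steps) else
    data.frame(iteration = integer(0), feature = character(0),
               score = numeric(0), baseline = numeric(0),
               params = character(0))
  structure(trace,
            selected = selected,
            stop_reason = stop_reason,
            criterion = criterion,
            model_name = config$model_name,
            candidate_scores = if (config$keep_candidate_scores)
              do.call(rbind, cand_tables) else NULL,
            class = c("fvs_trace", "data.frame"))
}

#' Selected features of a trace
#' @param trace an `fvs_trace`.
#' @return character vector in selection order.
#' @export
selected_features <- function(trace) attr(trace, "selected")
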