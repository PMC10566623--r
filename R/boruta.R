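# All-relevant feature selection by shadow-feature permutation importance
# with a random-forest learner. Each iteration appends one permuted shadow
# copy per undecided feature, fits a forest on originals + shadows, and
# counts a "hit" for every undecided feature whose importance exceeds the
# maximum shadow importance. Across iterations a two-sided binomial test on
# the hit counts (Bonferroni-corrected over currently undecided features)
# promotes features to accepted or rejected; survivors stay tentative.

#' Boruta configuration
#'
#' @param max_iter maximum shadow iterations (default 100).
#' @param alpha significance level of the binomial hit test (default
#'   0.05).
#' @param n_trees trees per random forest (default 100).
#' @param seed integer seed.
#' @param max_features_considered cap on features entered (default all).
#' @param importance `"impurity"` (default) or `"permutation"`
#'   (out-of-bag permutation importance; slower).
#' @return a `boruta_config` list.
#' @export
boruta_config <- function(max_iter = 100L, alpha = 0.05, n_trees = 100L,
                          seed = 1L, max_features_considered = Inf,
                          importance = c("impurity", "permutation")) {
  if (max_iter < 1) stopf("max_iter must be >= 1")
  stopifnot(alpha > 0, alpha < 1, n_trees >= 1)
  structure(list(max_iter = as.integer(max_iter), alpha = alpha,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 max_features_considered = max_features_considered,
                 importance = match.arg(importance)),
            class = "boruta_config")
}

#' Boruta all-relevant feature selection
#'
#' @param dataset an `fvs_dataset`; classification uses the random-forest
#'   classifier (the canonical formulation), regression the random-forest
#'   regressor.
#' @param config a [boruta_config()].
#' @param verbose log per-iteration progress.
#' @return a `boruta_result`: data.frame (feature, decision in
#'   accepted/rejected/tentative, mean_z, hits, n_tested) with attribute
#'   `z_history` (iterations x features matrix of importance z-scores
#'   against the shadow distribution) and `n_iterations`.
#' @export
boruta_select <- function(dataset, config = boruta_config(), verbose = FALSE) {
  feats <- dataset$feature_names
  if (is.finite(config$max_features_considered))
    feats <- feats[seq_len(min(length(feats), config$max_features_considered))]
  task <- dataset$task
  classes <- if (task == "classification") levels(dataset$y) else NULL
  n <- nrow(dataset$X)

  status <- stats::setNames(rep("tentative", length(feats)), feats)
  hits <- stats::setNames(rep(0L, length(feats)), feats)
  tested <- stats::setNames(rep(0L, length(feats)), feats)
  zsum <- stats::setNames(rep(0, length(feats)), feats)
  z_history <- list()

  rf_params <- list(n_trees = config$n_trees,
                    keep_inbag = config$importance == "permutation")

  it <- 0L
  while (it < config$max_iter) {
    undecided <- names(status)[status == "tentative"]
    if (!length(undecided)) break
    it <- it + 1L

    keep <- names(status)[status != "rejected"]
    # one shadow per undecided feature, padded to a minimum of 5 shadows
    # (extra permutations cycling over the undecided set): with fewer
    # shadows the max-shadow bar degenerates and late lucky survivors of
    # a pure-noise endgame would be accepted at an inflated rate
    n_shadow <- max(length(undecided), 5L)
    src <- undecided[(seq_len(n_shadow) - 1L) %% length(undecided) + 1L]
    shadows <- vapply(seq_len(n_shadow), function(j)
      with_seed(derive_seed(config$seed, "perm", it, j),
                sample(dataset$X[, src[j]])),
      numeric(n))
    colnames(shadows) <- paste0(".shadow_", seq_len(n_shadow), "_", src)
    Xb <- cbind(dataset$X[, keep, drop = FALSE], shadows)

    fit <- fit_random_forest(Xb, dataset$y, rf_params,
                             seed = derive_seed(config$seed, "rf", it),
                             classes = classes)
    imp <- if (config$importance == "permutation") {
      rf_permutation_importance(fit, Xb, dataset$y,
                                seed = derive_seed(config$seed, "pimp", it))
    } else {
      fit$importance
    }
    names(imp) <- colnames(Xb)
    sh <- imp[colnames(shadows)]
    sh_max <- max(sh)
    sh_sd <- stats::sd(sh)
    if (!is.finite(sh_sd) || sh_sd == 0) sh_sd <- 1e-12

    z <- (imp[undecided] - mean(sh)) / sh_sd
    zsum[undecided] <- zsum[undecided] + z
    z_history[[it]] <- stats::setNames(as.numeric(z), undecided)

    hit <- imp[undecided] > sh_max
    hits[undecided] <- hits[undecided] + as.integer(hit)
    tested[undecided] <- tested[undecided] + 1L

    # two-sided binomial test at level alpha, Bonferroni over undecided
    alpha_adj <- config$alpha / length(undecided)
    for (f in undecided) {
      p_hi <- stats::pbinom(hits[f] - 1L, tested[f], 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[f], tested[f], 0.5)
      if (p_hi < alpha_adj) status[f] <- "accepted"
      else if (p_lo < alpha_adj) status[f] <- "rejected"
    }
    fvs_log(verbose, "boruta iter %d: %d accepted, %d rejected, %d tentative",
            it, sum(status == "accepted"), sum(status == "rejected"),
            sum(status == "tentative"))
  }

  zh <- matrix(NA_real_, it, length(feats), dimnames = list(NULL, feats))
  for (i in seq_len(it)) zh[i, names(z_history[[i]])] <- z_history[[i]]
  res <- data.frame(feature = feats,
                    decision = unname(status),
                    mean_z = unname(ifelse(tested > 0, zsum / pmax(tested, 1L),
                                           NA_real_)),
                    hits = unname(hits),
                    n_tested = unname(tested),
                    stringsAsFactors = FALSE)
  structure(res, z_history = zh, n_iterations = it,
            class = c("boruta_result", "data.frame"))
}

#' Features accepted by Boruta
#' @param result a `boruta_result`.
#' @return character vector of accepted feature names.
#' @export
boruta_accepted <- function(result) result$feature[result$decision == "accepted"]
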