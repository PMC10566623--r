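# Synthetic ROI-style tables: equicorrelated Gaussian features, a small
# planted informative subset driving a latent score, and a TIV-like global
# covariate correlated with many features.

#' Simulation configuration
#'
#' @param n samples (default 300).
#' @param m features (default 100).
#' @param k informative features (default 5).
#' @param effect absolute generating coefficient of each informative
#'   feature (default 2; signs alternate).
#' @param rho equicorrelation between features, in `[0, 1)` (default 0.3,
#'   mimicking regional-volume correlations).
#' @param covariate_strength scale of the feature loading of the TIV-like
#'   covariate (default 1).
#' @param task `"regression"` or `"classification"`.
#' @param n_classes classes for a classification target (default 2:
#'   median split; more classes use quantile bins).
#' @param n_ordinal_levels if > 0, discretize the regression target into
#'   this many equal-frequency ordinal codes 0..L-1 (age-range analogue);
#'   0 keeps the continuous latent score (default).
#' @param noise_sd Gaussian noise on the latent score (default 1).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 300L, m = 100L, k = 5L, effect = 2, rho = 0.3,
                       covariate_strength = 1,
                       task = c("regression", "classification"),
                       n_classes = 2L, n_ordinal_levels = 0L, noise_sd = 1,
                       seed = 1L) {
  task <- match.arg(task)
  if (k > m) stopf("k (%d) must be <= m (%d)", k, m)
  if (rho < 0 || rho >= 1) stopf("rho must be in [0, 1)")
  stopifnot(noise_sd >= 0, n_classes >= 2)
  structure(list(n = as.integer(n), m = as.integer(m), k = as.integer(k),
                 effect = effect, rho = rho,
                 covariate_strength = covariate_strength, task = task,
                 n_classes = as.integer(n_classes),
                 n_ordinal_levels = as.integer(n_ordinal_levels),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a decoding dataset with planted signal
#'
#' Features are equicorrelated Gaussian (`X_j = sqrt(rho) Z0 +
#' sqrt(1-rho) Z_j`). A latent score is a linear combination of the first
#' `k` features with coefficients of magnitude `effect` and alternating
#' sign, plus `noise_sd` Gaussian noise. Regression targets are the latent
#' score itself or its equal-frequency ordinal codes; classification
#' targets threshold the latent score at its median (binary) or quantiles
#' (multiclass). A TIV-like covariate — a weighted sum of many features
#' plus noise — is attached.
#'
#' @param config a [sim_config()].
#' @return an `fvs_dataset` with attributes `informative` (planted feature
#'   names), `beta` (generating coefficients), and `latent` (the continuous
#'   latent score).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    Z0 <- stats::rnorm(cfg$n)
    X <- sqrt(cfg$rho) * matrix(Z0, cfg$n, cfg$m) +
      sqrt(1 - cfg$rho) * matrix(stats::rnorm(cfg$n * cfg$m), cfg$n, cfg$m)
    colnames(X) <- sprintf("roi_%03d", seq_len(cfg$m))

    beta <- numeric(cfg$m)
    if (cfg$k > 0)
      beta[seq_len(cfg$k)] <- cfg$effect * (-1)^(seq_len(cfg$k) - 1)
    latent <- drop(X %*% beta) + stats::rnorm(cfg$n, sd = cfg$noise_sd)

    # TIV analogue: loads on every feature, like global head size
    w <- abs(stats::rnorm(cfg$m, mean = 1, sd = 0.3)) / cfg$m
    tiv <- cfg$covariate_strength * drop(X %*% w) + stats::rnorm(cfg$n, sd = 0.1)

    y <- if (cfg$task == "regression") {
      if (cfg$n_ordinal_levels > 1) {
        qs <- stats::quantile(latent,
                              probs = seq_len(cfg$n_ordinal_levels - 1) /
                                cfg$n_ordinal_levels)
        as.numeric(findInterval(latent, qs))
      } else latent
    } else {
      if (cfg$n_classes == 2) {
        factor(ifelse(latent > stats::median(latent), "case", "control"),
               levels = c("case", "control"))
      } else {
        qs <- stats::quantile(latent, probs = seq_len(cfg$n_classes - 1) /
                                cfg$n_classes)
        factor(paste0("c", findInterval(latent, qs)))
      }
    }
    ds <- new_dataset(X, y, task = cfg$task,
                      covariates = matrix(tiv, ncol = 1,
                                          dimnames = list(NULL, "TIV")))
    attr(ds, "informative") <- colnames(X)[seq_len(cfg$k)]
    attr(ds, "beta") <- beta
    attr(ds, "latent") <- latent
    ds
  })
}
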