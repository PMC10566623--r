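# Kernel machinery shared by kernel ridge regression and Gaussian process
# regression, plus Gaussian naive Bayes.

# Gram matrix between rows of X1 and X2.
#   linear    x.z
#   gaussian  exp(-gamma ||x-z||^2)      (RBF)
#   laplacian exp(-gamma ||x-z||_1)
#   sigmoid   tanh(gamma x.z + coef0)    (not PSD; solve may fail -> the
#                                         config is scored as worst upstream)
kernel_matrix <- function(kind, X1, X2, gamma = 0.1, coef0 = 1) {
  switch(kind,
    linear = X1 %*% t(X2),
    gaussian = {
      d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
      exp(-gamma * pmax(d2, 0))
    },
    laplacian = {
      d1 <- matrix(0, nrow(X1), nrow(X2))
      for (j in seq_len(ncol(X1)))
        d1 <- d1 + abs(outer(X1[, j], X2[, j], "-"))
      exp(-gamma * d1)
    },
    sigmoid = tanh(gamma * (X1 %*% t(X2)) + coef0),
    stopf("unknown kernel '%s'", kind))
}

# Shared solver: prediction = K(x*, X) (K + reg I)^{-1} (y - mean(y)) + mean(y).
# Kernel ridge uses reg = alpha; GP regression is the same algebra with
# reg = noise variance (the posterior mean).
fit_kernel_machine <- function(X, y, kind, gamma, reg, coef0 = 1) {
  ym <- mean(y)
  K <- kernel_matrix(kind, X, X, gamma, coef0)
  dual <- solve(K + diag(reg, nrow(X)), y - ym)
  list(kind = "kernel_machine", kernel = kind, gamma = gamma, coef0 = coef0,
       X_train = X, dual = as.numeric(dual), ym = ym)
}

fit_kernel_ridge <- function(X, y, params, seed) {
  fit_kernel_machine(X, y,
                     kind = params$kernel %||% "gaussian",
                     gamma = params$gamma %||% 0.1,
                     reg = params$alpha %||% 1)
}

fit_gaussian_process <- function(X, y, params, seed) {
  ls <- params$length_scale %||% 1
  fit_kernel_machine(X, y,
                     kind = params$kernel %||% "gaussian",
                     gamma = 1 / (2 * ls^2),
                     reg = params$noise %||% 0.1)
}

predict_kernel_machine <- function(fit, X) {
  Ks <- kernel_matrix(fit$kernel, X, fit$X_train, fit$gamma, fit$coef0)
  as.numeric(Ks %*% fit$dual + fit$ym)
}

# ---- Gaussian naive Bayes ------------------------------------------------

# Continuous-feature naive Bayes with an additive smoothing parameter:
# `smoothing` times the largest feature variance is added to every
# class-conditional variance (the continuous analogue of Laplace/Lidstone
# count smoothing; it regularises degenerate variances the same way).
fit_naive_bayes <- function(X, y, params, seed, classes) {
  smoothing <- params$smoothing %||% 1e-9
  K <- length(classes)
  p <- ncol(X)
  mu <- matrix(0, K, p); v <- matrix(0, K, p)
  prior <- numeric(K)
  for (k in seq_len(K)) {
    rows <- which(as.character(y) == classes[k])
    prior[k] <- length(rows) / nrow(X)
    Xi <- X[rows, , drop = FALSE]
    mu[k, ] <- colMeans(Xi)
    v[k, ] <- apply(Xi, 2, function(z) mean((z - mean(z))^2))
  }
  v <- v + smoothing * max(v, 1e-12)
  list(kind = "naive_bayes", mu = mu, var = v, prior = prior,
       classes = classes)
}

predict_naive_bayes <- function(fit, X) {
  K <- length(fit$classes)
  ll <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    m <- fit$mu[k, ]; v <- fit$var[k, ]
    ll[, k] <- log(fit$prior[k]) -
      0.5 * rowSums(sweep(sweep(X, 2, m)^2, 2, v, "/") +
                      matrix(log(2 * pi * v), nrow(X), ncol(X), byrow = TRUE))
  }
  ll <- ll - apply(ll, 1, max)
  prob <- exp(ll)
  prob <- prob / rowSums(prob)
  colnames(prob) <- fit$classes
  prob
}
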