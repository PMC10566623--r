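# Linear estimator families: closed-form ridge, glmnet-backed shrinkage
# models, least angle regression (LAR / LassoLAR), and a stochastic
# gradient descent linear learner.

# ---- ridge (closed form on standardized features) -------------------------

fit_ridge <- function(X, y, params, seed) {
  lambda <- params$alpha %||% 1
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ym <- mean(y)
  p <- ncol(Xs)
  A <- crossprod(Xs) + diag(lambda, p)
  beta_s <- solve(A, crossprod(Xs, y - ym))
  beta <- beta_s / scl
  list(kind = "ridge", beta = as.numeric(beta),
       intercept = ym - sum(ctr * beta))
}

predict_ridge <- function(fit, X) {
  as.numeric(X %*% fit$beta + fit$intercept)
}

# ---- glmnet-backed families ----------------------------------------------

# glmnet refuses single-column designs; pad with an all-zero column (its
# coefficient is always 0) and mirror the padding at prediction time.
pad_single_col <- function(X) {
  if (ncol(X) == 1) cbind(X, `..pad..` = 0) else X
}

# Single-configuration glmnet fit at a fixed penalty. A short decreasing
# path ending at the target lambda stabilises the coordinate descent.
glmnet_fit_at <- function(X, y, family, alpha_mix, lambda) {
  path <- sort(unique(c(lambda * c(50, 10, 4, 2), lambda)), decreasing = TRUE)
  glmnet::glmnet(pad_single_col(X), y, family = family, alpha = alpha_mix,
                 lambda = path, standardize = TRUE)
}

fit_lasso <- function(X, y, params, seed) {
  lambda <- params$alpha %||% 0.1
  list(kind = "glmnet_reg", lambda = lambda,
       fit = glmnet_fit_at(X, y, "gaussian", 1, lambda))
}

fit_elastic_net <- function(X, y, params, seed) {
  lambda <- params$alpha %||% 0.1
  l1 <- params$l1_ratio %||% 0.5
  list(kind = "glmnet_reg", lambda = lambda,
       fit = glmnet_fit_at(X, y, "gaussian", l1, lambda))
}

# Multitask lasso with a single response: the block (sup-norm family)
# penalty on a one-column coefficient group coincides with the plain L1
# penalty, handled by glmnet's multiresponse Gaussian family.
fit_multitask_lasso <- function(X, y, params, seed) {
  lambda <- params$alpha %||% 0.1
  fit <- glmnet_fit_at(X, cbind(y = y), "mgaussian", 1, lambda)
  list(kind = "glmnet_mtl", lambda = lambda, fit = fit)
}

predict_glmnet_reg <- function(fit, X) {
  as.numeric(glmnet::predict.glmnet(fit$fit, pad_single_col(X), s = fit$lambda))
}

# predict.mrelnet mishandles single-response fits; read the coefficient
# block directly instead
predict_glmnet_mtl <- function(fit, X) {
  i <- which.min(abs(fit$fit$lambda - fit$lambda))
  B <- fit$fit$beta
  if (is.list(B)) B <- B[[1]]
  beta <- as.numeric(as.matrix(B)[, i])
  as.numeric(pad_single_col(X) %*% beta + as.numeric(fit$fit$a0)[i])
}

fit_logistic_l1 <- function(X, y, params, seed, classes) {
  lambda <- params$alpha %||% 0.01
  l1 <- params$l1_ratio %||% 1
  fam <- if (length(classes) == 2) "binomial" else "multinomial"
  fit <- glmnet_fit_at(X, y, fam, l1, lambda)
  list(kind = "logistic_l1", lambda = lambda, fit = fit, classes = classes)
}

predict_logistic_l1 <- function(fit, X) {
  K <- length(fit$classes)
  pr <- predict(fit$fit, pad_single_col(X), s = fit$lambda, type = "response")
  prob <- if (K == 2) cbind(1 - pr[, 1], pr[, 1]) else pr[, , 1]
  colnames(prob) <- fit$classes
  prob
}

# ---- least angle regression ----------------------------------------------

# Full LAR / lasso-modified LAR path (Efron et al. style) on centered,
# sd-scaled predictors. Returns knot penalties lambda_k = ||X'r||_inf / n
# (matching the 1/(2n) RSS + alpha*L1 objective) and the coefficient path,
# both on the standardized scale, plus the scaling needed to map back.
lars_path <- function(X, y, lasso = TRUE, max_steps = 8 * ncol(X)) {
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ym <- mean(y)
  r <- y - ym
  beta <- numeric(p)
  path <- list(beta)
  cvec <- drop(crossprod(Xs, r))
  lambdas <- max(abs(cvec))
  active <- integer(0)
  last_dropped <- integer(0)
  eps <- 1e-10
  step <- 0
  while (step < max_steps) {
    step <- step + 1
    C <- max(abs(cvec))
    if (C < eps || length(active) >= min(p, n - 1)) break
    # a variable dropped by the lasso modification sits exactly at the
    # correlation boundary; bar it from immediate re-entry
    inactive <- setdiff(seq_len(p), c(active, last_dropped))
    if (length(inactive)) {
      j_new <- inactive[abs(cvec[inactive]) >= C - eps]
      active <- c(active, setdiff(j_new, active))
    }
    last_dropped <- integer(0)
    s <- sign(cvec[active])
    XA <- sweep(Xs[, active, drop = FALSE], 2, s, "*")
    G <- crossprod(XA)
    Ginv1 <- tryCatch(solve(G, rep(1, length(active))),
                      error = function(e) NULL)
    if (is.null(Ginv1)) break          # collinear active set: stop the path
    AA <- 1 / sqrt(sum(Ginv1))
    w <- AA * Ginv1
    u <- XA %*% w                       # equiangular direction
    a <- drop(crossprod(Xs, u))
    inactive <- setdiff(seq_len(p), active)
    if (length(inactive)) {
      cj <- cvec[inactive]; aj <- a[inactive]
      cand <- c((C - cj) / (AA - aj), (C + cj) / (AA + aj))
      cand <- cand[is.finite(cand) & cand > eps]
      gamma <- if (length(cand)) min(cand) else C / AA
    } else {
      gamma <- C / AA
    }
    d <- s * w                          # coefficient direction, original signs
    dropped <- integer(0)
    if (lasso) {
      gj <- -beta[active] / d
      hit <- which(is.finite(gj) & gj > eps & gj < gamma - eps)
      if (length(hit)) {
        gamma <- min(gj[hit])
        dropped <- active[which(abs(gj - gamma) < eps & gj > eps)]
      }
    }
    beta[active] <- beta[active] + gamma * d
    if (length(dropped)) {
      beta[dropped] <- 0
      active <- setdiff(active, dropped)
      last_dropped <- dropped
    }
    r <- r - gamma * u
    cvec <- drop(crossprod(Xs, r))
    path[[length(path) + 1]] <- beta
    lambdas <- c(lambdas, max(abs(cvec)))
  }
  list(lambda = lambdas / n, path = do.call(rbind, path),
       ctr = ctr, scl = scl, ym = ym,
       active_sizes = vapply(path, function(b) sum(b != 0), 0L))
}

# coefficients (standardized scale) at penalty alpha by linear interpolation
# between knots; the path is piecewise linear in lambda.
lars_coef_at <- function(pathobj, alpha) {
  lam <- pathobj$lambda
  B <- pathobj$path
  if (alpha >= lam[1]) return(B[1, ])
  K <- length(lam)
  if (alpha <= lam[K]) return(B[K, ])
  k <- max(which(lam >= alpha))        # lam[k] >= alpha > lam[k+1]
  t <- (lam[k] - alpha) / (lam[k] - lam[k + 1])
  B[k, ] + t * (B[k + 1, ] - B[k, ])
}

fit_lassolar <- function(X, y, params, seed) {
  alpha <- params$alpha %||% 0.1
  pth <- lars_path(X, y, lasso = TRUE)
  bs <- lars_coef_at(pth, alpha)
  beta <- bs / pth$scl
  list(kind = "lars", beta = as.numeric(beta),
       intercept = pth$ym - sum(pth$ctr * beta))
}

fit_lar <- function(X, y, params, seed) {
  k <- params$n_nonzero_coefs %||% ncol(X)
  k <- min(k, ncol(X))
  pth <- lars_path(X, y, lasso = FALSE, max_steps = k)
  i <- which(pth$active_sizes <= k)
  bs <- pth$path[max(i), ]
  beta <- bs / pth$scl
  list(kind = "lars", beta = as.numeric(beta),
       intercept = pth$ym - sum(pth$ctr * beta))
}

predict_lars <- function(fit, X) {
  as.numeric(X %*% fit$beta + fit$intercept)
}

# ---- SGD linear regression -----------------------------------------------

fit_sgd <- function(X, y, params, seed) {
  loss <- params$loss %||% "squared"
  penalty <- params$penalty %||% "l2"
  alpha <- params$alpha %||% 1e-4
  schedule <- params$learning_rate %||% "invscaling"
  eta0 <- params$eta0 %||% 0.01
  epochs <- params$epochs %||% 30L
  l1_ratio <- if (penalty == "l1") 1 else if (penalty == "elasticnet") 0.15 else 0
  huber_delta <- 1

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ym <- mean(y); ys <- stats::sd(y); if (ys == 0) ys <- 1
  yt <- (y - ym) / ys
  n <- nrow(Xs); p <- ncol(Xs)
  w <- numeric(p); b <- 0
  t_glob <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        t_glob <- t_glob + 1
        eta <- if (schedule == "constant") eta0 else eta0 / t_glob^0.25
        xi <- Xs[i, ]
        m <- sum(w * xi) + b
        e <- m - yt[i]
        gl <- if (loss == "huber" && abs(e) > huber_delta)
          huber_delta * sign(e) else e
        grad <- gl * xi
        if (l1_ratio < 1) grad <- grad + alpha * (1 - l1_ratio) * w
        w <- w - eta * grad
        if (l1_ratio > 0) {             # proximal shrink for the L1 part
          sh <- eta * alpha * l1_ratio
          w <- sign(w) * pmax(abs(w) - sh, 0)
        }
        b <- b - eta * gl
      }
    }
  })
  beta <- w / scl * ys
  list(kind = "sgd", beta = as.numeric(beta),
       intercept = (b * ys) + ym - sum(ctr * beta))
}

predict_sgd <- function(fit, X) {
  as.numeric(X %*% fit$beta + fit$intercept)
}
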