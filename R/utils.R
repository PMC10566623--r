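# Internal helpers: deterministic seed derivation, score orientation,
# lightweight logging.

#' Derive a reproducible substream seed
#'
#' All randomness in the pipeline flows from one master seed through named
#' substreams so results are independent of scheduling (worker count,
#' evaluation order). Components may be integers or short strings; strings
#' are hashed by code point.
#'
#' @param ... integer or character components identifying the substream,
#'   e.g. `derive_seed(1, "fvs-iter", 3L)`.
#' @return a single integer in `[1, 2^31 - 2]`, usable with `set.seed()`.
#' @export
derive_seed <- function(...) {
  parts <- list(...)
  mod <- 2147483647  # 2^31 - 1, prime
  h <- 104729
  for (p in parts) {
    vals <- if (is.character(p)) utf8ToInt(paste(p, collapse = "\r")) else as.integer(p)
    if (anyNA(vals)) stop("derive_seed: NA component")
    for (v in vals) {
      # keep intermediate products in double range: h < 2^31, |v| small
      h <- (h * 31 + (as.numeric(v) %% mod) + 7) %% mod
    }
    h <- (h * 269 + 1) %% mod
  }
  as.integer(h %% (mod - 2) + 1)
}

# Evaluate expr with a local RNG state seeded by `seed`; global RNG untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Score orientation. Internally every criterion keeps its natural scale;
# `better()` and `worst_score()` encapsulate the direction.
is_loss_criterion <- function(criterion) {
  criterion %in% c("mse", "mae")
}

worst_score <- function(criterion) {
  if (is_loss_criterion(criterion)) Inf else -Inf
}

# is a strictly better than b by more than tol?
better <- function(a, b, criterion, tol = 0) {
  if (is.na(a)) return(FALSE)
  if (is.na(b)) return(TRUE)
  if (is_loss_criterion(criterion)) a < b - tol else a > b + tol
}

fvs_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
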