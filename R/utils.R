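# Internal helpers shared across the package.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic seed splitting: derive independent sub-seeds from one master
# seed and a stream index, kept inside 32-bit integer range.
split_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}

# Least squares with an optional intercept and a tiny trace-scaled ridge term.
# The ridge keeps rank-deficient designs (duplicated or collinear regulators,
# hub genes with more neighbours than training cells) solvable and
# deterministic; at lambda_rel = 1e-6 it is numerically invisible for
# well-conditioned problems.
ridge_lstsq <- function(X, y, intercept = TRUE, lambda_rel = 1e-6) {
  X <- as.matrix(X)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  xtx <- crossprod(X)
  p <- ncol(X)
  lambda <- lambda_rel * sum(diag(xtx)) / p
  beta <- solve(xtx + diag(lambda, p), crossprod(X, y))
  drop(beta)
}

# Predict from ridge_lstsq coefficients; `beta` carries the intercept first
# when the model was fit with one.
lstsq_predict <- function(beta, X, intercept = TRUE) {
  X <- as.matrix(X)
  if (intercept) drop(beta[1L] + X %*% beta[-1L]) else drop(X %*% beta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
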