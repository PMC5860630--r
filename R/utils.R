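# Internal numerical helpers shared across modules.

# log(1 + exp(x)) without overflow; x > 33 gives log1p(exp(x)) == x in double.
log1pexp <- function(x) {
  out <- x
  small <- x <= 33
  out[small] <- log1p(exp(x[small]))
  out
}

# Round half-up to `digits` decimals (display convention for percentages;
# base round() uses banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic RNG substream id from a base seed plus stream indices.
# Kept below 2^31 - 1 so it is a valid set.seed() argument.  Multipliers are
# distinct primes so that (seed, stratum, m) collisions are not systematic.
seed_stream <- function(seed, ...) {
  idx <- c(...)
  mod <- 2147483647
  # multipliers < 2^22 keep s * mult below 2^53, so the double arithmetic of
  # the modular recurrence stays exact
  mult <- c(2654435, 40503, 2246822, 3266489, 668265)
  s <- as.double(seed) %% mod
  for (i in seq_along(idx)) {
    s <- (s * mult[((i - 1) %% length(mult)) + 1] + as.double(idx[i]) * 7919 + 1) %% mod
  }
  as.integer(s)
}

# Project a symmetric matrix onto the PSD cone by flooring eigenvalues at 0.
nearest_psd <- function(v, warn = TRUE) {
  v <- (v + t(v)) / 2
  e <- eigen(v, symmetric = TRUE)
  if (min(e$values) < -1e-8 && warn) {
    warning(sprintf("covariance repaired: eigenvalue floor applied (min was %.3g)",
                    min(e$values)))
  }
  vals <- pmax(e$values, 0)
  v2 <- e$vectors %*% (vals * t(e$vectors))
  (v2 + t(v2)) / 2
}

# Lower-triangular factor L with L %*% t(L) == v, tolerant of semi-definiteness.
psd_chol <- function(v) {
  L <- tryCatch(t(chol(v)), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen((v + t(v)) / 2, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(v))
  }
  L
}

# Ridge-penalized logistic regression by Newton iteration.  Used as the
# fallback when the MLE is (quasi-)separated.  The penalty is applied to
# standardized non-intercept columns; lambda is on that standardized scale.
# Returns coefficients on the original scale plus the penalized-curvature
# covariance (X'WX + P)^{-1}.
ridge_logit <- function(x, y, lambda, max_iter = 100, tol = 1e-10) {
  p <- ncol(x)
  is_int <- apply(x, 2, function(col) all(col == col[1]))
  scales <- apply(x, 2, stats::sd)
  scales[is_int | scales == 0] <- 1
  xs <- sweep(x, 2, scales, "/")
  pen <- rep(lambda, p)
  pen[is_int] <- 0
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    h <- crossprod(xs * w, xs) + diag(pen, p)
    g <- crossprod(xs, y - mu) - pen * beta
    step <- solve(h, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(xs %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  h <- crossprod(xs * w, xs) + diag(pen, p)
  vcov_s <- solve(h)
  d <- 1 / scales
  list(coefficients = beta * d,
       vcov = vcov_s * tcrossprod(d),
       converged = it < max_iter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
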