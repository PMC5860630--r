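#' Rubin's rules for a scalar estimand
#'
#' Pools M per-imputation estimates and their variances: point estimate
#' Qbar = mean of estimates; within-imputation variance W = mean of
#' variances; between-imputation variance B = sample variance of estimates;
#' total variance T = W + (1 + 1/M) B; degrees of freedom
#' nu = (M - 1) (1 + W / ((1 + 1/M) B))^2 when B > 0, infinite otherwise.
#' The (1 - alpha) interval uses the t quantile with nu degrees of freedom.
#'
#' @param estimates Numeric vector of M per-imputation point estimates.
#' @param variances Numeric vector of M per-imputation variances (>= 0).
#' @param alpha Interval level complement (default 0.05 for 95% CIs).
#' @return A `pooled_scalar` with fields `estimate`, `within`, `between`,
#'   `total`, `se`, `df`, `lo`, `hi`, `m`.
#' @examples
#' pool_scalar(c(0.2, 0.3, 0.4), c(0.01, 0.01, 0.01))
#' @export
pool_scalar <- function(estimates, variances, alpha = 0.05) {
  m <- length(estimates)
  if (m == 0) stop("no imputations to pool")
  stopifnot(length(variances) == m, all(variances >= 0))
  qbar <- mean(estimates)
  w <- mean(variances)
  if (m == 1) {
    warning("M = 1: between-imputation variance undefined, set to 0")
    b <- 0
  } else {
    b <- stats::var(estimates)
  }
  tot <- w + (1 + 1 / m) * b
  df <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  se <- sqrt(tot)
  q <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else stats::qnorm(1 - alpha / 2)
  structure(list(estimate = qbar, within = w, between = b, total = tot,
                 se = se, df = df, lo = qbar - q * se, hi = qbar + q * se,
                 m = m, alpha = alpha),
            class = "pooled_scalar")
}

#' @export
print.pooled_scalar <- function(x, ...) {
  cat(sprintf("pooled_scalar (M = %d): %.5g (SE %.4g), %g%% CI [%.5g, %.5g], df %.4g\n",
              x$m, x$estimate, x$se, 100 * (1 - x$alpha), x$lo, x$hi, x$df))
  invisible(x)
}

#' Rubin's rules for GLM coefficient vectors
#'
#' Element-wise pooling of coefficient vectors across imputations, with the
#' pooled covariance Wbar + (1 + 1/M) B, where Wbar is the mean of the
#' per-imputation covariance matrices and B is the between-imputation
#' covariance of the coefficient vectors (outer-product sum over
#' (beta_m - betabar), divided by M - 1).
#'
#' @param fits List of M fits, each a list with `coefficients` (named numeric)
#'   and `vcov` (matrix); `glm` objects are also accepted.
#' @return A `pooled_glm` with `coefficients`, `vcov`, `within`, `between`,
#'   `labels`, `m`.
#' @export
pool_glm <- function(fits) {
  m <- length(fits)
  if (m == 0) stop("no fits to pool")
  fits <- lapply(fits, function(f) {
    if (inherits(f, "glm")) list(coefficients = stats::coef(f), vcov = stats::vcov(f))
    else f
  })
  labels <- names(fits[[1]]$coefficients)
  for (i in seq_along(fits)) {
    li <- names(fits[[i]]$coefficients)
    if (!identical(li, labels)) {
      stop("coefficient labels differ across imputations: ",
           paste(union(setdiff(li, labels), setdiff(labels, li)), collapse = ", "))
    }
  }
  betas <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  betabar <- colMeans(betas)
  w <- Reduce(`+`, lapply(fits, function(f) f$vcov)) / m
  if (m > 1) {
    centered <- sweep(betas, 2, betabar)
    b <- crossprod(centered) / (m - 1)
  } else {
    b <- matrix(0, length(labels), length(labels))
  }
  v <- w + (1 + 1 / m) * b
  dimnames(v) <- list(labels, labels)
  dimnames(b) <- list(labels, labels)
  structure(list(coefficients = stats::setNames(betabar, labels),
                 vcov = (v + t(v)) / 2, within = w, between = b,
                 labels = labels, m = m),
            class = "pooled_glm")
}

#' @export
print.pooled_glm <- function(x, ...) {
  cat(sprintf("pooled_glm (M = %d): %d coefficients\n", x$m, length(x$labels)))
  out <- data.frame(estimate = x$coefficients, se = sqrt(diag(x$vcov)))
  print(round(out, 4))
  invisible(x)
}

#' Rubin-pooled prevalence of the imputed target
#'
#' Per-imputation estimate: the proportion of ones in the (optionally
#' filtered) completed table; per-imputation variance: binomial
#' p(1 - p)/n.  Pooled with [pool_scalar()] on the proportion scale and
#' also reported as a percentage.  A logit-scale option is available for
#' prevalences near the boundary.
#'
#' @param completed A `completed_set`.
#' @param filter Optional function taking a completed data frame and
#'   returning a logical row mask (subgroup selector), or `NULL` for overall.
#' @param scale `"proportion"` (default) or `"logit"` for pooling on the
#'   log-odds scale (back-transformed interval).
#' @param alpha Interval level complement.
#' @return A `pooled_scalar` with extra fields `percent`, `percent_se`, `n`.
#' @export
pooled_prevalence <- function(completed, filter = NULL,
                              scale = c("proportion", "logit"), alpha = 0.05) {
  stopifnot(inherits(completed, "completed_set"))
  scale <- match.arg(scale)
  target <- completed$provenance$roles$target
  ests <- vars <- numeric(length(completed$imputations))
  ns <- integer(length(completed$imputations))
  for (i in seq_along(completed$imputations)) {
    df <- completed$imputations[[i]]
    rows <- if (is.null(filter)) rep(TRUE, nrow(df)) else filter(df)
    y <- df[[target]][rows]
    n <- length(y)
    if (n == 0) {
      out <- structure(list(estimate = NA_real_, se = NA_real_, empty = TRUE,
                            m = length(completed$imputations)),
                       class = "pooled_scalar")
      return(out)
    }
    p <- mean(y)
    ns[i] <- n
    if (scale == "proportion") {
      ests[i] <- p
      vars[i] <- p * (1 - p) / n
    } else {
      p_adj <- (sum(y) + 0.5) / (n + 1)   # avoid infinite logits at 0/1
      ests[i] <- stats::qlogis(p_adj)
      vars[i] <- 1 / (n * p_adj * (1 - p_adj))
    }
  }
  out <- pool_scalar(ests, vars, alpha = alpha)
  if (scale == "logit") {
    out$percent <- 100 * stats::plogis(out$estimate)
    lo <- 100 * stats::plogis(out$lo); hi <- 100 * stats::plogis(out$hi)
    out$percent_lo <- lo; out$percent_hi <- hi
    out$percent_se <- (hi - lo) / (2 * stats::qnorm(1 - alpha / 2))
  } else {
    out$percent <- 100 * out$estimate
    out$percent_se <- 100 * out$se
    out$percent_lo <- 100 * out$lo; out$percent_hi <- 100 * out$hi
  }
  out$n <- ns[1]
  out$scale <- scale
  out
}
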