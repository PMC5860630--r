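#' Configuration for the imputation model
#'
#' Describes the logistic imputation model for the incomplete binary target:
#' its predictors, the number of imputations M, the base RNG seed, an
#' optional stratification column (the model is fitted separately within each
#' stratum, e.g. for men and women), and the fitting engine.
#'
#' @param predictors Character vector of fully observed predictor columns.
#' @param M Number of imputations (default 25).
#' @param seed Base RNG seed; all parameter draws and imputation uniforms are
#'   derived from it through per-(stratum, m) substreams, so changing M does
#'   not perturb earlier draws.
#' @param strata Optional fully observed column to fit within.
#' @param engine `"mle"` (with automatic ridge fallback on separation) or
#'   `"penalized"` to force the ridge fit.
#' @return An `imputation_config`.
#' @export
imputation_config <- function(predictors, M = 25, seed = 1, strata = NULL,
                              engine = c("mle", "penalized")) {
  stopifnot(is.character(predictors), length(predictors) >= 0,
            M >= 1, M == as.integer(M))
  engine <- match.arg(engine)
  structure(list(predictors = predictors, M = as.integer(M),
                 seed = as.integer(seed), strata = strata, engine = engine),
            class = "imputation_config")
}

#' Build the imputation design matrix
#'
#' Dummy-codes the predictors with their declared reference levels (first
#' declared level first), intercept column first, no interaction terms.
#' Categorical predictors that are constant within the stratum (e.g.
#' circumcision status among women) are dropped with a warning, as are dummy
#' columns for levels that never occur among the rows used for fitting.
#'
#' @param table A `study_table` or data frame.
#' @param predictors Character vector of predictor columns.
#' @param rows Optional logical/integer row subset (e.g. one stratum).
#' @param fit_rows Optional logical vector (relative to `rows`) marking the
#'   rows that will be used for fitting; dummy columns that are identically
#'   zero on those rows are dropped.
#' @return List with `x` (numeric matrix, intercept first) and `labels`.
#' @export
build_design <- function(table, predictors, rows = NULL, fit_rows = NULL) {
  df <- as.data.frame(table)
  if (!is.null(rows)) df <- df[rows, , drop = FALSE]
  stopifnot(all(predictors %in% names(df)))
  keep <- character()
  for (col in predictors) {
    v <- df[[col]]
    nlev <- if (is.factor(v)) nlevels(droplevels(v)) else length(unique(v))
    if (nlev < 2) {
      warning(sprintf("predictor '%s' is constant in this stratum; dropped", col))
    } else {
      keep <- c(keep, col)
    }
  }
  if (!length(keep)) {
    x <- matrix(1, nrow = nrow(df), ncol = 1, dimnames = list(NULL, "(Intercept)"))
    return(list(x = x, labels = "(Intercept)"))
  }
  for (col in keep) {
    if (is.factor(df[[col]])) df[[col]] <- droplevels(df[[col]])
  }
  form <- stats::as.formula(paste("~", paste(keep, collapse = " + ")))
  x <- stats::model.matrix(form, df)
  if (!is.null(fit_rows)) {
    dead <- colnames(x)[apply(x[fit_rows, , drop = FALSE], 2,
                              function(col) all(col == 0))]
    if (length(dead)) {
      warning("dummy columns absent among fitting rows dropped: ",
              paste(dead, collapse = ", "))
      x <- x[, setdiff(colnames(x), dead), drop = FALSE]
    }
  }
  list(x = x, labels = colnames(x))
}

#' Fit the logistic imputation model under MAR
#'
#' Maximum-likelihood logistic regression of the target on the design,
#' using only rows where the target is observed (R = 1).  If the fit does
#' not converge or any coefficient exceeds 15 in absolute value
#' (quasi-separation — expected when a self-report category nearly
#' determines the serological result), the model is refitted with a small
#' ridge penalty and the engine recorded as `"penalized"`.
#'
#' @param x Design matrix (intercept first), all rows of the stratum.
#' @param y Target values for those rows (NA where unobserved).
#' @param engine `"mle"` or `"penalized"`.
#' @return A `fitted_imputer`: coefficients, vcov, labels, engine, convergence.
#' @export
fit_imputation_model <- function(x, y, engine = c("mle", "penalized")) {
  engine <- match.arg(engine)
  obs <- !is.na(y)
  xo <- x[obs, , drop = FALSE]
  yo <- y[obs]
  if (length(unique(yo)) < 2) stop("degenerate target: all observed values equal")
  used <- engine
  if (engine == "mle") {
    fit <- suppressWarnings(stats::glm.fit(xo, yo, family = stats::binomial()))
    beta <- fit$coefficients
    sep <- !fit$converged || anyNA(beta) || any(abs(beta) > 15)
    if (!sep) {
      w <- fit$weights
      vc <- tryCatch(solve(crossprod(xo * sqrt(w))),
                     error = function(e) NULL)
      if (is.null(vc)) sep <- TRUE
    }
    if (sep) used <- "penalized"
  }
  if (used == "penalized") {
    rfit <- ridge_logit(xo, yo, lambda = 1e-4 * nrow(xo))
    beta <- rfit$coefficients
    vc <- rfit$vcov
    conv <- rfit$converged
  } else {
    conv <- TRUE
  }
  names(beta) <- colnames(x)
  dimnames(vc) <- list(colnames(x), colnames(x))
  structure(list(coefficients = beta, vcov = (vc + t(vc)) / 2,
                 labels = colnames(x), engine = used, converged = conv,
                 n_fit = sum(obs)),
            class = "fitted_imputer")
}

#' @export
print.fitted_imputer <- function(x, ...) {
  cat(sprintf("fitted_imputer: %d coefficients, engine=%s, n=%d\n",
              length(x$coefficients), x$engine, x$n_fit))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Draw imputation-model parameters for one imputation
#'
#' Proper imputation: one multivariate-normal draw centred at the fitted
#' coefficients with the estimated covariance (the approximate posterior of
#' the logistic MLE).  Deterministic given (seed, stratum, m): the RNG
#' substream is keyed on those three, so M can grow without perturbing
#' earlier draws.  A non-PSD covariance is repaired by eigenvalue flooring.
#'
#' @param fitted A `fitted_imputer`.
#' @param m Imputation index (1-based).
#' @param seed Base seed.
#' @param stratum Integer stratum index (1-based).
#' @return Named numeric vector of drawn coefficients.
#' @export
draw_parameters <- function(fitted, m, seed, stratum = 1L) {
  v <- fitted$vcov
  ev <- eigen((v + t(v)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) v <- nearest_psd(v)
  L <- psd_chol(v)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed_stream(seed, 11L, stratum, m))
  z <- stats::rnorm(length(fitted$coefficients))
  stats::setNames(fitted$coefficients + drop(L %*% z), fitted$labels)
}

stratum_levels <- function(table, strata) {
  if (is.null(strata)) return(list(all = rep(TRUE, nrow(table))))
  v <- table[[strata]]
  if (!is.factor(v)) v <- factor(v)
  out <- lapply(levels(v), function(lv) !is.na(v) & v == lv)
  names(out) <- levels(v)
  out[vapply(out, any, logical(1))]
}

#' Fit per-stratum imputation models
#'
#' Internal workhorse shared by the MAR and MNAR imputers: builds the design
#' and fits [fit_imputation_model()] within each stratum level.
#'
#' @param table A `study_table`.
#' @param roles A `role_map`.
#' @param config An `imputation_config`.
#' @return Named list per stratum: `fit`, `x` (full-stratum design), `rows`.
#' @keywords internal
fit_strata <- function(table, roles, config) {
  check_roles(table, roles)
  y <- table[[roles$target]]
  strata <- stratum_levels(table, config$strata)
  lapply(strata, function(rows) {
    dsg <- build_design(table, config$predictors, rows = rows,
                        fit_rows = !is.na(y[rows]))
    fit <- fit_imputation_model(dsg$x, y[rows], engine = config$engine)
    list(fit = fit, x = dsg$x, rows = which(rows))
  })
}

#' Multiple imputation under MAR
#'
#' Equivalent to [impute_mnar()] with every delta offset equal to zero
#' (by construction: both run the same engine), provided as the named
#' baseline analysis.
#'
#' @inheritParams impute_mnar
#' @return A `completed_set`.
#' @export
impute_mar <- function(table, roles, config, common_rng = TRUE) {
  impute_mnar(table, roles, config, delta = delta_spec(0), common_rng = common_rng)
}
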