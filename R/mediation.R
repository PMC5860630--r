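# Parametric causal mediation for a binary outcome and binary mediator with a
# categorical exposure: natural direct/indirect/total effects on the
# odds-ratio scale (rare-outcome form of the two-regression framework), with
# multivariate delta-method standard errors and MI integration.

# Logistic fit keeping the pieces needed to rebuild model-matrix rows later;
# ridge fallback on separation, mirroring the imputation engine.
glm_with_fallback <- function(formula, data) {
  fit <- suppressWarnings(stats::glm(formula, family = stats::binomial(), data = data))
  beta <- stats::coef(fit)
  engine <- "mle"
  if (!fit$converged || anyNA(beta) || any(abs(beta) > 15)) {
    x <- stats::model.matrix(fit)
    yy <- as.numeric(stats::model.response(stats::model.frame(fit)))
    rfit <- ridge_logit(x, yy, lambda = 1e-4 * nrow(x))
    beta <- stats::setNames(rfit$coefficients, colnames(x))
    vc <- rfit$vcov
    dimnames(vc) <- list(colnames(x), colnames(x))
    engine <- "penalized"
  } else {
    vc <- stats::vcov(fit)
  }
  list(coefficients = beta, vcov = (vc + t(vc)) / 2,
       terms = stats::delete.response(stats::terms(fit)),
       xlevels = fit$xlevels, contrasts = fit$contrasts, engine = engine)
}

prep_mediation_data <- function(table, roles) {
  df <- as.data.frame(table)
  stopifnot(!is.null(roles$outcome), !is.null(roles$mediator),
            !is.null(roles$exposure))
  if (!is.factor(df[[roles$exposure]])) df[[roles$exposure]] <- factor(df[[roles$exposure]])
  if (!is.null(roles$exposure_ref)) {
    df[[roles$exposure]] <- stats::relevel(df[[roles$exposure]], roles$exposure_ref)
  }
  df
}

#' Fit the outcome regression of a mediation analysis
#'
#' Logistic regression of the binary outcome on the categorical exposure, the
#' binary mediator, the confounders, and (optionally) the exposure-mediator
#' interaction.  A Wald test of the interaction block is reported so the
#' usual drop decision (refit without the interaction when there is no
#' evidence for it) can be made on the output.
#'
#' @param table A `study_table` or data frame with no missing values in the
#'   model columns.
#' @param roles A `role_map` with `outcome`, `mediator`, `exposure` (and its
#'   reference level) and `confounders` set.
#' @param interaction Include the exposure-mediator interaction block.
#' @return A `med_glm` (role `"outcome"`) with coefficients, vcov, labels and,
#'   when `interaction = TRUE`, `wald_interaction` (statistic, df, p).
#' @export
fit_outcome_model <- function(table, roles, interaction = FALSE) {
  df <- prep_mediation_data(table, roles)
  rhs <- c(roles$exposure, roles$mediator,
           if (interaction) paste0(roles$exposure, ":", roles$mediator),
           roles$confounders)
  form <- stats::as.formula(paste(roles$outcome, "~", paste(rhs, collapse = " + ")))
  fit <- glm_with_fallback(form, df)
  fit$role <- "outcome"
  fit$roles <- roles
  fit$interaction <- interaction
  if (interaction) {
    ia <- grep(":", names(fit$coefficients), fixed = TRUE, value = TRUE)
    b <- fit$coefficients[ia]
    v <- fit$vcov[ia, ia, drop = FALSE]
    stat <- drop(t(b) %*% solve(v, b))
    fit$wald_interaction <- list(statistic = stat, df = length(ia),
                                 p = stats::pchisq(stat, length(ia), lower.tail = FALSE))
  }
  class(fit) <- "med_glm"
  fit
}

#' Fit the mediator regression of a mediation analysis
#'
#' Logistic regression of the binary mediator on the exposure and the
#' confounders (never the outcome).
#'
#' @inheritParams fit_outcome_model
#' @return A `med_glm` (role `"mediator"`).
#' @export
fit_mediator_model <- function(table, roles) {
  df <- prep_mediation_data(table, roles)
  rhs <- c(roles$exposure, roles$confounders)
  form <- stats::as.formula(paste(roles$mediator, "~", paste(rhs, collapse = " + ")))
  fit <- glm_with_fallback(form, df)
  fit$role <- "mediator"
  fit$roles <- roles
  class(fit) <- "med_glm"
  fit
}

#' @export
print.med_glm <- function(x, ...) {
  cat(sprintf("med_glm (%s model, engine=%s): %d coefficients\n",
              x$role, x$engine, length(x$coefficients)))
  print(round(x$coefficients, 4))
  if (!is.null(x$wald_interaction)) {
    cat(sprintf("  exposure-mediator interaction Wald chi2(%d) = %.3f, p = %.4f\n",
                x$wald_interaction$df, x$wald_interaction$statistic,
                x$wald_interaction$p))
  }
  invisible(x)
}

# One model-matrix row at a given exposure level / mediator value / pattern.
mm_row <- function(fit, exposure_level, pattern, mediator_value = NULL) {
  roles <- fit$roles
  vals <- c(as.list(pattern),
            stats::setNames(list(exposure_level), roles$exposure))
  if (!is.null(mediator_value)) vals[[roles$mediator]] <- mediator_value
  row <- as.data.frame(vals, stringsAsFactors = FALSE)
  for (v in names(fit$xlevels)) {
    if (v %in% names(row)) row[[v]] <- factor(row[[v]], levels = fit$xlevels[[v]])
  }
  mf <- stats::model.frame(fit$terms, row, xlev = fit$xlevels)
  drop(stats::model.matrix(fit$terms, mf, contrasts.arg = fit$contrasts))
}

# Precompute the five model-matrix rows the effect formulas are linear in.
effect_rows <- function(outcome_fit, mediator_fit, a, a_star, pattern) {
  list(
    xo_a0  = mm_row(outcome_fit, a, pattern, 0),
    xo_a1  = mm_row(outcome_fit, a, pattern, 1),
    xo_as0 = mm_row(outcome_fit, a_star, pattern, 0),
    xo_as1 = mm_row(outcome_fit, a_star, pattern, 1),
    xm_a   = mm_row(mediator_fit, a, pattern),
    xm_as  = mm_row(mediator_fit, a_star, pattern)
  )
}

# Log natural effects as a function of the stacked parameter (theta, beta).
# theta_a(a) - theta_a(a*) and theta_m + theta_am(a) are recovered as
# model-matrix row differences so arbitrary codings are handled.
log_effects_from_par <- function(rows, n_theta) {
  function(par) {
    theta <- par[seq_len(n_theta)]
    beta <- par[-seq_len(n_theta)]
    th_a_diff <- sum((rows$xo_a0 - rows$xo_as0) * theta)
    th_m_a <- sum((rows$xo_a1 - rows$xo_a0) * theta)
    th_m_as <- sum((rows$xo_as1 - rows$xo_as0) * theta)
    lm_a <- sum(rows$xm_a * beta)
    lm_as <- sum(rows$xm_as * beta)
    eta_a_as <- th_m_a + lm_as
    eta_as_as <- th_m_as + lm_as
    eta_a_a <- th_m_a + lm_a
    log_nde <- th_a_diff + log1pexp(eta_a_as) - log1pexp(eta_as_as)
    log_nie <- log1pexp(lm_as) + log1pexp(eta_a_a) -
      log1pexp(lm_a) - log1pexp(eta_a_as)
    c(nde = log_nde, nie = log_nie, te = log_nde + log_nie)
  }
}

#' Natural direct, indirect and total effects for one covariate pattern
#'
#' Odds-ratio-scale natural effects of setting the exposure to `a` rather
#' than `a_star`, at confounder values `pattern`, computed in closed form
#' from the outcome and mediator logistic fits (rare-outcome approximation).
#' The total effect factorizes exactly as `or_te = or_nde * or_nie`.
#'
#' @param outcome_fit,mediator_fit `med_glm` fits from [fit_outcome_model()]
#'   and [fit_mediator_model()], or pooled versions with the same labels
#'   (see [mediation_mi()]).
#' @param a,a_star Exposure levels to contrast (`a` vs reference `a_star`).
#' @param pattern Named list/one-row data frame of confounder values.
#' @return List with `log_nde`, `log_nie`, `log_te` and the ORs.
#' @export
natural_effects <- function(outcome_fit, mediator_fit, a, a_star, pattern) {
  rows <- effect_rows(outcome_fit, mediator_fit, a, a_star, pattern)
  f <- log_effects_from_par(rows, length(outcome_fit$coefficients))
  logs <- f(c(outcome_fit$coefficients, mediator_fit$coefficients))
  list(log_nde = unname(logs["nde"]), log_nie = unname(logs["nie"]),
       log_te = unname(logs["te"]),
       or_nde = exp(unname(logs["nde"])), or_nie = exp(unname(logs["nie"])),
       or_te = exp(unname(logs["te"])))
}

# Numeric gradient of the log-effect triple, central differences with a
# relative step of 1e-6; returns a 3 x p matrix.
effect_gradient <- function(f, par) {
  p <- length(par)
  g <- matrix(0, 3, p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(1, abs(par[j]))
    up <- par; up[j] <- par[j] + h
    dn <- par; dn[j] <- par[j] - h
    g[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  rownames(g) <- c("nde", "nie", "te")
  g
}

# Block-diagonal (theta, beta) covariance; the cross-covariance is zero
# because the two models are fitted separately.
stacked_vcov <- function(outcome_fit, mediator_fit) {
  vo <- outcome_fit$vcov
  vm <- mediator_fit$vcov
  p <- nrow(vo) + nrow(vm)
  v <- matrix(0, p, p)
  v[seq_len(nrow(vo)), seq_len(nrow(vo))] <- vo
  v[nrow(vo) + seq_len(nrow(vm)), nrow(vo) + seq_len(nrow(vm))] <- vm
  v
}

#' Delta-method standard errors for the log natural effects
#'
#' Multivariate delta method on the stacked (outcome, mediator) coefficient
#' vector, with block-diagonal covariance (the models are fitted separately,
#' so the cross block is zero).  Gradients are central-difference numeric
#' derivatives of the closed-form log-effect functions.  A singular
#' covariance triggers a pseudo-inverse-style PSD repair with a warning.
#'
#' @inheritParams natural_effects
#' @param conf_level Confidence level for the reported intervals.
#' @param df Degrees of freedom for the interval quantile (`Inf` gives the
#'   normal quantile).
#' @return Data frame with one row per effect: `effect`, `log_or`, `se`,
#'   `or`, `lo`, `hi`; the gradient matrix is attached as attribute
#'   `"gradient"` for reuse in pattern averaging.
#' @export
effect_standard_errors <- function(outcome_fit, mediator_fit, a, a_star, pattern,
                                   conf_level = 0.95, df = Inf) {
  rows <- effect_rows(outcome_fit, mediator_fit, a, a_star, pattern)
  n_theta <- length(outcome_fit$coefficients)
  par <- c(outcome_fit$coefficients, mediator_fit$coefficients)
  f <- log_effects_from_par(rows, n_theta)
  g <- effect_gradient(f, par)
  v <- stacked_vcov(outcome_fit, mediator_fit)
  var3 <- diag(g %*% v %*% t(g))
  if (any(var3 < -1e-10)) {
    warning("singular covariance: PSD repair applied")
    v <- nearest_psd(v, warn = FALSE)
    var3 <- diag(g %*% v %*% t(g))
  }
  se <- sqrt(pmax(var3, 0))
  logs <- f(par)
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df)
       else stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(effect = c("nde", "nie", "te"), log_or = unname(logs),
                    se = unname(se), or = exp(unname(logs)),
                    lo = exp(unname(logs) - q * se), hi = exp(unname(logs) + q * se))
  attr(out, "gradient") <- g
  out
}

#' Observed covariate patterns and their frequency weights
#'
#' @param table Data with the confounder columns.
#' @param confounders Character vector of confounder names.
#' @return Data frame of unique confounder combinations with a `weight`
#'   column (observed relative frequencies summing to 1).
#' @export
covariate_patterns <- function(table, confounders) {
  df <- as.data.frame(table)[confounders]
  key <- interaction(df, drop = TRUE, lex.order = TRUE)
  idx <- !duplicated(key)
  pat <- df[idx, , drop = FALSE]
  w <- as.numeric(table(key)[as.character(key[idx])]) / nrow(df)
  pat$weight <- w
  rownames(pat) <- NULL
  pat[order(as.character(interaction(pat[confounders], lex.order = TRUE))), ,
      drop = FALSE]
}

#' Average natural effects over covariate patterns
#'
#' Weighted mean of the per-pattern log odds ratios (observed-frequency
#' weights), i.e. a weighted geometric mean on the OR scale.  When per-
#' pattern gradients and the stacked covariance are supplied, the standard
#' error of the averaged log-OR is the delta-method SE of the weighted-sum
#' functional (gradient = weighted sum of pattern gradients).
#'
#' @param log_ors Numeric matrix, patterns x effects (columns nde/nie/te),
#'   of per-pattern log odds ratios.
#' @param weights Pattern weights; renormalized with a warning if they do
#'   not sum to 1.
#' @param gradients Optional list of per-pattern 3 x p gradient matrices.
#' @param vcov Optional stacked parameter covariance matching the gradients.
#' @return List with `log_or` (length-3), `or`, and (when gradients are
#'   given) `se`.
#' @export
average_effects <- function(log_ors, weights, gradients = NULL, vcov = NULL) {
  log_ors <- as.matrix(log_ors)
  stopifnot(nrow(log_ors) == length(weights))
  s <- sum(weights)
  if (abs(s - 1) > 1e-8) {
    warning("pattern weights do not sum to 1; renormalized")
    weights <- weights / s
  }
  avg <- drop(crossprod(log_ors, weights))
  out <- list(log_or = avg, or = exp(avg))
  if (!is.null(gradients) && !is.null(vcov)) {
    g <- Reduce(`+`, Map(function(gi, wi) wi * gi, gradients, weights))
    out$se <- sqrt(pmax(diag(g %*% vcov %*% t(g)), 0))
  }
  out
}

#' Full mediation-effect table from a pair of fits
#'
#' Per-pattern and pattern-averaged NDE/NIE/TE with delta-method SEs and
#' confidence intervals, for each requested exposure contrast.
#'
#' @param outcome_fit,mediator_fit `med_glm` (or pooled) fits.
#' @param patterns Data frame of covariate patterns with a `weight` column
#'   (see [covariate_patterns()]).
#' @param contrasts Character vector of exposure levels to contrast against
#'   the reference; default all non-reference levels.
#' @param conf_level Confidence level.
#' @return A `mediation_effects` data frame: `contrast`, `pattern` (id or
#'   `"average"`), `effect`, `or`, `lo`, `hi`, `se_log`.
#' @export
mediation_effects <- function(outcome_fit, mediator_fit, patterns,
                              contrasts = NULL, conf_level = 0.95) {
  roles <- outcome_fit$roles
  exp_levels <- outcome_fit$xlevels[[roles$exposure]]
  ref <- exp_levels[1]
  if (is.null(contrasts)) contrasts <- setdiff(exp_levels, ref)
  stopifnot("weight" %in% names(patterns))
  conf_cols <- setdiff(names(patterns), "weight")
  v <- stacked_vcov(outcome_fit, mediator_fit)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list()
  for (a in contrasts) {
    logs <- matrix(NA_real_, nrow(patterns), 3)
    grads <- vector("list", nrow(patterns))
    for (i in seq_len(nrow(patterns))) {
      pat <- patterns[i, conf_cols, drop = FALSE]
      se_tab <- effect_standard_errors(outcome_fit, mediator_fit, a, ref, pat,
                                       conf_level = conf_level)
      logs[i, ] <- se_tab$log_or
      grads[[i]] <- attr(se_tab, "gradient")
      out[[length(out) + 1]] <- data.frame(
        contrast = paste(a, "vs", ref), pattern = i,
        effect = se_tab$effect, or = se_tab$or, lo = se_tab$lo, hi = se_tab$hi,
        se_log = se_tab$se)
    }
    avg <- average_effects(logs, patterns$weight, grads, v)
    out[[length(out) + 1]] <- data.frame(
      contrast = paste(a, "vs", ref), pattern = "average",
      effect = c("nde", "nie", "te"), or = avg$or,
      lo = exp(avg$log_or - q * avg$se), hi = exp(avg$log_or + q * avg$se),
      se_log = avg$se)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mediation_effects", "data.frame")
  res
}

#' Mediation analysis integrated with multiple imputation
#'
#' Fits the outcome and mediator regressions in every completed data set,
#' pools the coefficient vectors and covariance matrices with Rubin's rules
#' ([pool_glm()]), and computes the natural-effect estimates and their
#' delta-method standard errors once from the pooled fits (pool-first, the
#' default ordering).  The alternative ordering — compute the log effects and
#' their variances per imputation, then pool them as scalars — is available
#' with `order = "compute_first"` for comparison.
#'
#' @param completed A `completed_set`.
#' @param roles A `role_map` with mediation roles set; the mediator defaults
#'   to the imputation target.
#' @param contrasts Exposure levels to contrast against the reference
#'   (default: all non-reference levels).
#' @param patterns Covariate patterns with weights; default: observed
#'   patterns of the first completed table.
#' @param interaction Include the exposure-mediator interaction in the
#'   outcome model.
#' @param order `"pool_first"` (default) or `"compute_first"`.
#' @param conf_level Confidence level.
#' @return A `mediation_effects` data frame (see [mediation_effects()]).
#' @export
mediation_mi <- function(completed, roles = NULL, contrasts = NULL,
                         patterns = NULL, interaction = FALSE,
                         order = c("pool_first", "compute_first"),
                         conf_level = 0.95) {
  stopifnot(inherits(completed, "completed_set"))
  order <- match.arg(order)
  if (is.null(roles)) roles <- completed$provenance$roles
  if (is.null(roles$mediator)) roles$mediator <- roles$target
  tabs <- completed$imputations
  ofits <- lapply(tabs, fit_outcome_model, roles = roles, interaction = interaction)
  mfits <- lapply(tabs, fit_mediator_model, roles = roles)
  if (is.null(patterns)) {
    patterns <- covariate_patterns(tabs[[1]], roles$confounders)
  }
  if (order == "pool_first") {
    po <- pool_glm(ofits)
    pm <- pool_glm(mfits)
    outcome_fit <- ofits[[1]]
    outcome_fit$coefficients <- po$coefficients
    outcome_fit$vcov <- po$vcov
    mediator_fit <- mfits[[1]]
    mediator_fit$coefficients <- pm$coefficients
    mediator_fit$vcov <- pm$vcov
    res <- mediation_effects(outcome_fit, mediator_fit, patterns,
                             contrasts = contrasts, conf_level = conf_level)
    attr(res, "pooled_outcome") <- po
    attr(res, "pooled_mediator") <- pm
  } else {
    per <- lapply(seq_along(tabs), function(m) {
      mediation_effects(ofits[[m]], mfits[[m]], patterns,
                        contrasts = contrasts, conf_level = conf_level)
    })
    base <- per[[1]][c("contrast", "pattern", "effect")]
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    pooled <- lapply(seq_len(nrow(base)), function(i) {
      ests <- vapply(per, function(p) log(p$or[i]), numeric(1))
      vars <- vapply(per, function(p) p$se_log[i]^2, numeric(1))
      ps <- pool_scalar(ests, vars, alpha = 1 - conf_level)
      data.frame(or = exp(ps$estimate), lo = exp(ps$lo), hi = exp(ps$hi),
                 se_log = ps$se)
    })
    res <- cbind(base, do.call(rbind, pooled))
    class(res) <- c("mediation_effects", "data.frame")
  }
  attr(res, "order") <- order
  attr(res, "patterns") <- patterns
  res
}

#' @export
print.mediation_effects <- function(x, ...) {
  cat(sprintf("mediation_effects: %d rows (%s)\n", nrow(x),
              attr(x, "order") %||% "single fit"))
  avg <- x[x$pattern == "average", , drop = FALSE]
  show <- if (nrow(avg)) avg else utils::head(as.data.frame(x), 12)
  df <- as.data.frame(show)
  df$or <- round(df$or, 3); df$lo <- round(df$lo, 3); df$hi <- round(df$hi, 3)
  df$se_log <- round(df$se_log, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
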