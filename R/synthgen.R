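# Pattern-mixture synthetic-data generator emulating a TB/HIV prevalence
# survey with an incomplete serological target, a 4-level self-report
# auxiliary, and known group-specific MNAR deltas.  Because Y is generated
# directly from its distribution given (X, Z, R) — the pattern-mixture
# factorization — the true delta offsets are exact by construction, and all
# covariates are discrete, so every population quantity is computable by
# exact enumeration over the covariate lattice.

synth_levels <- list(
  sex = c("M", "F"),
  age = c("18-24", "25-29", "30-34", "35-39", "40-49", "50+"),
  region = c("rural_lowARTI", "urban_lowARTI", "urban_highARTI", "lusaka_highARTI"),
  educ = c("none", "primary", "lower_secondary", "upper_secondary", "college"),
  aux = c("neg", "pos", "refused", "never")
)

#' Generator parameters
#'
#' Bundles the covariate distributions and model coefficients of the
#' synthetic survey.  All categorical distributions must sum to 1 and the
#' delta map must cover every auxiliary level.  See [default_params()] for
#' the documented default world.
#'
#' @param n Number of rows.
#' @param seed RNG seed (same params + seed give a byte-identical table).
#' @param p_sex,p_age,p_region,p_educ Named marginal distributions.
#' @param aux_base Named list (per sex) of log-weights over auxiliary levels.
#' @param aux_age Per-level slopes on the scaled age index (0..1).
#' @param aux_region Matrix (region x auxiliary level) of log-weight shifts.
#' @param y_intercept,y_sex,y_age,y_region,y_educ,y_aux Log-odds coefficients
#'   of the target model given (X, Z): intercept, female shift, and per-level
#'   vectors (reference level 0).
#' @param delta Named per-auxiliary-level log-odds offsets added for rows
#'   with the target missing — the true pattern-mixture deltas.
#' @param r_intercept,r_sex,r_age,r_region,r_aux Log-odds coefficients of
#'   the missingness model Pr(R = 0 | X, Z).
#' @param t_intercept,t_mediator,t_sex,t_age,t_region,t_educ Log-odds
#'   coefficients of the binary outcome (TB) model given the target
#'   (mediator), exposure (education) and confounders.
#' @return A `synth_params` object.
#' @export
synth_params <- function(n, seed,
                         p_sex, p_age, p_region, p_educ,
                         aux_base, aux_age, aux_region,
                         y_intercept, y_sex, y_age, y_region, y_educ, y_aux,
                         delta,
                         r_intercept, r_sex, r_age, r_region, r_aux,
                         t_intercept, t_mediator, t_sex, t_age, t_region, t_educ) {
  lv <- synth_levels
  check_dist <- function(p, levs, nm) {
    if (!isTRUE(all.equal(sum(p), 1)) || any(p < 0) ||
        !setequal(names(p), levs)) {
      stop(sprintf("'%s' must be a distribution over {%s} summing to 1",
                   nm, paste(levs, collapse = ", ")))
    }
    p[levs]
  }
  p_sex <- check_dist(p_sex, lv$sex, "p_sex")
  p_age <- check_dist(p_age, lv$age, "p_age")
  p_region <- check_dist(p_region, lv$region, "p_region")
  p_educ <- check_dist(p_educ, lv$educ, "p_educ")
  if (!setequal(names(delta), lv$aux)) {
    stop("delta map must cover all auxiliary levels: ",
         paste(lv$aux, collapse = ", "))
  }
  stopifnot(n >= 1, all(is.finite(delta)))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 p_sex = p_sex, p_age = p_age, p_region = p_region,
                 p_educ = p_educ,
                 aux_base = aux_base, aux_age = aux_age, aux_region = aux_region,
                 y_intercept = y_intercept, y_sex = y_sex, y_age = y_age[lv$age],
                 y_region = y_region[lv$region], y_educ = y_educ[lv$educ],
                 y_aux = y_aux[lv$aux], delta = delta[lv$aux],
                 r_intercept = r_intercept, r_sex = r_sex, r_age = r_age[lv$age],
                 r_region = r_region[lv$region], r_aux = r_aux[lv$aux],
                 t_intercept = t_intercept, t_mediator = t_mediator,
                 t_sex = t_sex, t_age = t_age[lv$age],
                 t_region = t_region[lv$region], t_educ = t_educ[lv$educ]),
            class = "synth_params")
}

#' Default synthetic world
#'
#' A documented parameter set echoing the margins of a large Zambian TB/HIV
#' prevalence survey: roughly 34%/66% male/female, six age bands, four
#' regions, five education levels; self-report distribution varying by sex,
#' age and region; a strongly coupled auxiliary (self-reported positives
#' have target prevalence above 0.9); about 32% missingness in the target,
#' with refusal ordered non-disclosers > self-reported positives > never
#' tested > self-reported negatives; overall target prevalence about 18%;
#' and true pattern-mixture deltas exp(delta) = (2.5, 1, 2.5, 1) for the
#' (negative, positive, non-discloser, never-tested) self-report groups.
#' The outcome (TB) model couples to the target with log-odds ln 3.
#'
#' @param n Number of rows (default 30000).
#' @param seed RNG seed.
#' @return A `synth_params` object.
#' @export
default_params <- function(n = 30000, seed = 1) {
  lv <- synth_levels
  nm <- function(x, levs) stats::setNames(x, levs)
  synth_params(
    n = n, seed = seed,
    p_sex = nm(c(0.34, 0.66), lv$sex),
    p_age = nm(c(0.345, 0.172, 0.126, 0.088, 0.113, 0.156), lv$age),
    p_region = nm(c(0.29, 0.22, 0.19, 0.30), lv$region),
    p_educ = nm(c(0.065, 0.32, 0.26, 0.285, 0.07), lv$educ),
    aux_base = list(M = nm(log(c(0.37, 0.035, 0.026, 0.555)), lv$aux),
                    F = nm(log(c(0.52, 0.060, 0.032, 0.362)), lv$aux)),
    aux_age = nm(c(0.6, 1.2, 0.8, 0), lv$aux),
    aux_region = matrix(c(0.15, 0.1, 0.0, 0,
                          -0.1, 0.2, 0.1, 0,
                          0.0, 0.1, 0.0, 0,
                          0.25, -0.1, -0.1, 0),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(lv$region, lv$aux)),
    y_intercept = -3.45, y_sex = 0.55,
    y_age = nm(c(0, 1.25, 1.75, 1.95, 1.85, 0.55), lv$age),
    y_region = nm(c(0, 0.6, 0.35, 0.3), lv$region),
    y_educ = nm(c(-0.1, 0, -0.05, -0.35, -0.5), lv$educ),
    y_aux = nm(c(-0.9, 6.0, 0.8, 0), lv$aux),
    delta = nm(log(c(2.5, 1, 2.5, 1)), lv$aux),
    r_intercept = -0.88, r_sex = -0.1,
    r_age = nm(c(0, 0.1, 0.17, 0.22, 0.16, 0.1), lv$age),
    r_region = nm(c(0.25, 0.5, 0.35, -0.35), lv$region),
    r_aux = nm(c(-0.25, 0.35, 0.65, 0), lv$aux),
    t_intercept = -4.3, t_mediator = log(3),
    t_sex = -0.35,
    t_age = nm(c(0, 0.25, 0.35, 0.4, 0.35, 0.3), lv$age),
    t_region = nm(c(0, 0.2, 0.15, 0.1), lv$region),
    t_educ = nm(c(0.3, 0, -0.2, -0.3, -0.8), lv$educ)
  )
}

#' @export
print.synth_params <- function(x, ...) {
  cat(sprintf("synth_params: n = %d, seed = %d\n", x$n, x$seed))
  cat("  true exp(delta):",
      paste(sprintf("%s=%.3g", names(x$delta), exp(x$delta)), collapse = ", "), "\n")
  invisible(x)
}

# Auxiliary-level probabilities for given (sex, age index 0..1, region rows).
aux_probs <- function(params, sex, age_idx, region) {
  lw <- do.call(rbind, lapply(seq_along(sex), function(i) {
    params$aux_base[[sex[i]]] + params$aux_age * age_idx[i] +
      params$aux_region[region[i], ]
  }))
  p <- exp(lw)
  p / rowSums(p)
}

# One categorical draw per row from a matrix of row-wise probabilities.
sample_cat <- function(prob, levels) {
  u <- stats::runif(nrow(prob))
  cum <- t(apply(prob, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  levels[idx]
}

y_linpred <- function(params, sex, age, region, educ, aux) {
  params$y_intercept + params$y_sex * (sex == "F") +
    params$y_age[age] + params$y_region[region] +
    params$y_educ[educ] + params$y_aux[aux]
}

miss_linpred <- function(params, sex, age, region, aux) {
  params$r_intercept + params$r_sex * (sex == "F") +
    params$r_age[age] + params$r_region[region] + params$r_aux[aux]
}

tb_linpred <- function(params, y, sex, age, region, educ) {
  params$t_intercept + params$t_mediator * y + params$t_sex * (sex == "F") +
    params$t_age[age] + params$t_region[region] + params$t_educ[educ]
}

#' Generate a synthetic study table with ground truth
#'
#' Draws covariates and the auxiliary self-report, then the missingness
#' indicator R given (X, Z), then the target from
#' `logit Pr(Y = 1 | X, Z, R) = linpred(X, Z) + delta_z (1 - R)` — the
#' pattern-mixture construction, so the generating delta is exactly the
#' offset a delta-adjusted imputer should use — then the binary outcome from
#' the outcome model given (Y, exposure, confounders).  The emitted table has
#' the target blanked where R = 0.  The accompanying `truth_record` is
#' computed by exact enumeration over the discrete covariate lattice, not by
#' simulation.
#'
#' @param params A `synth_params` object.
#' @return List with `table` (a `study_table`), `truth` (a `truth_record`),
#'   `roles` (a ready-made `role_map`), and `schema`.
#' @export
generate_study <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  lv <- synth_levels
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  n <- params$n
  sex <- sample(lv$sex, n, replace = TRUE, prob = params$p_sex)
  age <- sample(lv$age, n, replace = TRUE, prob = params$p_age)
  region <- sample(lv$region, n, replace = TRUE, prob = params$p_region)
  educ <- sample(lv$educ, n, replace = TRUE, prob = params$p_educ)
  age_idx <- (match(age, lv$age) - 1) / (length(lv$age) - 1)
  aux <- sample_cat(aux_probs(params, sex, age_idx, region), lv$aux)
  p_miss <- stats::plogis(miss_linpred(params, sex, age, region, aux))
  r <- as.integer(stats::runif(n) >= p_miss)    # R = 1 observed
  eta_y <- y_linpred(params, sex, age, region, educ, aux) +
    params$delta[aux] * (1 - r)
  y <- as.integer(stats::runif(n) < stats::plogis(eta_y))
  tb <- as.integer(stats::runif(n) < stats::plogis(
    tb_linpred(params, y, sex, age, region, educ)))
  y_out <- ifelse(r == 1L, y, NA_integer_)
  df <- data.frame(hiv = y_out, tb = tb, sex = sex, age = age,
                   region = region, educ = educ, selfreport = aux,
                   stringsAsFactors = FALSE)
  schema <- list(hiv = "binary", tb = "binary", sex = lv$sex, age = lv$age,
                 region = lv$region,
                 educ = c("primary", setdiff(lv$educ, "primary")),
                 selfreport = lv$aux)
  tab <- study_table(df, schema)
  roles <- role_map(target = "hiv", auxiliary = "selfreport",
                    exposure = "educ", exposure_ref = "primary",
                    outcome = "tb", mediator = "hiv",
                    confounders = c("age", "sex", "region"), strata = "sex")
  list(table = tab, truth = enumerate_truth(params), roles = roles,
       schema = schema)
}

# Joint lattice over (sex, age, region, educ, aux, r) with cell probabilities
# and P(Y = 1 | cell).
truth_lattice <- function(params) {
  lv <- synth_levels
  g <- expand.grid(sex = lv$sex, age = lv$age, region = lv$region,
                   educ = lv$educ, aux = lv$aux, r = c(1L, 0L),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  age_idx <- (match(g$age, lv$age) - 1) / (length(lv$age) - 1)
  pa <- aux_probs(params, g$sex, age_idx, g$region)
  p_aux <- pa[cbind(seq_len(nrow(g)), match(g$aux, lv$aux))]
  pm <- stats::plogis(miss_linpred(params, g$sex, g$age, g$region, g$aux))
  p_r <- ifelse(g$r == 1L, 1 - pm, pm)
  g$prob <- params$p_sex[g$sex] * params$p_age[g$age] *
    params$p_region[g$region] * params$p_educ[g$educ] * p_aux * p_r
  g$p_y <- stats::plogis(
    y_linpred(params, g$sex, g$age, g$region, g$educ, g$aux) +
      params$delta[g$aux] * (1 - g$r))
  g
}

#' Exact population truth of a synthetic world
#'
#' Computed by enumeration over the discrete covariate lattice: overall,
#' sex-specific and self-report-group prevalences of the target; the
#' observed-rows (complete-case estimand) prevalence; the missingness
#' fraction; and, when the target model has no auxiliary coupling and zero
#' deltas (so the mediator regression on exposure + confounders is exactly
#' the generating model), closed-form natural effects per exposure contrast.
#'
#' @param params A `synth_params` object.
#' @return A `truth_record` list.
#' @export
enumerate_truth <- function(params) {
  lat <- truth_lattice(params)
  stopifnot(isTRUE(all.equal(sum(lat$prob), 1)))
  wmean <- function(mask) {
    sum(lat$prob[mask] * lat$p_y[mask]) / sum(lat$prob[mask])
  }
  all_rows <- rep(TRUE, nrow(lat))
  by_sex <- vapply(synth_levels$sex, function(s) wmean(lat$sex == s), numeric(1))
  by_aux <- vapply(synth_levels$aux, function(z) wmean(lat$aux == z), numeric(1))
  med <- NULL
  if (all(params$y_aux == 0) && all(params$delta == 0)) {
    med <- truth_mediation(params)
  }
  structure(list(
    prevalence = wmean(all_rows),
    prevalence_by_sex = by_sex,
    prevalence_by_aux = by_aux,
    prevalence_observed = wmean(lat$r == 1L),
    prevalence_missing_rows = wmean(lat$r == 0L),
    missing_fraction = sum(lat$prob[lat$r == 0L]),
    delta = params$delta,
    mediation = med
  ), class = "truth_record")
}

# Closed-form natural effects (no exposure-mediator interaction in the
# generator, so the NDE is exp of the outcome-model exposure contrast).
truth_mediation <- function(params) {
  lv <- synth_levels
  pats <- expand.grid(sex = lv$sex, age = lv$age, region = lv$region,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  w <- params$p_sex[pats$sex] * params$p_age[pats$age] * params$p_region[pats$region]
  lm_at <- function(a, i) {
    params$y_intercept + params$y_sex * (pats$sex[i] == "F") +
      params$y_age[pats$age[i]] + params$y_region[pats$region[i]] +
      params$y_educ[a]
  }
  ref <- "primary"
  out <- list()
  for (a in setdiff(lv$educ, ref)) {
    log_nde <- params$t_educ[a] - params$t_educ[ref]
    log_nie <- vapply(seq_len(nrow(pats)), function(i) {
      la <- lm_at(a, i); lr <- lm_at(ref, i)
      log1pexp(lr) + log1pexp(params$t_mediator + la) -
        log1pexp(la) - log1pexp(params$t_mediator + lr)
    }, numeric(1))
    out[[a]] <- list(log_nde = unname(log_nde), log_nie = log_nie,
                     avg_log_nie = sum(w * log_nie),
                     avg_log_te = unname(log_nde) + sum(w * log_nie))
  }
  list(contrast_ref = ref, patterns = pats, weights = unname(w), effects = out)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("truth_record (exact enumeration):\n")
  cat(sprintf("  prevalence          %.4f\n", x$prevalence))
  cat(sprintf("  missing fraction    %.4f\n", x$missing_fraction))
  cat(sprintf("  prevalence | R=1    %.4f\n", x$prevalence_observed))
  cat("  by sex:", paste(sprintf("%s=%.4f", names(x$prevalence_by_sex),
                                 x$prevalence_by_sex), collapse = ", "), "\n")
  cat("  by selfreport:", paste(sprintf("%s=%.4f", names(x$prevalence_by_aux),
                                        x$prevalence_by_aux), collapse = ", "), "\n")
  invisible(x)
}
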