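# Fixtures shared across test files; everything is built in code.

# Small table with an incomplete binary target, one binary covariate and a
# 2-level auxiliary.  n_obs rows observed (n_pos of them 1), n_miss missing.
toy_table <- function(n_obs = 10, n_pos = 3, n_miss = 2, seed = 42) {
  set.seed(seed)
  n <- n_obs + n_miss
  y <- c(rep(1L, n_pos), rep(0L, n_obs - n_pos), rep(NA_integer_, n_miss))
  df <- data.frame(y = y,
                   x = rep(c(0L, 1L), length.out = n),
                   z = rep(c("u", "v"), length.out = n))
  study_table(df, list(y = "binary", x = "binary", z = c("u", "v")))
}

toy_roles <- function() {
  role_map(target = "y", auxiliary = "z")
}

# completed_set with hand-chosen completed tables (for pooling unit tests).
fake_completed <- function(dfs, target = "y") {
  structure(list(imputations = dfs,
                 provenance = list(roles = list(target = target),
                                   delta = delta_spec(0),
                                   n_missing = 0L, common_rng = TRUE)),
            class = "completed_set")
}

# A completed table with n rows of which k are ones.
prev_df <- function(k, n) data.frame(y = rep(c(1L, 0L), c(k, n - k)))

# Mediation fits with exact, hand-set coefficients.  The models are fitted on
# a balanced toy layout only to obtain the terms/xlevels scaffolding; the
# coefficients and covariances are then overwritten.
toy_med_fits <- function(theta0, theta_a, theta_m, theta_am = NULL,
                         beta0, beta_a, vcov_scale = 0) {
  grid <- expand.grid(x = c("a0", "a1"), m = 0:1, y = 0:1,
                      stringsAsFactors = FALSE)
  df <- grid[rep(seq_len(nrow(grid)), 5), ]
  roles <- role_map(target = "m", exposure = "x", exposure_ref = "a0",
                    outcome = "y", mediator = "m", confounders = character())
  with_int <- !is.null(theta_am)
  ofit <- suppressWarnings(fit_outcome_model(df, roles, interaction = with_int))
  mfit <- suppressWarnings(fit_mediator_model(df, roles))
  oc <- c("(Intercept)" = theta0, "xa1" = theta_a, "m" = theta_m)
  if (with_int) oc <- c(oc, "xa1:m" = theta_am)
  stopifnot(setequal(names(oc), names(ofit$coefficients)))
  ofit$coefficients[names(oc)] <- oc
  ofit$vcov <- diag(vcov_scale, length(oc))
  dimnames(ofit$vcov) <- list(names(ofit$coefficients), names(ofit$coefficients))
  mc <- c("(Intercept)" = beta0, "xa1" = beta_a)
  mfit$coefficients[names(mc)] <- mc
  mfit$vcov <- diag(vcov_scale, 2)
  dimnames(mfit$vcov) <- list(names(mfit$coefficients), names(mfit$coefficients))
  list(outcome = ofit, mediator = mfit, roles = roles)
}

# Synthetic mediation data with known coefficients: binary exposure (factor),
# one binary confounder, binary mediator and outcome.
sim_mediation_data <- function(n, theta0 = -2, theta_a = log(2),
                               theta_m = log(3), theta_am = 0,
                               beta0 = -1, beta_a = 1, beta_c = 0.5,
                               theta_c = 0.3, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  cvar <- rbinom(n, 1, 0.4)
  m <- rbinom(n, 1, plogis(beta0 + beta_a * x + beta_c * cvar))
  y <- rbinom(n, 1, plogis(theta0 + theta_a * x + theta_m * m +
                             theta_am * x * m + theta_c * cvar))
  data.frame(y = y, m = m, x = factor(ifelse(x == 1, "a1", "a0")),
             cvar = factor(ifelse(cvar == 1, "c1", "c0")))
}

med_roles <- function() {
  role_map(target = "m", exposure = "x", exposure_ref = "a0",
           outcome = "y", mediator = "m", confounders = "cvar")
}
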