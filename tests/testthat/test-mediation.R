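test_that("natural effects reduce to closed forms on hand-set coefficients", {
  # theta_am = 0: NDE = exp(theta_a) regardless of the mediator model
  f <- toy_med_fits(theta0 = -3, theta_a = log(2), theta_m = log(3),
                    beta0 = -1, beta_a = 1)
  ne <- natural_effects(f$outcome, f$mediator, "a1", "a0", list())
  expect_equal(ne$or_nde, 2, tolerance = 1e-12)
  # hand-evaluated NIE on the same coefficients: (1.36788 * 4)/(2 * 2.10364)
  expect_equal(ne$or_nie,
               ((1 + exp(-1)) * (1 + exp(log(3)))) /
                 ((1 + exp(0)) * (1 + 3 * exp(-1))), tolerance = 1e-12)
  expect_equal(ne$or_nie, 1.3005, tolerance = 1e-4)
  # decomposition identity to machine precision
  expect_equal(ne$or_te, ne$or_nde * ne$or_nie, tolerance = 1e-15)

  # beta_a = 0: the exposure does not move the mediator, NIE exactly 1
  f2 <- toy_med_fits(theta0 = -3, theta_a = log(2), theta_m = log(3),
                     beta0 = -1, beta_a = 0)
  expect_equal(natural_effects(f2$outcome, f2$mediator, "a1", "a0", list())$or_nie,
               1, tolerance = 1e-12)

  # theta_m = 0 also forces NIE = 1
  f3 <- toy_med_fits(theta0 = -3, theta_a = log(2), theta_m = 0,
                     beta0 = -1, beta_a = 1)
  expect_equal(natural_effects(f3$outcome, f3$mediator, "a1", "a0", list())$or_nie,
               1, tolerance = 1e-12)
})

test_that("without exposure-mediator interaction the NDE is constant over patterns", {
  d <- sim_mediation_data(4000, theta_am = 0, seed = 2)
  roles <- med_roles()
  ofit <- fit_outcome_model(d, roles, interaction = FALSE)
  mfit <- fit_mediator_model(d, roles)
  pats <- covariate_patterns(d, "cvar")
  ndes <- vapply(seq_len(nrow(pats)), function(i) {
    natural_effects(ofit, mfit, "a1", "a0", pats[i, "cvar", drop = FALSE])$or_nde
  }, numeric(1))
  expect_equal(ndes, rep(exp(unname(ofit$coefficients["xa1"])), nrow(pats)),
               tolerance = 1e-12)
  # identity audit on every pattern
  for (i in seq_len(nrow(pats))) {
    ne <- natural_effects(ofit, mfit, "a1", "a0", pats[i, "cvar", drop = FALSE])
    expect_equal(ne$or_te, ne$or_nde * ne$or_nie, tolerance = 1e-14)
  }
})

test_that("interaction Wald p-values are uniform under a zero-interaction truth", {
  pvals <- vapply(1:200, function(s) {
    d <- sim_mediation_data(2000, theta_am = 0, seed = 1000 + s)
    fit_outcome_model(d, med_roles(), interaction = TRUE)$wald_interaction$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("outcome-model coefficients are recovered on large samples", {
  d <- sim_mediation_data(50000, theta_m = log(3), seed = 6)
  ofit <- fit_outcome_model(d, med_roles())
  se_m <- sqrt(ofit$vcov["m", "m"])
  expect_lt(abs(ofit$coefficients[["m"]] - log(3)), 3 * se_m)
  # zero-signal data: all non-intercept coefficients within 3 SEs of 0
  d0 <- sim_mediation_data(20000, theta_a = 0, theta_m = 0, theta_am = 0,
                           beta_a = 0, beta_c = 0, theta_c = 0, seed = 8)
  o0 <- fit_outcome_model(d0, med_roles())
  for (nm in setdiff(names(o0$coefficients), "(Intercept)")) {
    expect_lt(abs(o0$coefficients[[nm]]), 3 * sqrt(o0$vcov[nm, nm]))
  }
})

test_that("delta-method machinery: zero vcov, triangle inequality, analytic gradients", {
  f <- toy_med_fits(theta0 = -3, theta_a = log(2), theta_m = log(3),
                    theta_am = 0.4, beta0 = -1, beta_a = 1, vcov_scale = 0)
  se0 <- effect_standard_errors(f$outcome, f$mediator, "a1", "a0", list())
  expect_equal(se0$se, rep(0, 3))

  # triangle inequality on real fits
  d <- sim_mediation_data(3000, theta_am = 0.3, seed = 4)
  roles <- med_roles()
  ofit <- fit_outcome_model(d, roles, interaction = TRUE)
  mfit <- fit_mediator_model(d, roles)
  se <- effect_standard_errors(ofit, mfit, "a1", "a0", list(cvar = "c0"))
  expect_lte(se$se[se$effect == "te"],
             se$se[se$effect == "nde"] + se$se[se$effect == "nie"] + 1e-12)

  # numeric gradients agree with hand-derived analytic gradients
  # (no-confounder binary-exposure case with interaction)
  th0 <- -3; tha <- log(2); thm <- log(3); tham <- 0.4; b0 <- -1; ba <- 1
  fa <- toy_med_fits(th0, tha, thm, tham, b0, ba, vcov_scale = 0)
  rows <- deltami:::effect_rows(fa$outcome, fa$mediator, "a1", "a0", list())
  fn <- deltami:::log_effects_from_par(rows, 4)
  g <- deltami:::effect_gradient(fn, c(fa$outcome$coefficients,
                                       fa$mediator$coefficients))
  s <- plogis
  lm1 <- b0 + ba; lm0 <- b0
  e_a_as <- thm + tham + lm0; e_as_as <- thm + lm0; e_a_a <- thm + tham + lm1
  g_nde <- c(0, 1, s(e_a_as) - s(e_as_as), s(e_a_as),
             s(e_a_as) - s(e_as_as), 0)
  g_nie <- c(0, 0, s(e_a_a) - s(e_a_as), s(e_a_a) - s(e_a_as),
             s(lm0) + s(e_a_a) - s(lm1) - s(e_a_as), s(e_a_a) - s(lm1))
  expect_equal(unname(g["nde", ]), g_nde, tolerance = 1e-6)
  expect_equal(unname(g["nie", ]), g_nie, tolerance = 1e-6)
  expect_equal(unname(g["te", ]), g_nde + g_nie, tolerance = 1e-6)
})

test_that("delta-method SEs agree with a nonparametric bootstrap", {
  n <- 2000
  d <- sim_mediation_data(n, seed = 12)
  roles <- med_roles()
  ofit <- fit_outcome_model(d, roles)
  mfit <- fit_mediator_model(d, roles)
  pat <- list(cvar = "c0")
  se_delta <- effect_standard_errors(ofit, mfit, "a1", "a0", pat)
  set.seed(99)
  boot <- t(vapply(1:500, function(b) {
    db <- d[sample.int(n, n, replace = TRUE), ]
    ob <- fit_outcome_model(db, roles)
    mb <- fit_mediator_model(db, roles)
    ne <- natural_effects(ob, mb, "a1", "a0", pat)
    c(ne$log_nde, ne$log_nie)
  }, numeric(2)))
  se_boot <- apply(boot, 2, sd)
  expect_lt(abs(se_delta$se[se_delta$effect == "nde"] - se_boot[1]) / se_boot[1], 0.15)
  expect_lt(abs(se_delta$se[se_delta$effect == "nie"] - se_boot[2]) / se_boot[2], 0.15)
})

test_that("pattern averaging is a weighted geometric mean with sane edge cases", {
  # two patterns, log-ORs (0, ln 4), equal weights -> averaged OR = 2
  lo <- rbind(c(0, 0, 0), c(log(4), log(4), log(4)))
  colnames(lo) <- c("nde", "nie", "te")
  avg <- average_effects(lo, c(0.5, 0.5))
  expect_equal(unname(avg$or), rep(2, 3))
  # identical per-pattern effects average to the common value
  lo2 <- rbind(c(0.3, -0.1, 0.2), c(0.3, -0.1, 0.2))
  expect_equal(unname(average_effects(lo2, c(0.4, 0.6))$log_or), c(0.3, -0.1, 0.2))
  # non-normalized weights renormalize with a warning
  expect_warning(a3 <- average_effects(lo, c(1, 1)), "renormalized")
  expect_equal(unname(a3$or), rep(2, 3))
})

test_that("MI mediation with identical completed tables equals the single-data analysis", {
  d <- sim_mediation_data(1500, seed = 21)
  cs <- fake_completed(list(d, d, d), target = "m")
  cs$provenance$roles <- med_roles()
  res_mi <- mediation_mi(cs)
  ofit <- fit_outcome_model(d, med_roles())
  mfit <- fit_mediator_model(d, med_roles())
  res_1 <- mediation_effects(ofit, mfit, covariate_patterns(d, "cvar"))
  expect_equal(res_mi$or, res_1$or, tolerance = 1e-10)
  expect_equal(res_mi$se_log, res_1$se_log, tolerance = 1e-10)
  # identity audit across the whole output
  for (ctr in unique(res_mi$contrast)) for (p in unique(res_mi$pattern)) {
    sl <- res_mi[res_mi$contrast == ctr & res_mi$pattern == p, ]
    expect_equal(sl$or[sl$effect == "te"],
                 sl$or[sl$effect == "nde"] * sl$or[sl$effect == "nie"],
                 tolerance = 1e-12)
  }
  # the compute-then-pool ordering agrees here exactly (B = 0)
  res_alt <- mediation_mi(cs, order = "compute_first")
  expect_equal(res_alt$or, res_1$or, tolerance = 1e-10)
})

test_that("MI mediation recovers generator truth under MAR missingness", {
  par <- default_params(n = 30000, seed = 17)
  par$y_aux[] <- 0          # no auxiliary coupling: mediator model is exact
  par$delta[] <- 0          # MAR world
  g <- generate_study(par)
  cfg <- imputation_config(c("age", "region", "educ", "selfreport", "tb"),
                           M = 25, seed = 33, strata = "sex")
  cs <- impute_mar(g$table, g$roles, cfg)
  res <- mediation_mi(cs)
  truth <- g$truth$mediation
  expect_false(is.null(truth))
  # compare at one fixed covariate pattern so estimate and truth share weights
  pats <- attr(res, "patterns")
  target_pat <- list(sex = "F", age = "25-29", region = "urban_lowARTI")
  i_est <- which(pats$sex == target_pat$sex & pats$age == target_pat$age &
                   pats$region == target_pat$region)
  tp <- truth$patterns
  i_tru <- which(tp$sex == target_pat$sex & tp$age == target_pat$age &
                   tp$region == target_pat$region)
  for (a in c("upper_secondary", "college")) {
    ctr <- paste(a, "vs primary")
    sl <- res[res$contrast == ctr & res$pattern == i_est, ]
    expect_lt(abs(log(sl$or[sl$effect == "nde"]) - truth$effects[[a]]$log_nde),
              3 * sl$se_log[sl$effect == "nde"])
    expect_lt(abs(log(sl$or[sl$effect == "nie"]) - truth$effects[[a]]$log_nie[i_tru]),
              3 * sl$se_log[sl$effect == "nie"])
  }
})
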