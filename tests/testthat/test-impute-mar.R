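test_that("design matrices use reference-level dummy coding without interactions", {
  g <- generate_study(default_params(n = 2000, seed = 11))
  tab <- g$table
  # 6 age bands + 4 regions -> 1 + 5 + 3 = 9 columns
  d <- build_design(tab, c("age", "region"))
  expect_equal(ncol(d$x), 9)
  expect_equal(d$labels[1], "(Intercept)")
  expect_false(any(grepl(":", d$labels)))
  # 5-level education -> 4 dummies, declared reference (primary) absorbed
  d2 <- build_design(tab, "educ")
  expect_equal(ncol(d2$x), 5)
  expect_false("educprimary" %in% d2$labels)
})

test_that("constant predictors within a stratum are dropped with a warning", {
  df <- data.frame(y = c(1L, 0L, 1L, NA),
                   w = c("k", "k", "k", "k"),
                   x = c(0L, 1L, 0L, 1L))
  tab <- study_table(df, list(y = "binary", w = c("k", "l"), x = "binary"))
  expect_warning(d <- build_design(tab, c("w", "x")), "constant")
  expect_equal(ncol(d$x), 2)  # intercept + x only
})

test_that("logistic imputation fits match closed-form MLEs", {
  # intercept-only: 3 positives of 10 observed -> intercept ln(3/7)
  tab <- toy_table(n_obs = 10, n_pos = 3, n_miss = 2)
  d <- build_design(tab, character())
  fit <- fit_imputation_model(d$x, tab$y)
  expect_equal(unname(fit$coefficients), log(3 / 7), tolerance = 1e-6)

  # saturated one-binary-covariate fit on counts (a,b;c,d): slope ln(ad/bc)
  a <- 4; b <- 6; c_ <- 2; d_ <- 8
  df <- data.frame(y = c(rep(1L, a), rep(0L, b), rep(1L, c_), rep(0L, d_)),
                   x = rep(c(1L, 0L), c(a + b, c_ + d_)))
  tab2 <- study_table(df, list(y = "binary", x = "binary"))
  d2 <- build_design(tab2, "x")
  fit2 <- fit_imputation_model(d2$x, tab2$y)
  expect_equal(unname(fit2$coefficients["x"]), log(a * d_ / (b * c_)),
               tolerance = 1e-6)
  # saturated fit reproduces observed cell frequencies
  p_hat <- unname(plogis(drop(unique(d2$x) %*% fit2$coefficients)))
  expect_equal(sort(p_hat), sort(c(a / (a + b), c_ / (c_ + d_))),
               tolerance = 1e-6)
})

test_that("all-equal observed target is rejected", {
  df <- data.frame(y = c(1L, 1L, NA), x = c(0L, 1L, 0L))
  tab <- study_table(df, list(y = "binary", x = "binary"))
  d <- build_design(tab, "x")
  expect_error(fit_imputation_model(d$x, tab$y), "degenerate target")
})

test_that("near-separated strata fall back to a penalized fit with finite coefficients", {
  set.seed(5)
  n <- 60
  z <- rep(c("hi", "lo"), c(30, 30))
  y <- ifelse(z == "hi", rbinom(n, 1, 0.995), rbinom(n, 1, 0.1))
  df <- data.frame(y = as.integer(y), z = z)
  tab <- study_table(df, list(y = "binary", z = c("lo", "hi")))
  d <- build_design(tab, "z")
  fit <- fit_imputation_model(d$x, tab$y)
  expect_equal(fit$engine, "penalized")
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(diag(fit$vcov))))
})

test_that("fitting uses only observed rows: unobserved covariates are inert", {
  g <- generate_study(default_params(n = 3000, seed = 21))
  tab <- g$table
  cfg <- imputation_config(c("age", "region", "selfreport"), M = 2, seed = 3,
                           strata = "sex")
  miss <- is.na(tab$hiv)
  tab_perm <- tab
  perm <- sample(which(miss))
  tab_perm$age[miss] <- tab$age[perm]     # permute covariates on unobserved rows
  f1 <- deltami:::fit_strata(tab, g$roles, cfg)
  f2 <- deltami:::fit_strata(tab_perm, g$roles, cfg)
  for (s in seq_along(f1)) {
    expect_identical(f1[[s]]$fit$coefficients, f2[[s]]$fit$coefficients)
    expect_identical(f1[[s]]$fit$vcov, f2[[s]]$fit$vcov)
  }
})

test_that("sex-stratified fits equal a fully interacted single fit on a saturated design", {
  set.seed(9)
  n <- 400
  s <- rep(c("M", "F"), each = n / 2)
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + x + 0.5 * (s == "F") - 0.8 * x * (s == "F")))
  df <- data.frame(y = as.integer(y), x = as.integer(x), s = s)
  tab <- study_table(df, list(y = "binary", x = "binary", s = c("M", "F")))
  # stratified fit for the stratum that is the interacted model's baseline
  full <- glm(y ~ x * s, family = binomial(), data = df)  # baseline level "F"
  dF <- build_design(tab, "x", rows = tab$s == "F")
  fF <- fit_imputation_model(dF$x, tab$y[tab$s == "F"])
  expect_equal(unname(fF$coefficients),
               unname(coef(full)[c("(Intercept)", "x")]), tolerance = 1e-5)
  # and the other stratum matches baseline + interaction contrasts
  dM <- build_design(tab, "x", rows = tab$s == "M")
  fM <- fit_imputation_model(dM$x, tab$y[tab$s == "M"])
  expect_equal(unname(fM$coefficients),
               unname(c(coef(full)["(Intercept)"] + coef(full)["sM"],
                        coef(full)["x"] + coef(full)["x:sM"])), tolerance = 1e-5)
})

test_that("parameter draws are proper, reproducible and centred at the MLE", {
  tab <- toy_table(n_obs = 40, n_pos = 12, n_miss = 5)
  d <- build_design(tab, "x")
  fit <- fit_imputation_model(d$x, tab$y)

  # deterministic: same (seed, stratum, m) gives the same draw
  expect_identical(draw_parameters(fit, m = 3, seed = 99),
                   draw_parameters(fit, m = 3, seed = 99))
  expect_false(identical(draw_parameters(fit, m = 3, seed = 99),
                         draw_parameters(fit, m = 4, seed = 99)))

  # zero covariance collapses the draw to the MLE exactly
  fit0 <- fit
  fit0$vcov <- matrix(0, 2, 2, dimnames = dimnames(fit$vcov))
  expect_equal(draw_parameters(fit0, m = 1, seed = 1), fit$coefficients)

  # Monte Carlo: sample mean of many draws is within 3 SEs of the MLE
  fit_i <- fit_imputation_model(build_design(tab, character())$x, tab$y)
  draws <- vapply(1:10000, function(m) draw_parameters(fit_i, m, seed = 7)[1],
                  numeric(1))
  se_mean <- sqrt(fit_i$vcov[1, 1] / 10000)
  expect_lt(abs(mean(draws) - fit_i$coefficients[1]), 3 * se_mean)
})
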