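test_that("complete-case prevalence reproduces printed survey percentages", {
  # 77 positives of 2,932 tested -> 2.6%; 1,166 of 1,200 -> 97.2%
  df <- data.frame(
    y = c(rep(1L, 77), rep(0L, 2932 - 77), rep(NA_integer_, 50),
          rep(1L, 1166), rep(0L, 1200 - 1166), rep(NA_integer_, 20)),
    grp = rep(c("men_18_24", "women_selfpos"), c(2982, 1220)))
  tab <- study_table(df, list(y = "binary", grp = c("men_18_24", "women_selfpos")))
  roles <- role_map(target = "y")
  subs <- list(men_18_24 = function(d) d$grp == "men_18_24",
               women_selfpos = function(d) d$grp == "women_selfpos")
  cc <- complete_case(tab, roles, subs)
  expect_equal(deltami:::round_half_up(cc$percent[cc$subgroup == "men_18_24"], 1), 2.6)
  expect_equal(deltami:::round_half_up(cc$percent[cc$subgroup == "women_selfpos"], 1), 97.2)
  expect_equal(cc$n, c(2932, 1200))
})

test_that("complete-case equals full-data prevalence when nothing is missing", {
  df <- data.frame(y = rep(c(1L, 0L), c(4, 6)))
  tab <- study_table(df, list(y = "binary"))
  cc <- complete_case(tab, role_map(target = "y"))
  expect_equal(cc$estimate[cc$subgroup == "overall"], 0.4)
})

test_that("best/worst-case fills bound the table deterministically", {
  df <- data.frame(y = c(1L, 0L, NA, NA))
  tab <- study_table(df, list(y = "binary"))
  roles <- role_map(target = "y")
  expect_equal(extreme_case(tab, roles, fill = 1)$percent, 75)
  expect_equal(extreme_case(tab, roles, fill = 0)$percent, 25)
  # no missing rows: both fills give the complete-case value
  df2 <- data.frame(y = c(1L, 0L, 0L, 0L))
  tab2 <- study_table(df2, list(y = "binary"))
  expect_equal(extreme_case(tab2, roles, fill = 1)$percent,
               extreme_case(tab2, roles, fill = 0)$percent)
})

test_that("sensitivity grids conserve rows, hit the MAR point exactly, and stay bounded", {
  g <- generate_study(default_params(n = 3000, seed = 19))
  cfg <- imputation_config(c("age", "region", "selfreport"), M = 3, seed = 77,
                           strata = "sex")
  grid <- delta_grid_spec(ranges = list(neg = c(1, 2.5), pos = 1,
                                        refused = c(1, 2.5), never = c(1, 1.33)),
                          auxiliary = "selfreport")
  subs <- list(overall = function(df) rep(TRUE, nrow(df)),
               men = function(df) df$sex == "M")
  sg <- run_sensitivity(g$table, g$roles, cfg, grid, subgroups = subs)
  # conservation: |grid| x |estimands| x |subgroups|
  expect_equal(nrow(sg), length(grid) * 1 * length(subs))

  # the all-ones grid point reproduces the standalone MAR run bit-exactly
  mar_row <- sg[sg$exp_neg == 1 & sg$exp_refused == 1 & sg$exp_never == 1 &
                  sg$subgroup == "overall", ]
  mar_cs <- impute_mar(g$table, g$roles, cfg)
  mar_pp <- pooled_prevalence(mar_cs)
  expect_identical(mar_row$estimate, mar_pp$percent)

  # bounding by the deterministic extremes, per subgroup
  best <- extreme_case(g$table, g$roles, fill = 0, subgroups = subs)
  worst <- extreme_case(g$table, g$roles, fill = 1, subgroups = subs)
  for (lab in names(subs)) {
    sl <- sg[sg$subgroup == lab, ]
    expect_true(all(sl$estimate >= best$percent[best$subgroup == lab]))
    expect_true(all(sl$estimate <= worst$percent[worst$subgroup == lab]))
  }

  # common random numbers: monotone along each delta axis
  for (ax in c("exp_neg", "exp_refused", "exp_never")) {
    others <- setdiff(c("exp_neg", "exp_refused", "exp_never"), ax)
    sl <- sg[sg$subgroup == "overall", ]
    key <- interaction(sl[others])
    for (k in levels(key)) {
      s2 <- sl[key == k, ]
      s2 <- s2[order(s2[[ax]]), ]
      expect_true(all(diff(s2$estimate) >= 0))
    }
  }
})

test_that("tipping points are reported as bracketing intervals with interpolation", {
  # toy grid: estimates (0.19, 0.21) at exp(delta) = (2.5, 5.0), threshold 0.20
  toy <- structure(
    data.frame(exp_delta = c(2.5, 5.0), estimand = "prevalence",
               subgroup = "overall", estimate = c(0.19, 0.21),
               se = c(0.01, 0.01)),
    class = c("sensitivity_grid", "data.frame"),
    delta_cols = "exp_delta")
  tp <- tipping_point(toy, threshold = 0.20)
  expect_equal(nrow(tp), 1)
  expect_equal(tp$lower, 2.5)
  expect_equal(tp$upper, 5.0)
  # linear interpolation on the log-delta axis, halfway here
  expect_equal(tp$crossing, exp(mean(log(c(2.5, 5)))), tolerance = 1e-12)

  # constant grid: no crossing in range
  toy$estimate <- c(0.19, 0.19)
  tp2 <- tipping_point(toy, threshold = 0.20)
  expect_equal(nrow(tp2), 0)
  expect_equal(attr(tp2, "status"), "no crossing in range")

  # monotone grid: exactly one crossing per axis
  toy3 <- structure(
    data.frame(exp_delta = c(1, 2, 4, 8), estimand = "prevalence",
               subgroup = "overall", estimate = c(0.10, 0.15, 0.25, 0.30),
               se = 0.01),
    class = c("sensitivity_grid", "data.frame"),
    delta_cols = "exp_delta")
  tp3 <- tipping_point(toy3, threshold = 0.20)
  expect_equal(nrow(tp3), 1)
  expect_true(tp3$lower == 2 && tp3$upper == 4)
})

test_that("contour matrices reshape one slice of the grid", {
  g <- generate_study(default_params(n = 1200, seed = 3))
  cfg <- imputation_config(c("age", "selfreport"), M = 2, seed = 5, strata = "sex")
  grid <- delta_grid_spec(ranges = list(neg = c(1, 2), pos = 1,
                                        refused = c(1, 3), never = 1),
                          auxiliary = "selfreport")
  sg <- run_sensitivity(g$table, g$roles, cfg, grid,
                        subgroups = list(overall = function(df) rep(TRUE, nrow(df))))
  m <- contour_matrix(sg, "exp_neg", "exp_refused")
  expect_equal(dim(m), c(2, 2))
  expect_false(anyNA(m))
  # matrix cells agree with the long-format rows
  expect_equal(m["1", "3"],
               sg$estimate[sg$exp_neg == 1 & sg$exp_refused == 3])
})
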