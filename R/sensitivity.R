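# Orchestrates the analysis suite around the imputers: complete-case and
# best/worst-case benchmarks, MNAR delta grids, and tipping-point scans.

binom_prev <- function(y) {
  n <- length(y)
  p <- if (n) mean(y) else NA_real_
  data.frame(n = n, estimate = p, se = if (n) sqrt(p * (1 - p) / n) else NA_real_,
             percent = 100 * p, percent_se = if (n) 100 * sqrt(p * (1 - p) / n)
             else NA_real_)
}

#' Default subgroup set for prevalence tables
#'
#' Overall, one subgroup per stratum level (e.g. by sex), and one per
#' auxiliary self-report category — the column layout of the survey's
#' prevalence tables.
#'
#' @param table A `study_table`.
#' @param roles A `role_map`.
#' @return Named list of filter functions (data frame -> logical mask).
#' @export
default_subgroups <- function(table, roles) {
  subs <- list(overall = function(df) rep(TRUE, nrow(df)))
  make_filter <- function(col, lv) {
    force(col); force(lv)
    function(df) as.character(df[[col]]) == lv
  }
  for (col in c(roles$strata, roles$auxiliary)) {
    if (is.null(col)) next
    v <- table[[col]]
    levs <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
    for (lv in levs) subs[[paste(col, lv, sep = ":")]] <- make_filter(col, lv)
  }
  subs
}

#' Complete-case prevalence by subgroup
#'
#' Restricts to rows with the target observed (R = 1) and reports the
#' proportion of ones per subgroup with its binomial standard error.
#'
#' @param table A `study_table`.
#' @param roles A `role_map`.
#' @param subgroups Named list of filter functions; default [default_subgroups()].
#' @return Data frame: `subgroup`, `n`, `estimate`, `se`, `percent`, `percent_se`.
#' @export
complete_case <- function(table, roles, subgroups = NULL) {
  check_roles(table, roles)
  if (is.null(subgroups)) subgroups <- default_subgroups(table, roles)
  df <- as.data.frame(table)
  obs <- !is.na(df[[roles$target]])
  rows <- lapply(names(subgroups), function(lab) {
    keep <- obs & subgroups[[lab]](df)
    cbind(data.frame(subgroup = lab), binom_prev(df[[roles$target]][keep]))
  })
  do.call(rbind, rows)
}

#' Best- and worst-case single imputation
#'
#' Deterministically fills every missing target value with 0 (best case for
#' a low-prevalence condition) or 1 (worst case) and reports the resulting
#' prevalence per subgroup.  These two fills bound every stochastic
#' delta-adjusted analysis on the same table.
#'
#' @param table A `study_table`.
#' @param roles A `role_map`.
#' @param fill 0 or 1.
#' @param subgroups Named list of filter functions.
#' @return Data frame as in [complete_case()].
#' @export
extreme_case <- function(table, roles, fill, subgroups = NULL) {
  check_roles(table, roles)
  stopifnot(fill %in% c(0, 1))
  if (is.null(subgroups)) subgroups <- default_subgroups(table, roles)
  df <- as.data.frame(table)
  y <- df[[roles$target]]
  y[is.na(y)] <- as.integer(fill)
  df[[roles$target]] <- y
  rows <- lapply(names(subgroups), function(lab) {
    keep <- subgroups[[lab]](df)
    cbind(data.frame(subgroup = lab), binom_prev(y[keep]))
  })
  do.call(rbind, rows)
}

#' Run a delta-adjustment sensitivity grid
#'
#' For every `delta_spec` in the grid, imputes M completed data sets (with
#' common random numbers across grid points by default, so surfaces are
#' exactly monotone in each delta component) and computes the requested
#' estimands: Rubin-pooled prevalence per subgroup, and/or pattern-averaged
#' mediation effects per exposure contrast.  A failed grid point is recorded
#' with `NA` estimates rather than aborting the run.
#'
#' @param table A `study_table`.
#' @param roles A `role_map`.
#' @param config An `imputation_config`.
#' @param grid List of `delta_spec`s, e.g. from [delta_grid_spec()].
#' @param estimands Any of `"prevalence"`, `"mediation"`.
#' @param subgroups Named list of filter functions for prevalence.
#' @param contrasts Exposure contrasts for mediation (default all).
#' @param common_rng Share imputation uniforms across grid points.
#' @return A `sensitivity_grid` data frame in long format: the exp(delta)
#'   columns of the grid, `estimand`, `subgroup`, `estimate` (percent for
#'   prevalence, OR for mediation), `se` (percent SE / SE of the log-OR).
#' @export
run_sensitivity <- function(table, roles, config, grid,
                            estimands = "prevalence", subgroups = NULL,
                            contrasts = NULL, common_rng = TRUE) {
  stopifnot(length(grid) >= 1)
  if (is.null(subgroups)) subgroups <- default_subgroups(table, roles)
  gridvals <- attr(grid, "grid")
  if (is.null(gridvals)) {
    gridvals <- data.frame(point = seq_along(grid))
  }
  out <- list()
  for (i in seq_along(grid)) {
    spec <- grid[[i]]
    res <- tryCatch({
      completed <- impute_mnar(table, roles, config, delta = spec,
                               common_rng = common_rng)
      rows <- list()
      if ("prevalence" %in% estimands) {
        for (lab in names(subgroups)) {
          ps <- pooled_prevalence(completed, filter = subgroups[[lab]])
          rows[[length(rows) + 1]] <- data.frame(
            estimand = "prevalence", subgroup = lab,
            estimate = ps$percent, se = ps$percent_se)
        }
      }
      if ("mediation" %in% estimands) {
        me <- mediation_mi(completed, roles, contrasts = contrasts)
        avg <- me[me$pattern == "average", , drop = FALSE]
        for (j in seq_len(nrow(avg))) {
          rows[[length(rows) + 1]] <- data.frame(
            estimand = paste0("mediation:", avg$effect[j]),
            subgroup = avg$contrast[j],
            estimate = avg$or[j], se = avg$se_log[j])
        }
      }
      do.call(rbind, rows)
    }, error = function(e) {
      warning(sprintf("grid point %d failed: %s", i, conditionMessage(e)))
      data.frame(estimand = estimands[1], subgroup = NA_character_,
                 estimate = NA_real_, se = NA_real_)
    })
    out[[i]] <- cbind(gridvals[rep(i, nrow(res)), , drop = FALSE], res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res,
            class = c("sensitivity_grid", "data.frame"),
            delta_cols = names(gridvals),
            common_rng = common_rng,
            config = config)
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("sensitivity_grid: %d rows, %d grid points, common_rng=%s\n",
              nrow(x), nrow(unique(x[attr(x, "delta_cols")])),
              attr(x, "common_rng")))
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Contour matrix from a sensitivity grid
#'
#' Reshapes one estimand/subgroup slice into a matrix with one delta axis on
#' the rows and another on the columns (input for filled contour plots).
#' Remaining delta columns must be constant in the slice.
#'
#' @param grid A `sensitivity_grid`.
#' @param row_axis,col_axis Names of the exp(delta) columns to spread.
#' @param estimand,subgroup Slice selectors.
#' @return Numeric matrix with axis values as dimnames.
#' @export
contour_matrix <- function(grid, row_axis, col_axis,
                           estimand = "prevalence", subgroup = "overall") {
  df <- as.data.frame(grid)
  df <- df[df$estimand == estimand & df$subgroup == subgroup, , drop = FALSE]
  other <- setdiff(attr(grid, "delta_cols"), c(row_axis, col_axis, "point"))
  for (col in other) {
    if (length(unique(df[[col]])) > 1) {
      stop(sprintf("axis '%s' is not constant in the slice; subset first", col))
    }
  }
  rows <- sort(unique(df[[row_axis]]))
  cols <- sort(unique(df[[col_axis]]))
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (i in seq_len(nrow(df))) {
    m[as.character(df[[row_axis]][i]), as.character(df[[col_axis]][i])] <-
      df$estimate[i]
  }
  m
}

#' Tipping-point scan of a sensitivity grid
#'
#' Finds, along each delta axis (holding the other axes fixed), every pair of
#' adjacent grid points between which the estimand crosses the threshold, and
#' reports the linearly interpolated crossing on the estimate-versus-log-delta
#' scale.  The crossing is always reported as a bracketing interval plus the
#' interpolated value, never a point alone; a grid with no crossing returns a
#' zero-row result flagged "no crossing in range".
#'
#' @param grid A `sensitivity_grid`.
#' @param threshold Estimand value whose crossing is sought (same scale as
#'   the grid's `estimate` column, i.e. percent for prevalence).
#' @param estimand,subgroup Slice selectors.
#' @return Data frame with `axis`, the fixed values of the other axes,
#'   `lower`, `upper` (bracketing exp(delta) values), `estimate_lower`,
#'   `estimate_upper`, and `crossing` (interpolated exp(delta)).
#' @export
tipping_point <- function(grid, threshold, estimand = "prevalence",
                          subgroup = "overall") {
  df <- as.data.frame(grid)
  df <- df[df$estimand == estimand & df$subgroup == subgroup, , drop = FALSE]
  axes <- setdiff(attr(grid, "delta_cols"), "point")
  out <- list()
  for (ax in axes) {
    others <- setdiff(axes, ax)
    key <- if (length(others)) {
      interaction(df[others], drop = TRUE, lex.order = TRUE)
    } else {
      factor(rep("all", nrow(df)))
    }
    for (k in levels(key)) {
      slice <- df[key == k, , drop = FALSE]
      slice <- slice[order(slice[[ax]]), , drop = FALSE]
      if (nrow(slice) < 2) next
      est <- slice$estimate
      for (i in seq_len(nrow(slice) - 1)) {
        e1 <- est[i]; e2 <- est[i + 1]
        if (is.na(e1) || is.na(e2)) next
        if ((e1 - threshold) * (e2 - threshold) <= 0 && e1 != e2) {
          l1 <- log(slice[[ax]][i]); l2 <- log(slice[[ax]][i + 1])
          lc <- l1 + (threshold - e1) / (e2 - e1) * (l2 - l1)
          row <- data.frame(axis = ax, lower = slice[[ax]][i],
                            upper = slice[[ax]][i + 1],
                            estimate_lower = e1, estimate_upper = e2,
                            crossing = exp(lc))
          for (o in others) row[[o]] <- slice[[o]][1]
          out[[length(out) + 1]] <- row
        }
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(axis = character(), lower = numeric(), upper = numeric(),
                      estimate_lower = numeric(), estimate_upper = numeric(),
                      crossing = numeric())
    attr(res, "status") <- "no crossing in range"
    return(res)
  }
  res <- do.call(rbind, lapply(out, function(r) {
    for (col in setdiff(unique(unlist(lapply(out, names))), names(r))) r[[col]] <- NA
    r
  }))
  rownames(res) <- NULL
  attr(res, "status") <- "crossings found"
  res
}
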