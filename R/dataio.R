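#' Study tables with declared column kinds
#'
#' A `study_table` is a data frame whose columns have declared kinds
#' (`"binary"`, `"count"`, or a character vector of category levels), and in
#' which at most one column — the incomplete target — may contain missing
#' values.  The missingness indicator R (1 = observed) is derived from the
#' target column rather than stored.
#'
#' @param data A data frame.
#' @param schema Named list, one entry per column: the string `"binary"`,
#'   the string `"count"`, or a character vector of allowed category levels
#'   (the first level is the reference for model coding unless a role map
#'   overrides it).
#' @return An object of class `study_table` (a data frame carrying the schema
#'   as an attribute).
#' @examples
#' sch <- list(y = "binary", grp = c("a", "b"))
#' tab <- study_table(data.frame(y = c(1L, 0L, NA), grp = c("a", "b", "a")), sch)
#' n_missing(tab, "y")
#' @export
study_table <- function(data, schema) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  schema <- normalize_schema(schema)
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols)) {
    stop("schema names columns absent from the data: ",
         paste(missing_cols, collapse = ", "))
  }
  data <- data[names(schema)]
  for (col in names(schema)) {
    data[[col]] <- coerce_column(data[[col]], schema[[col]], col)
  }
  has_na <- vapply(data, anyNA, logical(1))
  if (sum(has_na) > 1) {
    stop("univariate missingness violated: missing values in columns ",
         paste(names(data)[has_na], collapse = ", "))
  }
  structure(data, schema = schema, class = c("study_table", "data.frame"))
}

normalize_schema <- function(schema) {
  stopifnot(is.list(schema), length(schema) >= 1, !is.null(names(schema)))
  lapply(schema, function(s) {
    if (is.character(s) && length(s) == 1 && s %in% c("binary", "count")) return(s)
    if (is.character(s) && length(s) >= 2) return(s)
    stop("schema entries must be \"binary\", \"count\", or >=2 category levels")
  })
}

coerce_column <- function(x, kind, col) {
  if (identical(kind, "binary")) {
    v <- suppressWarnings(as.integer(as.character(x)))
    bad <- !is.na(x) & (is.na(v) | !v %in% c(0L, 1L))
    if (any(bad)) {
      stop(sprintf("column '%s': non-binary value '%s'", col, as.character(x)[bad][1]))
    }
    return(v)
  }
  if (identical(kind, "count")) {
    v <- suppressWarnings(as.integer(as.character(x)))
    bad <- !is.na(x) & (is.na(v) | v < 0L)
    if (any(bad)) {
      stop(sprintf("column '%s': non-count value '%s'", col, as.character(x)[bad][1]))
    }
    return(v)
  }
  ch <- as.character(x)
  bad <- !is.na(ch) & !ch %in% kind
  if (any(bad)) {
    stop(sprintf("column '%s': unknown category level '%s'", col, ch[bad][1]))
  }
  factor(ch, levels = kind)
}

#' @export
print.study_table <- function(x, ...) {
  sch <- attr(x, "schema")
  kinds <- vapply(sch, function(s) {
    if (length(s) == 1) s else sprintf("categorical(%d)", length(s))
  }, character(1))
  has_na <- vapply(x, anyNA, logical(1))
  cat(sprintf("study_table: %d rows, %d columns\n", nrow(x), ncol(x)))
  for (col in names(sch)) {
    cat(sprintf("  %-16s %s%s\n", col, kinds[[col]],
                if (has_na[[col]]) sprintf("  [%d missing]", sum(is.na(x[[col]]))) else ""))
  }
  invisible(x)
}

table_schema <- function(table) attr(table, "schema")

#' Number of missing values in a column
#' @param table A `study_table`.
#' @param col Column name.
#' @export
n_missing <- function(table, col) sum(is.na(table[[col]]))

#' Assign analysis roles to columns
#'
#' Records which column plays which part in the analyses: the incomplete
#' binary target (e.g. HIV serostatus), the fully observed categorical
#' auxiliary (e.g. self-reported HIV status) used both in the imputation
#' model and to index group-specific delta offsets, the exposure/outcome/
#' mediator triple for mediation analysis, confounders, and an optional
#' stratification column (e.g. sex) for stratum-wise imputation-model fits.
#'
#' @param target Name of the incomplete binary column.
#' @param auxiliary Optional name of the auxiliary categorical column.
#' @param exposure Optional name of the categorical exposure column.
#' @param exposure_ref Optional reference level for the exposure; defaults to
#'   the first declared level.
#' @param outcome,mediator Optional column names for mediation analysis.
#' @param confounders Character vector of confounder column names.
#' @param strata Optional name of a fully observed stratification column.
#' @return An object of class `role_map`.
#' @export
role_map <- function(target, auxiliary = NULL, exposure = NULL,
                     exposure_ref = NULL, outcome = NULL, mediator = NULL,
                     confounders = character(), strata = NULL) {
  roles <- list(target = target, auxiliary = auxiliary, exposure = exposure,
                exposure_ref = exposure_ref, outcome = outcome,
                mediator = mediator, confounders = confounders, strata = strata)
  single <- c("target", "auxiliary", "exposure", "outcome", "mediator", "strata")
  cols <- c(unlist(roles[single]), confounders)
  conflicting <- intersect(
    roles$target,
    c(roles$auxiliary, roles$exposure, roles$outcome, confounders, roles$strata))
  if (length(conflicting)) {
    stop("target column also holds another role: ", paste(conflicting, collapse = ", "))
  }
  structure(roles, class = "role_map", columns = unique(cols))
}

#' @export
print.role_map <- function(x, ...) {
  cat("role_map:\n")
  for (r in names(x)) {
    v <- x[[r]]
    if (!is.null(v) && length(v)) cat(sprintf("  %-12s %s\n", r, paste(v, collapse = ", ")))
  }
  invisible(x)
}

check_roles <- function(table, roles) {
  cols <- attr(roles, "columns")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("roles reference absent columns: ", paste(missing_cols, collapse = ", "))
  }
  sch <- table_schema(table)
  if (!identical(sch[[roles$target]], "binary")) {
    stop(sprintf("target column '%s' must be binary", roles$target))
  }
  if (!is.null(roles$auxiliary) && length(sch[[roles$auxiliary]]) < 2) {
    stop(sprintf("auxiliary column '%s' must be categorical with >=2 levels",
                 roles$auxiliary))
  }
  for (col in setdiff(cols, roles$target)) {
    if (anyNA(table[[col]])) {
      stop(sprintf("role column '%s' has missing values; only the target may", col))
    }
  }
  invisible(TRUE)
}

#' Read a study table from CSV
#'
#' Reads a headered CSV, coerces columns according to the schema, and derives
#' the missingness indicator from the target column's missing entries (empty
#' strings and `"NA"` are both accepted as missing markers).  At most one
#' column may contain missing values; rows with missing values in other
#' columns are either rejected or, with `drop_incomplete_covariates = TRUE`,
#' deleted (with a message reporting the count) so that missingness is
#' univariate.
#'
#' @param path CSV file path.
#' @param schema Column kind declarations, as for [study_table()].
#' @param target Name of the column allowed to contain missing values.
#'   Required when `drop_incomplete_covariates = TRUE`.
#' @param drop_incomplete_covariates Drop rows with missing non-target values
#'   instead of erroring.
#' @return A `study_table`.
#' @export
load_table <- function(path, schema, target = NULL,
                       drop_incomplete_covariates = FALSE) {
  stopifnot(file.exists(path))
  schema <- normalize_schema(schema)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols)) {
    stop("CSV header lacks schema columns: ", paste(missing_cols, collapse = ", "))
  }
  if (drop_incomplete_covariates) {
    if (is.null(target)) stop("target must be given to drop incomplete covariates")
    other <- setdiff(names(schema), target)
    bad <- Reduce(`|`, lapply(raw[other], is.na))
    if (any(bad)) {
      message(sprintf("dropped %d rows with missing non-target values", sum(bad)))
      raw <- raw[!bad, , drop = FALSE]
    }
  }
  study_table(raw, schema)
}

#' Write a study table to CSV
#'
#' Missing entries are written as `"NA"`; factors as their labels.  A
#' write-then-load round trip through the same schema reproduces the table.
#'
#' @param table A `study_table`.
#' @param path Output path.
#' @export
write_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Summarize missingness of the target by subgroup
#'
#' For every cross-category of the `by` columns, reports the number of rows
#' with the target missing, the number at risk, and the percentage missing
#' (rounded half-up to one decimal, the display convention of survey tables).
#' Empty subgroups are flagged rather than propagated as NaN.
#'
#' @param table A `study_table`.
#' @param roles A `role_map` naming the target.
#' @param by Character vector of fully observed column names to cross.
#' @return Data frame with the `by` columns plus `n_missing`, `n_at_risk`,
#'   `percent`, and a logical `empty` flag.
#' @export
missingness_summary <- function(table, roles, by) {
  check_roles(table, roles)
  stopifnot(all(by %in% names(table)))
  for (col in by) {
    if (anyNA(table[[col]])) stop(sprintf("'%s' must be fully observed", col))
  }
  miss <- is.na(table[[roles$target]])
  groups <- lapply(by, function(col) {
    v <- table[[col]]
    if (is.factor(v)) v else factor(v)
  })
  names(groups) <- by
  grid <- expand.grid(lapply(groups, levels), stringsAsFactors = FALSE)
  names(grid) <- by
  cell <- interaction(groups, drop = FALSE, lex.order = FALSE)
  key <- interaction(grid, drop = FALSE, lex.order = FALSE)
  n_cell <- tapply(rep(1L, length(miss)), cell, sum, default = 0L)
  m_cell <- tapply(miss, cell, sum, default = 0L)
  grid$n_missing <- as.integer(m_cell[as.character(key)])
  grid$n_at_risk <- as.integer(n_cell[as.character(key)])
  grid$n_missing[is.na(grid$n_missing)] <- 0L
  grid$n_at_risk[is.na(grid$n_at_risk)] <- 0L
  grid$empty <- grid$n_at_risk == 0L
  grid$percent <- ifelse(grid$empty, NA_real_,
                         round_half_up(100 * grid$n_missing / grid$n_at_risk, 1))
  grid[c(by, "n_missing", "n_at_risk", "percent", "empty")]
}

#' Crude and adjusted odds ratios for a binary event
#'
#' Fits one logistic regression of the event on a categorical factor (plus
#' optional adjusters) and reports odds ratios with Wald 95% confidence
#' intervals for each non-reference level.  When the maximum-likelihood fit
#' fails to converge or is quasi-separated, a lightly ridge-penalized fit is
#' substituted and the rows are flagged (`engine == "penalized"`).
#'
#' @param table A `study_table` (or data frame).
#' @param event Name of a fully observed binary column within the analysis rows.
#' @param factor_col Name of the factor of interest.
#' @param adjusters Character vector of adjustment covariates (e.g. age, region).
#' @param conf_level Confidence level for the Wald intervals.
#' @return Data frame with columns `level`, `or`, `lo`, `hi`, `engine`; the
#'   reference level row has `or = 1` and no interval.
#' @export
crude_and_adjusted_or <- function(table, event, factor_col,
                                  adjusters = character(), conf_level = 0.95) {
  df <- as.data.frame(table)
  df <- df[!is.na(df[[event]]), , drop = FALSE]
  stopifnot(all(df[[event]] %in% c(0, 1)))
  for (col in c(factor_col, adjusters)) {
    if (!is.factor(df[[col]])) df[[col]] <- factor(df[[col]])
    df[[col]] <- droplevels(df[[col]])
  }
  rhs <- paste(c(factor_col, adjusters), collapse = " + ")
  form <- stats::as.formula(paste(event, "~", rhs))
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
  engine <- "mle"
  beta <- stats::coef(fit)
  if (!fit$converged || any(abs(beta) > 15, na.rm = TRUE) || anyNA(beta)) {
    x <- stats::model.matrix(form, df)
    rfit <- ridge_logit(x, df[[event]], lambda = 1e-4 * nrow(x))
    beta <- stats::setNames(rfit$coefficients, colnames(x))
    vc <- rfit$vcov
    dimnames(vc) <- list(colnames(x), colnames(x))
    engine <- "penalized"
  } else {
    vc <- stats::vcov(fit)
  }
  levs <- levels(df[[factor_col]])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(levs, function(lv) {
    if (lv == levs[1]) {
      return(data.frame(level = lv, or = 1, lo = NA_real_, hi = NA_real_,
                        engine = "referent"))
    }
    nm <- paste0(factor_col, lv)
    b <- beta[[nm]]
    se <- sqrt(vc[nm, nm])
    data.frame(level = lv, or = exp(b), lo = exp(b - z * se), hi = exp(b + z * se),
               engine = engine)
  })
  do.call(rbind, rows)
}

#' Write run metadata as JSON
#'
#' Records seeds, the number of imputations, delta settings and the model
#' specification alongside analysis outputs, so a run can be reproduced.
#'
#' @param path Output path for the JSON file.
#' @param ... Named metadata fields.
#' @export
write_run_metadata <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
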