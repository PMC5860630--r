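#' Delta offsets for MNAR imputation
#'
#' A `delta_spec` holds the log-odds offset(s) added to the imputation
#' model's linear predictor for rows with the target missing.  In common
#' mode a single offset applies to every missing row; in by-group mode each
#' level of a fully observed auxiliary variable (e.g. 4-level self-reported
#' HIV status) carries its own offset.  `delta = 0` (odds ratio 1) is the
#' MAR special case.
#'
#' @param delta Common log-odds offset (common mode), or `NULL`.
#' @param by Named numeric vector mapping auxiliary levels to log-odds
#'   offsets (by-group mode).
#' @param auxiliary Auxiliary column name; required in by-group mode.
#' @param exp_delta,exp_by Alternatives to `delta`/`by` on the odds-ratio
#'   scale; stored internally as logs.
#' @param default_delta Offset for auxiliary levels absent from `by`.  There
#'   is deliberately no silent default: leaving a level unmapped is an error
#'   unless `default_delta` is set explicitly.
#' @return A `delta_spec` with `mode` `"common"` or `"by_group"`.
#' @examples
#' delta_spec(log(2))                                   # common exp(delta) = 2
#' delta_spec(by = log(c(neg = 2.5, pos = 1, refused = 2.5, never = 1)),
#'            auxiliary = "selfreport")
#' @export
delta_spec <- function(delta = NULL, by = NULL, auxiliary = NULL,
                       exp_delta = NULL, exp_by = NULL, default_delta = NULL) {
  if (!is.null(exp_delta)) {
    stopifnot(is.null(delta), all(exp_delta > 0))
    delta <- log(exp_delta)
  }
  if (!is.null(exp_by)) {
    stopifnot(is.null(by), all(exp_by > 0))
    by <- log(exp_by)
    names(by) <- names(exp_by)
  }
  if (!is.null(by)) {
    stopifnot(is.numeric(by), !is.null(names(by)), all(is.finite(by)))
    if (is.null(auxiliary)) stop("by-group delta_spec requires an auxiliary column name")
    structure(list(mode = "by_group", by = by, auxiliary = auxiliary,
                   default_delta = default_delta),
              class = "delta_spec")
  } else {
    stopifnot(is.numeric(delta), length(delta) == 1, is.finite(delta))
    structure(list(mode = "common", delta = unname(delta)),
              class = "delta_spec")
  }
}

#' @export
print.delta_spec <- function(x, ...) {
  if (x$mode == "common") {
    cat(sprintf("delta_spec: common, exp(delta) = %.4g\n", exp(x$delta)))
  } else {
    cat(sprintf("delta_spec: by '%s': %s\n", x$auxiliary,
                paste(sprintf("%s=%.4g", names(x$by), exp(x$by)), collapse = ", ")))
  }
  invisible(x)
}

# Per-row offsets for the missing rows of a table.
row_deltas <- function(spec, table, rows) {
  if (spec$mode == "common") return(rep(spec$delta, length(rows)))
  z <- as.character(table[[spec$auxiliary]][rows])
  unmapped <- setdiff(unique(z), names(spec$by))
  if (length(unmapped)) {
    if (is.null(spec$default_delta)) {
      stop("auxiliary level(s) without a delta: ", paste(unmapped, collapse = ", "),
           " (set default_delta explicitly to allow)")
    }
    full <- c(spec$by, stats::setNames(rep(spec$default_delta, length(unmapped)),
                                       unmapped))
  } else {
    full <- spec$by
  }
  unname(full[z])
}

#' Delta-shifted imputation probability
#'
#' The probability used to impute a missing binary value: the inverse logit
#' of the MAR linear predictor plus the log-odds offset delta.  Strictly
#' increasing in delta; delta = 0 recovers the MAR probability; adding delta
#' multiplies the odds by exp(delta).
#'
#' @param linpred Linear predictor value(s) on the log-odds scale.
#' @param delta Log-odds offset(s).
#' @return Probabilities in (0, 1).
#' @examples
#' adjusted_probability(log(3 / 7), log(2))  # odds 3/7 doubled -> 0.4615
#' @export
adjusted_probability <- function(linpred, delta) {
  stopifnot(is.finite(linpred), is.finite(delta))
  stats::plogis(linpred + delta)
}

#' Multiple imputation under MNAR via delta adjustment
#'
#' Two-step procedure: the logistic imputation model is fitted to the
#' observed rows under MAR (per stratum); then, for each of M imputations, a
#' proper parameter draw is taken, the linear predictor is computed for rows
#' with the target missing, the applicable delta offset is added (common, or
#' the offset of the row's auxiliary level), and the missing values are
#' imputed as Bernoulli draws.  Delta never enters the model fit.
#'
#' With `common_rng = TRUE` (default) one uniform per missing row per
#' imputation is drawn from a substream keyed only on (seed, m), so the same
#' uniforms are reused across delta settings: imputed totals are then exactly
#' monotone in each delta component and sensitivity surfaces are smooth.
#'
#' @param table A `study_table`.
#' @param roles A `role_map`; in by-group mode the auxiliary column must be
#'   among the imputation predictors.
#' @param config An `imputation_config`.
#' @param delta A `delta_spec` (default: common 0, i.e. MAR).
#' @param common_rng Reuse imputation uniforms across delta settings.
#' @return A `completed_set`: M completed data frames plus provenance.
#' @export
impute_mnar <- function(table, roles, config, delta = delta_spec(0),
                        common_rng = TRUE) {
  stopifnot(inherits(config, "imputation_config"), inherits(delta, "delta_spec"))
  if (delta$mode == "by_group") {
    if (!delta$auxiliary %in% config$predictors) {
      stop("by-group delta adjustment requires the auxiliary column '",
           delta$auxiliary, "' among the imputation predictors")
    }
  }
  y <- table[[roles$target]]
  miss_idx <- which(is.na(y))
  fits <- fit_strata(table, roles, config)
  # linear-predictor scaffolding for missing rows, per stratum
  parts <- lapply(seq_along(fits), function(si) {
    st <- fits[[si]]
    mrows <- intersect(st$rows, miss_idx)
    xm <- st$x[match(mrows, st$rows), , drop = FALSE]
    list(si = si, rows = mrows, x = xm,
         delta = if (length(mrows)) row_deltas(delta, table, mrows) else numeric())
  })
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  imputations <- vector("list", config$M)
  for (m in seq_len(config$M)) {
    if (common_rng) {
      set.seed(seed_stream(config$seed, 29L, m))
    } else {
      set.seed(seed_stream(config$seed, 31L, m, delta_hash(delta)))
    }
    u <- stats::runif(length(miss_idx))
    names(u) <- as.character(miss_idx)
    completed <- as.data.frame(table)
    for (p in parts) {
      if (!length(p$rows)) next
      beta <- draw_parameters(fits[[p$si]]$fit, m, config$seed, stratum = p$si)
      eta <- drop(p$x %*% beta) + p$delta
      completed[[roles$target]][p$rows] <-
        as.integer(u[as.character(p$rows)] < stats::plogis(eta))
    }
    imputations[[m]] <- completed
  }
  structure(list(imputations = imputations,
                 provenance = list(delta = delta, config = config,
                                   roles = roles, common_rng = common_rng,
                                   engines = vapply(fits, function(s) s$fit$engine,
                                                    character(1)),
                                   n_missing = length(miss_idx))),
            class = "completed_set")
}

delta_hash <- function(spec) {
  v <- if (spec$mode == "common") spec$delta else spec$by
  as.integer(sum(abs(v) * 1e4) %% 104729)
}

#' @export
print.completed_set <- function(x, ...) {
  pr <- x$provenance
  cat(sprintf("completed_set: M = %d imputations, %d missing values filled\n",
              length(x$imputations), pr$n_missing))
  print(pr$delta)
  invisible(x)
}

#' Extract completed data sets
#'
#' @param set A `completed_set`.
#' @param m Imputation index, or `NULL` for the full list.
#' @export
completed_tables <- function(set, m = NULL) {
  stopifnot(inherits(set, "completed_set"))
  if (is.null(m)) set$imputations else set$imputations[[m]]
}

#' Cartesian grid of delta specifications
#'
#' Builds the list of `delta_spec`s for a sensitivity grid, either from a
#' single common range or from per-group ranges (Cartesian product, ordered
#' lexicographically with the last group's range varying fastest held
#' conventionally: the product is generated with the first group slowest).
#' The default by-group grid pairs a strongly-MNAR range
#' exp(delta) = 1.00...5.00 for self-reported-negative and non-disclosing
#' groups, MAR (exp(delta) = 1) for self-reported positives, and a weak
#' range 0.75...1.33 for the never-tested group: 10 x 1 x 10 x 5 = 500 points.
#'
#' @param ranges Named list of per-group exp(delta) ranges (by-group mode),
#'   or `NULL` to use the default grid.
#' @param common Numeric vector of common exp(delta) values (common mode).
#' @param auxiliary Auxiliary column name for by-group specs.
#' @param scale `"or"` if ranges are on the odds-ratio (exp) scale, `"log"`
#'   if already log-odds offsets.
#' @return List of `delta_spec` objects; attribute `"grid"` holds the
#'   expanded value table.
#' @export
delta_grid_spec <- function(ranges = NULL, common = NULL, auxiliary = "selfreport",
                            scale = c("or", "log")) {
  scale <- match.arg(scale)
  to_log <- function(v) if (scale == "or") log(v) else v
  to_exp <- function(v) if (scale == "or") v else exp(v)  # keep grid values exact
  if (!is.null(common)) {
    stopifnot(length(common) >= 1)
    specs <- lapply(to_log(common), delta_spec)
    attr(specs, "grid") <- data.frame(exp_delta = to_exp(common))
    return(specs)
  }
  if (is.null(ranges)) {
    strong <- c(1.00, 1.25, 1.33, 1.50, 1.67, 2.00, 2.50, 3.00, 4.00, 5.00)
    ranges <- list(neg = strong, pos = 1.00, refused = strong,
                   never = c(0.75, 0.80, 1.00, 1.25, 1.33))
  }
  stopifnot(is.list(ranges), !is.null(names(ranges)),
            all(vapply(ranges, length, integer(1)) >= 1))
  # first group varies slowest (lexicographic in declared group order)
  grid <- rev(expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE))
  names(grid) <- names(ranges)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    delta_spec(by = to_log(unlist(grid[i, , drop = FALSE])), auxiliary = auxiliary)
  })
  expg <- as.data.frame(lapply(grid, to_exp))
  names(expg) <- paste0("exp_", names(ranges))
  attr(specs, "grid") <- expg
  specs
}
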