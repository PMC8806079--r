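# Preprocessing: turns a raw cohort_table into the numeric design used by
# the models (telomere unit conversion, log transforms with LOD policies,
# covariate coding, complete-case filtering, standardization).

# qPCR calibration: LTL in base pairs is an affine function of the
# telomere/single-copy (T/S) ratio.
TS_INTERCEPT_BP <- 3274
TS_SLOPE_BP <- 2413

#' Convert a T/S ratio to telomere length in base pairs
#'
#' Applies the qPCR calibration `bp = 3274 + 2413 * T/S`.
#'
#' @param ts_ratio T/S ratio(s), > 0.
#' @param allow_zero permit the boundary value 0 (returns the intercept);
#'   used only to exercise the formula itself.
#' @return telomere length in base pairs.
#' @seealso [bp_to_ts()] for the inverse.
#' @export
ts_to_bp <- function(ts_ratio, allow_zero = FALSE) {
  lower_ok <- if (allow_zero) ts_ratio >= 0 else ts_ratio > 0
  if (any(!is.na(ts_ratio) & !lower_ok))
    msg_stop("medsupp_domain_error", "T/S ratio must be positive")
  TS_INTERCEPT_BP + TS_SLOPE_BP * ts_ratio
}

#' Convert telomere length in base pairs to a T/S ratio
#'
#' Inverse of [ts_to_bp()]: `T/S = (bp - 3274) / 2413`.
#'
#' @param ltl_bp telomere length in base pairs, > 3274 for a positive ratio.
#' @return T/S ratio.
#' @export
bp_to_ts <- function(ltl_bp) {
  (ltl_bp - TS_INTERCEPT_BP) / TS_SLOPE_BP
}

LOD_POLICIES <- c("lod_over_sqrt2", "half_lod", "strict")

#' Natural-log transform with a below-LOD substitution policy
#'
#' Right-skewed biomarkers (serum cotinine, CRP) are log-transformed before
#' modelling.  Values below the assay limit of detection carry no numeric
#' value, only the LOD threshold; the policy decides the substitute used
#' before taking logs:
#' \describe{
#'   \item{`lod_over_sqrt2`}{substitute `LOD / sqrt(2)` (default; standard
#'     exposure-science practice for a single detection limit).}
#'   \item{`half_lod`}{substitute `LOD / 2`.}
#'   \item{`strict`}{refuse below-LOD (and non-positive) values.}
#' }
#'
#' @param values numeric vector; `NA` where below LOD (or missing).
#' @param lod numeric vector of LOD thresholds, `NA` for quantified values.
#' @param policy one of `"lod_over_sqrt2"`, `"half_lod"`, `"strict"`.
#' @return list with `log`: the natural-log values (missing stays `NA`), and
#'   `n_substituted`: how many below-LOD entries were imputed.
#' @export
log_transform <- function(values, lod = NULL, policy = "lod_over_sqrt2") {
  policy <- match.arg(policy, LOD_POLICIES)
  if (is.null(lod)) lod <- rep(NA_real_, length(values))
  stopifnot(length(lod) == length(values))
  below <- is.na(values) & !is.na(lod)
  if (policy == "strict" && any(below))
    msg_stop("medsupp_domain_error",
             "%d below-LOD value(s) with policy 'strict'", sum(below))
  x <- values
  x[below] <- switch(policy,
                     lod_over_sqrt2 = lod[below] / sqrt(2),
                     half_lod = lod[below] / 2)
  nonpos <- !is.na(x) & x <= 0
  if (any(nonpos))
    msg_stop("medsupp_domain_error",
             "%d non-positive value(s) cannot be log-transformed",
             sum(nonpos))
  list(log = log(x), n_substituted = sum(below))
}

#' Numeric covariate coding
#'
#' Fixed coding used throughout: `race` -> indicator `black` (black = 1);
#' `sex` -> indicator `female` (female = 1); `physical_activity` -> indicator
#' `active_pa` (moderate or vigorous = 1, none = 0); `alcohol_use` ->
#' ordinal score `alcohol` 0-3 in category order (never ... 4-7 days/week);
#' `current_smoker` -> 0/1.
#'
#' @param cohort a [cohort_table()].
#' @param variables which raw variables to code (default: all categorical).
#' @return data frame of numeric columns named by the codes above.
#' @export
encode_covariates <- function(cohort,
                              variables = c("race", "sex",
                                            "physical_activity",
                                            "alcohol_use",
                                            "current_smoker")) {
  code_one <- function(var) {
    x <- cohort[[var]]
    check_levels <- function(levels) {
      bad <- !is.na(x) & !(x %in% levels)
      if (any(bad))
        msg_stop("medsupp_coding_error",
                 "unknown %s category: '%s'", var, x[bad][1L])
    }
    switch(var,
      race = { check_levels(RACE_LEVELS)
               data.frame(black = as.numeric(x == "black")) },
      sex = { check_levels(SEX_LEVELS)
              data.frame(female = as.numeric(x == "female")) },
      physical_activity = { check_levels(PA_LEVELS)
        data.frame(active_pa = as.numeric(x %in% c("moderate", "vigorous"))) },
      alcohol_use = { check_levels(ALCOHOL_LEVELS)
        data.frame(alcohol = as.numeric(match(x, ALCOHOL_LEVELS) - 1L)) },
      current_smoker = data.frame(current_smoker = as.numeric(x)),
      msg_stop("medsupp_coding_error", "no coding rule for '%s'", var))
  }
  out <- do.call(cbind, lapply(variables, code_one))
  rownames(out) <- NULL
  out
}

# Is the variable observed in this row? Below-LOD counts as observed.
variable_observed <- function(cohort, var) {
  switch(var,
    cotinine = !is.na(cohort$cotinine) | !is.na(cohort$cotinine_lod),
    crp = !is.na(cohort$crp) | !is.na(cohort$crp_lod),
    ltl_bp = !is.na(cohort$ltl_bp) | !is.na(cohort$ts_ratio),
    ts_ratio = !is.na(cohort$ts_ratio) | !is.na(cohort$ltl_bp),
    !is.na(cohort[[var]]))
}

#' Complete-case filter
#'
#' Retains rows with observed values for every variable named in the model
#' spec (predictor, outcome, third variables, covariates).  Below-LOD
#' biomarker entries count as observed; the outcome counts as observed if
#' either telomere measure is present.  No imputation is performed.
#'
#' @param cohort a [cohort_table()].
#' @param spec a [model_spec()].
#' @return the filtered `cohort_table`, with attribute `n_removed`.
#' @export
complete_case_filter <- function(cohort, spec) {
  vars <- unique(c(spec$predictor, spec$outcome, spec$third_variables,
                   spec$covariates))
  keep <- Reduce(`&`, lapply(vars, function(v) variable_observed(cohort, v)))
  if (!any(keep))
    msg_stop("medsupp_empty_analysis_error",
             "no rows remain after complete-case filtering")
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(cohort)
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Z-score a numeric column
#'
#' Centers and scales to unit variance using the n-1 (sample) standard
#' deviation, recording the scaling so the transform can be inverted.
#'
#' @param column numeric vector without missing values.
#' @return list(`values`, `mean`, `sd`).
#' @export
standardize <- function(column) {
  if (anyNA(column))
    msg_stop("medsupp_domain_error", "cannot standardize missing values")
  m <- mean(column)
  s <- stats::sd(column)
  if (!is.finite(s) || s == 0)
    msg_stop("medsupp_degenerate_scale_error",
             "column has zero variance; standardized coefficient undefined")
  list(values = (column - m) / s, mean = m, sd = s)
}

# Design column name a variable maps to under the coding/transform rules.
design_col_name <- function(var, transforms) {
  coded <- c(race = "black", sex = "female", physical_activity = "active_pa",
             alcohol_use = "alcohol", current_smoker = "current_smoker")
  if (var %in% names(coded)) return(unname(coded[[var]]))
  tr <- if (!is.null(transforms) && var %in% names(transforms))
    transforms[[var]] else "identity"
  if (tr == "log") paste0("log_", var) else var
}

# Numeric analysis column for one model variable, on the modelled scale.
numeric_column <- function(cohort, var, transforms, lod_policy, log_counts) {
  tr <- if (!is.null(transforms) && var %in% names(transforms))
    transforms[[var]] else "identity"
  if (var %in% c("race", "sex", "physical_activity", "alcohol_use",
                 "current_smoker")) {
    col <- encode_covariates(cohort, var)
    return(list(values = col[[1L]], name = names(col)[1L], n_sub = 0L))
  }
  if (var == "ltl_bp") {
    v <- cohort$ltl_bp
    from_ts <- is.na(v) & !is.na(cohort$ts_ratio)
    v[from_ts] <- ts_to_bp(cohort$ts_ratio[from_ts])
    return(list(values = v, name = "ltl_bp", n_sub = 0L))
  }
  if (var == "ts_ratio") {
    v <- cohort$ts_ratio
    from_bp <- is.na(v) & !is.na(cohort$ltl_bp)
    v[from_bp] <- bp_to_ts(cohort$ltl_bp[from_bp])
    return(list(values = v, name = "ts_ratio", n_sub = 0L))
  }
  lod <- switch(var, cotinine = cohort$cotinine_lod,
                crp = cohort$crp_lod, rep(NA_real_, nrow(cohort)))
  v <- cohort[[var]]
  if (tr == "log") {
    lt <- log_transform(v, lod, lod_policy)
    return(list(values = lt$log, name = paste0("log_", var),
                n_sub = lt$n_substituted))
  }
  if (any(!is.na(lod))) {
    # identity-scale below-LOD values still need a substitute
    below <- is.na(v) & !is.na(lod)
    v[below] <- switch(lod_policy,
                       lod_over_sqrt2 = lod[below] / sqrt(2),
                       half_lod = lod[below] / 2,
                       strict = msg_stop("medsupp_domain_error",
                                         "below-LOD values with policy 'strict'"))
  }
  list(values = v, name = var, n_sub = 0L)
}

#' Build the numeric design for a model spec
#'
#' Applies, in order: complete-case filtering on the union of all spec
#' variables (so every sub-model of a decomposition shares one sample),
#' T/S-to-base-pair conversion where only the ratio is available, log
#' transforms with the below-LOD policy, covariate coding, and records each
#' column's mean and n-1 SD for standardized-coefficient computation.
#'
#' @param cohort a [cohort_table()].
#' @param spec a [model_spec()].
#' @param lod_policy below-LOD policy, see [log_transform()].
#' @return a `design_matrix`: list with `y` (outcome vector), `x` (numeric
#'   matrix: predictor, third variables, covariate codes), `scaling` (data
#'   frame column/mean/sd incl. the outcome), `n`, `n_removed`,
#'   `n_lod_substituted`, `role` (named list mapping predictor/outcome/
#'   third_variables to design column names), and `spec`.
#' @export
build_design <- function(cohort, spec, lod_policy = "lod_over_sqrt2") {
  lod_policy <- match.arg(lod_policy, LOD_POLICIES)
  filtered <- complete_case_filter(cohort, spec)
  n_removed <- attr(filtered, "n_removed")
  vars <- c(spec$predictor, spec$third_variables, spec$covariates)
  n_sub <- 0L
  cols <- list()
  for (v in vars) {
    nc <- numeric_column(filtered, v, spec$transforms, lod_policy, NULL)
    n_sub <- n_sub + nc$n_sub
    cols[[nc$name]] <- nc$values
  }
  yc <- numeric_column(filtered, spec$outcome, spec$transforms, lod_policy,
                       NULL)
  n_sub <- n_sub + yc$n_sub
  x <- do.call(cbind, cols)
  if (anyNA(x) || anyNA(yc$values))
    msg_stop("medsupp_internal_error",
             "design contains missing values after complete-case filtering")
  all_names <- c(colnames(x), yc$name)
  scaling <- data.frame(
    column = all_names,
    mean = c(colMeans(x), mean(yc$values)),
    sd = c(apply(x, 2L, stats::sd), stats::sd(yc$values)),
    stringsAsFactors = FALSE
  )
  rownames(scaling) <- NULL
  degenerate <- !is.finite(scaling$sd) | scaling$sd <= 0
  if (any(degenerate))
    msg_stop("medsupp_degenerate_scale_error",
             "constant column(s) in analysis sample: %s",
             paste(scaling$column[degenerate], collapse = ", "))
  col_for <- function(vs) {
    vapply(vs, function(v) design_col_name(v, spec$transforms), character(1))
  }
  structure(list(
    y = yc$values, x = x, scaling = scaling, n = nrow(filtered),
    n_removed = n_removed, n_lod_substituted = n_sub,
    role = list(predictor = unname(col_for(spec$predictor)),
                outcome = yc$name,
                third_variables = unname(col_for(spec$third_variables)),
                covariates = unname(col_for(spec$covariates))),
    spec = spec
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> n = %d (%d rows dropped, %d LOD substitutions)\n",
              x$n, x$n_removed, x$n_lod_substituted))
  cat("  outcome:", x$role$outcome, "\n")
  cat("  columns:", paste(colnames(x$x), collapse = ", "), "\n")
  invisible(x)
}
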