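# Subgroup analysis: race/sex path-difference testing via interaction
# models, and the sensitivity analysis swapping the exposure biomarker for
# self-reported smoking.

# Path labels understood by interaction_test: "c" (total), "c_prime"
# (direct), "beta1_<z>" (X -> Z), "beta2_<z>" (Z -> Y adjusted).
parse_path <- function(path, design) {
  zs <- design$role$third_variables
  if (path == "c")
    return(list(y = design$role$outcome, focal = design$role$predictor,
                include_z = character(0)))
  if (path == "c_prime")
    return(list(y = design$role$outcome, focal = design$role$predictor,
                include_z = zs))
  m <- regmatches(path, regexec("^(beta1|beta2)_(.+)$", path))[[1L]]
  if (length(m) == 3L) {
    z <- m[3L]
    if (!z %in% zs)
      msg_stop("medsupp_contract_error",
               "'%s' is not a third variable of this spec", z)
    if (m[2L] == "beta1")
      return(list(y = z, focal = design$role$predictor,
                  include_z = character(0)))
    return(list(y = design$role$outcome, focal = z, include_z = zs))
  }
  msg_stop("medsupp_contract_error", "unknown path label '%s'", path)
}

# Design columns for a path's model within one stratum / the pooled sample.
path_design_x <- function(design, parsed, rows = NULL, drop_cols = character(0)) {
  keep <- setdiff(unique(c(design$role$predictor, parsed$include_z,
                           design$role$covariates)),
                  c(parsed$y, drop_cols))
  x <- design$x[, keep, drop = FALSE]
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  x
}

path_y <- function(design, parsed, rows = NULL) {
  y <- if (parsed$y == design$role$outcome) design$y
       else design$x[, parsed$y]
  if (!is.null(rows)) y <- y[rows]
  y
}

#' Test a path difference between two groups
#'
#' For one decomposition path (total effect `"c"`, direct effect
#' `"c_prime"`, `"beta1_<z>"` or `"beta2_<z>"`), compares the two levels of
#' a binary grouping variable.  Per-group standardized coefficients come
#' from stratified fits (each stratum standardized with its own SDs); the
#' difference p-value comes from the pooled model with the group main
#' effect plus a single focal-predictor-by-group interaction term, one
#' interaction at a time.
#'
#' @param spec a [model_spec()]; the grouping variable may be one of its
#'   covariates (it is then dropped from the adjustment set and handled as
#'   the group factor).
#' @param cohort a [cohort_table()].
#' @param group_var grouping variable name (`"race"`, `"sex"`, or any
#'   cohort variable binary in the analysis sample).
#' @param path path label, see above.
#' @param min_group_n minimum stratum size (default 50).
#' @param lod_policy below-LOD policy.
#' @return a `group_comparison`: list with `path`, `group_var`, `groups`
#'   (per-group std beta, se, p, n), `interaction_p`, `interaction_beta`.
#' @export
interaction_test <- function(spec, cohort, group_var, path,
                             min_group_n = 50L,
                             lod_policy = "lod_over_sqrt2") {
  # adjustment set without the grouping variable
  spec2 <- model_spec(predictor = spec$predictor, outcome = spec$outcome,
                      third_variables = spec$third_variables,
                      covariates = setdiff(spec$covariates, group_var),
                      transforms = spec$transforms)
  # filter on the union incl. the group variable so strata share the sample
  filt_spec <- model_spec(predictor = spec$predictor, outcome = spec$outcome,
                          third_variables = spec$third_variables,
                          covariates = unique(c(spec$covariates, group_var)),
                          transforms = spec$transforms)
  filtered <- complete_case_filter(cohort, filt_spec)
  g_raw <- filtered[[group_var]]
  levels <- sort(unique(as.character(g_raw)))
  if (length(levels) != 2L)
    msg_stop("medsupp_insufficient_group_error",
             "group variable '%s' must take exactly 2 values in the sample (found %d)",
             group_var, length(levels))
  g <- as.numeric(as.character(g_raw) == levels[2L])
  if (min(table(g)) < min_group_n)
    msg_stop("medsupp_insufficient_group_error",
             "smallest group has fewer than %d members", min_group_n)

  design <- build_design(filtered, spec2, lod_policy)
  parsed <- parse_path(path, design)

  # per-group standardized coefficients from stratified fits
  strat <- lapply(c(0, 1), function(lv) {
    rows <- which(g == lv)
    x <- path_design_x(design, parsed, rows)
    y <- path_y(design, parsed, rows)
    scaling <- data.frame(
      column = c(colnames(x), parsed$y),
      mean = c(colMeans(x), mean(y)),
      sd = c(apply(x, 2, stats::sd), stats::sd(y)),
      stringsAsFactors = FALSE)
    fit <- standardized_betas(fit_ols(y, x), scaling, parsed$y)
    eff <- std_term(fit, parsed$focal)
    list(std_beta = eff$std_beta, se = eff$se, p = eff$p,
         n = length(rows))
  })
  names(strat) <- levels

  # pooled model: group main effect + focal x group interaction (raw scale;
  # the interaction p-value is scale invariant)
  x_pool <- path_design_x(design, parsed)
  inter <- design$x[, parsed$focal] * g
  x_full <- cbind(x_pool, group = g, `focal:group` = inter)
  fit_pool <- fit_ols(path_y(design, parsed), x_full)
  bi <- fit_pool$coefficients[["focal:group"]]
  sei <- fit_pool$se[["focal:group"]]
  t <- bi / sei
  p_int <- 2 * stats::pt(-abs(t), fit_pool$df_residual)

  structure(list(path = path, group_var = group_var, groups = strat,
                 interaction_beta = bi, interaction_se = sei,
                 interaction_p = p_int, n = design$n),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> path %s by %s (n = %d)\n",
              x$path, x$group_var, x$n))
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf("  %-10s beta = %+.4f (se %.4f, p %.3g, n %d)\n",
                g, s$std_beta, s$se, s$p, s$n))
  }
  cat(sprintf("  interaction p = %.4g\n", x$interaction_p))
  invisible(x)
}

#' Subgroup table across all decomposition paths
#'
#' Runs [interaction_test()] for every path of the (dual) decomposition
#' and one grouping variable, mirroring the usual published layout: rows =
#' paths, columns = per-group standardized coefficients + interaction p.
#'
#' @inheritParams interaction_test
#' @return data frame with one row per path.
#' @export
subgroup_table <- function(spec, cohort, group_var, min_group_n = 50L,
                           lod_policy = "lod_over_sqrt2") {
  design_cols <- vapply(spec$third_variables,
                        function(v) design_col_name(v, spec$transforms),
                        character(1))
  paths <- c("c",
             as.vector(rbind(paste0("beta1_", design_cols),
                             paste0("beta2_", design_cols))),
             "c_prime")
  rows <- lapply(paths, function(p) {
    cmp <- interaction_test(spec, cohort, group_var, p, min_group_n,
                            lod_policy)
    gs <- names(cmp$groups)
    data.frame(path = p,
               group1 = gs[1L], beta1 = cmp$groups[[1L]]$std_beta,
               p1 = cmp$groups[[1L]]$p,
               group2 = gs[2L], beta2 = cmp$groups[[2L]]$std_beta,
               p2 = cmp$groups[[2L]]$p,
               interaction_p = cmp$interaction_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity analysis: replace the exposure with another predictor
#'
#' Reruns the full third-variable analysis with the predictor swapped (for
#' instance serum cotinine replaced by self-reported current smoking) and
#' summarises sign agreement of every path between the two runs.
#'
#' @param spec a [model_spec()].
#' @param cohort a [cohort_table()].
#' @param new_predictor replacement predictor variable name.
#' @param lod_policy below-LOD policy.
#' @return list with `original`, `swapped` (both `thirdvar_result`) and
#'   `sign_agreement` (named logical per path).
#' @export
sensitivity_swap_predictor <- function(spec, cohort, new_predictor,
                                       lod_policy = "lod_over_sqrt2") {
  spec2 <- if (identical(new_predictor, spec$predictor)) spec else
    model_spec(predictor = new_predictor, outcome = spec$outcome,
               third_variables = spec$third_variables,
               covariates = setdiff(spec$covariates, new_predictor),
               transforms = spec$transforms)
  original <- run_third_variable_analysis(spec, cohort, lod_policy)
  swapped <- run_third_variable_analysis(spec2, cohort, lod_policy)
  paths <- function(r) {
    out <- c(c = r$paths$c$std_beta, c_prime = r$paths$c_prime$std_beta)
    for (z in names(r$paths$per_z)) {
      out[paste0("beta1_", z)] <- r$paths$per_z[[z]]$beta1$std_beta
      out[paste0("beta2_", z)] <- r$paths$per_z[[z]]$beta2$std_beta
    }
    out
  }
  po <- paths(original); ps <- paths(swapped)
  common <- intersect(names(po), names(ps))
  list(original = original, swapped = swapped,
       sign_agreement = stats::setNames(
         sign(po[common]) == sign(ps[common]), common))
}
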