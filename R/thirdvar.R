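# Third-variable decomposition: four-step total/direct/indirect analysis
# with one or two intermediates, delta-method indirect-effect tests,
# mediation/suppression classification and effect percentages.
#
# All sub-models are fit on one shared complete-case sample and
# standardized with that sample's SDs, which makes the decomposition
# c = c' + sum_k beta1_k * beta2_k an exact algebraic identity of nested
# least squares.

# Columns of the design used in each sub-model.
submodel_cols <- function(design, include_z = character(0), outcome_col = NULL) {
  keep <- c(design$role$predictor, include_z, design$role$covariates)
  if (!is.null(outcome_col)) keep <- setdiff(keep, outcome_col)
  design$x[, keep, drop = FALSE]
}

fit_std <- function(design, y_col, x_cols) {
  y <- if (y_col == design$role$outcome) design$y
       else design$x[, y_col]
  fit <- fit_ols(y, x_cols)
  standardized_betas(fit, design$scaling, y_col)
}

#' Step 1: total effect of the predictor on the outcome
#'
#' Standardized coefficient `c` of X from `Y ~ X + covariates` (third
#' variables excluded).
#'
#' @param design a [build_design()] result.
#' @return a `std_reg_result` with attribute `effect`: the X term's row.
#' @export
total_effect <- function(design) {
  res <- fit_std(design, design$role$outcome,
                 submodel_cols(design))
  attr(res, "effect") <- std_term(res, design$role$predictor)
  res
}

#' Step 2: predictor-to-third-variable path
#'
#' Standardized coefficient `beta1_k` of X from `Z_k ~ X + covariates`
#' (other third variables excluded).
#'
#' @param design a [build_design()] result.
#' @param z_index which third variable (1 or 2).
#' @return a `std_reg_result` with attribute `effect`: the X term's row.
#' @export
path_a <- function(design, z_index = 1L) {
  zs <- design$role$third_variables
  if (z_index < 1L || z_index > length(zs))
    msg_stop("medsupp_contract_error", "no third variable at index %d",
             z_index)
  z_col <- zs[z_index]
  res <- fit_std(design, z_col,
                 submodel_cols(design, outcome_col = NULL))
  attr(res, "effect") <- std_term(res, design$role$predictor)
  res
}

#' Step 3: outcome model with all third variables
#'
#' `Y ~ X + Z_1 [+ Z_2] + covariates`; the X term is the direct effect `c'`
#' and each Z term is that variable's outcome path `beta2_k`, adjusted for X
#' and the other Z.
#'
#' @param design a [build_design()] result.
#' @return a `std_reg_result` with attributes `c_prime` and `beta2` (named
#'   list per third variable).
#' @export
outcome_model <- function(design) {
  zs <- design$role$third_variables
  if (length(zs) == 0L)
    msg_stop("medsupp_contract_error", "model spec names no third variables")
  res <- fit_std(design, design$role$outcome, submodel_cols(design, zs))
  attr(res, "c_prime") <- std_term(res, design$role$predictor)
  attr(res, "beta2") <- lapply(stats::setNames(zs, zs),
                               function(z) std_term(res, z))
  res
}

#' Indirect effect through one third variable
#'
#' Product of the predictor-to-Z path and the Z-to-outcome path:
#' `beta_Ind = beta1 * beta2`.
#'
#' @param beta1 standardized X-to-Z coefficient.
#' @param beta2 standardized Z-to-Y coefficient (adjusted for X).
#' @return the product.
#' @export
indirect_effect <- function(beta1, beta2) beta1 * beta2

#' Sobel-type test of an indirect effect
#'
#' First-order delta-method (multivariate normal approximation) z-test of
#' the product of two path coefficients:
#' `SE = sqrt(beta1^2 se2^2 + beta2^2 se1^2)` (optionally adding the
#' second-order term `se1^2 se2^2`), `z = beta1 beta2 / SE`, two-sided
#' normal p-value.
#'
#' @param beta1,se1 first path coefficient and its standard error.
#' @param beta2,se2 second path coefficient and its standard error.
#' @param second_order add the second-order variance term.
#' @return list(`z`, `p`, `se`).
#' @export
sobel_test <- function(beta1, se1, beta2, se2, second_order = FALSE) {
  if (!is.finite(se1) || !is.finite(se2) || se1 <= 0 || se2 <= 0)
    msg_stop("medsupp_contract_error", "standard errors must be > 0")
  v <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (second_order) v <- v + se1^2 * se2^2
  se <- sqrt(v)
  ind <- beta1 * beta2
  if (se == 0) {
    if (ind == 0) return(list(z = 0, p = 1, se = 0))
    msg_stop("medsupp_undefined_statistic_error",
             "zero delta-method SE with nonzero indirect effect")
  }
  z <- ind / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), se = se)
}

#' Step 4: classify a third variable as mediator or suppressor
#'
#' The rule compares magnitudes of the total effect `c` and direct effect
#' `c'`, and is defined only when `|c| > |indirect|`:
#' mediation if `|c| > |c'|` (part of the total effect flows through Z),
#' suppression if `|c| < |c'|` (Z masks part of the X-Y association).
#' `|c| <= |indirect|` returns `"undefined"`.  The measure-zero tie
#' `|c| = |c'|` is broken deterministically: mediation when the indirect
#' effect has the sign of `c`, suppression otherwise.
#'
#' @param c standardized total effect.
#' @param c_prime standardized direct effect.
#' @param indirect standardized indirect effect (`beta1 * beta2`).
#' @return `"mediation"`, `"suppression"` or `"undefined"`.
#' @export
classify <- function(c, c_prime, indirect) {
  if (abs(c) <= abs(indirect)) return("undefined")
  if (abs(c) > abs(c_prime)) return("mediation")
  if (abs(c) < abs(c_prime)) return("suppression")
  if (sign(indirect) == sign(c)) "mediation" else "suppression"
}

#' Mediation / suppression effect percentage
#'
#' Mediation: `|indirect| / |c| * 100`; suppression:
#' `|indirect| / |c'| * 100`.  For an `"undefined"` role the result is `NA`
#' with a warning.
#'
#' @param role output of [classify()].
#' @param indirect standardized indirect effect.
#' @param c standardized total effect.
#' @param c_prime standardized direct effect.
#' @return percentage (0-100 scale).
#' @export
effect_percent <- function(role, indirect, c, c_prime) {
  if (role == "undefined") {
    warning("effect percentage undefined when |c| <= |indirect|")
    return(NA_real_)
  }
  denom <- switch(role, mediation = abs(c), suppression = abs(c_prime),
                  msg_stop("medsupp_contract_error", "unknown role '%s'", role))
  if (denom == 0)
    msg_stop("medsupp_domain_error",
             "zero denominator for %s percentage", role)
  abs(indirect) / denom * 100
}

# Dual-Z per-variable role: attribution by the sign relationship of each
# component to the total effect (component opposing c suppresses part of
# it; component aligned with c carries part of it).
dual_role <- function(indirect_k, c) {
  if (indirect_k == 0) return("undefined")
  if (sign(indirect_k) == sign(c)) "mediation" else "suppression"
}

#' Run the full third-variable analysis
#'
#' Orchestrates the four steps on one shared complete-case sample:
#' (1) total effect `c` from `Y ~ X + covariates`; (2) per third variable,
#' the path `beta1_k` from `Z_k ~ X + covariates`; (3) direct effect `c'`
#' and outcome paths `beta2_k` from `Y ~ X + all Z + covariates`;
#' (4) indirect effects `beta1_k * beta2_k`, delta-method tests,
#' mediation/suppression classification and effect percentages.  With two
#' third variables the total effect decomposes into three components
#' (direct + one indirect per Z) and per-Z roles are assigned by the sign
#' of each component relative to `c`.
#'
#' @param spec a [model_spec()] with 1 or 2 third variables.
#' @param cohort a [cohort_table()].
#' @param lod_policy below-LOD substitution policy, see [log_transform()].
#' @param second_order_sobel use the second-order delta-method variance.
#' @return a `thirdvar_result`: list with `paths` (c, c_prime, per-Z beta1/
#'   beta2/indirect with SEs, indirect_overall), `roles`, `effect_percent`,
#'   `indirect_test` (per Z and overall), `models` (the underlying
#'   `std_reg_result`s), `n`, `n_removed`, `spec`.
#' @export
run_third_variable_analysis <- function(spec, cohort,
                                        lod_policy = "lod_over_sqrt2",
                                        second_order_sobel = FALSE) {
  if (length(spec$third_variables) < 1L)
    msg_stop("medsupp_spec_error",
             "third-variable analysis needs 1 or 2 third variables")
  design <- build_design(cohort, spec, lod_policy)
  zs <- design$role$third_variables
  m_total <- total_effect(design)
  m_paths <- lapply(seq_along(zs), function(k) path_a(design, k))
  m_out <- outcome_model(design)
  c_eff <- attr(m_total, "effect")
  cp <- attr(m_out, "c_prime")
  beta2 <- attr(m_out, "beta2")
  per_z <- lapply(seq_along(zs), function(k) {
    b1 <- attr(m_paths[[k]], "effect")
    b2 <- beta2[[zs[k]]]
    ind <- indirect_effect(b1$std_beta, b2$std_beta)
    test <- sobel_test(b1$std_beta, b1$se, b2$std_beta, b2$se,
                       second_order = second_order_sobel)
    list(z_col = zs[k], beta1 = b1, beta2 = b2, indirect = ind,
         sobel = test)
  })
  names(per_z) <- zs
  ind_overall <- sum(vapply(per_z, `[[`, numeric(1), "indirect"))
  # overall test: delta-method variances add across components
  # (cross-model covariances between the Z-equations are ignored; exact for
  # a single Z, a documented first-order approximation for two)
  v_overall <- sum(vapply(per_z, function(p) p$sobel$se^2, numeric(1)))
  overall_test <- if (v_overall > 0) {
    z <- ind_overall / sqrt(v_overall)
    list(z = z, p = 2 * stats::pnorm(-abs(z)), se = sqrt(v_overall))
  } else list(z = 0, p = 1, se = 0)

  roles <- if (length(zs) == 1L) {
    stats::setNames(list(classify(c_eff$std_beta, cp$std_beta,
                                  per_z[[1L]]$indirect)), zs)
  } else {
    stats::setNames(lapply(per_z, function(p)
      dual_role(p$indirect, c_eff$std_beta)), zs)
  }
  pct <- stats::setNames(lapply(zs, function(z) {
    role <- roles[[z]]
    if (role == "undefined") return(NA_real_)
    effect_percent(role, per_z[[z]]$indirect, c_eff$std_beta, cp$std_beta)
  }), zs)

  identity_gap <- c_eff$std_beta - cp$std_beta - ind_overall
  if (!is.finite(identity_gap) || abs(identity_gap) > 1e-8)
    msg_stop("medsupp_internal_error",
             "decomposition identity violated (gap %.3g): sub-models do not share a sample",
             identity_gap)

  structure(list(
    paths = list(c = c_eff, c_prime = cp, per_z = per_z,
                 indirect_overall = ind_overall),
    roles = roles,
    effect_percent = pct,
    indirect_test = list(per_z = lapply(per_z, `[[`, "sobel"),
                         overall = overall_test),
    models = list(total = m_total, paths_a = m_paths, outcome = m_out),
    n = design$n, n_removed = design$n_removed,
    n_lod_substituted = design$n_lod_substituted,
    spec = spec
  ), class = "thirdvar_result")
}

#' @export
print.thirdvar_result <- function(x, ...) {
  cat(sprintf("<thirdvar_result> n = %d (%d rows dropped)\n",
              x$n, x$n_removed))
  cat(sprintf("  total effect   c  = %+.4f (p = %.3g)\n",
              x$paths$c$std_beta, x$paths$c$p))
  cat(sprintf("  direct effect  c' = %+.4f (p = %.3g)\n",
              x$paths$c_prime$std_beta, x$paths$c_prime$p))
  for (z in names(x$paths$per_z)) {
    p <- x$paths$per_z[[z]]
    pct <- x$effect_percent[[z]]
    cat(sprintf("  %-12s beta1 = %+.4f, beta2 = %+.4f, indirect = %+.4f (p = %.3g) -> %s%s\n",
                z, p$beta1$std_beta, p$beta2$std_beta, p$indirect,
                p$sobel$p, x$roles[[z]],
                if (is.na(pct)) "" else sprintf(" (%.1f%%)", pct)))
  }
  cat(sprintf("  overall indirect = %+.4f (z = %.2f, p = %.3g)\n",
              x$paths$indirect_overall, x$indirect_test$overall$z,
              x$indirect_test$overall$p))
  invisible(x)
}

#' Serialize a third-variable result
#'
#' `thirdvar_to_json()` emits the full result (paths, roles, percentages,
#' tests, per-model coefficient tables); `thirdvar_to_tsv()` writes the flat
#' path-coefficient table (one row per path: label, estimate, SE, p).
#'
#' @param result a `thirdvar_result`.
#' @param path optional output file.
#' @return JSON string / data frame (invisibly when written).
#' @export
thirdvar_to_json <- function(result, path = NULL) {
  term_list <- function(t) t[c("term", "std_beta", "se", "ci_low",
                               "ci_high", "p")]
  payload <- list(
    n = result$n, n_removed = result$n_removed,
    n_lod_substituted = result$n_lod_substituted,
    c = term_list(result$paths$c),
    c_prime = term_list(result$paths$c_prime),
    third_variables = lapply(result$paths$per_z, function(p) list(
      beta1 = term_list(p$beta1), beta2 = term_list(p$beta2),
      indirect = p$indirect, sobel = p$sobel,
      role = result$roles[[p$z_col]],
      effect_percent = result$effect_percent[[p$z_col]])),
    indirect_overall = result$paths$indirect_overall,
    indirect_overall_test = result$indirect_test$overall,
    models = lapply(result$models[c("total", "outcome")], as.data.frame)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null")
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' @rdname thirdvar_to_json
#' @export
thirdvar_to_tsv <- function(result, path = NULL) {
  rows <- list(
    data.frame(path = "c", estimate = result$paths$c$std_beta,
               se = result$paths$c$se, p = result$paths$c$p),
    data.frame(path = "c_prime", estimate = result$paths$c_prime$std_beta,
               se = result$paths$c_prime$se, p = result$paths$c_prime$p))
  for (z in names(result$paths$per_z)) {
    p <- result$paths$per_z[[z]]
    rows <- c(rows, list(
      data.frame(path = paste0("beta1_", z), estimate = p$beta1$std_beta,
                 se = p$beta1$se, p = p$beta1$p),
      data.frame(path = paste0("beta2_", z), estimate = p$beta2$std_beta,
                 se = p$beta2$se, p = p$beta2$p),
      data.frame(path = paste0("indirect_", z), estimate = p$indirect,
                 se = p$sobel$se, p = p$sobel$p)))
  }
  rows <- c(rows, list(
    data.frame(path = "indirect_overall",
               estimate = result$paths$indirect_overall,
               se = result$indirect_test$overall$se,
               p = result$indirect_test$overall$p)))
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(out))
  }
  out
}
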