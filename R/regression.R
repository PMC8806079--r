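# Least-squares core: OLS with classical inference, standardized
# coefficients, ANCOVA-adjusted group means and Pearson chi-square tests.

#' Ordinary least squares fit
#'
#' Fits `y ~ 1 + X` by QR decomposition.  Standard errors use the classical
#' homoskedastic covariance estimator `sigma^2 (X'X)^{-1}`; inference
#' downstream uses the t distribution with the residual degrees of freedom.
#' Rank deficiency is an error naming the offending column rather than a
#' silently dropped term.
#'
#' @param y numeric response vector, no missing values.
#' @param x numeric matrix of predictors (no intercept column), with column
#'   names.
#' @return an `ols_fit`: list with `coefficients`, `se`, `df_residual`,
#'   `sigma2`, `r_squared`, `n`, `fitted`, `residuals`.
#' @export
fit_ols <- function(y, x) {
  x <- as.matrix(x)
  if (ncol(x) > 0L && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(y)
  if (nrow(x) != n)
    msg_stop("medsupp_contract_error", "y and x have different lengths")
  if (anyNA(y) || anyNA(x))
    msg_stop("medsupp_contract_error", "missing values in regression inputs")
  k <- ncol(x) + 1L
  if (n <= k)
    msg_stop("medsupp_contract_error",
             "need n > number of coefficients (%d); got n = %d", k, n)
  xm <- cbind(`(Intercept)` = 1, x)
  qrx <- qr(xm)
  if (qrx$rank < ncol(xm)) {
    dropped <- colnames(xm)[qrx$pivot[seq(qrx$rank + 1L, ncol(xm))]]
    msg_stop("medsupp_collinearity_error",
             "design is rank deficient; offending column(s): %s",
             paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(xm %*% beta)
  res <- y - fitted
  df_res <- n - ncol(xm)
  sigma2 <- sum(res^2) / df_res
  xtx_inv <- chol2inv(qr.R(qrx))
  # undo the QR pivot so the covariance rows match the column order
  unpivot <- order(qrx$pivot)
  xtx_inv <- xtx_inv[unpivot, unpivot, drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- names(beta)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = beta, se = se, df_residual = df_res,
                 sigma2 = sigma2,
                 r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
                 n = n, fitted = fitted, residuals = res),
            class = "ols_fit")
}

#' Standardized regression coefficients with inference
#'
#' Rescales each non-intercept coefficient by `SD(term) / SD(outcome)` so
#' effects are unit-free and comparable across terms (binary indicators are
#' scaled by the SD of the 0/1 column, like continuous terms).  Standard
#' errors and confidence limits scale by the same factor; t statistics and
#' p-values are therefore identical to the raw fit.
#'
#' @param fit an [fit_ols()] result.
#' @param scaling data frame with columns `column`, `mean`, `sd` covering
#'   every design column and the outcome (as produced by [build_design()]).
#' @param outcome name of the outcome column inside `scaling`.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return a `std_reg_result`: data frame `term`, `std_beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, with attributes `n`, `r_squared`,
#'   `df_residual`.
#' @export
standardized_betas <- function(fit, scaling, outcome, conf_level = 0.95) {
  stopifnot(inherits(fit, "ols_fit"))
  if (!outcome %in% scaling$column)
    msg_stop("medsupp_contract_error",
             "outcome '%s' missing from scaling table", outcome)
  sd_y <- scaling$sd[scaling$column == outcome]
  if (!is.finite(sd_y) || sd_y <= 0)
    msg_stop("medsupp_degenerate_scale_error", "outcome SD must be > 0")
  terms <- setdiff(names(fit$coefficients), "(Intercept)")
  missing_terms <- setdiff(terms, scaling$column)
  if (length(missing_terms) > 0L)
    msg_stop("medsupp_contract_error",
             "no recorded scaling for term(s): %s",
             paste(missing_terms, collapse = ", "))
  sd_x <- scaling$sd[match(terms, scaling$column)]
  if (any(!is.finite(sd_x) | sd_x <= 0))
    msg_stop("medsupp_degenerate_scale_error",
             "term(s) with non-positive SD: %s",
             paste(terms[!is.finite(sd_x) | sd_x <= 0], collapse = ", "))
  factor <- sd_x / sd_y
  b <- fit$coefficients[terms] * factor
  se <- fit$se[terms] * factor
  tstat <- b / se
  p <- 2 * stats::pt(-abs(tstat), fit$df_residual)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, fit$df_residual)
  out <- data.frame(term = terms, std_beta = unname(b), se = unname(se),
                    ci_low = unname(b - tcrit * se),
                    ci_high = unname(b + tcrit * se),
                    p = unname(p), stringsAsFactors = FALSE)
  attr(out, "n") <- fit$n
  attr(out, "r_squared") <- fit$r_squared
  attr(out, "df_residual") <- fit$df_residual
  class(out) <- c("std_reg_result", "data.frame")
  out
}

#' @export
print.std_reg_result <- function(x, digits = 4, ...) {
  cat(sprintf("<std_reg_result> n = %d, R^2 = %.4f\n",
              attr(x, "n"), attr(x, "r_squared")))
  df <- as.data.frame(x)
  df$std_beta <- round(df$std_beta, digits)
  df$se <- round(df$se, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  df$p <- signif(df$p, 3)
  print(df)
  invisible(x)
}

# One term's standardized row, as a simple list (used by thirdvar/subgroup).
std_term <- function(result, term) {
  row <- result[result$term == term, , drop = FALSE]
  if (nrow(row) != 1L)
    msg_stop("medsupp_contract_error", "term '%s' not in fit", term)
  list(term = term, std_beta = row$std_beta, se = row$se,
       ci_low = row$ci_low, ci_high = row$ci_high, p = row$p)
}

#' Covariate-adjusted group means (ANCOVA)
#'
#' Least-squares means per group from `outcome ~ group + adjuster`,
#' evaluated at the grand mean of the adjuster; the group p-value comes from
#' the F-test of the group term against the full model's residual.
#'
#' @param outcome numeric vector.
#' @param group factor or character group labels (>= 2 groups, each with
#'   >= 2 members).
#' @param adjuster numeric covariate (e.g. age).
#' @return list with `means` (named per group), `p` (group F-test),
#'   `f_statistic`, `df`.
#' @export
adjusted_means <- function(outcome, group, adjuster) {
  group <- factor(group)
  if (nlevels(group) < 2L)
    msg_stop("medsupp_contract_error", "need at least two groups")
  if (any(table(group) < 2L))
    msg_stop("medsupp_contract_error", "each group needs >= 2 members")
  keep <- !is.na(outcome) & !is.na(group) & !is.na(adjuster)
  outcome <- outcome[keep]; group <- droplevels(group[keep])
  adjuster <- adjuster[keep]
  gmat <- stats::model.matrix(~ group)[, -1L, drop = FALSE]
  fit_full <- fit_ols(outcome, cbind(gmat, adjuster = adjuster))
  fit_null <- fit_ols(outcome, cbind(adjuster = adjuster))
  rss_full <- sum(fit_full$residuals^2)
  rss_null <- sum(fit_null$residuals^2)
  df1 <- nlevels(group) - 1L
  df2 <- fit_full$df_residual
  f <- ((rss_null - rss_full) / df1) / (rss_full / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  grand <- mean(adjuster)
  b <- fit_full$coefficients
  base <- unname(b["(Intercept)"] + b["adjuster"] * grand)
  means <- c(base, base + unname(b[colnames(gmat)]))
  names(means) <- levels(group)
  list(means = means, p = p, f_statistic = f, df = c(df1, df2))
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic on a contingency table with
#' `(r - 1)(c - 1)` degrees of freedom and no continuity correction.
#'
#' @param table matrix of counts.
#' @return list(`statistic`, `df`, `p`).
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table))
    msg_stop("medsupp_contract_error", "counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0))
    msg_stop("medsupp_degenerate_table_error",
             "zero marginal total in contingency table")
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Descriptive table by race and sex
#'
#' Summarises a cohort the way epidemiological baseline tables do: for
#' continuous variables, mean (SD) per race-sex group with age-adjusted
#' ANCOVA p-values (sex difference within race, and race difference pooled
#' over sex); for categorical variables, counts (%) with chi-square
#' p-values.
#'
#' @param cohort a [cohort_table()].
#' @return data frame, one row per variable/level and group columns, with
#'   attributes `p_sex_within_race` and `p_race` (named lists).
#' @export
descriptive_table <- function(cohort) {
  grp <- interaction(cohort$race, cohort$sex, sep = ":")
  groups <- c("white:male", "white:female", "black:male", "black:female")
  cont_vars <- c("age", "cotinine", "crp", "bmi", "ltl_bp")
  cont_value <- function(var) {
    v <- cohort[[var]]
    if (var == "ltl_bp") {
      from_ts <- is.na(v) & !is.na(cohort$ts_ratio)
      v[from_ts] <- ts_to_bp(cohort$ts_ratio[from_ts])
    }
    v
  }
  rows <- list()
  p_sex <- list(); p_race <- list()
  for (var in cont_vars) {
    v <- cont_value(var)
    cells <- vapply(groups, function(g) {
      x <- v[as.character(grp) == g & !is.na(v)]
      sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
    }, character(1))
    rows[[var]] <- c(variable = var, cells)
    ok <- !is.na(v) & !is.na(cohort$age)
    if (var == "age") {
      # age itself: plain (unadjusted) group comparison
      p_sex[[var]] <- lapply(split(seq_len(nrow(cohort))[ok],
                                   cohort$race[ok]), function(idx)
        stats::t.test(v[idx] ~ cohort$sex[idx])$p.value)
      next
    }
    p_sex[[var]] <- lapply(RACE_LEVELS, function(r) {
      idx <- ok & cohort$race == r
      adjusted_means(v[idx], cohort$sex[idx], cohort$age[idx])$p
    })
    names(p_sex[[var]]) <- RACE_LEVELS
    p_race[[var]] <- adjusted_means(v[ok], cohort$race[ok], cohort$age[ok])$p
  }
  cat_vars <- list(physical_activity = PA_LEVELS,
                   alcohol_use = ALCOHOL_LEVELS,
                   current_smoker = c("TRUE"))
  for (var in names(cat_vars)) {
    x <- as.character(cohort[[var]])
    for (lev in cat_vars[[var]]) {
      cells <- vapply(groups, function(g) {
        in_g <- as.character(grp) == g & !is.na(x)
        sprintf("%d (%.1f)", sum(x[in_g] == lev),
                100 * mean(x[in_g] == lev))
      }, character(1))
      rows[[paste(var, lev, sep = ":")]] <-
        c(variable = paste(var, lev, sep = ":"), cells)
    }
    tab_race <- table(cohort$race, x)
    p_race[[var]] <- chi_square_test(tab_race)$p
    p_sex[[var]] <- lapply(RACE_LEVELS, function(r) {
      idx <- cohort$race == r & !is.na(x)
      chi_square_test(table(cohort$sex[idx], x[idx]))$p
    })
    names(p_sex[[var]]) <- RACE_LEVELS
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("variable", groups)
  rownames(out) <- NULL
  attr(out, "p_sex_within_race") <- p_sex
  attr(out, "p_race") <- p_race
  out
}
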