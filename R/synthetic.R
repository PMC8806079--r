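# Synthetic NHANES-like cohort generator and its analytic oracle.
#
# The generator draws from an explicit linear-Gaussian structural model on
# the modelled scales (log-cotinine, BMI, log-CRP, LTL in bp), with
# categorical demographics drawn at fixed frequencies.  Path strengths are
# specified on the standardized scale; the constructor converts them to raw
# structural coefficients using the known source variances, so the
# population standardized partial coefficients of the analysis models equal
# the requested values exactly.  implied_standardized_paths() computes those
# population values from the implied covariance matrix, giving an
# independent analytic oracle for every fitted path.

# Sources (mutually independent): age, female, black, active, alcohol,
# smoker, plus one unit-variance Gaussian error per structural equation.
SOURCE_NAMES <- c("age", "female", "black", "active", "alcohol", "smoker",
                  "e_x", "e_bmi", "e_crp", "e_ltl")

#' Parameters of the synthetic cohort generator
#'
#' Defaults state a cohort resembling the 1999-2002 NHANES Black/White
#' adult sample in size, demographic mix and path structure: n = 4,047,
#' ages uniform on 20-85, 47.4% female, 23.1% Black, 27.0% current smokers,
#' serum cotinine a two-component log-normal mixture (non-smokers centred
#' near the 0.05 ng/mL detection limit, smokers elevated about e^6.6-fold),
#' and standardized structural paths reproducing the published sign pattern:
#' cotinine lowers BMI (-0.079) and raises log-CRP (+0.109), both BMI
#' (-0.036) and log-CRP (-0.061) lower LTL, the direct cotinine-LTL path is
#' -0.0448, and LTL declines steeply with age (-0.386).
#'
#' @param n cohort size.
#' @param seed integer seed; the same params + seed give a byte-identical
#'   cohort.
#' @param age_range years, uniform.
#' @param p_female,p_black,smoking_prevalence fractions in (0,1).
#' @param pa_probs probabilities for none/moderate/vigorous activity.
#' @param alcohol_probs probabilities for the four alcohol categories.
#' @param cotinine_lod assay LOD, ng/mL; non-smoker draws below it are
#'   reported as censored ("<LOD").
#' @param crp_lod CRP LOD, mg/dL.
#' @param log_cotinine_nonsmoker mean log cotinine in non-smokers.
#' @param log_cotinine_smoker_shift added mean log cotinine for smokers.
#' @param log_cotinine_sd residual SD of log cotinine.
#' @param x_paths_raw raw (log-unit) nuisance paths female/black -> log
#'   cotinine; default zero.
#' @param bmi_mean,bmi_sd marginal BMI moments, kg/m^2.
#' @param bmi_paths standardized paths x/age/female/black -> BMI.
#' @param log_crp_mean,log_crp_sd marginal log-CRP moments (CRP in mg/dL).
#' @param crp_paths standardized paths x/age/female/black -> log-CRP.
#' @param ltl_mean,ltl_sd marginal LTL moments, base pairs.
#' @param ltl_paths standardized paths x/bmi/crp/age/female/black/active/
#'   alcohol -> LTL.
#' @param ltl_unit `"bp"` (default), `"ts"` (emit only the T/S ratio via the
#'   inverse calibration) or `"both"`.
#' @return a `synthetic_params` list.
#' @export
synthetic_params <- function(
    n = 4047L,
    seed = 20220118L,
    age_range = c(20, 85),
    p_female = 0.474,
    p_black = 0.2306,
    pa_probs = c(none = 0.5859, moderate = 0.2824, vigorous = 0.1317),
    alcohol_probs = c(0.3151, 0.4099, 0.1342, 0.1408),
    smoking_prevalence = 0.2703,
    cotinine_lod = 0.05,
    crp_lod = 0.01,
    log_cotinine_nonsmoker = log(0.2),
    log_cotinine_smoker_shift = 6.62,
    log_cotinine_sd = 1.1,
    x_paths_raw = c(female = 0, black = 0),
    bmi_mean = 28.2, bmi_sd = 6.3,
    bmi_paths = c(x = -0.079, age = 0.05, female = 0.05, black = 0.08),
    log_crp_mean = log(0.45), log_crp_sd = 1.05,
    crp_paths = c(x = 0.109, age = 0.15, female = 0.10, black = 0.05),
    ltl_mean = 5780, ltl_sd = 650,
    ltl_paths = c(x = -0.0448, bmi = -0.036, crp = -0.061, age = -0.386,
                  female = 0.062, black = 0.080, active = 0.040,
                  alcohol = 0.038),
    ltl_unit = c("bp", "ts", "both")) {
  ltl_unit <- match.arg(ltl_unit)
  params <- list(n = as.integer(n), seed = as.integer(seed),
                 age_range = age_range, p_female = p_female,
                 p_black = p_black, pa_probs = pa_probs,
                 alcohol_probs = alcohol_probs,
                 smoking_prevalence = smoking_prevalence,
                 cotinine_lod = cotinine_lod, crp_lod = crp_lod,
                 log_cotinine_nonsmoker = log_cotinine_nonsmoker,
                 log_cotinine_smoker_shift = log_cotinine_smoker_shift,
                 log_cotinine_sd = log_cotinine_sd,
                 x_paths_raw = x_paths_raw,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 bmi_paths = bmi_paths,
                 log_crp_mean = log_crp_mean, log_crp_sd = log_crp_sd,
                 crp_paths = crp_paths,
                 ltl_mean = ltl_mean, ltl_sd = ltl_sd,
                 ltl_paths = ltl_paths, ltl_unit = ltl_unit)
  validate_params(params)
  class(params) <- "synthetic_params"
  structural_model(params)  # fail fast on non-positive-definite structures
  params
}

validate_params <- function(p) {
  chk <- function(ok, fmt, ...) if (!ok)
    msg_stop("medsupp_config_error", fmt, ...)
  chk(p$n >= 1, "n must be >= 1")
  chk(length(p$age_range) == 2L && diff(p$age_range) > 0,
      "age_range must be an increasing pair")
  for (f in c("p_female", "p_black", "smoking_prevalence"))
    chk(p[[f]] > 0 && p[[f]] < 1, "%s must be in (0,1)", f)
  chk(abs(sum(p$pa_probs) - 1) < 1e-8, "pa_probs must sum to 1")
  chk(abs(sum(p$alcohol_probs) - 1) < 1e-8, "alcohol_probs must sum to 1")
  chk(p$log_cotinine_sd > 0, "log_cotinine_sd must be > 0")
  chk(p$bmi_sd > 0 && p$log_crp_sd > 0 && p$ltl_sd > 0,
      "marginal SDs must be > 0")
  chk(p$cotinine_lod > 0 && p$crp_lod > 0, "LODs must be > 0")
  invisible(TRUE)
}

# Source variances implied by the categorical frequencies.
source_variances <- function(p) {
  pa_active <- sum(p$pa_probs[c("moderate", "vigorous")])
  alc_scores <- 0:3
  alc_mean <- sum(alc_scores * p$alcohol_probs)
  alc_var <- sum(alc_scores^2 * p$alcohol_probs) - alc_mean^2
  c(age = diff(p$age_range)^2 / 12,
    female = p$p_female * (1 - p$p_female),
    black = p$p_black * (1 - p$p_black),
    active = pa_active * (1 - pa_active),
    alcohol = alc_var,
    smoker = p$smoking_prevalence * (1 - p$smoking_prevalence),
    e_x = 1, e_bmi = 1, e_crp = 1, e_ltl = 1)
}

source_means <- function(p) {
  pa_active <- sum(p$pa_probs[c("moderate", "vigorous")])
  c(age = mean(p$age_range), female = p$p_female, black = p$p_black,
    active = pa_active, alcohol = sum(0:3 * p$alcohol_probs),
    smoker = p$smoking_prevalence,
    e_x = 0, e_bmi = 0, e_crp = 0, e_ltl = 0)
}

# Resolve the structural model: raw coefficients per equation, residual
# SDs, and loadings of each modelled variable on the independent sources.
# Errors if a requested marginal variance is not attainable (the implied
# covariance would not be positive definite).
structural_model <- function(p) {
  v <- source_variances(p)
  m <- source_means(p)
  sds <- sqrt(v)
  load <- function() stats::setNames(numeric(length(SOURCE_NAMES)),
                                     SOURCE_NAMES)
  # X: log cotinine
  lx <- load()
  lx["smoker"] <- p$log_cotinine_smoker_shift
  lx["female"] <- p$x_paths_raw[["female"]]
  lx["black"] <- p$x_paths_raw[["black"]]
  lx["e_x"] <- p$log_cotinine_sd
  var_x <- sum(lx^2 * v)
  sd_x <- sqrt(var_x)
  mean_x <- p$log_cotinine_nonsmoker + sum(lx[names(m)] * m)

  # BMI: std paths -> raw
  bp <- p$bmi_paths
  raw_bmi <- c(x = bp[["x"]] * p$bmi_sd / sd_x,
               age = bp[["age"]] * p$bmi_sd / sds[["age"]],
               female = bp[["female"]] * p$bmi_sd / sds[["female"]],
               black = bp[["black"]] * p$bmi_sd / sds[["black"]])
  lb <- load()
  lb <- lb + raw_bmi[["x"]] * lx
  lb["age"] <- lb["age"] + raw_bmi[["age"]]
  lb["female"] <- lb["female"] + raw_bmi[["female"]]
  lb["black"] <- lb["black"] + raw_bmi[["black"]]
  resid_bmi2 <- p$bmi_sd^2 - sum(lb^2 * v)
  if (resid_bmi2 <= 0)
    msg_stop("medsupp_config_error",
             "bmi_paths imply variance above bmi_sd^2 (non-positive-definite model)")
  lb["e_bmi"] <- sqrt(resid_bmi2)

  # log CRP
  cp <- p$crp_paths
  raw_crp <- c(x = cp[["x"]] * p$log_crp_sd / sd_x,
               age = cp[["age"]] * p$log_crp_sd / sds[["age"]],
               female = cp[["female"]] * p$log_crp_sd / sds[["female"]],
               black = cp[["black"]] * p$log_crp_sd / sds[["black"]])
  lr <- load()
  lr <- lr + raw_crp[["x"]] * lx
  lr["age"] <- lr["age"] + raw_crp[["age"]]
  lr["female"] <- lr["female"] + raw_crp[["female"]]
  lr["black"] <- lr["black"] + raw_crp[["black"]]
  resid_crp2 <- p$log_crp_sd^2 - sum(lr^2 * v)
  if (resid_crp2 <= 0)
    msg_stop("medsupp_config_error",
             "crp_paths imply variance above log_crp_sd^2 (non-positive-definite model)")
  lr["e_crp"] <- sqrt(resid_crp2)

  # LTL
  yp <- p$ltl_paths
  raw_ltl <- c(x = yp[["x"]] * p$ltl_sd / sd_x,
               bmi = yp[["bmi"]] * p$ltl_sd / p$bmi_sd,
               crp = yp[["crp"]] * p$ltl_sd / p$log_crp_sd,
               age = yp[["age"]] * p$ltl_sd / sds[["age"]],
               female = yp[["female"]] * p$ltl_sd / sds[["female"]],
               black = yp[["black"]] * p$ltl_sd / sds[["black"]],
               active = yp[["active"]] * p$ltl_sd / sds[["active"]],
               alcohol = yp[["alcohol"]] * p$ltl_sd / sds[["alcohol"]])
  ly <- load()
  ly <- ly + raw_ltl[["x"]] * lx + raw_ltl[["bmi"]] * lb +
    raw_ltl[["crp"]] * lr
  for (s in c("age", "female", "black", "active", "alcohol"))
    ly[s] <- ly[s] + raw_ltl[[s]]
  resid_ltl2 <- p$ltl_sd^2 - sum(ly^2 * v)
  if (resid_ltl2 <= 0)
    msg_stop("medsupp_config_error",
             "ltl_paths imply variance above ltl_sd^2 (non-positive-definite model)")
  ly["e_ltl"] <- sqrt(resid_ltl2)

  list(v = v, m = m,
       loadings = rbind(x = lx, bmi = lb, crp = lr, ltl = ly),
       raw = list(bmi = raw_bmi, crp = raw_crp, ltl = raw_ltl),
       resid_sd = c(bmi = sqrt(resid_bmi2), crp = sqrt(resid_crp2),
                    ltl = sqrt(resid_ltl2)),
       sd_x = sd_x, mean_x = mean_x)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from the structural model described in
#' [synthetic_params()], in a fixed documented order from a single seeded
#' stream (age, sex, race, activity, alcohol, smoking, cotinine error, BMI
#' error, CRP error, LTL error).  Cotinine and CRP are exponentiated to
#' natural units and reported as censored (`"<LOD"` on disk, LOD columns in
#' memory) when below their detection limits.  Values are rounded to
#' laboratory-realistic precision (age and BMI 0.1, LTL 1 bp, biomarkers 4
#' significant digits).  BMI is winsorized to (10.1, 79.9) kg/m^2 and LTL
#' floored at 3,300 bp so every generated row satisfies the cohort validity
#' invariants; both tails are far (>2.8 SD) from the mean, so the distortion
#' of the linear structure is negligible (see the package vignette).
#'
#' @param params a [synthetic_params()] object.
#' @return a [cohort_table()] with provenance recording the seed.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  sm <- structural_model(params)
  n <- params$n
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  age <- round(stats::runif(n, params$age_range[1], params$age_range[2]), 1)
  female <- stats::rbinom(n, 1L, params$p_female)
  black <- stats::rbinom(n, 1L, params$p_black)
  pa <- sample(PA_LEVELS, n, replace = TRUE, prob = params$pa_probs)
  alcohol <- sample(ALCOHOL_LEVELS, n, replace = TRUE,
                    prob = params$alcohol_probs)
  smoker <- stats::rbinom(n, 1L, params$smoking_prevalence)

  log_cot <- params$log_cotinine_nonsmoker +
    params$log_cotinine_smoker_shift * smoker +
    params$x_paths_raw[["female"]] * female +
    params$x_paths_raw[["black"]] * black +
    stats::rnorm(n, 0, params$log_cotinine_sd)
  cotinine <- signif(exp(log_cot), 4)

  rb <- sm$raw$bmi
  bmi <- params$bmi_mean +
    rb[["x"]] * (log_cot - sm$mean_x) +
    rb[["age"]] * (age - sm$m[["age"]]) +
    rb[["female"]] * (female - sm$m[["female"]]) +
    rb[["black"]] * (black - sm$m[["black"]]) +
    stats::rnorm(n, 0, sm$resid_sd[["bmi"]])
  bmi <- round(pmin(pmax(bmi, 10.1), 79.9), 1)

  rc <- sm$raw$crp
  log_crp <- params$log_crp_mean +
    rc[["x"]] * (log_cot - sm$mean_x) +
    rc[["age"]] * (age - sm$m[["age"]]) +
    rc[["female"]] * (female - sm$m[["female"]]) +
    rc[["black"]] * (black - sm$m[["black"]]) +
    stats::rnorm(n, 0, sm$resid_sd[["crp"]])
  crp <- signif(exp(log_crp), 4)

  active <- as.numeric(pa %in% c("moderate", "vigorous"))
  alc_score <- match(alcohol, ALCOHOL_LEVELS) - 1
  ry <- sm$raw$ltl
  ltl <- params$ltl_mean +
    ry[["x"]] * (log_cot - sm$mean_x) +
    ry[["bmi"]] * (bmi - params$bmi_mean) +
    ry[["crp"]] * (log_crp - params$log_crp_mean) +
    ry[["age"]] * (age - sm$m[["age"]]) +
    ry[["female"]] * (female - sm$m[["female"]]) +
    ry[["black"]] * (black - sm$m[["black"]]) +
    ry[["active"]] * (active - sm$m[["active"]]) +
    ry[["alcohol"]] * (alc_score - sm$m[["alcohol"]]) +
    stats::rnorm(n, 0, sm$resid_sd[["ltl"]])
  ltl <- round(pmax(ltl, 3300))

  cot_below <- cotinine < params$cotinine_lod
  crp_below <- crp < params$crp_lod
  df <- data.frame(
    age = age,
    sex = ifelse(female == 1, "female", "male"),
    race = ifelse(black == 1, "black", "white"),
    physical_activity = pa,
    alcohol_use = alcohol,
    current_smoker = smoker == 1L,
    cotinine = ifelse(cot_below, NA_real_, cotinine),
    cotinine_lod = ifelse(cot_below, params$cotinine_lod, NA_real_),
    crp = ifelse(crp_below, NA_real_, crp),
    crp_lod = ifelse(crp_below, params$crp_lod, NA_real_),
    bmi = bmi,
    ltl_bp = ltl,
    ts_ratio = NA_real_,
    stringsAsFactors = FALSE
  )
  if (params$ltl_unit %in% c("ts", "both"))
    df$ts_ratio <- round(bp_to_ts(ltl), 6)
  if (params$ltl_unit == "ts") df$ltl_bp <- NA_real_
  cohort_table(df, provenance = sprintf("synthetic(seed=%d,n=%d)",
                                        params$seed, n))
}

# Population covariance matrix of the analysis-scale variables.
implied_covariance <- function(params) {
  sm <- structural_model(params)
  analysis_vars <- c("log_cotinine", "age", "female", "black", "active",
                     "alcohol", "bmi", "log_crp", "ltl_bp")
  L <- matrix(0, length(analysis_vars), length(SOURCE_NAMES),
              dimnames = list(analysis_vars, SOURCE_NAMES))
  L["log_cotinine", ] <- sm$loadings["x", ]
  L["bmi", ] <- sm$loadings["bmi", ]
  L["log_crp", ] <- sm$loadings["crp", ]
  L["ltl_bp", ] <- sm$loadings["ltl", ]
  for (s in c("age", "female", "black", "active", "alcohol"))
    L[s, s] <- 1
  sigma <- L %*% diag(sm$v) %*% t(L)
  dimnames(sigma) <- list(analysis_vars, analysis_vars)
  sigma
}

# Population standardized partial coefficient of each predictor in the
# least-squares projection of y_var on x_vars, from a covariance matrix.
pop_std_beta <- function(sigma, y_var, x_vars) {
  b <- solve(sigma[x_vars, x_vars, drop = FALSE],
             sigma[x_vars, y_var])
  sds <- sqrt(diag(sigma))
  stats::setNames(b * sds[x_vars] / sds[y_var], x_vars)
}

#' Analytic standardized paths implied by generator parameters
#'
#' Computes, from the population covariance matrix the structural equations
#' imply, the population standardized coefficients of every sub-model of
#' the third-variable analysis (covariates: age, female, black, active,
#' alcohol).  Returned values satisfy the decomposition identity
#' `c = c' + sum_k beta1_k beta2_k` exactly, and serve as the independent
#' oracle for fitted estimates.  The limit-of-detection censoring applied
#' by [generate_cohort()] is ignored here; with the default parameters its
#' effect on every standardized path is far below Monte-Carlo resolution
#' (see the vignette).
#'
#' @param params a [synthetic_params()] object.
#' @return list with `c` (total effect), `dual` (c_prime, beta1, beta2 per
#'   Z, indirect per Z, indirect_overall), `single` (per-Z one-intermediate
#'   models: c_prime, beta1, beta2, indirect), and `sigma` (the implied
#'   covariance matrix).
#' @export
implied_standardized_paths <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  sigma <- implied_covariance(params)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    msg_stop("medsupp_config_error",
             "implied covariance is not positive definite")
  covars <- c("age", "female", "black", "active", "alcohol")
  x <- "log_cotinine"; y <- "ltl_bp"
  zs <- c(bmi = "bmi", crp = "log_crp")

  c_total <- pop_std_beta(sigma, y, c(x, covars))[[x]]
  beta1 <- vapply(zs, function(z)
    pop_std_beta(sigma, z, c(x, covars))[[x]], numeric(1))
  dual_fit <- pop_std_beta(sigma, y, c(x, zs, covars))
  dual <- list(
    c_prime = dual_fit[[x]],
    beta1 = beta1,
    beta2 = stats::setNames(dual_fit[zs], names(zs)),
    indirect = stats::setNames(beta1 * dual_fit[zs], names(zs))
  )
  dual$indirect_overall <- sum(dual$indirect)
  single <- lapply(stats::setNames(names(zs), names(zs)), function(k) {
    z <- zs[[k]]
    fit <- pop_std_beta(sigma, y, c(x, z, covars))
    list(c_prime = fit[[x]], beta1 = beta1[[k]], beta2 = fit[[z]],
         indirect = beta1[[k]] * fit[[z]])
  })
  list(c = c_total, dual = dual, single = single, sigma = sigma)
}
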