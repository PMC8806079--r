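# thirdvar: decomposition arithmetic, delta-method test, classification,
# percentages, orchestration.

test_that("indirect effects reproduce the published worked examples", {
  # BMI path: beta1 x beta2, printed inputs
  expect_equal(round(indirect_effect(-0.079, -0.059), 4), 0.0047)
  # CRP path
  expect_equal(round(indirect_effect(0.109, -0.075), 4), -0.0082)
  expect_equal(indirect_effect(0, 123.4), 0)
})

test_that("sobel_test implements the first-order delta method", {
  res <- sobel_test(0.5, 0.1, 0.4, 0.1)
  expect_equal(res$se, 0.06403124, tolerance = 1e-7)
  expect_equal(res$z, 3.123475, tolerance = 1e-6)
  expect_equal(res$p, 2 * pnorm(-abs(res$z)))
  # zero path: z = 0, p = 1
  res0 <- sobel_test(0, 0.2, 0.7, 0.1)
  expect_equal(res0$z, 0)
  expect_equal(res0$p, 1)
  # symmetry in the two paths
  a <- sobel_test(0.3, 0.05, -0.2, 0.08)
  b <- sobel_test(-0.2, 0.08, 0.3, 0.05)
  expect_equal(a$z, b$z)
  # second-order variant adds se1^2 se2^2
  s2 <- sobel_test(0.5, 0.1, 0.4, 0.1, second_order = TRUE)
  expect_equal(s2$se, sqrt(0.0041 + 0.01^2), tolerance = 1e-10)
  expect_error_class(sobel_test(0.5, 0, 0.4, 0.1),
                     "medsupp_contract_error")
})

test_that("classification follows the |c| vs |c'| rule with tie-breaks", {
  # published single-intermediate results
  expect_equal(classify(-0.0486, -0.0533, 0.0047), "suppression")
  expect_equal(classify(-0.0486, -0.0404, -0.0082), "mediation")
  # rule restricted to |c| > |indirect|
  expect_equal(classify(0.001, 0.0, 0.01), "undefined")
  # deterministic tie-break at |c| == |c'|
  expect_equal(classify(-0.05, 0.05, -0.01), "mediation")
  expect_equal(classify(-0.05, 0.05, 0.01), "suppression")
})

test_that("effect percentages use the role-specific denominator", {
  expect_equal(round(effect_percent("suppression", 0.0047, -0.0486,
                                    -0.0533), 1), 8.8)
  expect_equal(round(effect_percent("mediation", -0.0082, -0.0486,
                                    -0.0404), 1), 16.9)
  expect_equal(effect_percent("mediation", 0, -0.05, -0.04), 0)
  expect_warning(out <- effect_percent("undefined", 0.01, 0.001, 0),
                 "undefined")
  expect_true(is.na(out))
  expect_error_class(effect_percent("mediation", 0.01, 0, -0.04),
                     "medsupp_domain_error")
})

test_that("decomposition identity holds on random cohorts", {
  set.seed(21)
  covariate_pool <- c("age", "race", "sex", "physical_activity",
                      "alcohol_use")
  for (rep in 1:12) {
    n <- sample(200:1500, 1)
    co <- small_synth(n = n, seed = sample.int(2^31 - 1, 1))
    zs <- if (rep %% 2 == 0) c("bmi", "crp") else sample(c("bmi", "crp"), 1)
    covs <- sample(covariate_pool, sample(1:5, 1))
    spec <- model_spec(third_variables = zs, covariates = covs)
    res <- run_third_variable_analysis(spec, co)
    gap <- res$paths$c$std_beta - res$paths$c_prime$std_beta -
      res$paths$indirect_overall
    expect_lt(abs(gap), 1e-10)
  }
})

test_that("classification and percentages are scale invariant", {
  co <- small_synth(n = 800, seed = 31)
  spec <- model_spec(third_variables = "bmi")
  r1 <- run_third_variable_analysis(spec, co)
  co2 <- co
  co2$ltl_bp <- co$ltl_bp * 7.3   # positive rescale of the outcome
  r2 <- run_third_variable_analysis(spec, co2)
  expect_identical(r1$roles, r2$roles)
  expect_equal(r1$effect_percent, r2$effect_percent, tolerance = 1e-8)
  expect_equal(r1$paths$c$std_beta, r2$paths$c$std_beta, tolerance = 1e-10)
})

test_that("null generator yields near-zero paths", {
  co <- generate_cohort(null_params(n = 10000, seed = 41))
  res <- run_third_variable_analysis(model_spec(), co)
  expect_lt(abs(res$paths$c$std_beta), 3 * res$paths$c$se)
  for (z in names(res$paths$per_z)) {
    pz <- res$paths$per_z[[z]]
    expect_lt(abs(pz$beta1$std_beta), 3 * pz$beta1$se)
    expect_lt(abs(pz$beta2$std_beta), 3 * pz$beta2$se)
  }
})

test_that("generator sign structure drives the expected roles", {
  # X->Z < 0, Z->Y < 0, X->Y < 0: indirect > 0 opposes c -> suppression
  p_sup <- synthetic_params(
    n = 6000, seed = 51,
    bmi_paths = c(x = -0.15, age = 0.05, female = 0.05, black = 0.08),
    ltl_paths = c(x = -0.08, bmi = -0.12, crp = 0, age = -0.386,
                  female = 0.062, black = 0.080, active = 0.040,
                  alcohol = 0.038))
  res_sup <- run_third_variable_analysis(
    model_spec(third_variables = "bmi"), generate_cohort(p_sup))
  expect_equal(res_sup$roles$bmi, "suppression")
  # X->Z > 0, Z->Y < 0, X->Y < 0: indirect < 0 aligns with c -> mediation
  p_med <- synthetic_params(
    n = 6000, seed = 52,
    crp_paths = c(x = 0.2, age = 0.15, female = 0.10, black = 0.05),
    ltl_paths = c(x = -0.08, bmi = 0, crp = -0.15, age = -0.386,
                  female = 0.062, black = 0.080, active = 0.040,
                  alcohol = 0.038))
  res_med <- run_third_variable_analysis(
    model_spec(third_variables = "crp"), generate_cohort(p_med))
  expect_equal(res_med$roles$log_crp, "mediation")
})

test_that("misuse raises typed errors", {
  co <- small_synth(n = 300)
  expect_error_class(
    run_third_variable_analysis(model_spec(third_variables = character(0)),
                                co),
    "medsupp_spec_error")
  # duplicate third variable columns -> collinearity
  design <- build_design(co, model_spec(third_variables = "bmi"))
  x_dup <- cbind(design$x, bmi2 = design$x[, "bmi"])
  expect_error_class(fit_ols(design$y, x_dup), "medsupp_collinearity_error")
})

test_that("step operations expose the modelled effects", {
  co <- small_synth(n = 1000, seed = 61)
  design <- build_design(co, model_spec())
  te <- total_effect(design)
  expect_true("log_cotinine" %in% te$term)
  expect_false(any(c("bmi", "log_crp") %in% te$term))
  pa1 <- path_a(design, 1)
  expect_false("log_crp" %in% pa1$term)   # other Z excluded from step 2
  om <- outcome_model(design)
  expect_true(all(c("bmi", "log_crp") %in% om$term))
  eff <- attr(om, "c_prime")
  expect_equal(eff$term, "log_cotinine")
})
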