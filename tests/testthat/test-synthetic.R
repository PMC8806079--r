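# synthetic_cohort: generator contracts and the analytic path oracle.

test_that("generation is deterministic and sized correctly", {
  p <- synthetic_params(n = 250, seed = 123)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_equal(nrow(c1), 250L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed differs
  c3 <- generate_cohort(synthetic_params(n = 250, seed = 124))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("generated cohorts pass validation for any seed", {
  for (seed in c(1, 77, 20240501)) {
    rep <- validate_cohort(generate_cohort(synthetic_params(n = 400,
                                                            seed = seed)))
    expect_true(all(rep$n_missing == 0L), label = paste("seed", seed))
    expect_true(all(rep$n_invalid == 0L), label = paste("seed", seed))
  }
})

test_that("cotinine and CRP are right-skewed in natural units", {
  co <- generate_cohort(synthetic_params(n = 10000, seed = 131))
  skew <- function(v) { v <- v[!is.na(v)]; mean((v - mean(v))^3) / sd(v)^3 }
  expect_gt(skew(co$cotinine), 1)
  expect_gt(skew(co$crp), 1)
  # non-smokers sit near the LOD, smokers are elevated
  med_ns <- median(co$cotinine[!co$current_smoker], na.rm = TRUE)
  med_s <- median(co$cotinine[co$current_smoker], na.rm = TRUE)
  expect_gt(med_s / med_ns, 50)
  # some non-smoker values are censored at the LOD
  expect_gt(sum(!is.na(co$cotinine_lod)), 0)
  expect_true(all(is.na(co$cotinine_lod) | !co$current_smoker |
                    co$cotinine_lod == 0.05))
})

test_that("T/S back-conversion round-trips through the calibration", {
  co <- generate_cohort(synthetic_params(n = 300, seed = 141,
                                         ltl_unit = "both"))
  expect_equal(ts_to_bp(bp_to_ts(co$ltl_bp)), co$ltl_bp, tolerance = 1e-9)
  expect_equal(co$ts_ratio, round(bp_to_ts(co$ltl_bp), 6))
})

test_that("zero-path parameters imply and produce null effects", {
  p <- null_params(n = 10000, seed = 151)
  imp <- implied_standardized_paths(p)
  expect_equal(imp$c, 0, tolerance = 1e-12)
  expect_equal(unname(imp$dual$beta1), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(imp$dual$beta2), c(0, 0), tolerance = 1e-12)
  expect_equal(imp$dual$c_prime, 0, tolerance = 1e-12)
})

test_that("implied paths satisfy the decomposition identity analytically", {
  set.seed(161)
  for (rep in 1:8) {
    p <- synthetic_params(
      n = 100, seed = 1,
      bmi_paths = c(x = runif(1, -0.2, 0.2), age = runif(1, -0.1, 0.1),
                    female = 0.05, black = 0.08),
      crp_paths = c(x = runif(1, -0.2, 0.2), age = 0.15, female = 0.10,
                    black = 0.05),
      ltl_paths = c(x = runif(1, -0.2, 0.2), bmi = runif(1, -0.2, 0.2),
                    crp = runif(1, -0.2, 0.2), age = -0.386,
                    female = 0.062, black = 0.080, active = 0.040,
                    alcohol = 0.038))
    imp <- implied_standardized_paths(p)
    expect_lt(abs(imp$c - imp$dual$c_prime - imp$dual$indirect_overall),
              1e-12)
    for (k in c("bmi", "crp"))
      expect_lt(abs(imp$c - imp$single[[k]]$c_prime -
                      imp$single[[k]]$indirect), 1e-12)
  }
})

test_that("default implied paths equal the requested standardized targets", {
  imp <- implied_standardized_paths(synthetic_params())
  expect_equal(unname(imp$dual$beta1), c(-0.079, 0.109), tolerance = 1e-10)
  expect_equal(unname(imp$dual$beta2), c(-0.036, -0.061), tolerance = 1e-10)
  expect_equal(imp$dual$c_prime, -0.0448, tolerance = 1e-10)
  expect_equal(imp$c, -0.0448 + (-0.079 * -0.036) + (0.109 * -0.061),
               tolerance = 1e-12)
  # qualitative pattern: BMI suppresses, CRP mediates
  expect_lt(imp$c, 0)
  expect_gt(abs(imp$single$bmi$c_prime), abs(imp$c))
  expect_lt(abs(imp$single$crp$c_prime), abs(imp$c))
})

test_that("invalid parameters raise config errors", {
  expect_error_class(synthetic_params(smoking_prevalence = 1.2),
                     "medsupp_config_error")
  expect_error_class(synthetic_params(log_cotinine_sd = -1),
                     "medsupp_config_error")
  expect_error_class(synthetic_params(pa_probs = c(none = 0.5,
                                                   moderate = 0.5,
                                                   vigorous = 0.5)),
                     "medsupp_config_error")
  # paths demanding more variance than the marginal SD allows
  expect_error_class(
    synthetic_params(bmi_paths = c(x = 0.9, age = 0.5, female = 0.05,
                                   black = 0.08)),
    "medsupp_config_error")
})

test_that("fitted paths at moderate n track the oracle", {
  p <- synthetic_params(n = 20000, seed = 171)
  imp <- implied_standardized_paths(p)
  res <- run_third_variable_analysis(model_spec(), generate_cohort(p))
  expect_lt(abs(res$paths$c$std_beta - imp$c), 3.5 * res$paths$c$se)
  expect_lt(abs(res$paths$c_prime$std_beta - imp$dual$c_prime),
            3.5 * res$paths$c_prime$se)
  pz <- res$paths$per_z
  expect_lt(abs(pz$bmi$beta1$std_beta - imp$dual$beta1[["bmi"]]),
            3.5 * pz$bmi$beta1$se)
  expect_lt(abs(pz$log_crp$beta2$std_beta - imp$dual$beta2[["crp"]]),
            3.5 * pz$log_crp$beta2$se)
})
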