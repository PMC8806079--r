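# Shared fixtures: tiny hand-built cohorts and convenience constructors.

# A minimal valid participant row; override fields as needed.
one_row <- function(...) {
  base <- list(age = 45, sex = "male", race = "white",
               physical_activity = "none", alcohol_use = "never",
               current_smoker = FALSE, cotinine = 1.5, crp = 0.4,
               bmi = 27.1, ltl_bp = 5700, ts_ratio = NA_real_,
               cotinine_lod = NA_real_, crp_lod = NA_real_)
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

tiny_cohort <- function(nrows = 3L) {
  rows <- lapply(seq_len(nrows), function(i)
    one_row(age = 30 + i * 5, cotinine = i, crp = 0.2 * i,
            bmi = 24 + i, ltl_bp = 6000 - 100 * i,
            sex = c("male", "female")[1 + i %% 2],
            race = c("white", "black")[1 + (i %/% 2) %% 2]))
  cohort_table(do.call(rbind, rows), provenance = "fixture")
}

# Default-structure synthetic cohort, small and fast.
small_synth <- function(n = 500, seed = 424242, ...) {
  generate_cohort(synthetic_params(n = n, seed = seed, ...))
}

default_spec <- function(...) model_spec(...)

# Null-structure params: every structural path zero.
null_params <- function(n, seed) {
  synthetic_params(
    n = n, seed = seed,
    bmi_paths = c(x = 0, age = 0, female = 0, black = 0),
    crp_paths = c(x = 0, age = 0, female = 0, black = 0),
    ltl_paths = c(x = 0, bmi = 0, crp = 0, age = 0, female = 0,
                  black = 0, active = 0, alcohol = 0))
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
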