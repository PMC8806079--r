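# regression: OLS core, standardized coefficients, ANCOVA means,
# chi-square.

test_that("fit_ols matches closed forms and the normal-equations oracle", {
  # identity fit
  x <- matrix(1:6, ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_ols(as.numeric(1:6), x)
  expect_equal(unname(fit$coefficients["x"]), 1, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 6), tolerance = 1e-12)
  # intercept-only
  y <- c(2, 4, 9, 1)
  fit0 <- fit_ols(y, matrix(numeric(0), nrow = 4, ncol = 0))
  expect_equal(unname(fit0$coefficients[1]), mean(y))
  # frozen 5-point normal-equations solution
  x5 <- matrix(1:5, ncol = 1, dimnames = list(NULL, "x"))
  y5 <- 2 * (1:5) + 1 + c(0.1, -0.2, 0.3, -0.1, 0)
  fit5 <- fit_ols(y5, x5)
  expect_equal(unname(fit5$coefficients), c(1.05, 1.99), tolerance = 1e-10)
})

test_that("fit_ols agrees with explicit normal equations on random designs", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(6:20, 1); k <- sample(1:3, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("v", 1:k)))
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    expect_equal(unname(fit$coefficients), as.numeric(beta),
                 tolerance = 1e-8)
    # classical SEs
    res <- y - Xi %*% beta
    s2 <- sum(res^2) / (n - k - 1)
    se <- sqrt(diag(s2 * solve(t(Xi) %*% Xi)))
    expect_equal(unname(fit$se), unname(se), tolerance = 1e-8)
  }
})

test_that("rank deficiency raises a collinearity error naming the column", {
  set.seed(12)
  x1 <- rnorm(20)
  X <- cbind(a = x1, b = rnorm(20), dup = x1)
  err <- tryCatch(fit_ols(rnorm(20), X), error = identity)
  expect_s3_class(err, "medsupp_collinearity_error")
  expect_match(conditionMessage(err), "dup|a")
})

test_that("standardized betas equal correlations and z-scored refits", {
  set.seed(13)
  n <- 150
  x <- rnorm(n, 10, 3)
  y <- 2 + 0.5 * x + rnorm(n)
  scaling <- data.frame(column = c("x", "y"),
                        mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)))
  fit <- fit_ols(y, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  std <- standardized_betas(fit, scaling, "y")
  # simple regression: std beta is the Pearson correlation
  expect_equal(std$std_beta, cor(x, y), tolerance = 1e-12)
  # pre-standardized data: std beta equals raw beta
  zx <- standardize(x)$values; zy <- standardize(y)$values
  fitz <- fit_ols(zy, matrix(zx, ncol = 1, dimnames = list(NULL, "x")))
  stdz <- standardized_betas(fitz,
                             data.frame(column = c("x", "y"),
                                        mean = c(0, 0), sd = c(1, 1)), "y")
  expect_equal(stdz$std_beta, unname(fitz$coefficients["x"]),
               tolerance = 1e-12)

  # multi-covariate: scaling formula == refit on fully z-scored variables
  k <- 4
  X <- matrix(rnorm(n * k, 5, 2), n, k,
              dimnames = list(NULL, paste0("v", 1:k)))
  y2 <- drop(X %*% c(0.3, -0.2, 0, 0.1)) + rnorm(n)
  sc <- data.frame(column = c(colnames(X), "y"),
                   mean = c(colMeans(X), mean(y2)),
                   sd = c(apply(X, 2, sd), sd(y2)))
  std1 <- standardized_betas(fit_ols(y2, X), sc, "y")
  Xz <- scale(X); yz <- drop(scale(y2))
  fit_z <- fit_ols(yz, Xz)
  expect_equal(std1$std_beta, unname(fit_z$coefficients[colnames(X)]),
               tolerance = 1e-10)
})

test_that("CI and p-value are coherent under the same t reference", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(15:60, 1)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- drop(X %*% c(0.4, 0, -0.1)) + rnorm(n)
    sc <- data.frame(column = c(colnames(X), "y"),
                     mean = c(colMeans(X), mean(y)),
                     sd = c(apply(X, 2, sd), sd(y)))
    std <- standardized_betas(fit_ols(y, X), sc, "y")
    excludes0 <- std$ci_low > 0 | std$ci_high < 0
    expect_equal(std$p < 0.05, excludes0)
    expect_true(all(std$ci_low <= std$std_beta & std$std_beta <= std$ci_high))
    expect_true(all(std$p >= 0 & std$p <= 1))
  }
})

test_that("adjusted means handle limit cases and recover group effects", {
  set.seed(15)
  n <- 400
  # adjuster unrelated to group and outcome: adjusted == raw means
  g <- rep(c("a", "b"), each = n / 2)
  adj <- rnorm(n)
  y <- ifelse(g == "a", 5, 7) + rnorm(n, 0, 1e-8)
  am <- adjusted_means(y, g, adj)
  expect_equal(unname(am$means), tapply(y, g, mean), tolerance = 1e-4,
               ignore_attr = TRUE)
  # two identical groups: zero difference, p = 1
  y2 <- rep(c(1, 2, 3, 4), times = 2)
  g2 <- rep(c("a", "b"), each = 4)
  am2 <- adjusted_means(y2, g2, rep(c(0, 1), times = 4))
  expect_equal(unname(diff(am2$means)), 0, tolerance = 1e-12)
  expect_equal(am2$p, 1, tolerance = 1e-10)
  expect_error_class(adjusted_means(y2, rep("a", 8), rnorm(8)),
                     "medsupp_contract_error")
  # built-in confounding: age-adjusted difference recovers the truth
  age <- runif(n, 20, 80)
  grp <- rbinom(n, 1, 0.5)
  yc <- 10 + 0.5 * age + 3 * grp + rnorm(n, 0, 2)
  amc <- adjusted_means(yc, ifelse(grp == 1, "g1", "g0"), age)
  expect_equal(unname(amc$means["g1"] - amc$means["g0"]), 3,
               tolerance = 0.5)
  # oracle: lm on the same model
  lm_fit <- lm(yc ~ factor(grp) + age)
  expect_equal(unname(amc$means["g1"] - amc$means["g0"]),
               unname(coef(lm_fit)[2]), tolerance = 1e-10)
})

test_that("chi-square matches the textbook formula and flags degeneracy", {
  # perfectly proportional table: statistic 0, p 1
  prop <- matrix(c(10, 20, 30, 60), 2)
  res <- chi_square_test(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # smoker-by-sex counts (White adults): frozen textbook value
  tab <- matrix(c(416, 1630 - 416, 364, 1484 - 364), nrow = 2, byrow = TRUE)
  res2 <- chi_square_test(tab)
  expect_equal(res2$statistic, 0.408124, tolerance = 1e-5)
  expect_equal(res2$df, 1L)
  # independent oracle: stats::chisq.test without continuity correction
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res2$p, unname(ref$p.value), tolerance = 1e-10)
  expect_error_class(chi_square_test(matrix(c(0, 0, 5, 3), 2, byrow = TRUE)),
                     "medsupp_degenerate_table_error")
})

test_that("descriptive_table summarises by race-sex with test p-values", {
  co <- small_synth(n = 1200)
  tab <- descriptive_table(co)
  expect_setequal(names(tab)[-1],
                  c("white:male", "white:female", "black:male",
                    "black:female"))
  expect_true("age" %in% tab$variable)
  p_race <- attr(tab, "p_race")
  expect_true(all(unlist(p_race) >= 0 & unlist(p_race) <= 1))
})
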