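test_that("closed-form 2x2 odds ratios reproduce the printed quartile effects", {
  q4 <- odds_ratio_2x2(329, 959, 97, 1177)
  expect_equal(round(q4$odds_ratio, 2), 4.16)
  expect_equal(round(q4$ci_low, 2), 3.27)
  expect_equal(round(q4$ci_high, 2), 5.30)

  q3 <- odds_ratio_2x2(174, 1176, 97, 1177)
  expect_equal(round(c(q3$odds_ratio, q3$ci_low, q3$ci_high), 2),
               c(1.80, 1.38, 2.33))

  q2 <- odds_ratio_2x2(111, 1127, 97, 1177)
  expect_equal(round(c(q2$odds_ratio, q2$ci_low, q2$ci_high), 2),
               c(1.20, 0.90, 1.59))

  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$odds_ratio, 1)
  expect_error(odds_ratio_2x2(0, 5, 5, 5), "zero-cell")
})

test_that("proportion_ci matches the printed pooled mortality and bounds", {
  p <- proportion_ci(711, 5150)
  expect_equal(round(100 * p$proportion, 1), 13.8)
  expect_equal(round(100 * p$ci_low, 2), 12.86)
  expect_equal(round(100 * p$ci_high, 2), 14.75)

  z <- proportion_ci(0, 100)
  expect_equal(z$proportion, 0)
  expect_equal(z$ci_low, 0)

  h <- proportion_ci(50, 100)
  expect_equal(round(c(h$ci_low, h$ci_high), 3), c(0.402, 0.598))
  expect_error(proportion_ci(0, 0), "undefined-proportion")
})

test_that("logistic fit on a saturated 2x2 equals the closed form", {
  dat <- expand_2x2(329, 959, 97, 1177)
  fit <- fit_logistic(as_cohort(
    data.frame(lactate = dat$exposed + 1, mortality_28d = dat$death,
               exposed = dat$exposed)), terms = "exposed")
  or_glm <- exp(fit$coefficients[["exposed"]])
  or_cf <- odds_ratio_2x2(329, 959, 97, 1177)$odds_ratio
  expect_equal(or_glm, or_cf, tolerance = 1e-6)
  e <- effect_table(fit, "exposed")
  expect_equal(round(c(e$odds_ratio, e$ci_low, e$ci_high), 2),
               c(4.16, 3.27, 5.30))
})

test_that("effect_table applies the Wald transform and its monotonicity", {
  fake <- list(coefficients = c("(Intercept)" = -1, x = 0),
               covariance = diag(c(0.1, 1)))
  dimnames(fake$covariance) <- list(c("(Intercept)", "x"),
                                    c("(Intercept)", "x"))
  e <- effect_table(fake, "x")
  expect_equal(e$odds_ratio, 1)
  expect_equal(round(e$ci_low, 3), 0.141)
  expect_equal(round(e$ci_high, 2), 7.10)
  expect_equal(e$p_value, 1)

  # CI endpoints monotone in SE for fixed beta
  ses <- c(0.1, 0.5, 1, 2)
  lows <- highs <- numeric(length(ses))
  for (i in seq_along(ses)) {
    fk <- list(coefficients = c(x = 0.3), covariance = matrix(ses[i]^2, 1, 1,
               dimnames = list("x", "x")))
    ei <- effect_table(fk, "x")
    lows[i] <- ei$ci_low; highs[i] <- ei$ci_high
  }
  expect_true(all(diff(lows) < 0) && all(diff(highs) > 0))

  expect_error(effect_table(fake, "absent"), "lookup error")
})

test_that("null exposure gives an OR whose CI covers 1", {
  set.seed(42)
  n <- 10000
  x <- rlnorm(n, 0.7, 0.5)
  y <- rbinom(n, 1, 0.14)          # outcome independent of exposure
  tab <- as_cohort(data.frame(lactate = x, mortality_28d = y))
  e <- effect_table(fit_logistic(tab, terms = "lactate"), "lactate")
  expect_true(e$ci_low <= 1 && 1 <= e$ci_high)
})

test_that("degenerate and ill-posed designs raise explicit errors", {
  tab <- as_cohort(data.frame(lactate = runif(20, 1, 5), mortality_28d = 0))
  expect_error(fit_logistic(tab, terms = "lactate"), "degenerate-outcome")

  # perfect separation
  sep <- as_cohort(data.frame(lactate = c(1:10, 11:20),
                              mortality_28d = rep(c(0, 1), each = 10)))
  expect_error(fit_logistic(sep, terms = "lactate"), "separation")

  # aliased column
  df <- data.frame(lactate = runif(50, 1, 5),
                   mortality_28d = rbinom(50, 1, 0.4))
  df$dup <- df$lactate
  expect_error(fit_logistic(as_cohort(df), terms = c("lactate", "dup")),
               "collinearity")
})

test_that("adding a covariate never decreases the maximized log-likelihood", {
  g <- gen_clean(n = 1500, seed = 8)
  base <- fit_logistic(g, terms = "lactate")
  ll <- base$log_likelihood
  for (v in c("age", "sofa", "apache_iv")) {
    bigger <- fit_logistic(g, terms = c("lactate", v))
    expect_gte(bigger$log_likelihood, ll - 1e-8)
    ll <- bigger$log_likelihood
  }
})

test_that("model specs carry the documented adjustment sets", {
  expect_equal(model_spec(model = "model_I")$covariates, c("age", "gender"))
  expect_true(all(c("age", "gender", "sofa", "apache_iv", "unit_type") %in%
                    model_spec(model = "model_II")$covariates))
  expect_equal(length(model_ii_covariates()), 19)
})
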