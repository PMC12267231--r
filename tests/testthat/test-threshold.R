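test_that("hinge design is continuous at the knot", {
  expect_equal(unname(hinge_design(2.0, 3.7)[1, ]), c(2.0, 0))
  expect_equal(unname(hinge_design(5.0, 3.7)[1, ]), c(3.7, 1.3))
  expect_equal(unname(hinge_design(3.7, 3.7)[1, ]), c(3.7, 0))
  # the two terms always reassemble the exposure
  x <- c(0.3, 1, 3.69, 3.7, 3.71, 12)
  H <- hinge_design(x, 3.7)
  expect_equal(H[, "below"] + H[, "above"], x)
})

test_that("piecewise model with equal slopes collapses onto the one-line fit", {
  g <- gen_clean(n = 4000, seed = 21, or_below_true = 1.2,
                 or_above_true = 1.2)
  d <- lacthresh:::threshold_data(g, character(0))

  # constrained equality: slope on min(x,K)+max(x-K,0) IS the linear model
  for (K in c(1.8, 3.7, 5.2)) {
    H <- hinge_design(d$x, K)
    Xc <- cbind("(Intercept)" = 1, lactate = H[, "below"] + H[, "above"])
    Xl <- cbind("(Intercept)" = 1, lactate = d$x)
    llc <- lacthresh:::glmfit_matrix(d$y, Xc)$log_likelihood
    lll <- lacthresh:::glmfit_matrix(d$y, Xl)$log_likelihood
    expect_equal(llc, lll, tolerance = 1e-8)
  }

  # unconstrained piecewise at the true (irrelevant) knot gains only noise
  pw <- fit_piecewise_at(g, 3.7)
  lin <- fit_logistic(g, terms = "lactate")
  expect_gte(pw$log_likelihood, lin$log_likelihood - 1e-8)
  expect_lt(pw$log_likelihood - lin$log_likelihood, 0.5)
  # segment slopes agree within their joint confidence region
  e <- effect_table(pw, c("lactate_below", "lactate_above"))
  expect_true(e$ci_low[1] <= e$odds_ratio[2] & e$odds_ratio[2] <= e$ci_high[1])
})

test_that("infeasible knots raise contract errors", {
  g <- gen_clean(n = 500, seed = 4)
  expect_error(fit_piecewise_at(g, min(g$lactate) - 0.5),
               "degeneracy|collinearity")
  expect_error(fit_piecewise_at(g, max(g$lactate) + 0.5),
               "degeneracy|collinearity")
})

test_that("grid search equals an independent brute-force refit loop", {
  for (s in 1:10) {
    g <- gen_clean(n = 900, seed = 100 + s)
    grid <- search_grid(g$lactate, range = c(0.1, 0.9), step = 0.2)
    pw <- find_turning_point(g, grid)

    # oracle: refit every candidate through the public single-K operation
    ll <- vapply(grid$candidates, function(K)
      tryCatch(fit_piecewise_at(g, K)$log_likelihood,
               error = function(e) NA_real_), numeric(1))
    K_oracle <- grid$candidates[which.max(ll)]
    expect_identical(pw$K, K_oracle)
    expect_equal(pw$loglik_piecewise, max(ll, na.rm = TRUE))

    # argmax property over the recorded profile
    expect_true(all(pw$profile$loglik <= pw$loglik_piecewise + 1e-10,
                    na.rm = TRUE))

    # fitted logit is continuous at the selected knot
    co <- pw$piecewise_fit$coefficients
    eta <- function(x) co[1] + co["lactate_below"] * pmin(x, pw$K) +
      co["lactate_above"] * pmax(x - pw$K, 0)
    expect_equal(eta(pw$K - 1e-9), eta(pw$K + 1e-9), tolerance = 1e-7)
  }
})

test_that("a single feasible candidate is returned as the turning point", {
  g <- gen_clean(n = 800, seed = 31)
  grid <- structure(list(candidates = 2.1, range = c(2, 2.2), step = 0.1),
                    class = "search_grid")
  pw <- find_turning_point(g, grid)
  expect_equal(pw$K, 2.1)
})

test_that("likelihood-ratio test follows the chi-square df 1 reference", {
  same <- list(log_likelihood = -100)
  l0 <- lrt_linear_vs_piecewise(same, same)
  expect_equal(l0$statistic, 0)
  expect_equal(l0$p_value, 1)

  l1 <- lrt_linear_vs_piecewise(list(log_likelihood = -101.92),
                                list(log_likelihood = -100))
  expect_equal(l1$statistic, 3.84)
  expect_equal(l1$p_value, 0.050, tolerance = 1e-3)

  expect_error(lrt_linear_vs_piecewise(list(log_likelihood = -99),
                                       list(log_likelihood = -100)),
               "nesting violation")
})

test_that("piecewise truth is detected by the LRT in most replicates", {
  hits <- 0L
  for (s in 1:20) {
    g <- gen_clean(n = 5150, seed = 400 + s)
    pw <- find_turning_point(g)
    hits <- hits + (pw$lrt_p < 0.05)
  }
  expect_gte(hits, 11L)  # majority of replicates
})

test_that("bootstrap turning-point CI is reproducible and covers a strong knot", {
  g <- gen_clean(n = 6000, seed = 75, or_below_true = 1.7,
                 or_above_true = 1.03)
  grid <- search_grid(g$lactate, range = c(0.05, 0.95), step = 0.1)
  b1 <- bootstrap_turning_point(g, grid, B = 60, seed = 5)
  b2 <- bootstrap_turning_point(g, grid, B = 60, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci["low"] <= 3.7 && 3.7 <= b1$ci["high"])
  expect_lte(b1$n_failed, 12)

  # degenerate one-candidate grid: CI collapses onto the candidate
  dg <- structure(list(candidates = 2.5, range = c(2.4, 2.6), step = 0.1),
                  class = "search_grid")
  bd <- bootstrap_turning_point(g, dg, B = 5, seed = 2)
  expect_equal(unname(bd$ci), c(2.5, 2.5))

  expect_error(bootstrap_turning_point(g, grid, B = 10), "seed")
})

test_that("threshold_table mirrors the report layout", {
  g <- gen_clean(n = 2500, seed = 12)
  pw <- find_turning_point(g)
  tt <- threshold_table(pw)
  expect_equal(nrow(tt), 5)
  expect_equal(tt$model[2], "Turning point (K)")
  expect_match(tt$or_ci[1], "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}, \\d+\\.\\d{2}\\)$")
})
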