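test_that("a 1-df smooth is exactly the linear logistic fit", {
  g <- gen_clean(n = 3000, seed = 51)
  cv <- fit_smooth(g, covariates = c("age", "sofa"), spline_df = 1)
  fit <- fit_logistic(g, terms = c("lactate", "age", "sofa"))
  beta <- fit$coefficients[["lactate"]]
  slopes <- diff(cv$effect) / diff(cv$x)
  expect_equal(slopes, rep(beta, length(slopes)), tolerance = 1e-6)
})

test_that("smooth of a linear mechanism stays inside its band around the line", {
  g <- gen_clean(n = 6000, seed = 52, or_below_true = 1.27,
                 or_above_true = 1.27)
  sm <- fit_smooth(g, spline_df = 4)
  lin <- fit_smooth(g, spline_df = 1)
  half <- (sm$band_high - sm$band_low) / 2
  expect_lt(max(abs(sm$effect - lin$effect)), max(half))
  expect_true(mean(abs(sm$effect - lin$effect) < half) > 0.9)
})

test_that("no-signal outcome yields a flat smooth inside its band", {
  g <- gen_clean(n = 6000, seed = 53, or_below_true = 1,
                 or_above_true = 1)
  sm <- fit_smooth(g, spline_df = 4)
  half <- (sm$band_high - sm$band_low) / 2
  expect_true(all(abs(sm$effect) < pmax(half, 1e-6)))
})

test_that("piecewise truth bends the smooth: steeper below than above", {
  g <- gen_clean(n = 20000, seed = 54)
  sm <- fit_smooth(g, spline_df = 4)
  slope_in <- function(a, b) {
    i <- sm$x >= a & sm$x <= b
    coef(lm(sm$effect[i] ~ sm$x[i]))[2]
  }
  expect_gt(slope_in(1, 3), slope_in(5, 8))
})

test_that("spline flexibility never decreases the log-likelihood", {
  g <- gen_clean(n = 4000, seed = 55)
  ll <- vapply(c(1, 2, 4, 8), function(df)
    attr(fit_smooth(g, spline_df = df), "log_likelihood"), numeric(1))
  expect_true(all(diff(ll) > -1e-6))
})

test_that("pointwise band shrinks with sample size", {
  g1 <- gen_clean(n = 2000, seed = 56)
  g4 <- gen_clean(n = 8000, seed = 56)
  s1 <- fit_smooth(g1, spline_df = 4)
  s4 <- fit_smooth(g4, spline_df = 4)
  w1 <- s1$band_high - s1$band_low
  w4 <- approx(s4$x, s4$band_high - s4$band_low, xout = s1$x, rule = 2)$y
  expect_true(mean(w4 < w1) > 0.9)
})

test_that("stratified curves separate when the high stratum carries extra risk", {
  g <- gen_clean(n = 12000, seed = 57,
                 stratum_modifiers = list(stratifier = "sofa", cut = 5,
                                          intercept_shift = log(3)))
  curves <- stratified_smooth(g, "sofa", cut = 5, spline_df = 4)
  lo <- curves[["sofa <= 5"]]; hi <- curves[["sofa > 5"]]
  shared <- intersect(round(lo$x, 9), round(hi$x, 9))
  expect_gt(length(shared), 100)
  i_lo <- match(shared, round(lo$x, 9)); i_hi <- match(shared, round(hi$x, 9))
  expect_true(all(hi$effect[i_hi] > lo$effect[i_lo]))
})

test_that("a random split without effect modification keeps curves inside bands", {
  g <- gen_clean(n = 12000, seed = 58)
  set.seed(1)
  g$coin <- rbinom(nrow(g), 1, 0.5)
  curves <- stratified_smooth(g, "coin", cut = 0, spline_df = 4)
  a <- curves[[1]]; b <- curves[[2]]
  shared <- intersect(round(a$x, 9), round(b$x, 9))
  ia <- match(shared, round(a$x, 9)); ib <- match(shared, round(b$x, 9))
  inside <- b$effect[ib] >= a$band_low[ia] & b$effect[ib] <= a$band_high[ia]
  expect_gte(mean(inside), 0.9)
})

test_that("a single-stratum rule reproduces the pooled smooth", {
  g <- gen_clean(n = 3000, seed = 59)
  pooled <- fit_smooth(g, spline_df = 4, scale = "partial")
  one <- stratified_smooth(g, "sofa", cut = NULL, spline_df = 4,
                           scale = "partial")
  expect_equal(length(one), 1)
  expect_equal(one[[1]]$effect, pooled$effect, tolerance = 1e-10)
})
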