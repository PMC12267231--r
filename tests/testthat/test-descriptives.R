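test_that("chi-squared test matches direct evaluation and printed results", {
  hom <- chi_squared_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p_value, 1)

  # direct sum((O-E)^2/E) with E = 15 in every cell gives 20/3
  t1 <- chi_squared_test(matrix(c(20, 10, 10, 20), 2))
  expect_equal(t1$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(t1$df, 1)

  mort <- rbind(deaths = quartile_deaths, survivors = quartile_survivors)
  expect_lt(chi_squared_test(mort)$p_value, 0.001)

  # invariance to row/column permutation
  p1 <- chi_squared_test(mort)$statistic
  p2 <- chi_squared_test(mort[2:1, c(3, 1, 4, 2)])$statistic
  expect_equal(p1, p2)

  expect_error(chi_squared_test(matrix(c(0, 0, 5, 5), 2)),
               "degenerate-table")
})

make_groups_tab <- function(x, g, style = "mean_sd") {
  sch <- cohort_schema(
    name = c("lactate", "mortality_28d", "v"),
    role = c("exposure", "outcome", "covariate"),
    kind = c("continuous", "binary", "continuous"),
    summary_style = c("median_iqr", "count_pct", style))
  tab <- as_cohort(data.frame(lactate = seq_along(x),
                              mortality_28d = rep_len(c(0, 1), length(x)),
                              v = x), sch)
  list(tab = tab, g = g)
}

test_that("baseline table reproduces printed mortality cells and group tests", {
  # expand the printed 2x4 mortality table to rows
  g <- factor(rep(rep(paste0("Q", 1:4), 2),
                  times = c(quartile_deaths, quartile_survivors)))
  y <- rep(c(1, 0), times = c(sum(quartile_deaths), sum(quartile_survivors)))
  sch <- cohort_schema(c("lactate", "mortality_28d"),
                       c("exposure", "outcome"),
                       c("continuous", "binary"),
                       summary_style = c("median_iqr", "count_pct"))
  tab <- as_cohort(data.frame(lactate = seq_along(y) + 0.5,
                              mortality_28d = y), sch)
  bt <- baseline_table(tab, g)
  dead <- bt[bt$variable == "mortality_28d" & bt$level == "1", ]
  expect_equal(unname(unlist(dead[paste0("Q", 1:4)])),
               sprintf("%d (%s)", quartile_deaths,
                       c("7.61", "8.97", "12.89", "25.54")))
  expect_lt(bt$p_value[bt$variable == "mortality_28d" & bt$level == "0"], 0.001)
  expect_equal(bt$p_display[bt$variable == "mortality_28d" & bt$level == "0"],
               "< 0.001")

  # identical group proportions: chi-squared p = 1
  g2 <- factor(rep(paste0("Q", 1:4), each = 100))
  y2 <- rep(rep(c(1, 0), times = c(10, 90)), 4)
  tab2 <- as_cohort(data.frame(lactate = seq_along(y2) + 0.5,
                               mortality_28d = y2), sch)
  bt2 <- baseline_table(tab2, g2)
  expect_equal(bt2$p_value[1], 1)
})

test_that("Kruskal-Wallis and ANOVA group tests match their closed forms", {
  mk <- make_groups_tab(c(1, 2, 3, 4, 5, 6),
                        factor(rep(c("a", "b"), each = 3)), "median_iqr")
  bt <- baseline_table(mk$tab, mk$g)
  v <- bt[bt$variable == "v", ]
  expect_equal(v$test, "kruskal_wallis")
  # no-ties H = 12/(n(n+1)) sum R_i^2/n_i - 3(n+1) = 3.857143 on df 1
  H <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(v$p_value, pchisq(H, 1, lower.tail = FALSE), tolerance = 1e-6)

  # two-group ANOVA p equals the pooled-variance two-sample t-test p
  set.seed(5)
  x <- rnorm(40); g <- factor(rep(c("a", "b"), 20))
  mk2 <- make_groups_tab(x, g, "mean_sd")
  bt2 <- baseline_table(mk2$tab, mk2$g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(bt2$p_value[bt2$variable == "v"], tt$p.value,
               tolerance = 1e-10)

  # constant continuous variable: ANOVA undefined -> NA, not an error
  mk3 <- make_groups_tab(rep(1, 6), factor(rep(c("a", "b"), each = 3)))
  bt3 <- baseline_table(mk3$tab, mk3$g)
  expect_true(is.na(bt3$p_value[bt3$variable == "v"]))
})

test_that("p-value display styles apply the stated floors", {
  expect_equal(format_p(c(0.5, 0.0005), "table1"), c("0.500", "< 0.001"))
  expect_equal(format_p(c(0.2193, 5e-5)), c("0.2193", "< 0.0001"))
  expect_equal(format_p(NA_real_), "-")
})
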