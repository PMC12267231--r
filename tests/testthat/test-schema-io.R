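test_that("read_cohort types, validates and marks missing cells", {
  df <- toy_rows(5)
  expect_s3_class(read_cohort(write_toy_csv(df)), "cohort")
  expect_equal(nrow(read_cohort(write_toy_csv(df))), 5)

  bad <- df; bad$mortality_28d[2] <- 2
  expect_error(read_cohort(write_toy_csv(bad)), "outside \\{0, 1\\}")

  na_lac <- df; na_lac$lactate <- as.character(na_lac$lactate)
  na_lac$lactate[3] <- "NA"
  tab <- read_cohort(write_toy_csv(na_lac))
  expect_equal(nrow(tab), 5)           # row retained
  expect_true(is.na(tab$lactate[3]))

  dropped <- df; dropped$sofa <- NULL
  expect_error(read_cohort(write_toy_csv(dropped)), "schema error")

  # lower-case and NaN markers also become missing
  m2 <- df; m2$hr <- as.character(m2$hr); m2$hr[1] <- "nan"; m2$hr[2] <- ""
  tab2 <- read_cohort(write_toy_csv(m2))
  expect_true(all(is.na(tab2$hr[1:2])))
})

test_that("schema invariants are enforced", {
  expect_error(cohort_schema("x", "covariate", "continuous"),
               "exactly one variable must have role 'exposure'")
  expect_error(
    cohort_schema(c("x", "y"), c("exposure", "outcome"),
                  c("continuous", "continuous")),
    "outcome must be binary")
  expect_silent(validate_schema(default_schema()))
})

test_that("exclusions are applied sequentially with flow-chart accounting", {
  df <- toy_rows(10)
  df$age <- c(60, 64, rep(80, 8))                 # 2 under-65
  df$icu_los_hours <- c(72, 72, 10, rep(72, 7))   # 1 short stay
  df$sepsis_flag <- c(1, 1, 1, 0, rep(1, 6))      # 1 non-sepsis
  df$lactate_n_measurements <- c(2, 2, 2, 2, 0, rep(2, 5))  # 1 no lactate
  tab <- as_cohort(df)
  res <- apply_exclusions(tab)
  expect_equal(res$n_after, 5)
  expect_equal(unname(res$removed),
               c(2, 1, 1, 1))
  expect_equal(sum(res$removed) + res$n_after, res$n_before)

  # idempotence and identity cases
  res2 <- apply_exclusions(res$cohort)
  expect_equal(as.data.frame(res2$cohort), as.data.frame(res$cohort))
  expect_equal(unname(res2$removed), c(0, 0, 0, 0))

  lax <- exclusion_criteria(min_age = 0, min_icu_hours = 0,
                            require_sepsis_flag = FALSE,
                            min_exposure_measurements = 0)
  res3 <- apply_exclusions(tab, lax)
  expect_equal(res3$n_after, 10)

  df$age <- NULL
  expect_error(apply_exclusions(as_cohort(df)), "schema error")
})

test_that("a row failing several criteria is counted at the first", {
  df <- toy_rows(3)
  df$age[1] <- 50; df$icu_los_hours[1] <- 5   # fails two criteria
  res <- apply_exclusions(as_cohort(df))
  expect_equal(unname(res$removed), c(1, 0, 0, 0))
})

test_that("median imputation fills by median/mode and is conservative", {
  df <- toy_rows(4)
  df$hr <- c(1, 2, NA, 4)
  df$gender <- c(0, 0, 1, NA)
  tab <- impute_median(as_cohort(df))
  expect_equal(tab$hr[3], 2)        # median of {1,2,4}
  expect_equal(tab$gender[4], 0)    # mode of {0,0,1}
  expect_equal(nrow(tab), 4)
  expect_equal(attr(tab, "imputed_counts"), c(gender = 1L, hr = 1L))

  # untouched column identical; no covariate missing afterwards
  expect_identical(tab$sofa, df$sofa)
  covs <- intersect(covariate_vars(default_schema()), names(tab))
  expect_equal(sum(is.na(as.data.frame(tab)[, covs])), 0)

  df$rdw <- NA_real_
  expect_error(impute_median(as_cohort(df)), "unimputable error.*rdw")
})

test_that("quartile_bin partitions at empirical quartiles", {
  qb <- quartile_bin(1:100)
  expect_equal(unname(table(qb$bin)), rep(25L, 4), ignore_attr = TRUE)

  qb2 <- quartile_bin(rep(1:4, each = 25))
  expect_equal(unname(c(qb2$group_n)), rep(25L, 4))

  expect_error(quartile_bin(rep(2, 50)), "degenerate-binning")
  expect_error(quartile_bin(rep(c(1, 2), 50)), "degenerate-binning")

  # tie-free partition: group sizes sum to n and differ by at most 1
  set.seed(11)
  x <- rlnorm(1003)
  qb3 <- quartile_bin(x)
  expect_equal(sum(qb3$group_n), 1003)
  expect_lte(diff(range(qb3$group_n)), 1)
})

test_that("generated cohort reproduces the reference lactate quartiles", {
  g <- gen_clean(seed = 3)
  qb <- quartile_bin(g)
  # oracle: direct percentile of the generated sample
  expect_equal(unname(qb$cutpoints),
               unname(quantile(g$lactate, c(.25, .5, .75))))
  expect_lt(max(abs(qb$cutpoints - c(1.5, 2.10, 3.27))), 0.2)
})
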