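# Shared fixtures: all built in code at test time.

# Covariate specs with every outcome effect switched off (clean truth for
# estimator-correctness experiments).
clean_specs <- function() {
  specs <- lacthresh:::default_covariate_specs()
  for (nm in names(specs)) specs[[nm]]$effect <- 0
  specs
}

# Generator shortcut: clean truth, no missingness unless asked for.
gen_clean <- function(n = 5150, seed = 1, ...) {
  generate_cohort(synthetic_config(
    n = n, seed = seed, covariate_specs = clean_specs(),
    missingness = c(gender = 0), ...))
}

# Printed 2x4 quartile mortality table: deaths then survivors per quartile.
quartile_deaths <- c(97, 111, 174, 329)
quartile_survivors <- c(1177, 1127, 1176, 959)

# Minimal hand-built cohort data frame satisfying the default schema's
# non-admin columns, for IO tests.
toy_rows <- function(n = 5) {
  set.seed(99)
  data.frame(
    lactate = round(runif(n, 0.8, 8), 2),
    mortality_28d = rep_len(c(0, 1), n),
    age = round(runif(n, 66, 90)),
    gender = rep_len(c(0, 1), n),
    copd = 0, chf = 0, ami = 0, dm = 0,
    hr = 100, temperature = 36.5, hemoglobin = 10, potassium = 4,
    rbc = 3.5, sodium = 139, wbc = 12, bicarbonate = 22, rdw = 16,
    bun = 30, apache_iv = 80, sofa = 4,
    unit_type = "Medical surgical ICU", icu_los_days = 3,
    icu_los_hours = 72, sepsis_flag = 1, lactate_n_measurements = 2,
    death_hours = NA_real_)
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  path
}
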