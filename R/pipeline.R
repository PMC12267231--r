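#' Run configuration for the full analysis pipeline
#'
#' Exactly one of \code{input} (a cohort CSV path) or \code{simulate} (a
#' [synthetic_config()]) must be given. A seed is required whenever any
#' stochastic step is enabled (simulation or a bootstrap with
#' \code{B > 0}).
#'
#' @param input path to a cohort CSV, or NULL.
#' @param simulate a [synthetic_config()], or NULL.
#' @param schema variable schema (default [default_schema()]).
#' @param covariates adjustment covariate list for the fully adjusted
#'   models (default [model_ii_covariates()]).
#' @param grid_range,grid_step turning-point search range (percentiles) and
#'   step (mmol/L).
#' @param B bootstrap replicates for the turning-point CI (0 disables).
#' @param seed integer seed for stochastic steps.
#' @param spline_df degrees of freedom of the dose-response smooth.
#' @param sofa_cut SOFA stratification cutpoint (low: <= cut).
#' @param subgroups stratifier list for the subgroup analysis.
#' @param outdir output directory for the report bundle.
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       schema = default_schema(),
                       covariates = model_ii_covariates(),
                       grid_range = c(0.05, 0.95), grid_step = 0.1,
                       B = 200, seed = NULL, spline_df = 4, sofa_cut = 5,
                       subgroups = c("hr", "temperature", "potassium", "wbc",
                                     "bicarbonate", "rdw", "bun", "apache_iv",
                                     "sofa"),
                       outdir = tempfile("lacthresh_run_")) {
  if (is.null(input) == is.null(simulate))
    stop("config error: exactly one of 'input' and 'simulate' must be given")
  stochastic <- !is.null(simulate) || B > 0
  if (stochastic && is.null(seed))
    stop("config error: a seed is required for stochastic steps")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "synthetic_config"))
  validate_schema(schema)
  structure(list(input = input, simulate = simulate, schema = schema,
                 covariates = covariates, grid_range = grid_range,
                 grid_step = grid_step, B = B, seed = seed,
                 spline_df = spline_df, sofa_cut = sofa_cut,
                 subgroups = subgroups, outdir = outdir),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

fmt_or_ci <- function(e)
  sprintf("%s (%s, %s)", fmt_num(e$odds_ratio), fmt_num(e$ci_low),
          fmt_num(e$ci_high))

univariate_effects <- function(tab, schema) {
  xv <- exposure_var(schema)
  rows <- list()
  push <- function(term, e) rows[[length(rows) + 1L]] <<- data.frame(
    term = term, or_ci = fmt_or_ci(e), p = format_p(e$p_value),
    odds_ratio = e$odds_ratio, ci_low = e$ci_low, ci_high = e$ci_high,
    p_value = e$p_value, stringsAsFactors = FALSE)
  push(xv, effect_table(fit_logistic(tab, model_spec("continuous", "crude")),
                        xv))
  qfit <- fit_logistic(tab, model_spec("quartiles", "crude"))
  for (tm in grep("^lactate_quartile", names(qfit$coefficients), value = TRUE))
    push(tm, effect_table(qfit, tm))
  for (v in intersect(covariate_vars(schema), names(tab))) {
    e <- tryCatch({
      fit <- fit_logistic(tab, terms = v, outcome = outcome_var(schema))
      effect_table(fit)
    }, error = function(e) NULL)
    if (!is.null(e)) for (i in seq_len(nrow(e))) push(e$term[i], e[i, ])
  }
  do.call(rbind, rows)
}

adjusted_effects <- function(tab, covariates) {
  rows <- list()
  for (m in c("crude", "model_I", "model_II")) {
    covs <- switch(m, crude = character(0), model_I = model_i_covariates(),
                   model_II = covariates)
    for (ex in c("continuous", "quartiles")) {
      fit <- fit_logistic(tab, model_spec(ex, "custom", covariates = covs))
      terms <- if (ex == "continuous") "lactate" else
        grep("^lactate_quartile", names(fit$coefficients), value = TRUE)
      e <- effect_table(fit, terms)
      e$model <- m
      rows[[length(rows) + 1L]] <- e
    }
  }
  out <- do.call(rbind, rows)
  out$or_ci <- fmt_or_ci(out)
  out$p <- format_p(out$p_value)
  out[, c("model", "term", "or_ci", "p", "odds_ratio", "ci_low", "ci_high",
          "p_value")]
}

#' Run the full threshold analysis pipeline
#'
#' Executes, in order: load (or simulate) the cohort; exclusion filter;
#' median imputation; quartile binning; baseline table; univariate effect
#' models; adjusted effect models; dose-response smooth (pooled and
#' SOFA-stratified); two-piecewise threshold analysis with grid search,
#' LRT and bootstrap turning-point CI; subgroup effects with interaction
#' tests. Writes TSV tables, per-curve CSVs and a machine-readable
#' \code{manifest.json} (seed, per-stage row counts, per-file MD5 sums)
#' under \code{cfg$outdir}. A failing stage is recorded in the manifest and
#' does not abort unrelated stages.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$outdir, "curves"), showWarnings = FALSE)
  manifest <- list(package = "lacthresh",
                   version = as.character(utils::packageVersion("lacthresh")),
                   seed = cfg$seed, stages = list(), files = list())
  results <- list()
  stage <- function(name, n_in, expr) {
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "error",
      n_in = n_in,
      error = if (ok) NULL else conditionMessage(res))
    if (ok) res else NULL
  }

  tab <- stage("load", NA, {
    if (!is.null(cfg$simulate)) generate_cohort(cfg$simulate)
    else read_cohort(cfg$input, cfg$schema)
  })
  if (is.null(tab)) stop("pipeline error: cohort load failed")
  manifest$stages$load$n_out <- nrow(tab)

  ex <- stage("exclusions", nrow(tab), apply_exclusions(tab))
  if (!is.null(ex)) {
    manifest$stages$exclusions$n_out <- ex$n_after
    manifest$stages$exclusions$removed <- as.list(ex$removed)
    jsonlite::write_json(as.list(ex$removed),
                         file.path(cfg$outdir, "exclusion_flow.json"),
                         auto_unbox = TRUE)
    tab <- ex$cohort
  }

  imp <- stage("impute", nrow(tab), impute_median(tab))
  if (!is.null(imp)) tab <- imp
  manifest$stages$impute$n_out <- nrow(tab)

  qb <- stage("quartiles", nrow(tab), quartile_bin(tab))
  results$quartiles <- qb

  results$table1 <- stage("table1", nrow(tab), {
    t1 <- baseline_table(tab, qb$bin)
    write_tsv(t1, file.path(cfg$outdir, "table1.tsv"))
    t1
  })

  results$univariate <- stage("univariate", nrow(tab), {
    u <- univariate_effects(tab, cohort_schema_of(tab))
    write_tsv(u, file.path(cfg$outdir, "effects_univariate.tsv"))
    u
  })

  results$adjusted <- stage("adjusted", nrow(tab), {
    a <- adjusted_effects(tab, cfg$covariates)
    write_tsv(a, file.path(cfg$outdir, "effects_adjusted.tsv"))
    a
  })

  results$smooth <- stage("smooth", nrow(tab), {
    cv <- fit_smooth(tab, cfg$covariates, spline_df = cfg$spline_df)
    utils::write.csv(as.data.frame(cv),
                     file.path(cfg$outdir, "curves", "smooth_pooled.csv"),
                     row.names = FALSE)
    strat <- stratified_smooth(tab, "sofa", cfg$sofa_cut,
                               cfg$covariates, cfg$spline_df)
    for (nm in names(strat)) {
      safe <- gsub(">", "gt", gsub("<=", "le", nm))
      fn <- paste0("smooth_", gsub("[^a-z0-9]+", "_", tolower(safe)), ".csv")
      utils::write.csv(as.data.frame(strat[[nm]]),
                       file.path(cfg$outdir, "curves", fn), row.names = FALSE)
    }
    list(pooled = cv, stratified = strat)
  })

  results$threshold <- stage("threshold", nrow(tab), {
    grid <- search_grid(threshold_data(tab, cfg$covariates)$x,
                        range = cfg$grid_range, step = cfg$grid_step)
    pw <- find_turning_point(tab, grid, cfg$covariates)
    if (cfg$B > 0) {
      bs <- bootstrap_turning_point(tab, grid, cfg$covariates, B = cfg$B,
                                    seed = cfg$seed)
      pw$K_ci <- bs$ci
      pw$bootstrap <- bs[c("B", "n_failed", "seed")]
    }
    write_tsv(threshold_table(pw), file.path(cfg$outdir, "threshold.tsv"))
    jsonlite::write_json(pw$profile, file.path(cfg$outdir, "threshold_profile.json"),
                         dataframe = "columns", na = "null")
    pw
  })

  results$subgroups <- stage("subgroups", nrow(tab), {
    sg <- subgroup_effects(tab, cfg$subgroups, cfg$covariates)
    sg$or_ci <- ifelse(is.na(sg$odds_ratio), "-",
                       fmt_or_ci(sg))
    sg$interaction_p_display <- format_p(sg$interaction_p)
    write_tsv(sg, file.path(cfg$outdir, "subgroups.tsv"))
    sg
  })

  files <- list.files(cfg$outdir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  md5 <- tools::md5sum(files)
  names(md5) <- sub(paste0("^", cfg$outdir, "/?"), "", files)
  manifest$files <- as.list(md5)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  results$manifest <- manifest
  results$cohort <- tab
  invisible(results)
}

#' Sensitivity variants of the pipeline
#'
#' \code{"complete_case"} drops every row with a missing covariate instead
#' of imputing; \code{"drop_first_24h_deaths"} removes patients who died
#' within 24 h of admission (requires a \code{death_hours} column). The
#' variant pipeline runs into \code{<outdir>/sensitivity_<variant>} and a
#' \code{deltas.json} records the shift of the headline quantities
#' (turning point, per-segment and one-line ORs) against the main run.
#'
#' @param cfg a [run_config()].
#' @param variant one of \code{"complete_case"},
#'   \code{"drop_first_24h_deaths"}.
#' @param main optional result of a prior [run_pipeline()] on \code{cfg};
#'   recomputed when absent.
#' @return Invisibly, the variant results with element \code{deltas}.
#' @export
sensitivity_run <- function(cfg, variant = c("complete_case",
                                             "drop_first_24h_deaths"),
                            main = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(main)) main <- run_pipeline(cfg)

  # rebuild the post-exclusion, pre-imputation cohort for the variant
  tab0 <- if (!is.null(cfg$simulate)) generate_cohort(cfg$simulate)
          else read_cohort(cfg$input, cfg$schema)
  tab0 <- apply_exclusions(tab0)$cohort

  if (variant == "complete_case") {
    schema <- cohort_schema_of(tab0)
    cols <- intersect(c(outcome_var(schema), exposure_var(schema),
                        covariate_vars(schema)), names(tab0))
    keep <- stats::complete.cases(as.data.frame(tab0)[, cols, drop = FALSE])
    tab0 <- as_cohort(tab0[keep, , drop = FALSE], schema)
  } else {
    if (!"death_hours" %in% names(tab0))
      stop("schema error: variant 'drop_first_24h_deaths' needs a ",
           "'death_hours' column")
    early <- !is.na(tab0$death_hours) & tab0$death_hours < 24
    tab0 <- as_cohort(tab0[!early, , drop = FALSE], cohort_schema_of(tab0))
  }

  vdir <- file.path(cfg$outdir, paste0("sensitivity_", variant))
  vpath <- file.path(vdir, "cohort.csv")
  dir.create(vdir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(tab0, vpath)
  vcfg <- cfg
  vcfg$input <- vpath
  vcfg$simulate <- NULL
  vcfg$outdir <- vdir
  vres <- run_pipeline(vcfg)

  deltas <- list(variant = variant, n_main = nrow(main$cohort),
                 n_variant = nrow(vres$cohort))
  if (!is.null(main$threshold) && !is.null(vres$threshold)) {
    deltas$K_main <- main$threshold$K
    deltas$K_variant <- vres$threshold$K
    deltas$K_shift <- vres$threshold$K - main$threshold$K
    deltas$or_below_shift <-
      vres$threshold$or_below$odds_ratio - main$threshold$or_below$odds_ratio
    deltas$or_above_shift <-
      vres$threshold$or_above$odds_ratio - main$threshold$or_above$odds_ratio
    deltas$linear_or_shift <-
      vres$threshold$linear_or$odds_ratio - main$threshold$linear_or$odds_ratio
  }
  jsonlite::write_json(deltas, file.path(vdir, "deltas.json"),
                       auto_unbox = TRUE, na = "null")
  vres$deltas <- deltas
  invisible(vres)
}
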