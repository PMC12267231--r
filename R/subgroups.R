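dichotomize <- function(x, name) {
  if (all(x %in% c(0, 1) | is.na(x))) {
    cut_at <- NA_real_
    lab <- ifelse(is.na(x), NA, ifelse(x == 0, "no", "yes"))
    levels <- c("no", "yes")
  } else {
    cut_at <- stats::median(x, na.rm = TRUE)
    lab <- ifelse(is.na(x), NA, ifelse(x <= cut_at, "low", "high"))
    levels <- c("low", "high")
  }
  if (length(unique(lab[!is.na(lab)])) < 2)
    stop("stratification error: '", name,
         "' is constant (or one-sided) over the table")
  list(label = factor(lab, levels = levels), cut = cut_at)
}

#' Per-stratum lactate effects across clinical subgroups
#'
#' For each stratifier, rows are split into two strata (binary variables at
#' their levels; continuous variables at the in-sample median, low = at or
#' below), and the adjusted per-unit lactate odds ratio is estimated within
#' each stratum by logistic regression using the supplied covariate list
#' minus the stratifier itself. One interaction p-value per stratifier comes
#' from [interaction_test()]. Strata too small (or too degenerate) to fit
#' are flagged and skipped without aborting the run.
#'
#' @param tab a cohort data frame.
#' @param stratifiers character vector of stratifier column names.
#' @param covariates adjustment covariates (e.g. [model_ii_covariates()]).
#' @return A data frame with one row per stratum: \code{stratifier},
#'   \code{stratum}, \code{cut}, \code{n}, \code{odds_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{interaction_p}, \code{note}.
#' @export
subgroup_effects <- function(tab, stratifiers, covariates = character(0)) {
  schema <- cohort_schema_of(tab)
  xv <- exposure_var(schema); yv <- outcome_var(schema)
  rows <- list()
  for (s in stratifiers) {
    if (!s %in% names(tab))
      stop("schema error: stratifier column '", s, "' absent")
    covs <- setdiff(covariates, s)
    dch <- dichotomize(tab[[s]], s)
    int_p <- tryCatch(interaction_test(tab, s, covs),
                      error = function(e) NA_real_)
    for (st in levels(dch$label)) {
      sub <- tab[!is.na(dch$label) & dch$label == st, , drop = FALSE]
      est <- tryCatch({
        fit <- fit_logistic(as_cohort(sub, schema), terms = c(xv, covs),
                            outcome = yv)
        effect_table(fit, xv)
      }, error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        stratifier = s, stratum = st, cut = dch$cut, n = nrow(sub),
        odds_ratio = if (is.null(est)) NA_real_ else est$odds_ratio,
        ci_low = if (is.null(est)) NA_real_ else est$ci_low,
        ci_high = if (is.null(est)) NA_real_ else est$ci_high,
        p_value = if (is.null(est)) NA_real_ else est$p_value,
        interaction_p = int_p,
        note = if (is.null(est)) "fit failed; estimate absent" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio interaction test for effect modification
#'
#' Compares the adjusted logistic model with and without a lactate-by-
#' stratum product term, both fit on the same complete-case rows; the
#' stratum main effect is in both models. The statistic is referred to a
#' chi-square with (number of strata - 1) degrees of freedom.
#'
#' @param tab a cohort data frame.
#' @param stratifier stratifier column name (dichotomized as in
#'   [subgroup_effects()]).
#' @param covariates adjustment covariates (the stratifier is removed).
#' @return The interaction p-value (scalar).
#' @export
interaction_test <- function(tab, stratifier, covariates = character(0)) {
  schema <- cohort_schema_of(tab)
  xv <- exposure_var(schema); yv <- outcome_var(schema)
  covariates <- setdiff(covariates, stratifier)
  dch <- dichotomize(tab[[stratifier]], stratifier)
  tab$.stratum <- as.numeric(dch$label) - 1
  cols <- c(yv, xv, ".stratum", covariates)
  tab2 <- prepare_terms(tab, covariates, schema)
  use <- stats::complete.cases(tab2[, cols, drop = FALSE])
  dat <- as.data.frame(tab2)[use, , drop = FALSE]
  if (!all(c(0, 1) %in% dat$.stratum))
    stop("stratification error: a stratum is empty after missing handling")
  cov_rhs <- if (length(covariates))
    paste("+", paste(sprintf("`%s`", covariates), collapse = " + ")) else ""
  f0 <- stats::as.formula(paste(yv, "~", xv, "+ .stratum", cov_rhs))
  f1 <- stats::as.formula(paste(yv, "~", xv, "* .stratum", cov_rhs))
  m0 <- stats::glm(f0, data = dat, family = stats::binomial())
  m1 <- stats::glm(f1, data = dat, family = stats::binomial())
  if (m0$df.residual - m1$df.residual < 1)
    stop("alignment error: interaction model adds no parameter")
  stat <- max(0, 2 * (glm_loglik(m1) - glm_loglik(m0)))
  stats::pchisq(stat, df = m0$df.residual - m1$df.residual,
                lower.tail = FALSE)
}
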