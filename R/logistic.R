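Z95 <- 1.959964  # two-sided 95% normal critical value, fixed to 6 figures

#' Covariate list of the fully adjusted model
#'
#' The full adjustment set: age, gender, COPD, CHF, AMI, DM, heart rate,
#' temperature, hemoglobin, potassium, RBC, sodium, WBC, bicarbonate, RDW,
#' BUN, APACHE IV score, SOFA score and ICU unit type.
#'
#' @return Character vector of covariate column names.
#' @export
model_ii_covariates <- function() {
  c("age", "gender", "copd", "chf", "ami", "dm", "hr", "temperature",
    "hemoglobin", "potassium", "rbc", "sodium", "wbc", "bicarbonate",
    "rdw", "bun", "apache_iv", "sofa", "unit_type")
}

#' @rdname model_ii_covariates
#' @export
model_i_covariates <- function() c("age", "gender")

#' Specify a logistic effect model
#'
#' @param exposure \code{"continuous"} for the per-unit lactate effect or
#'   \code{"quartiles"} for reference-coded quartile indicators (Q1
#'   reference).
#' @param model \code{"crude"} (no covariates), \code{"model_I"}
#'   (age + gender), \code{"model_II"} (full adjustment set) or
#'   \code{"custom"} with an explicit \code{covariates} vector.
#' @param covariates covariate names for \code{model = "custom"}.
#' @param outcome,exposure_var column names.
#' @return A \code{model_spec} list.
#' @export
model_spec <- function(exposure = c("continuous", "quartiles"),
                       model = c("crude", "model_I", "model_II", "custom"),
                       covariates = NULL,
                       outcome = "mortality_28d", exposure_var = "lactate") {
  exposure <- match.arg(exposure)
  model <- match.arg(model)
  covs <- switch(model,
                 crude = character(0),
                 model_I = model_i_covariates(),
                 model_II = model_ii_covariates(),
                 custom = as.character(covariates))
  structure(list(exposure = exposure, model = model, covariates = covs,
                 outcome = outcome, exposure_var = exposure_var),
            class = "model_spec")
}

# Categorical columns become factors; unit_type gets the largest observed
# level ("Medical surgical ICU" in the reference cohort) as baseline.
prepare_terms <- function(tab, vars, schema = cohort_schema_of(tab)) {
  for (v in intersect(vars, names(tab))) {
    kind <- schema$kind[schema$name == v]
    if (length(kind) && kind == "categorical" && !is.factor(tab[[v]])) {
      f <- factor(tab[[v]])
      big <- names(sort(table(f), decreasing = TRUE))[1]
      tab[[v]] <- stats::relevel(f, ref = big)
    }
  }
  tab
}

glm_loglik <- function(fit) {
  mu <- fit$fitted.values
  y <- fit$y
  sum(stats::dbinom(y, 1, mu, log = TRUE))
}

check_glm_fit <- function(fit, label = "logistic model") {
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinearity error: aliased term(s) in ", label, ": ",
         paste(bad, collapse = ", "))
  }
  if (!fit$converged)
    stop("non-convergence error: ", label, " did not converge")
  eps <- 1e-8
  if (any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps))
    stop("separation error: fitted probabilities at the 0/1 boundary in ",
         label, " (complete or quasi-complete separation)")
  invisible(fit)
}

#' Binary logistic regression fit
#'
#' Maximum-likelihood logistic regression (IRLS via \code{stats::glm}) of the
#' outcome on the exposure term(s) plus covariates. Quartile exposure enters
#' as reference-coded indicators against Q1; categorical covariates are
#' expanded against their largest level. Rows with a missing value in any
#' used column are dropped (report \code{n_used}). Complete or
#' quasi-complete separation and rank deficiency raise explicit errors
#' rather than returning silently inflated estimates.
#'
#' @param tab a cohort data frame.
#' @param spec a [model_spec()]; alternatively pass \code{terms} directly.
#' @param terms optional character vector of right-hand-side columns,
#'   overriding \code{spec}.
#' @param outcome outcome column when \code{terms} is used.
#' @return A \code{logistic_fit} list: \code{coefficients},
#'   \code{covariance}, \code{log_likelihood}, \code{n_used},
#'   \code{converged}, plus the underlying \code{glm} object.
#' @export
fit_logistic <- function(tab, spec = model_spec(), terms = NULL,
                         outcome = NULL) {
  schema <- cohort_schema_of(tab)
  if (is.null(terms)) {
    outcome <- spec$outcome
    if (spec$exposure == "quartiles") {
      qb <- quartile_bin(tab, spec$exposure_var)
      tab$lactate_quartile <- qb$bin
      rhs <- c("lactate_quartile", spec$covariates)
    } else {
      rhs <- c(spec$exposure_var, spec$covariates)
    }
  } else {
    rhs <- terms
    if (is.null(outcome)) outcome <- outcome_var(schema)
  }
  miss <- setdiff(c(outcome, rhs), names(tab))
  if (length(miss))
    stop("schema error: model column(s) absent: ", paste(miss, collapse = ", "))
  tab <- prepare_terms(tab, rhs, schema)
  use <- stats::complete.cases(tab[, c(outcome, rhs), drop = FALSE])
  dat <- as.data.frame(tab)[use, c(outcome, rhs), drop = FALSE]
  y <- dat[[outcome]]
  if (length(unique(y)) < 2)
    stop("degenerate-outcome error: outcome has a single class (",
         paste(unique(y), collapse = ""), ") - model is inestimable")
  f <- stats::as.formula(paste(outcome, "~",
                               paste(sprintf("`%s`", rhs), collapse = " + ")))
  fit <- stats::glm(f, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  check_glm_fit(fit)
  structure(list(coefficients = stats::coef(fit),
                 covariance = stats::vcov(fit),
                 log_likelihood = glm_loglik(fit),
                 n_used = sum(use), converged = fit$converged,
                 glm = fit),
            class = "logistic_fit")
}

#' Odds ratios with Wald intervals from a logistic fit
#'
#' OR = exp(beta); 95% CI = exp(beta +/- 1.959964 * SE); two-sided Wald
#' z-test p-value.
#'
#' @param fit a \code{logistic_fit} (or \code{glm}) object.
#' @param terms coefficient names to report (default: all but the
#'   intercept).
#' @return A data frame with \code{term}, \code{odds_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}.
#' @export
effect_table <- function(fit, terms = NULL) {
  if (inherits(fit, "glm"))
    fit <- list(coefficients = stats::coef(fit), covariance = stats::vcov(fit))
  beta <- fit$coefficients
  se <- sqrt(diag(fit$covariance))
  if (is.null(terms)) terms <- setdiff(names(beta), "(Intercept)")
  absent <- setdiff(terms, names(beta))
  if (length(absent))
    stop("lookup error: term(s) not in fit: ", paste(absent, collapse = ", "))
  b <- beta[terms]; s <- se[terms]
  data.frame(term = terms,
             odds_ratio = exp(b),
             ci_low = exp(b - Z95 * s),
             ci_high = exp(b + Z95 * s),
             p_value = 2 * stats::pnorm(-abs(b / s)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Closed-form odds ratio for a 2x2 table
#'
#' OR = (d1 * s0) / (s1 * d0) with the Woolf log-scale Wald interval
#' exp(ln OR +/- 1.959964 * sqrt(1/d1 + 1/s1 + 1/d0 + 1/s0)). Serves as the
#' independent oracle for single-indicator logistic fits, which are exact on
#' a saturated 2x2.
#'
#' @param d1,s1 deaths and survivors in the exposed (index) group.
#' @param d0,s0 deaths and survivors in the reference group.
#' @return A one-row effect data frame (see [effect_table()]).
#' @export
odds_ratio_2x2 <- function(d1, s1, d0, s0) {
  cells <- c(d1, s1, d0, s0)
  if (any(cells <= 0))
    stop("zero-cell error: all four counts must be > 0 ",
         "(continuity corrections are not provided)")
  lor <- log((d1 * s0) / (s1 * d0))
  se <- sqrt(sum(1 / cells))
  data.frame(term = "exposed",
             odds_ratio = exp(lor),
             ci_low = exp(lor - Z95 * se),
             ci_high = exp(lor + Z95 * se),
             p_value = 2 * stats::pnorm(-abs(lor / se)),
             stringsAsFactors = FALSE)
}

#' Normal-approximation confidence interval for a proportion
#'
#' p-hat +/- 1.959964 * sqrt(p-hat (1 - p-hat) / n), clipped to [0, 1].
#'
#' @param k event count.
#' @param n total count.
#' @return A list with \code{proportion}, \code{ci_low}, \code{ci_high}
#'   (all on the 0-1 scale).
#' @export
proportion_ci <- function(k, n) {
  if (n <= 0) stop("undefined-proportion error: n must be positive")
  stopifnot(k >= 0, k <= n)
  p <- k / n
  half <- Z95 * sqrt(p * (1 - p) / n)
  list(proportion = p,
       ci_low = max(0, p - half),
       ci_high = min(1, p + half))
}

#' Expand a 2x2 mortality table to individual rows
#'
#' Returns one row per patient with a binary \code{exposed} indicator and
#' \code{death} outcome, so closed-form 2x2 estimates can be cross-checked
#' against a logistic fit on individual data.
#'
#' @inheritParams odds_ratio_2x2
#' @return A data frame with columns \code{exposed}, \code{death}.
#' @export
expand_2x2 <- function(d1, s1, d0, s0) {
  data.frame(
    exposed = rep(c(1, 1, 0, 0), times = c(d1, s1, d0, s0)),
    death = rep(c(1, 0, 1, 0), times = c(d1, s1, d0, s0)))
}
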