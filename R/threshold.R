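#' Hinge design terms for a two-piecewise logit
#'
#' The continuous two-segment parameterization: \code{below = min(x, K)},
#' \code{above = max(x - K, 0)}. The implied logit
#' \code{a + b_below * min(x, K) + b_above * max(x - K, 0)} is continuous at
#' the knot; \code{exp(b_below)} is the per-unit odds ratio below K and
#' \code{exp(b_above)} the per-unit odds ratio at or above K.
#'
#' @param x exposure values.
#' @param K turning point (finite scalar).
#' @return A two-column matrix \code{below}, \code{above}.
#' @export
hinge_design <- function(x, K) {
  stopifnot(is.finite(K))
  cbind(below = pmin(x, K), above = pmax(x - K, 0))
}

# Complete-case outcome/exposure/covariate matrices, factors expanded.
threshold_data <- function(tab, covariates = character(0),
                           exposure = NULL, outcome = NULL) {
  schema <- cohort_schema_of(tab)
  if (is.null(exposure)) exposure <- exposure_var(schema)
  if (is.null(outcome)) outcome <- outcome_var(schema)
  miss <- setdiff(c(outcome, exposure, covariates), names(tab))
  if (length(miss))
    stop("schema error: model column(s) absent: ", paste(miss, collapse = ", "))
  tab <- prepare_terms(tab, covariates, schema)
  cols <- c(outcome, exposure, covariates)
  use <- stats::complete.cases(tab[, cols, drop = FALSE])
  dat <- as.data.frame(tab)[use, cols, drop = FALSE]
  C <- if (length(covariates)) {
    f <- stats::as.formula(paste("~", paste(sprintf("`%s`", covariates),
                                            collapse = " + ")))
    stats::model.matrix(f, dat)[, -1, drop = FALSE]
  } else matrix(numeric(0), nrow(dat), 0)
  list(y = dat[[outcome]], x = dat[[exposure]], C = C, n = nrow(dat))
}

# Logistic fit on an explicit design matrix via IRLS (stats::glm.fit),
# returning coefficients, covariance and the binomial log-likelihood.
glmfit_matrix <- function(y, X, label = "model", start = NULL) {
  if (!is.null(start) && (length(start) != ncol(X) || anyNA(start)))
    start <- NULL
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), start = start,
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("collinearity error: aliased term(s) in ", label, ": ",
         paste(colnames(X)[is.na(beta)], collapse = ", "))
  if (!fit$converged)
    stop("non-convergence error: ", label, " did not converge")
  p1 <- seq_len(fit$rank)
  vcov <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  dimnames(vcov) <- list(colnames(X), colnames(X))
  mu <- fit$fitted.values
  list(coefficients = beta, covariance = vcov,
       log_likelihood = sum(stats::dbinom(y, 1, mu, log = TRUE)),
       n_used = length(y), converged = TRUE)
}

pw_fit_matrices <- function(y, x, C, K, start = NULL) {
  below_idx <- x < K
  above_idx <- x > K
  for (side in c("below", "above")) {
    idx <- if (side == "below") below_idx else above_idx
    ys <- y[idx]
    if (!length(ys) || all(ys == 0) || all(ys == 1))
      stop("segment-degeneracy error: no outcome variation ", side,
           " the candidate turning point K = ", K)
  }
  H <- hinge_design(x, K)
  X <- cbind("(Intercept)" = 1, lactate_below = H[, "below"],
             lactate_above = H[, "above"], C)
  out <- glmfit_matrix(y, X, label = paste0("piecewise fit at K = ", K),
                       start = start)
  out$K <- K
  out
}

#' Two-piecewise logistic fit at a fixed turning point
#'
#' Logistic MLE of the outcome on the hinge terms \code{min(x, K)} and
#' \code{max(x - K, 0)} plus covariates. Both sides of K must contain events
#' and non-events.
#'
#' @param tab a cohort data frame.
#' @param K turning point on the exposure scale (mmol/L).
#' @param covariates covariate column names (e.g.
#'   [model_ii_covariates()]).
#' @return A \code{logistic_fit}-style list with element \code{K}.
#' @export
fit_piecewise_at <- function(tab, K, covariates = character(0)) {
  d <- threshold_data(tab, covariates)
  structure(pw_fit_matrices(d$y, d$x, d$C, K), class = "logistic_fit")
}

#' Candidate grid for the turning-point search
#'
#' Exposure values from the 5th to the 95th percentile in fixed steps of
#' 0.1 mmol/L (matching the 1-decimal precision at which turning points are
#' reported), aligned to multiples of the step.
#'
#' @param x observed exposure values.
#' @param range percentile bounds of the search (default 0.05, 0.95).
#' @param step grid increment in exposure units (default 0.1).
#' @return A \code{search_grid} list with \code{candidates}, \code{range},
#'   \code{step}.
#' @export
search_grid <- function(x, range = c(0.05, 0.95), step = 0.1) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, range, names = FALSE)
  lo <- ceiling(q[1] / step) * step
  hi <- floor(q[2] / step) * step
  if (hi < lo) stop("search-failure error: empty candidate grid")
  structure(list(candidates = round(seq(lo, hi, by = step), 10),
                 range = q, step = step),
            class = "search_grid")
}

grid_scan <- function(y, x, C, candidates, start = NULL) {
  ll <- rep(NA_real_, length(candidates))
  warm <- start  # IRLS warm start: adjacent knots have near-identical MLEs
  for (i in seq_along(candidates)) {
    fit_i <- tryCatch(pw_fit_matrices(y, x, C, candidates[i], start = warm),
                      error = function(e) NULL)
    if (!is.null(fit_i)) {
      ll[i] <- fit_i$log_likelihood
      warm <- fit_i$coefficients
    }
  }
  feasible <- !is.na(ll)
  if (!any(feasible))
    stop("search-failure error: no feasible turning-point candidate")
  best <- which(ll == max(ll, na.rm = TRUE))[1]  # ties -> smallest K
  list(K_hat = candidates[best], loglik = ll[best],
       profile = data.frame(K = candidates, loglik = ll, feasible = feasible))
}

#' Profile-likelihood grid search for the turning point
#'
#' Fits the two-piecewise logistic model at every grid candidate and returns
#' the candidate maximizing the log-likelihood (ties broken toward the
#' smallest K), together with the one-line (linear) fit on the same data,
#' the likelihood-ratio test between them, and per-segment odds ratios at
#' the selected K. Candidates whose fit fails (segment degeneracy,
#' collinearity) are skipped and recorded in the profile.
#'
#' @param tab a cohort data frame.
#' @param grid a [search_grid()]; default built from the analyzed exposure.
#' @param covariates covariate column names.
#' @return A \code{piecewise_fit} list: \code{K}, \code{or_below},
#'   \code{or_above} (one-row effect frames), \code{linear_or},
#'   \code{loglik_piecewise}, \code{loglik_linear}, \code{lrt_statistic},
#'   \code{lrt_p}, \code{profile}, \code{n_used}, \code{K_ci} (NULL until
#'   [bootstrap_turning_point()] fills it).
#' @export
find_turning_point <- function(tab, grid = NULL, covariates = character(0)) {
  d <- threshold_data(tab, covariates)
  if (is.null(grid)) grid <- search_grid(d$x)
  if (length(grid$candidates) < 1)
    stop("search-failure error: empty candidate grid")
  scan <- grid_scan(d$y, d$x, d$C, grid$candidates)
  pw <- pw_fit_matrices(d$y, d$x, d$C, scan$K_hat)
  Xlin <- cbind("(Intercept)" = 1, lactate = d$x, d$C)
  lin <- glmfit_matrix(d$y, Xlin, label = "one-line fit")
  lrt <- lrt_linear_vs_piecewise(lin, pw)
  structure(list(
    K = scan$K_hat,
    or_below = effect_table(pw, "lactate_below"),
    or_above = effect_table(pw, "lactate_above"),
    linear_or = effect_table(lin, "lactate"),
    loglik_piecewise = pw$log_likelihood,
    loglik_linear = lin$log_likelihood,
    lrt_statistic = lrt$statistic, lrt_p = lrt$p_value,
    profile = scan$profile, grid = grid, covariates = covariates,
    n_used = d$n, K_ci = NULL,
    piecewise_fit = pw, linear_fit = lin),
    class = "piecewise_fit")
}

#' Likelihood-ratio test of one-line vs two-piecewise model
#'
#' statistic = 2 (LL_piecewise - LL_linear), referred to an upper-tail
#' chi-square with 1 degree of freedom (the added slope-change parameter).
#' The reference distribution does not account for the estimation of K and
#' is mildly anticonservative; see the methods vignette.
#'
#' @param fit_lin,fit_pw fits on the same data, linear nested in piecewise.
#' @param df test degrees of freedom (default 1).
#' @return A list with \code{statistic} and \code{p_value}.
#' @export
lrt_linear_vs_piecewise <- function(fit_lin, fit_pw, df = 1) {
  stat <- 2 * (fit_pw$log_likelihood - fit_lin$log_likelihood)
  if (stat < -1e-8)
    stop("nesting violation error: piecewise log-likelihood below linear")
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Percentile bootstrap confidence interval for the turning point
#'
#' Resamples rows with replacement B times, reruns the full grid search on
#' each resample, and takes the empirical 2.5/97.5 percentiles of the
#' replicate turning points. Replicates on which every candidate is
#' infeasible are dropped and counted; more than 20% failures aborts with a
#' diagnostic.
#'
#' @param tab a cohort data frame.
#' @param grid a [search_grid()]; default built from the analyzed exposure.
#' @param covariates covariate column names.
#' @param B number of bootstrap replicates (default 500).
#' @param seed integer RNG seed (mandatory; no silent default).
#' @return A list with \code{ci} (low, high), \code{K_hats} (replicate
#'   estimates), \code{n_failed}, \code{B}, \code{seed}.
#' @export
bootstrap_turning_point <- function(tab, grid = NULL,
                                    covariates = character(0),
                                    B = 500, seed) {
  if (missing(seed) || is.null(seed))
    stop("bootstrap requires an explicit seed")
  stopifnot(B >= 2)
  d <- threshold_data(tab, covariates)
  if (is.null(grid)) grid <- search_grid(d$x)
  base <- grid_scan(d$y, d$x, d$C, grid$candidates)
  base_beta <- tryCatch(
    pw_fit_matrices(d$y, d$x, d$C, base$K_hat)$coefficients,
    error = function(e) NULL)
  set.seed(seed)
  K_hats <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(d$n, d$n, replace = TRUE)
    K_hats[b] <- tryCatch(
      grid_scan(d$y[idx], d$x[idx], d$C[idx, , drop = FALSE],
                grid$candidates, start = base_beta)$K_hat,
      error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(K_hats))
  if (n_failed > 0.2 * B)
    stop("unstable-bootstrap error: ", n_failed, " of ", B,
         " replicates failed the grid search")
  ok <- K_hats[!is.na(K_hats)]
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  list(ci = c(low = ci[1], high = ci[2]), K_hats = K_hats,
       n_failed = n_failed, B = B, seed = seed)
}

#' Table-4 style summary of a threshold analysis
#'
#' @param pw a \code{piecewise_fit} from [find_turning_point()].
#' @return A data frame mirroring the threshold-effect report: one-line OR,
#'   turning point, per-segment ORs, LRT p.
#' @export
threshold_table <- function(pw) {
  fmt_or <- function(e)
    sprintf("%s (%s, %s)", fmt_num(e$odds_ratio), fmt_num(e$ci_low),
            fmt_num(e$ci_high))
  ci_txt <- if (!is.null(pw$K_ci))
    sprintf(" (%s, %s)", fmt_num(pw$K_ci["low"], 1), fmt_num(pw$K_ci["high"], 1))
  else ""
  data.frame(
    model = c("One line effect",
              "Turning point (K)",
              sprintf("Lactate < %s", fmt_num(pw$K, 1)),
              sprintf("Lactate >= %s", fmt_num(pw$K, 1)),
              "P-value for LRT test"),
    or_ci = c(fmt_or(pw$linear_or),
              paste0(fmt_num(pw$K, 1), ci_txt),
              fmt_or(pw$or_below), fmt_or(pw$or_above), "-"),
    p_value = c(format_p(pw$linear_or$p_value),
                "-",
                format_p(pw$or_below$p_value),
                format_p(pw$or_above$p_value),
                format_p(pw$lrt_p)),
    stringsAsFactors = FALSE)
}
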