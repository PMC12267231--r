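#' Adjusted smooth dose-response curve
#'
#' Generalized additive logistic model with a spline in the exposure and
#' linear covariate terms, evaluated on an even grid of 200 points across
#' the observed exposure range. The curve is the centered partial effect of
#' the exposure on the log-odds scale (covariate contributions removed, the
#' smooth centered over the analyzed sample as usual for GAM terms), with a
#' pointwise 95% Wald band from the fitted coefficient covariance.
#'
#' \code{spline_df} counts the effective degrees of freedom of the exposure
#' term: \code{spline_df = 1} is a straight line (plain logistic fit);
#' larger values use a fixed-dimension thin-plate regression spline basis.
#'
#' @param tab a cohort data frame.
#' @param covariates covariate column names.
#' @param spline_df degrees of freedom of the exposure smooth (default 4).
#' @param grid_n number of evaluation points (default 200).
#' @param stratum optional label carried into the result.
#' @param scale \code{"partial"} (default) for the centered exposure term
#'   only; \code{"linked"} for the full adjusted log-odds (intercept plus
#'   exposure term, covariates held at their means / reference level), the
#'   scale on which baseline-risk differences between strata remain
#'   visible.
#' @return A \code{smooth_curve} data frame with columns \code{x},
#'   \code{effect}, \code{band_low}, \code{band_high} and attributes
#'   \code{spline_df}, \code{log_likelihood}, \code{n_used},
#'   \code{stratum}.
#' @export
fit_smooth <- function(tab, covariates = character(0), spline_df = 4,
                       grid_n = 200, stratum = NA_character_,
                       scale = c("partial", "linked")) {
  scale <- match.arg(scale)
  schema <- cohort_schema_of(tab)
  xv <- exposure_var(schema); yv <- outcome_var(schema)
  stopifnot(spline_df >= 1)
  tab <- prepare_terms(tab, covariates, schema)
  cols <- c(yv, xv, covariates)
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("schema error: model column(s) absent: ", paste(miss, collapse = ", "))
  dat <- as.data.frame(tab)[stats::complete.cases(tab[, cols, drop = FALSE]),
                            cols, drop = FALSE]
  if (length(unique(dat[[xv]])) < spline_df + 1)
    stop("basis error: exposure has fewer distinct values than spline_df + 1")
  cov_rhs <- if (length(covariates))
    paste("+", paste(sprintf("`%s`", covariates), collapse = " + ")) else ""
  if (spline_df == 1) {
    f <- stats::as.formula(paste(yv, "~", sprintf("`%s`", xv), cov_rhs))
    fit <- stats::glm(f, data = dat, family = stats::binomial())
    term_label <- xv
  } else {
    f <- stats::as.formula(paste0(
      yv, " ~ s(", xv, ", k = ", spline_df + 1, ", fx = TRUE)", cov_rhs))
    fit <- mgcv::gam(f, data = dat, family = stats::binomial(), method = "REML")
    term_label <- paste0("s(", xv, ")")
  }
  xr <- range(dat[[xv]])
  nd <- dat[rep(1L, grid_n), , drop = FALSE]
  nd[[xv]] <- seq(xr[1], xr[2], length.out = grid_n)
  for (v in covariates) {
    nd[[v]] <- if (is.numeric(dat[[v]])) mean(dat[[v]])
               else factor(levels(factor(dat[[v]]))[1],
                           levels = levels(factor(dat[[v]])))
  }
  if (scale == "partial") {
    pr <- stats::predict(fit, newdata = nd, type = "terms", se.fit = TRUE)
    eff <- pr$fit[, term_label]
    se <- pr$se.fit[, term_label]
  } else {
    pr <- stats::predict(fit, newdata = nd, type = "link", se.fit = TRUE)
    eff <- pr$fit
    se <- pr$se.fit
  }
  out <- data.frame(x = nd[[xv]], effect = as.numeric(eff),
                    band_low = as.numeric(eff - Z95 * se),
                    band_high = as.numeric(eff + Z95 * se))
  structure(out, class = c("smooth_curve", "data.frame"),
            spline_df = spline_df,
            log_likelihood = as.numeric(stats::logLik(fit)),
            n_used = nrow(dat), stratum = stratum)
}

#' Stratified smooth curves
#'
#' Fits [fit_smooth()] independently within strata defined by cutting a
#' stratifier column (default SOFA score at <= 5 vs > 5). Curves share a
#' common exposure grid spanning the pooled observed range, so strata can be
#' compared pointwise. The stratifier is removed from the covariate set of
#' its own analysis.
#'
#' @param tab a cohort data frame.
#' @param stratifier stratifier column name (default \code{"sofa"}).
#' @param cut numeric cutpoint: strata are \code{<= cut} ("low") and
#'   \code{> cut} ("high"). \code{NULL} puts all rows in one stratum.
#' @param covariates covariate column names.
#' @param spline_df degrees of freedom of the exposure smooth.
#' @param grid_n number of evaluation points.
#' @param scale curve scale passed to [fit_smooth()]; default
#'   \code{"linked"} so baseline-risk separation between strata is
#'   retained.
#' @return A named list of \code{smooth_curve} objects.
#' @export
stratified_smooth <- function(tab, stratifier = "sofa", cut = 5,
                              covariates = character(0), spline_df = 4,
                              grid_n = 200, scale = c("linked", "partial")) {
  scale <- match.arg(scale)
  if (!stratifier %in% names(tab))
    stop("stratification error: column '", stratifier, "' absent")
  covariates <- setdiff(covariates, stratifier)
  s <- tab[[stratifier]]
  lab <- if (is.null(cut)) rep("all", nrow(tab))
         else ifelse(s <= cut, paste0(stratifier, " <= ", cut),
                     paste0(stratifier, " > ", cut))
  lab[is.na(s)] <- NA
  strata <- if (is.null(cut)) "all" else
    c(paste0(stratifier, " <= ", cut), paste0(stratifier, " > ", cut))
  schema <- cohort_schema_of(tab)
  xv <- exposure_var(schema)
  curves <- list()
  for (st in strata) {
    sub <- tab[!is.na(lab) & lab == st, , drop = FALSE]
    if (!nrow(sub))
      stop("stratification error: empty stratum '", st, "'")
    curves[[st]] <- fit_smooth(as_cohort(sub, schema), covariates,
                               spline_df = spline_df, grid_n = grid_n,
                               stratum = st, scale = scale)
  }
  # re-evaluate on the pooled grid for comparability
  pooled <- range(tab[[xv]], na.rm = TRUE)
  shared_x <- seq(pooled[1], pooled[2], length.out = grid_n)
  curves <- lapply(curves, function(cv) {
    xr <- range(cv$x)
    keep <- shared_x >= xr[1] & shared_x <= xr[2]
    out <- data.frame(
      x = shared_x[keep],
      effect = stats::approx(cv$x, cv$effect, xout = shared_x[keep])$y,
      band_low = stats::approx(cv$x, cv$band_low, xout = shared_x[keep])$y,
      band_high = stats::approx(cv$x, cv$band_high, xout = shared_x[keep])$y)
    attributes(out)[c("spline_df", "log_likelihood", "n_used", "stratum")] <-
      attributes(cv)[c("spline_df", "log_likelihood", "n_used", "stratum")]
    class(out) <- c("smooth_curve", "data.frame")
    out
  })
  curves
}
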