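#' Pearson chi-squared test on a contingency table
#'
#' Plain Pearson statistic sum((O-E)^2/E) with df = (r-1)(c-1) and an
#' upper-tail chi-square p-value. No continuity correction by default (group
#' tables in this setting are large); set \code{correct = TRUE} for the
#' Yates-corrected 2x2 variant.
#'
#' @param counts an r x c matrix (or table) of non-negative counts.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return A list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
chi_squared_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate-table error: zero row or column marginal")
  # marginals validated above; the small-expected-count note is routine on
  # sparse strata and not actionable here
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

group_test <- function(x, g, style) {
  g <- droplevels(as.factor(g))
  switch(style,
    mean_sd = {
      if (length(unique(x[!is.na(x)])) < 2)
        return(list(test = "anova", p = NA_real_))
      fit <- stats::aov(x ~ g)
      list(test = "anova",
           p = summary(fit)[[1]][["Pr(>F)"]][1])
    },
    median_iqr = {
      kt <- stats::kruskal.test(x, g)
      list(test = "kruskal_wallis", p = kt$p.value)
    },
    count_pct = {
      tb <- table(x, g)
      if (nrow(tb) < 2) return(list(test = "chi_squared", p = NA_real_))
      list(test = "chi_squared", p = chi_squared_test(tb)$p_value)
    })
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

summarise_cell <- function(x, style) {
  switch(style,
    mean_sd = paste0(fmt_num(mean(x, na.rm = TRUE)), " ± ",
                     fmt_num(stats::sd(x, na.rm = TRUE))),
    median_iqr = {
      q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
      paste0(fmt_num(q[1]), " (", fmt_num(q[2]), "-", fmt_num(q[3]), ")")
    },
    count_pct = NA_character_)
}

#' Baseline characteristics table by exposure group
#'
#' One row per level of every non-administrative variable, with per-group
#' summary cells (mean +/- SD, median (Q1-Q3), or n (%) using column
#' percentages within group) and a single group-comparison p-value per
#' variable. The test follows the declared summary style: ANOVA for mean/SD
#' variables, Kruskal-Wallis for median/IQR, chi-squared for counts.
#' P-values below 0.001 render as "< 0.001".
#'
#' @param tab a cohort data frame.
#' @param groups per-row group labels (factor), e.g. the \code{bin} element
#'   of [quartile_bin()].
#' @param schema a schema; defaults to the cohort's own.
#' @return A data frame with columns \code{variable}, \code{level},
#'   \code{test}, one summary column per group, \code{p_value} (numeric) and
#'   \code{p_display}.
#' @export
baseline_table <- function(tab, groups, schema = cohort_schema_of(tab)) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2)
    stop("baseline_table needs at least 2 groups")
  vars <- schema[schema$role %in% c("covariate", "stratifier", "outcome") &
                   schema$name %in% names(tab), , drop = FALSE]
  glev <- levels(groups)
  rows <- list()
  for (i in seq_len(nrow(vars))) {
    v <- vars$name[i]; style <- vars$summary_style[i]
    x <- tab[[v]]
    ts <- group_test(x, groups, style)
    if (style == "count_pct") {
      lev <- sort(unique(x[!is.na(x)]))
      for (l in lev) {
        cells <- vapply(glev, function(g) {
          ing <- groups == g & !is.na(x)
          k <- sum(x[ing] == l); n <- sum(ing)
          paste0(k, " (", fmt_num(100 * k / max(n, 1)), ")")
        }, character(1))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = as.character(l), test = ts$test,
          t(cells), p_value = ts$p, stringsAsFactors = FALSE,
          check.names = FALSE)
        ts$p <- NA_real_  # p printed once per variable
      }
    } else {
      cells <- vapply(glev, function(g)
        summarise_cell(x[groups == g], style), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "", test = ts$test, t(cells),
        p_value = ts$p, stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[4:(3 + length(glev))] <- glev
  out$p_display <- format_p(out$p_value, style = "table1")
  rownames(out) <- NULL
  out
}

#' Format p-values for report tables
#'
#' \code{style = "table1"}: 3 decimals with a "< 0.001" floor.
#' \code{style = "effects"}: 4 decimals with a "< 0.0001" floor.
#'
#' @param p numeric vector of p-values.
#' @param style display style.
#' @return Character vector.
#' @export
format_p <- function(p, style = c("effects", "table1")) {
  style <- match.arg(style)
  floorv <- if (style == "table1") 1e-3 else 1e-4
  digits <- if (style == "table1") 3 else 4
  out <- ifelse(is.na(p), "-",
         ifelse(p < floorv,
                paste0("< ", formatC(floorv, format = "f", digits = digits)),
                formatC(p, format = "f", digits = digits)))
  out
}
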