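#' Cohort variable schema
#'
#' A schema is a data frame with one row per variable and columns
#' \code{name}, \code{role}, \code{kind}, \code{units}, \code{summary_style}.
#' Roles: \code{exposure} (exactly one, continuous), \code{outcome} (exactly
#' one, binary), \code{covariate}, \code{stratifier}, \code{admin}. Kinds:
#' \code{continuous}, \code{binary}, \code{categorical}. The
#' \code{summary_style} (\code{mean_sd}, \code{median_iqr}, \code{count_pct})
#' controls both the baseline-table rendering and the group test used:
#' mean/SD rows get one-way ANOVA, median/IQR rows the Kruskal-Wallis H test,
#' count rows the chi-squared test.
#'
#' @param name character vector of variable names.
#' @param role character vector of roles.
#' @param kind character vector of kinds.
#' @param units character vector of measurement units ("" if unitless).
#' @param summary_style character vector of summary styles.
#' @return A validated schema data frame.
#' @export
cohort_schema <- function(name, role, kind, units = "", summary_style = "mean_sd") {
  sch <- data.frame(
    name = as.character(name),
    role = as.character(role),
    kind = as.character(kind),
    units = rep_len(as.character(units), length(name)),
    summary_style = rep_len(as.character(summary_style), length(name)),
    stringsAsFactors = FALSE
  )
  validate_schema(sch)
  sch
}

#' @rdname cohort_schema
#' @param schema a schema data frame to validate.
#' @export
validate_schema <- function(schema) {
  req <- c("name", "role", "kind", "units", "summary_style")
  if (!is.data.frame(schema) || !all(req %in% names(schema)))
    stop("schema must be a data frame with columns ", paste(req, collapse = ", "))
  if (anyDuplicated(schema$name))
    stop("schema error: duplicated variable names")
  ok_role <- c("exposure", "outcome", "covariate", "stratifier", "admin")
  ok_kind <- c("continuous", "binary", "categorical")
  ok_style <- c("mean_sd", "median_iqr", "count_pct")
  if (!all(schema$role %in% ok_role)) stop("schema error: unknown role")
  if (!all(schema$kind %in% ok_kind)) stop("schema error: unknown kind")
  if (!all(schema$summary_style %in% ok_style)) stop("schema error: unknown summary_style")
  if (sum(schema$role == "exposure") != 1L)
    stop("schema error: exactly one variable must have role 'exposure'")
  if (sum(schema$role == "outcome") != 1L)
    stop("schema error: exactly one variable must have role 'outcome'")
  if (schema$kind[schema$role == "exposure"] != "continuous")
    stop("schema error: exposure must be continuous")
  if (schema$kind[schema$role == "outcome"] != "binary")
    stop("schema error: outcome must be binary")
  invisible(schema)
}

#' Default eICU-like cohort schema
#'
#' The variable set of the elderly-sepsis lactate analysis: first serum
#' lactate (mmol/L) as the continuous exposure, 28-day mortality as the
#' binary outcome, demographics, comorbidities, first-24h vitals and labs,
#' severity scores (APACHE IV, SOFA) and ICU unit type as covariates, plus
#' administrative columns used only for exclusion filtering and sensitivity
#' variants. Skewed labs (WBC, BUN) and the integer scores use median/IQR
#' summaries (hence Kruskal-Wallis); the remaining continuous variables use
#' mean/SD (ANOVA).
#'
#' @return A schema data frame (see [cohort_schema()]).
#' @export
default_schema <- function() {
  cohort_schema(
    name = c("lactate", "mortality_28d",
             "age", "gender", "copd", "chf", "ami", "dm",
             "hr", "temperature", "hemoglobin", "potassium", "rbc", "sodium",
             "wbc", "bicarbonate", "rdw", "bun", "apache_iv", "sofa",
             "unit_type", "icu_los_days",
             "icu_los_hours", "sepsis_flag", "lactate_n_measurements",
             "death_hours"),
    role = c("exposure", "outcome",
             rep("covariate", 18),
             "covariate", "admin",
             rep("admin", 4)),
    kind = c("continuous", "binary",
             "continuous", "binary", "binary", "binary", "binary", "binary",
             rep("continuous", 6),
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous",
             "categorical", "continuous",
             "continuous", "binary", "continuous", "continuous"),
    units = c("mmol/L", "",
              "years", "", "", "", "", "",
              "beats/min", "degC", "g/dL", "mmol/L", "M/mcL", "mmol/L",
              "1e9/L", "mmol/L", "%", "mg/dL", "points", "points",
              "", "days", "hours", "", "count", "hours"),
    summary_style = c("median_iqr", "count_pct",
                      "mean_sd", "count_pct", "count_pct", "count_pct",
                      "count_pct", "count_pct",
                      "mean_sd", "mean_sd", "mean_sd", "mean_sd", "mean_sd",
                      "mean_sd",
                      "median_iqr", "mean_sd", "mean_sd", "median_iqr",
                      "mean_sd", "median_iqr",
                      "count_pct", "median_iqr",
                      "mean_sd", "count_pct", "mean_sd", "mean_sd")
  )
}

#' Read a schema from a JSON or YAML file
#'
#' The file holds a list of records with fields name/role/kind/units/
#' summary_style. JSON is detected by the \code{.json} extension; anything
#' else is parsed as YAML (requires the \pkg{yaml} package).
#'
#' @param path file path.
#' @return A validated schema data frame.
#' @export
read_schema <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML schema files require the 'yaml' package; use JSON instead")
    lst <- do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  }
  lst <- as.data.frame(lst, stringsAsFactors = FALSE)
  if (is.null(lst$units)) lst$units <- ""
  if (is.null(lst$summary_style)) lst$summary_style <- "mean_sd"
  cohort_schema(lst$name, lst$role, lst$kind, lst$units, lst$summary_style)
}

schema_var <- function(schema, role) schema$name[schema$role == role]

#' Exposure / outcome variable name of a schema
#' @param schema a schema data frame.
#' @return A single column name.
#' @export
exposure_var <- function(schema) schema_var(schema, "exposure")

#' @rdname exposure_var
#' @export
outcome_var <- function(schema) schema_var(schema, "outcome")

#' Covariate names of a schema
#'
#' Covariate (and stratifier) variables, excluding exposure, outcome and
#' administrative columns.
#'
#' @param schema a schema data frame.
#' @return Character vector of column names.
#' @export
covariate_vars <- function(schema) {
  schema$name[schema$role %in% c("covariate", "stratifier")]
}
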