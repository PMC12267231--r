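#' Read and validate a cohort table
#'
#' Reads a delimited text file (CSV, header row) whose header contains every
#' schema variable, types each column according to the schema and validates
#' the core contracts: the outcome must be 0/1 (or missing), the exposure
#' strictly positive where present. Cells that cannot be parsed under the
#' declared kind, as well as the missing markers \code{""}, \code{"NA"} and
#' \code{"NaN"} (case-insensitive), become \code{NA}.
#'
#' @param path path to a CSV file.
#' @param schema a schema data frame (default [default_schema()]); columns
#'   in the file but not in the schema are dropped, schema columns absent
#'   from the file raise a schema error (administrative columns excepted).
#' @return A \code{cohort} data frame with attributes \code{schema} and
#'   \code{n}.
#' @export
read_cohort <- function(path, schema = default_schema()) {
  validate_schema(schema)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  need <- schema$name[schema$role != "admin"]
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("schema error: required column(s) missing from file: ",
         paste(miss, collapse = ", "))
  keep <- intersect(schema$name, names(raw))
  raw <- raw[, keep, drop = FALSE]
  out <- raw
  for (v in keep) {
    kind <- schema$kind[schema$name == v]
    x <- trimws(raw[[v]])
    x[x == "" | tolower(x) %in% c("na", "nan")] <- NA_character_
    if (kind %in% c("continuous", "binary")) {
      num <- suppressWarnings(as.numeric(x))
      out[[v]] <- num
    } else {
      out[[v]] <- x
    }
  }
  as_cohort(out, schema)
}

#' Construct a validated cohort from a data frame
#'
#' @param df a data frame with schema-named columns.
#' @param schema a schema data frame.
#' @return A \code{cohort} data frame.
#' @export
as_cohort <- function(df, schema = default_schema()) {
  validate_schema(schema)
  y <- outcome_var(schema)
  x <- exposure_var(schema)
  if (y %in% names(df)) {
    bad <- !(df[[y]] %in% c(0, 1) | is.na(df[[y]]))
    if (any(bad))
      stop("validation error: outcome '", y, "' has value(s) outside {0, 1}: ",
           paste(unique(df[[y]][bad]), collapse = ", "))
  }
  if (x %in% names(df)) {
    bad <- !is.na(df[[x]]) & df[[x]] <= 0
    if (any(bad))
      stop("validation error: exposure '", x, "' must be > 0 where present")
  }
  for (v in intersect(schema$name[schema$kind == "binary"], names(df))) {
    ok <- df[[v]] %in% c(0, 1) | is.na(df[[v]])
    if (!all(ok))
      stop("validation error: binary column '", v, "' has non-0/1 values")
  }
  structure(as.data.frame(df), schema = schema, n = nrow(df),
            class = c("cohort", "data.frame"))
}

cohort_schema_of <- function(tab) {
  sch <- attr(tab, "schema")
  if (is.null(sch)) default_schema() else sch
}

#' Exclusion criteria for cohort filtering
#'
#' The elderly-sepsis inclusion rules: age at least \code{min_age} years, an
#' ICU stay of at least \code{min_icu_hours} hours, a sepsis diagnosis flag
#' when \code{require_sepsis_flag}, and at least
#' \code{min_exposure_measurements} lactate measurements in the first 24 h.
#'
#' @param min_age minimum age in years (default 65).
#' @param min_icu_hours minimum ICU length of stay in hours (default 24).
#' @param require_sepsis_flag require \code{sepsis_flag == 1} (default TRUE).
#' @param min_exposure_measurements minimum exposure measurement count
#'   (default 1).
#' @return An \code{exclusion_criteria} list.
#' @export
exclusion_criteria <- function(min_age = 65, min_icu_hours = 24,
                               require_sepsis_flag = TRUE,
                               min_exposure_measurements = 1) {
  stopifnot(min_age >= 0, min_icu_hours >= 0, min_exposure_measurements >= 0)
  structure(list(min_age = min_age, min_icu_hours = min_icu_hours,
                 require_sepsis_flag = isTRUE(require_sepsis_flag),
                 min_exposure_measurements = min_exposure_measurements),
            class = "exclusion_criteria")
}

#' Apply exclusion criteria sequentially
#'
#' Filters the cohort in the fixed order age, ICU stay, sepsis flag,
#' exposure-measurement count, attributing each removed row to the first
#' criterion it fails (flow-chart accounting: removal counts plus retained n
#' always reconstruct the input n). Rows with a missing value in a filter
#' column fail that criterion. The operation is idempotent.
#'
#' @param tab a cohort data frame.
#' @param criteria an [exclusion_criteria()] list.
#' @return A list with \code{cohort} (retained rows), \code{removed} (named
#'   per-criterion counts), \code{n_before}, \code{n_after}.
#' @export
apply_exclusions <- function(tab, criteria = exclusion_criteria()) {
  need <- c("age", "icu_los_hours")
  if (criteria$require_sepsis_flag) need <- c(need, "sepsis_flag")
  if (criteria$min_exposure_measurements > 0)
    need <- c(need, "lactate_n_measurements")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("schema error: exclusion filter column(s) absent: ",
         paste(miss, collapse = ", "))

  fails <- list(
    under_age = is.na(tab$age) | tab$age < criteria$min_age,
    short_stay = is.na(tab$icu_los_hours) |
      tab$icu_los_hours < criteria$min_icu_hours,
    no_sepsis = if (criteria$require_sepsis_flag)
      is.na(tab$sepsis_flag) | tab$sepsis_flag != 1 else rep(FALSE, nrow(tab)),
    no_exposure = if (criteria$min_exposure_measurements > 0)
      is.na(tab$lactate_n_measurements) |
        tab$lactate_n_measurements < criteria$min_exposure_measurements
      else rep(FALSE, nrow(tab))
  )
  removed <- integer(length(fails))
  names(removed) <- names(fails)
  alive <- rep(TRUE, nrow(tab))
  for (k in names(fails)) {
    hit <- alive & fails[[k]]
    removed[[k]] <- sum(hit)
    alive <- alive & !hit
  }
  out <- as_cohort(tab[alive, , drop = FALSE], cohort_schema_of(tab))
  list(cohort = out, removed = removed,
       n_before = nrow(tab), n_after = nrow(out))
}

col_mode <- function(x) {
  x <- x[!is.na(x)]
  tb <- sort(table(x), decreasing = TRUE)
  v <- names(tb)[1]
  if (is.numeric(x)) as.numeric(v) else v
}

#' Median/mode imputation of covariates
#'
#' Continuous covariate missings are replaced by the column median of the
#' observed values (even counts use the mean of the two central order
#' statistics, the \code{stats::median} convention); binary and categorical
#' missings by the observed mode. Exposure, outcome and administrative
#' columns are never imputed; observed cells are left untouched.
#'
#' @param tab a cohort data frame.
#' @param schema a schema; defaults to the cohort's own.
#' @return The imputed cohort, with an \code{imputed_counts} attribute naming
#'   how many cells were filled per column.
#' @export
impute_median <- function(tab, schema = cohort_schema_of(tab)) {
  cols <- intersect(covariate_vars(schema), names(tab))
  filled <- integer(0)
  for (v in cols) {
    x <- tab[[v]]
    nmiss <- sum(is.na(x))
    if (nmiss == 0) next
    if (all(is.na(x)))
      stop("unimputable error: column '", v, "' has no observed values")
    kind <- schema$kind[schema$name == v]
    fill <- if (kind == "continuous") stats::median(x, na.rm = TRUE)
            else col_mode(x)
    x[is.na(x)] <- fill
    tab[[v]] <- x
    filled[v] <- nmiss
  }
  out <- as_cohort(tab, schema)
  attr(out, "imputed_counts") <- filled
  out
}

#' Empirical quartile binning of the exposure
#'
#' Cutpoints are the empirical 25/50/75 percentiles of the observed exposure
#' (default quantile definition, linear interpolation of order statistics).
#' Intervals are left-closed/right-open except the last: [min, q25),
#' [q25, q50), [q50, q75), [q75, max]. The printed range labels of grouped
#' reports round these cutpoints; the bins themselves are contiguous.
#'
#' @param tab a cohort data frame (or numeric exposure vector).
#' @param exposure exposure column name when \code{tab} is a data frame.
#' @return A list with \code{cutpoints} (named q25/q50/q75), \code{labels}
#'   (Q1..Q4), \code{bin} (per-row factor), \code{group_n}.
#' @export
quartile_bin <- function(tab, exposure = NULL) {
  x <- if (is.data.frame(tab)) {
    if (is.null(exposure)) exposure <- exposure_var(cohort_schema_of(tab))
    tab[[exposure]]
  } else as.numeric(tab)
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 4)
    stop("degenerate-binning error: exposure has fewer than 4 distinct values")
  q <- stats::quantile(obs, c(0.25, 0.5, 0.75), names = FALSE)
  if (any(diff(q) <= 0))
    stop("degenerate-binning error: quartile cutpoints are not strictly increasing")
  labels <- c("Q1", "Q2", "Q3", "Q4")
  idx <- findInterval(x, q) + 1L  # 1..4; NA propagates
  bin <- factor(labels[idx], levels = labels)
  list(cutpoints = c(q25 = q[1], q50 = q[2], q75 = q[3]),
       labels = labels, bin = bin,
       group_n = table(bin))
}

#' Write a cohort to CSV
#' @param tab a cohort data frame.
#' @param path output file path.
#' @export
write_cohort <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "NA")
  invisible(path)
}
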