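#' Variable schema for heat-vulnerability indicators
#'
#' A variable schema is an ordered table of indicator names together with the
#' direction in which each indicator moves heat vulnerability. The direction
#' is used to orient rotated components so that "high score = high
#' vulnerability" holds for every component: rotated loadings have arbitrary
#' sign, and a protective indicator (such as open undeveloped land, which
#' buffers the urban heat island) must not be allowed to flip a component's
#' meaning.
#'
#' @param variables Character vector of indicator (column) names.
#' @param direction Character vector, one of `"vulnerability_increasing"` or
#'   `"vulnerability_decreasing"` per variable. Recycled if length 1.
#' @param type Character vector giving the value type per variable:
#'   `"percentage"` (bounded to \[0, 100\]) or `"density"` (non-negative,
#'   unbounded). Recycled if length 1.
#' @return A tibble of class `uc_schema` with columns `variable`,
#'   `direction`, `type`.
#' @examples
#' variable_schema(c("pct_poor", "pct_parkland"),
#'                 c("vulnerability_increasing", "vulnerability_decreasing"))
#' @export
variable_schema <- function(variables,
                            direction = "vulnerability_increasing",
                            type = "percentage") {
  stopifnot(is.character(variables), length(variables) >= 2)
  if (anyDuplicated(variables)) {
    stop("schema variable names must be unique: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "),
         call. = FALSE)
  }
  direction <- rep_len(direction, length(variables))
  type <- rep_len(type, length(variables))
  ok_dir <- c("vulnerability_increasing", "vulnerability_decreasing")
  if (!all(direction %in% ok_dir)) {
    stop("direction must be one of: ", paste(ok_dir, collapse = ", "),
         call. = FALSE)
  }
  if (!all(type %in% c("percentage", "density"))) {
    stop("type must be 'percentage' or 'density'", call. = FALSE)
  }
  out <- tibble::tibble(variable = variables, direction = direction,
                        type = type)
  class(out) <- c("uc_schema", class(out))
  out
}

#' Default 13-variable heat-vulnerability schema
#'
#' The standard indicator set for a tract-level heat vulnerability index:
#' nine sociodemographic percentages (Hispanic, Black, foreign-born, limited
#' English, below poverty, over 65, over 65 living alone, disability at ages
#' 18-64, unemployed at ages 18-64), the percentage of housing built before
#' 1980, housing-unit density per square mile, and the percentages of
#' high-intensity developed and of open undeveloped land. Open undeveloped
#' land is marked vulnerability-decreasing: it is the one indicator in the
#' set whose presence buffers, rather than amplifies, neighbourhood heat
#' risk.
#'
#' @return A `uc_schema` tibble with 13 rows.
#' @export
default_schema <- function() {
  variable_schema(
    variables = c(
      "pct_hispanic", "pct_black", "pct_foreign_born", "pct_limited_english",
      "pct_below_poverty", "pct_over65", "pct_over65_alone",
      "pct_disability_18_64", "pct_unemployed_18_64",
      "pct_housing_pre1980", "housing_density",
      "pct_high_intensity_developed", "pct_open_undeveloped"
    ),
    direction = c(rep("vulnerability_increasing", 12),
                  "vulnerability_decreasing"),
    type = c(rep("percentage", 10), "density", "percentage", "percentage")
  )
}

assert_schema <- function(schema) {
  if (!inherits(schema, "uc_schema")) {
    stop("`schema` must be created with variable_schema() or default_schema()",
         call. = FALSE)
  }
  invisible(schema)
}

#' Validate a tract variable table against a schema
#'
#' Checks GEOID format and uniqueness, presence and numeric type of every
#' schema column, percentage ranges and density non-negativity. Missing
#' values are rejected by default; `impute = "median"` replaces them with the
#' per-variable cohort median (each imputation is reported via [message()]),
#' which suits exploratory runs but should not feed a published index
#' silently.
#'
#' @param data A data frame with a `tract_id` column plus one numeric column
#'   per schema variable.
#' @param schema A `uc_schema`; default [default_schema()].
#' @param impute `"none"` (default: any missing value is an error) or
#'   `"median"`.
#' @return A validated tibble with `tract_id` first and columns in schema
#'   order.
#' @export
validate_tract_table <- function(data, schema = default_schema(),
                                 impute = c("none", "median")) {
  assert_schema(schema)
  impute <- match.arg(impute)
  data <- tibble::as_tibble(data)
  if (!"tract_id" %in% names(data)) {
    stop("tract table must have a 'tract_id' column", call. = FALSE)
  }
  missing_cols <- setdiff(schema$variable, names(data))
  if (length(missing_cols)) {
    stop("tract table is missing schema column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$tract_id <- assert_geoid(data$tract_id, width = 11L, what = "tract_id")
  if (anyDuplicated(data$tract_id)) {
    stop("duplicate tract_id: ",
         paste(unique(data$tract_id[duplicated(data$tract_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (v in schema$variable) {
    col <- data[[v]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))) &
                     !is.na(col))
      stop("column '", v, "' is not numeric (first bad row: ",
           if (length(bad)) bad[1] else "?", ")", call. = FALSE)
    }
    if (anyNA(col)) {
      if (impute == "median") {
        med <- stats::median(col, na.rm = TRUE)
        n_imp <- sum(is.na(col))
        message("imputing ", n_imp, " missing value(s) in '", v,
                "' with median ", format(med))
        col[is.na(col)] <- med
        data[[v]] <- col
      } else {
        stop("column '", v, "' has ", sum(is.na(col)),
             " missing value(s); rerun with impute = 'median' to fill them",
             call. = FALSE)
      }
    }
    ty <- schema$type[schema$variable == v]
    if (ty == "percentage" && (any(col < 0) || any(col > 100))) {
      stop("column '", v, "' outside the percentage range [0,100] (row ",
           which(col < 0 | col > 100)[1], ")", call. = FALSE)
    }
    if (ty == "density" && any(col < 0)) {
      stop("column '", v, "' must be non-negative (row ",
           which(col < 0)[1], ")", call. = FALSE)
    }
  }
  dplyr::select(data, "tract_id", dplyr::all_of(schema$variable))
}

# GEOIDs are fixed-width FIPS strings; leading zeros are significant.
assert_geoid <- function(x, width, what) {
  x <- as.character(x)
  bad <- nchar(x) != width | !grepl("^[0-9]+$", x)
  if (any(bad)) {
    stop(what, " must be a ", width, "-digit GEOID string (bad: ",
         paste(utils::head(x[bad], 3), collapse = ", "), ")", call. = FALSE)
  }
  x
}
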