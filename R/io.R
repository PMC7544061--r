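#' Read a census-tract indicator table from CSV
#'
#' Reads a comma-separated, UTF-8, header-first CSV emulating an ACS-style
#' extract. GEOIDs are read as strings so leading zeros survive, every schema
#' variable is required and range-checked, and columns are reordered to
#' schema order.
#'
#' @param path Path to the CSV file.
#' @param schema A `uc_schema`; default [default_schema()].
#' @param impute Missing-value handling, see [validate_tract_table()].
#' @return A validated tibble of tract indicators.
#' @export
read_tract_table <- function(path, schema = default_schema(),
                             impute = c("none", "median")) {
  assert_file(path)
  raw <- readr::read_csv(path, col_types = readr::cols(
    tract_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  validate_tract_table(raw, schema, impute = match.arg(impute))
}

landcover_classes <- c("tree_canopy", "vegetation_grass_shrub",
                       "impervious", "building", "other")

#' Read a block-group land-cover table from CSV
#'
#' Expects columns `block_group_id` (12-digit GEOID), `class` (one of
#' `tree_canopy`, `vegetation_grass_shrub`, `impervious`, `building`,
#' `other`) and `area_sqft` (square feet, non-negative). The parent tract is
#' derived as the first 11 GEOID digits; a `tract_id` column, if present,
#' must agree with that prefix.
#'
#' @param path Path to the CSV file.
#' @return A tibble of land-cover records with columns `block_group_id`,
#'   `tract_id`, `class`, `area_sqft`.
#' @export
read_landcover <- function(path) {
  assert_file(path)
  raw <- readr::read_csv(path, col_types = readr::cols(
    block_group_id = readr::col_character(),
    class = readr::col_character(),
    area_sqft = readr::col_double(),
    .default = readr::col_character()  # optional tract_id stays a string
  ), progress = FALSE)
  validate_landcover(raw)
}

#' Validate land-cover records
#'
#' @param data Data frame of land-cover records (see [read_landcover()]).
#' @return A validated tibble.
#' @export
validate_landcover <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("block_group_id", "class", "area_sqft")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("land-cover table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$block_group_id <- assert_geoid(data$block_group_id, 12L,
                                      "block_group_id")
  derived_tract <- substr(data$block_group_id, 1L, 11L)
  if ("tract_id" %in% names(data) && !all(is.na(data$tract_id))) {
    data$tract_id <- assert_geoid(data$tract_id, 11L, "tract_id")
    bad <- data$tract_id != derived_tract
    if (any(bad)) {
      stop("tract_id does not prefix block_group_id (row ", which(bad)[1],
           ")", call. = FALSE)
    }
  } else {
    data$tract_id <- derived_tract
  }
  unknown <- setdiff(unique(data$class), landcover_classes)
  if (length(unknown)) {
    stop("unknown land-cover class(es): ", paste(unknown, collapse = ", "),
         "; accepted classes are: ",
         paste(landcover_classes, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data$area_sqft) || any(data$area_sqft < 0)) {
    stop("area_sqft must be non-negative and non-missing (row ",
         which(is.na(data$area_sqft) | data$area_sqft < 0)[1], ")",
         call. = FALSE)
  }
  key <- paste(data$block_group_id, data$class)
  if (anyDuplicated(key)) {
    stop("duplicate (block_group_id, class) pair: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  dplyr::select(data, "block_group_id", "tract_id", "class", "area_sqft")
}

#' Read tract-level mean summer land-surface temperature from CSV
#'
#' Expects columns `tract_id` (11-digit GEOID) and `mean_summer_lst`
#' (degrees Celsius).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `tract_id`, `mean_summer_lst`.
#' @export
read_lst <- function(path) {
  assert_file(path)
  raw <- readr::read_csv(path, col_types = readr::cols(
    tract_id = readr::col_character(),
    mean_summer_lst = readr::col_double()
  ), progress = FALSE)
  raw <- tibble::as_tibble(raw)
  missing_cols <- setdiff(c("tract_id", "mean_summer_lst"), names(raw))
  if (length(missing_cols)) {
    stop("LST table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$tract_id <- assert_geoid(raw$tract_id, 11L, "tract_id")
  if (anyDuplicated(raw$tract_id)) {
    stop("duplicate tract_id in LST table", call. = FALSE)
  }
  if (any(!is.finite(raw$mean_summer_lst))) {
    stop("mean_summer_lst must be finite (row ",
         which(!is.finite(raw$mean_summer_lst))[1], ")", call. = FALSE)
  }
  dplyr::select(raw, "tract_id", "mean_summer_lst")
}

species_columns <- c("species_name", "common_name", "canopy_spread_ft",
                     "height_ft", "light_requirement", "breakage_resistant",
                     "site_type", "allergenicity", "growth_rate",
                     "transpiration_rate", "leaf_area")

light_levels <- c("full_sun", "partial", "shade_tolerant")
allergenicity_levels <- c("low", "medium", "high")
growth_levels <- c("slow", "medium", "fast")

#' Read a tree-species attribute table from CSV
#'
#' One row per approved species with the attributes the selector filters on:
#' scientific and common name, canopy spread and height (feet), light
#' requirement (`full_sun` < `partial` < `shade_tolerant`, a tolerance
#' ordering), breakage resistance, suitable site types (`street`,
#' `park_yard`, or `street|park_yard`), pollen allergenicity (`low` <
#' `medium` < `high`), growth rate, and the two drivers of cooling
#' potential: relative transpiration rate and relative leaf area. A
#' `high_heat_reduction` column is optional on read; it is recomputed by
#' [flag_high_heat_reduction()].
#'
#' @param path Path to the CSV file.
#' @return A tibble of species records; `site_type` is a list-column of
#'   character vectors.
#' @export
read_species_table <- function(path) {
  assert_file(path)
  raw <- readr::read_csv(path, col_types = readr::cols(
    species_name = readr::col_character(),
    common_name = readr::col_character(),
    light_requirement = readr::col_character(),
    breakage_resistant = readr::col_logical(),
    site_type = readr::col_character(),
    allergenicity = readr::col_character(),
    growth_rate = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_species_table(raw)
}

#' Validate a species table
#'
#' @param data Data frame of species records (see [read_species_table()]).
#' @return A validated tibble with `site_type` as a list-column.
#' @export
validate_species_table <- function(data) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(species_columns, names(data))
  if (length(missing_cols)) {
    stop("species table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) {
    warning("species table is empty", call. = FALSE)
    data$site_type <- list()
    return(data)
  }
  if (anyDuplicated(data$species_name)) {
    stop("duplicate species_name: ",
         paste(unique(data$species_name[duplicated(data$species_name)]),
               collapse = ", "), call. = FALSE)
  }
  for (v in c("canopy_spread_ft", "height_ft", "transpiration_rate",
              "leaf_area")) {
    if (any(!is.finite(data[[v]]) | data[[v]] <= 0)) {
      stop("column '", v, "' must be positive (row ",
           which(!is.finite(data[[v]]) | data[[v]] <= 0)[1], ")",
           call. = FALSE)
    }
  }
  check_enum <- function(col, levels, name) {
    bad <- !data[[col]] %in% levels
    if (any(bad)) {
      stop("column '", name, "' has invalid value '",
           data[[col]][bad][1], "'; accepted: ",
           paste(levels, collapse = ", "), call. = FALSE)
    }
  }
  check_enum("light_requirement", light_levels, "light_requirement")
  check_enum("allergenicity", allergenicity_levels, "allergenicity")
  check_enum("growth_rate", growth_levels, "growth_rate")
  if (is.character(data$site_type)) {
    data$site_type <- strsplit(data$site_type, "\\|")
  }
  ok_site <- vapply(data$site_type, function(s) {
    length(s) > 0 && all(s %in% c("street", "park_yard"))
  }, logical(1))
  if (!all(ok_site)) {
    stop("site_type must be a non-empty subset of {street, park_yard} (row ",
         which(!ok_site)[1], ")", call. = FALSE)
  }
  if (anyNA(data$breakage_resistant)) {
    stop("breakage_resistant must be TRUE/FALSE", call. = FALSE)
  }
  data
}

#' Path to the packaged synthetic species fixture
#'
#' A 34-row table of tree species approved for urban planting. Scientific
#' names are real; every attribute value (spread, height, light, site,
#' allergenicity, transpiration, leaf area) is a plausible synthetic
#' placeholder, not authoritative horticultural data — selector output on
#' this fixture demonstrates the mechanics, not real species rankings.
#'
#' @return Path to the installed CSV.
#' @export
species_fixture_path <- function() {
  system.file("extdata", "boston_species_synthetic.csv",
              package = "urbancanopy", mustWork = TRUE)
}

assert_file <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  invisible(path)
}
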