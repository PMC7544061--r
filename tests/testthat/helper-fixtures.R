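# Small in-code fixtures shared across tests.

tiny_tract_ids <- function(n) paste0("25025", sprintf("%06d", seq_len(n)))

# a 5-tract table with hand-picked, in-range values for all 13 variables
tiny_tract_table <- function() {
  sch <- default_schema()
  set.seed(99)
  out <- tibble::tibble(tract_id = tiny_tract_ids(5))
  for (v in sch$variable) {
    out[[v]] <- if (v == "housing_density") {
      c(1200, 3400, 560, 7800, 2100)
    } else {
      round(runif(5, 5, 80), 1)
    }
  }
  out
}

tiny_landcover <- function() {
  tibble::tibble(
    block_group_id = c("250250000011", "250250000011", "250250000011",
                       "250250000011", "250250000011",
                       "250250000012", "250250000012", "250250000012",
                       "250250000012", "250250000012",
                       "250250000021", "250250000021", "250250000021",
                       "250250000021", "250250000021"),
    class = rep(c("tree_canopy", "vegetation_grass_shrub", "impervious",
                  "building", "other"), 3),
    area_sqft = c(1000, 2500, 4000, 2000, 500,
                  500, 1500, 5000, 2500, 500,
                  3000, 1000, 3000, 2500, 500)
  )
}

tiny_species <- function(n = 6) {
  tibble::tibble(
    species_name = paste("Genus species", seq_len(n)),
    common_name = paste("tree", seq_len(n)),
    canopy_spread_ft = seq(10, by = 10, length.out = n),
    height_ft = seq(20, by = 10, length.out = n),
    light_requirement = rep(c("full_sun", "partial", "shade_tolerant"),
                            length.out = n),
    breakage_resistant = rep(c(TRUE, FALSE), length.out = n),
    site_type = rep(c("street", "park_yard", "street|park_yard"),
                    length.out = n),
    allergenicity = rep(c("low", "medium", "high"), length.out = n),
    growth_rate = rep(c("slow", "medium", "fast"), length.out = n),
    transpiration_rate = seq(0.5, by = 0.5, length.out = n),
    leaf_area = rep(2, n)
  )
}

# random species table + random filter, for brute-force oracle comparisons
random_species_table <- function(n) {
  tibble::tibble(
    species_name = paste("Sp", seq_len(n)),
    common_name = paste("cn", seq_len(n)),
    canopy_spread_ft = round(runif(n, 5, 70), 1),
    height_ft = round(runif(n, 10, 90), 1),
    light_requirement = sample(c("full_sun", "partial", "shade_tolerant"),
                               n, replace = TRUE),
    breakage_resistant = sample(c(TRUE, FALSE), n, replace = TRUE),
    site_type = sample(c("street", "park_yard", "street|park_yard"),
                       n, replace = TRUE),
    allergenicity = sample(c("low", "medium", "high"), n, replace = TRUE),
    growth_rate = sample(c("slow", "medium", "fast"), n, replace = TRUE),
    transpiration_rate = round(runif(n, 0.2, 3), 2),
    leaf_area = round(runif(n, 0.2, 4), 2)
  )
}

random_filter <- function() {
  species_filter(
    max_canopy_spread_ft = if (runif(1) < 0.5) runif(1, 5, 70),
    light = if (runif(1) < 0.5)
      sample(c("full_sun", "partial", "shade_tolerant"), 1),
    site_type = if (runif(1) < 0.5) sample(c("street", "park_yard"), 1),
    max_allergenicity = if (runif(1) < 0.5)
      sample(c("low", "medium", "high"), 1),
    require_breakage_resistant = if (runif(1) < 0.5) TRUE,
    min_growth_rate = if (runif(1) < 0.5)
      sample(c("slow", "medium", "fast"), 1)
  )
}

# explicit per-record predicate, the independent oracle for filter_species
brute_force_filter <- function(records, f) {
  light_rank <- c(full_sun = 1, partial = 2, shade_tolerant = 3)
  allerg_rank <- c(low = 1, medium = 2, high = 3)
  growth_rank <- c(slow = 1, medium = 2, fast = 3)
  records <- validate_species_table(records)
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ok <- TRUE
    if (!is.null(f$max_canopy_spread_ft) &&
        r$canopy_spread_ft > f$max_canopy_spread_ft) ok <- FALSE
    if (!is.null(f$light) &&
        light_rank[r$light_requirement] < light_rank[f$light]) ok <- FALSE
    if (!is.null(f$site_type) && !f$site_type %in% r$site_type[[1]])
      ok <- FALSE
    if (!is.null(f$max_allergenicity) &&
        allerg_rank[r$allergenicity] > allerg_rank[f$max_allergenicity])
      ok <- FALSE
    if (isTRUE(f$require_breakage_resistant) && !r$breakage_resistant)
      ok <- FALSE
    if (!is.null(f$min_growth_rate) &&
        growth_rank[r$growth_rate] < growth_rank[f$min_growth_rate])
      ok <- FALSE
    keep[i] <- ok
  }
  records[keep, ]
}

write_temp_csv <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".csv")
  readr::write_csv(df, path)
  path
}
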