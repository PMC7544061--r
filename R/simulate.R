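#' Default planted loading matrix for synthetic cohorts
#'
#' Three latent dimensions mirror the structure a tract-level heat
#' vulnerability analysis typically recovers: (1) a sociodemographic factor
#' loading on the seven race/ethnicity, language, poverty, disability and
#' unemployment percentages; (2) an urbanicity factor loading positively on
#' pre-1980 housing, housing density and high-intensity development and
#' negatively on open undeveloped land (parkland is where urbanicity is
#' low); (3) an age-and-isolation factor loading on the two over-65
#' indicators.
#'
#' @return A 13 x 3 numeric matrix (variables x factors) with dimnames.
#' @export
default_loading_matrix <- function() {
  vars <- default_schema()$variable
  lambda <- matrix(0, nrow = 13, ncol = 3,
                   dimnames = list(vars, c("sociodemographic", "urbanicity",
                                           "age_isolation")))
  socio <- c("pct_hispanic", "pct_black", "pct_foreign_born",
             "pct_limited_english", "pct_below_poverty",
             "pct_disability_18_64", "pct_unemployed_18_64")
  urban <- c("pct_housing_pre1980", "housing_density",
             "pct_high_intensity_developed")
  age <- c("pct_over65", "pct_over65_alone")
  lambda[socio, "sociodemographic"] <- 0.85
  lambda[urban, "urbanicity"] <- 0.85
  lambda["pct_open_undeveloped", "urbanicity"] <- -0.80
  lambda[age, "age_isolation"] <- 0.85
  lambda
}

#' Specification of a synthetic tract cohort
#'
#' @param n_tracts Number of tracts (>= 10); default 500.
#' @param loading_matrix Planted variables x factors loading matrix; default
#'   [default_loading_matrix()].
#' @param noise_sd Standard deviation of the unique (variable-specific)
#'   Gaussian noise; default 0.1.
#' @param seed Integer seed.
#' @return A list of class `uc_cohort_spec`.
#' @export
cohort_spec <- function(n_tracts = 500, loading_matrix =
                          default_loading_matrix(), noise_sd = 0.1,
                        seed = 1) {
  loading_matrix <- as.matrix(loading_matrix)
  if (n_tracts < 10) stop("n_tracts must be >= 10", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (any(colSums(abs(loading_matrix)) == 0)) {
    stop("every factor must load on at least one variable", call. = FALSE)
  }
  if (is.null(rownames(loading_matrix))) {
    stop("loading_matrix needs variable rownames", call. = FALSE)
  }
  structure(list(n_tracts = as.integer(n_tracts),
                 loading_matrix = loading_matrix,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "uc_cohort_spec")
}

# per-variable location shifts so synthetic marginals sit at plausible
# levels rather than all centring on 50%
squash_shifts <- function(vars) {
  shifts <- c(pct_hispanic = -1.2, pct_black = -1.0, pct_foreign_born = -1.2,
              pct_limited_english = -1.6, pct_below_poverty = -1.3,
              pct_over65 = -1.8, pct_over65_alone = -2.2,
              pct_disability_18_64 = -2.0, pct_unemployed_18_64 = -2.3,
              pct_housing_pre1980 = 0.5, housing_density = 0,
              pct_high_intensity_developed = -1.0,
              pct_open_undeveloped = -1.5)
  out <- shifts[vars]
  out[is.na(out)] <- 0
  names(out) <- vars
  out
}

#' Generate a synthetic tract indicator cohort
#'
#' Draws independent standard-normal latent factors per tract, forms latent
#' variable values `loadings %*% factors + noise`, then maps each latent
#' value into its valid range through a documented monotone transform:
#' percentage variables through a shifted logistic, `100 * plogis(y +
#' shift)`, and density variables through an exponential,
#' `3000 * exp(0.8 * y)` (housing units per square mile). The squash
#' distorts correlations mildly but preserves ranks and produces
#' schema-valid tables. Identical seed, identical table.
#'
#' The pre-squash latent matrix and the factor draws are attached as
#' attributes `"latent"` and `"factors"` for calibration checks.
#'
#' @param spec A `uc_cohort_spec`.
#' @param schema A `uc_schema` describing the variable types; default
#'   [default_schema()].
#' @return A validated tract tibble with attributes `latent` and `factors`.
#' @export
generate_tract_cohort <- function(spec = cohort_spec(),
                                  schema = default_schema()) {
  stopifnot(inherits(spec, "uc_cohort_spec"))
  assert_schema(schema)
  vars <- rownames(spec$loading_matrix)
  if (!setequal(vars, schema$variable)) {
    stop("loading_matrix rownames must match the schema variables",
         call. = FALSE)
  }
  lambda <- spec$loading_matrix[schema$variable, , drop = FALSE]
  n <- spec$n_tracts
  set.seed(spec$seed)
  f <- matrix(stats::rnorm(n * ncol(lambda)), nrow = n)
  # plant the factors exactly: centre and whiten the draws so their sample
  # covariance is the identity, making the realized correlation structure
  # track lambda lambda' + sigma^2 I rather than it plus sampling noise
  f <- scale(f, center = TRUE, scale = FALSE)
  f <- f %*% backsolve(chol(stats::cov(f)), diag(ncol(f)))
  noise <- matrix(stats::rnorm(n * nrow(lambda), sd = spec$noise_sd),
                  nrow = n)
  latent <- f %*% t(lambda) + noise
  colnames(latent) <- schema$variable
  shifts <- squash_shifts(schema$variable)
  out <- tibble::tibble(tract_id = synthetic_tract_ids(n))
  for (v in schema$variable) {
    ty <- schema$type[schema$variable == v]
    out[[v]] <- if (ty == "percentage") {
      100 * stats::plogis(latent[, v] + shifts[v])
    } else {
      3000 * exp(0.8 * latent[, v])
    }
  }
  out <- validate_tract_table(out, schema)
  attr(out, "latent") <- latent
  attr(out, "factors") <- f
  out
}

synthetic_tract_ids <- function(n) {
  paste0("25025", sprintf("%06d", seq_len(n)))
}

#' Generate synthetic block-group land cover
#'
#' For each block group, a lognormal total area is split across the five
#' mutually exclusive cover classes by a Dirichlet draw, so class areas sum
#' to the block-group total exactly (up to floating point).
#'
#' @param tract_ids Character vector of 11-digit tract GEOIDs.
#' @param blockgroups_per_tract Block groups per tract (1-9); default 3.
#' @param class_mix Named positive Dirichlet concentrations over the five
#'   cover classes; the default mixes mostly impervious/building area with
#'   moderate canopy and vegetation, a dense-city profile.
#' @param total_meanlog,total_sdlog Lognormal parameters of block-group
#'   total area in square feet (default: median about 5 million sq ft).
#' @param seed Integer seed.
#' @return A validated land-cover tibble
#'   (`tract_ids x blockgroups_per_tract x 5` rows).
#' @export
generate_landcover <- function(tract_ids, blockgroups_per_tract = 3,
                               class_mix = c(tree_canopy = 2,
                                             vegetation_grass_shrub = 2,
                                             impervious = 3, building = 2,
                                             other = 1),
                               total_meanlog = log(5e6), total_sdlog = 0.4,
                               seed = 1) {
  if (length(tract_ids) == 0) stop("tract_ids is empty", call. = FALSE)
  stopifnot(blockgroups_per_tract >= 1, blockgroups_per_tract <= 9,
            setequal(names(class_mix), landcover_classes),
            all(class_mix > 0))
  set.seed(seed)
  bg_ids <- as.vector(vapply(tract_ids, function(t) {
    paste0(t, seq_len(blockgroups_per_tract))
  }, character(blockgroups_per_tract)))
  n_bg <- length(bg_ids)
  totals <- stats::rlnorm(n_bg, total_meanlog, total_sdlog)
  alpha <- class_mix[landcover_classes]
  # Dirichlet draw: independent gammas normalized to the simplex
  g <- matrix(stats::rgamma(n_bg * 5, shape = rep(alpha, each = n_bg)),
              nrow = n_bg)
  shares <- g / rowSums(g)
  areas <- shares * totals
  validate_landcover(tibble::tibble(
    block_group_id = rep(bg_ids, times = 5),
    class = rep(landcover_classes, each = n_bg),
    area_sqft = as.vector(areas)
  ))
}

#' Generate synthetic tract land-surface temperatures
#'
#' Emulates the cooling relationship that motivates canopy expansion: mean
#' summer LST falls linearly with canopy percentage,
#' `lst = baseline - slope * canopy_pct + noise`. With positive slope and
#' vanishing noise, LST is strictly decreasing in canopy.
#'
#' @param tract_ids Character vector of tract GEOIDs.
#' @param canopy_pct Canopy percentage per tract (same length).
#' @param baseline Intercept in degrees Celsius at zero canopy; default 35
#'   (a mid-morning summer surface in a dense city).
#' @param slope Cooling per canopy percentage point, degrees C; default 0.1.
#' @param noise_sd Gaussian noise SD in degrees C; default 1.
#' @param seed Integer seed.
#' @return A tibble with `tract_id`, `mean_summer_lst`.
#' @export
generate_lst <- function(tract_ids, canopy_pct, baseline = 35, slope = 0.1,
                         noise_sd = 1, seed = 1) {
  stopifnot(length(tract_ids) == length(canopy_pct))
  set.seed(seed)
  noise <- if (noise_sd > 0) {
    stats::rnorm(length(tract_ids), sd = noise_sd)
  } else {
    rep(0, length(tract_ids))
  }
  tibble::tibble(tract_id = as.character(tract_ids),
                 mean_summer_lst = baseline - slope * canopy_pct + noise)
}

#' Generate synthetic square tract geometries
#'
#' Lays tracts out as a grid of square cells in WGS84 near the latitude of a
#' mid-latitude coastal city; areas are the planar cell areas converted to
#' square feet. Purely synthetic shapes for exercising the GeoJSON layer.
#'
#' @param tract_ids Character vector of tract GEOIDs.
#' @param origin Longitude/latitude of the grid's south-west corner.
#' @param cell_deg Cell edge length in degrees; default 0.01.
#' @return A `uc_geometry` tibble.
#' @export
generate_tract_geometries <- function(tract_ids, origin = c(-71.10, 42.30),
                                      cell_deg = 0.01) {
  n <- length(tract_ids)
  ncol_grid <- ceiling(sqrt(n))
  m_per_deg_lat <- 110574
  m_per_deg_lon <- 111320 * cos(origin[2] * pi / 180)
  area_m2 <- (cell_deg * m_per_deg_lat) * (cell_deg * m_per_deg_lon)
  area_sqft <- area_m2 * 10.7639
  geoms <- lapply(seq_len(n) - 1L, function(i) {
    x0 <- origin[1] + (i %% ncol_grid) * cell_deg
    y0 <- origin[2] + (i %/% ncol_grid) * cell_deg
    ring <- rbind(c(x0, y0), c(x0 + cell_deg, y0),
                  c(x0 + cell_deg, y0 + cell_deg), c(x0, y0 + cell_deg),
                  c(x0, y0))
    list(type = "Polygon", coordinates = list(ring))
  })
  tract_geometry(tract_ids, geoms, rep(area_sqft, n))
}

#' Generate the full synthetic input bundle
#'
#' Produces every input the pipeline consumes — tract indicators, block-group
#' land cover, tract LST (coupled to the generated existing-canopy
#' percentage so heat and canopy anti-correlate as in real cities), square
#' tract geometries, and the packaged synthetic species table. One integer
#' seed governs all generators through derived sub-seeds, so bundles compose
#' reproducibly.
#'
#' @param seed Integer master seed.
#' @param n_tracts Number of tracts; default 500.
#' @param noise_sd Unique-noise SD for the indicator cohort; default 0.1.
#' @param lst_slope,lst_noise_sd Parameters of the LST generator.
#' @param blockgroups_per_tract Block groups per tract; default 3.
#' @param dir If non-NULL, the bundle is also written there as
#'   `tracts.csv`, `landcover.csv`, `lst.csv`, `tracts.geojson`,
#'   `species.csv` and a `config.yaml` capturing the generation settings.
#' @return A list with elements `tracts`, `landcover`, `lst`, `geometries`,
#'   `species`, invisibly if `dir` is given.
#' @export
simulate_inputs <- function(seed = 1, n_tracts = 500, noise_sd = 0.1,
                            lst_slope = 0.1, lst_noise_sd = 1,
                            blockgroups_per_tract = 3, dir = NULL) {
  set.seed(seed)
  sub <- sample.int(2^31 - 1, 3)
  tracts <- generate_tract_cohort(
    cohort_spec(n_tracts = n_tracts, noise_sd = noise_sd, seed = sub[1]))
  landcover <- generate_landcover(tracts$tract_id,
                                  blockgroups_per_tract =
                                    blockgroups_per_tract, seed = sub[2])
  canopy <- canopy_metrics(aggregate_to_tracts(landcover))
  canopy <- canopy[match(tracts$tract_id, canopy$tract_id), ]
  lst <- generate_lst(tracts$tract_id, canopy$existing_canopy_pct,
                      slope = lst_slope, noise_sd = lst_noise_sd,
                      seed = sub[3])
  geometries <- generate_tract_geometries(tracts$tract_id)
  species <- read_species_table(species_fixture_path())
  bundle <- list(tracts = tracts, landcover = landcover, lst = lst,
                 geometries = geometries, species = species)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(strip_attrs(tracts), file.path(dir, "tracts.csv"))
    readr::write_csv(landcover, file.path(dir, "landcover.csv"))
    readr::write_csv(lst, file.path(dir, "lst.csv"))
    sp_out <- species
    sp_out$site_type <- vapply(sp_out$site_type, paste, character(1),
                               collapse = "|")
    readr::write_csv(sp_out, file.path(dir, "species.csv"))
    write_tract_scores_geojson(geometries,
                               tibble::tibble(tract_id = tracts$tract_id),
                               file.path(dir, "tracts.geojson"))
    cfg <- default_config(dir, seed = seed)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    return(invisible(bundle))
  }
  bundle
}

strip_attrs <- function(x) {
  attr(x, "latent") <- NULL
  attr(x, "factors") <- NULL
  x
}
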