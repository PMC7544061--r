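#' Build a species filter
#'
#' All fields are optional; an empty filter matches every species. Light is
#' matched on a tolerance ordering (`full_sun` < `partial` <
#' `shade_tolerant`): a shade-tolerant tree satisfies any site's light
#' request, while a full-sun tree satisfies only full-sun sites. Growth rate
#' is ordered `slow` < `medium` < `fast` and filtered as a minimum.
#'
#' @param max_canopy_spread_ft Maximum canopy spread in feet (site space).
#' @param light Site light availability: `"full_sun"`, `"partial"`, or
#'   `"shade_tolerant"` (least light).
#' @param site_type `"street"` or `"park_yard"`.
#' @param max_allergenicity `"low"`, `"medium"`, or `"high"`.
#' @param require_breakage_resistant `TRUE` to keep only breakage-resistant
#'   species (lower maintenance).
#' @param min_growth_rate `"slow"`, `"medium"`, or `"fast"`.
#' @return A list of class `uc_species_filter`.
#' @export
species_filter <- function(max_canopy_spread_ft = NULL, light = NULL,
                           site_type = NULL, max_allergenicity = NULL,
                           require_breakage_resistant = NULL,
                           min_growth_rate = NULL) {
  if (!is.null(light)) light <- match.arg(light, light_levels)
  if (!is.null(site_type)) {
    site_type <- match.arg(site_type, c("street", "park_yard"))
  }
  if (!is.null(max_allergenicity)) {
    max_allergenicity <- match.arg(max_allergenicity, allergenicity_levels)
  }
  if (!is.null(min_growth_rate)) {
    min_growth_rate <- match.arg(min_growth_rate, growth_levels)
  }
  if (!is.null(max_canopy_spread_ft)) {
    stopifnot(is.numeric(max_canopy_spread_ft), max_canopy_spread_ft > 0)
  }
  structure(list(max_canopy_spread_ft = max_canopy_spread_ft,
                 light = light, site_type = site_type,
                 max_allergenicity = max_allergenicity,
                 require_breakage_resistant = require_breakage_resistant,
                 min_growth_rate = min_growth_rate),
            class = "uc_species_filter")
}

#' Filter the approved-species table by site constraints
#'
#' A species passes when it satisfies every set filter field (conjunction):
#' canopy spread no wider than the available space; light tolerance at least
#' the site's shade level; the requested site type among the species'
#' suitable sites; allergenicity at or below the cap (high-allergen
#' plantings can aggravate asthma, an environmental-health concern);
#' breakage resistance if required; growth rate at or above the minimum.
#' Input order is preserved; an empty result is valid.
#'
#' @param records A validated species table (see [read_species_table()]).
#' @param filter A `uc_species_filter`; default matches everything.
#' @return The subset of `records` passing the filter.
#' @export
filter_species <- function(records, filter = species_filter()) {
  stopifnot(inherits(filter, "uc_species_filter"))
  records <- validate_species_table(records)
  if (nrow(records) == 0) return(records)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(filter$max_canopy_spread_ft)) {
    keep <- keep & records$canopy_spread_ft <= filter$max_canopy_spread_ft
  }
  if (!is.null(filter$light)) {
    # tolerance ordering: a species tolerating deeper shade than the site
    # requires still thrives; one needing more light does not
    keep <- keep & (match(records$light_requirement, light_levels) >=
                      match(filter$light, light_levels))
  }
  if (!is.null(filter$site_type)) {
    keep <- keep & vapply(records$site_type,
                          function(s) filter$site_type %in% s, logical(1))
  }
  if (!is.null(filter$max_allergenicity)) {
    keep <- keep & (match(records$allergenicity, allergenicity_levels) <=
                      match(filter$max_allergenicity, allergenicity_levels))
  }
  if (isTRUE(filter$require_breakage_resistant)) {
    keep <- keep & records$breakage_resistant
  }
  if (!is.null(filter$min_growth_rate)) {
    keep <- keep & (match(records$growth_rate, growth_levels) >=
                      match(filter$min_growth_rate, growth_levels))
  }
  records[keep, , drop = FALSE]
}

#' Heat-reduction score of a species
#'
#' The cooling potential of a tree scales with how much water it moves and
#' how much leaf surface it does it through; the score is the product of
#' relative transpiration rate and relative leaf area.
#'
#' @param transpiration_rate,leaf_area Positive numeric vectors (relative
#'   units).
#' @return Positive numeric vector of scores.
#' @export
heat_reduction_score <- function(transpiration_rate, leaf_area) {
  if (any(!is.finite(transpiration_rate) | transpiration_rate <= 0) ||
      any(!is.finite(leaf_area) | leaf_area <= 0)) {
    stop("transpiration_rate and leaf_area must be positive", call. = FALSE)
  }
  transpiration_rate * leaf_area
}

#' Flag species with high heat-reduction potential
#'
#' Recomputes the heat-reduction score for every species and flags those at
#' or above the cohort quantile `q` of scores (default 0.75, roughly the top
#' quarter). Ties at the threshold flag `TRUE`, so identical-score tables
#' flag every species; the flag depends only on the score values, not on
#' record order.
#'
#' @param records A validated species table.
#' @param q Quantile cutoff in (0, 1); default 0.75.
#' @return `records` with `heat_reduction` (the score) and
#'   `high_heat_reduction` (logical) columns set.
#' @export
flag_high_heat_reduction <- function(records, q = 0.75) {
  records <- validate_species_table(records)
  stopifnot(nrow(records) >= 1, q > 0, q < 1)
  score <- heat_reduction_score(records$transpiration_rate,
                                records$leaf_area)
  thr <- stats::quantile(score, q, type = 7, names = FALSE)
  records$heat_reduction <- score
  records$high_heat_reduction <- score >= thr
  records
}

#' Plot species heat-reduction scores
#'
#' @param object A species table with the columns set by
#'   [flag_high_heat_reduction()] (applied first if absent).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_species_heat_reduction <- function(object, ...) {
  if (!"high_heat_reduction" %in% names(object)) {
    object <- flag_high_heat_reduction(object)
  }
  d <- object
  d$species_name <- stats::reorder(d$species_name, d$heat_reduction)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$heat_reduction,
                                  y = .data$species_name,
                                  fill = .data$high_heat_reduction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b7837",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "heat-reduction score (transpiration x leaf area)",
                  y = NULL, fill = "high potential") +
    ggplot2::theme_minimal()
}
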