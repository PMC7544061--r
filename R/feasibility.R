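#' Aggregate block-group land cover to census tracts
#'
#' Sums class areas over the block groups of each tract (block-group GEOIDs
#' extend their tract's GEOID by one digit, so the parent is the 11-digit
#' prefix). The sum is exact and order-invariant; tracts absent from the
#' input are absent from the output.
#'
#' @param records Validated land-cover records (see [read_landcover()]).
#' @return A tibble with `tract_id`, `class`, `area_sqft`, one row per
#'   (tract, class) present in the input.
#' @export
aggregate_to_tracts <- function(records) {
  records <- validate_landcover(records)
  records |>
    dplyr::group_by(.data$tract_id, .data$class) |>
    dplyr::summarise(area_sqft = sum(.data$area_sqft), .groups = "drop") |>
    dplyr::arrange(.data$tract_id, .data$class)
}

#' Existing and potential canopy per tract
#'
#' Potential canopy is the grass/shrub vegetation class — land plantable
#' today; impervious surface never counts as potential canopy. Existing
#' canopy is the tree-canopy class. Both are reported in square feet and as
#' a percentage of tract area, since tract sizes vary widely; tract area is
#' the sum of all land-cover classes so the percentages are internally
#' consistent with the land-cover table.
#'
#' @param tract_totals Per-(tract, class) totals from
#'   [aggregate_to_tracts()].
#' @return A tibble with `tract_id`, `existing_canopy_sqft`,
#'   `potential_canopy_sqft`, `impervious_sqft`, `total_sqft`,
#'   `existing_canopy_pct`, `potential_canopy_pct`.
#' @export
canopy_metrics <- function(tract_totals) {
  wide <- tidyr::pivot_wider(tract_totals, names_from = "class",
                             values_from = "area_sqft", values_fill = 0)
  for (cl in landcover_classes) {
    if (!cl %in% names(wide)) wide[[cl]] <- 0
  }
  total <- rowSums(as.matrix(wide[, landcover_classes]))
  if (any(total <= 0)) {
    stop("tract(s) with zero total land-cover area: ",
         paste(wide$tract_id[total <= 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    tract_id = wide$tract_id,
    existing_canopy_sqft = wide$tree_canopy,
    potential_canopy_sqft = wide$vegetation_grass_shrub,
    impervious_sqft = wide$impervious,
    total_sqft = total,
    existing_canopy_pct = 100 * wide$tree_canopy / total,
    potential_canopy_pct = 100 * wide$vegetation_grass_shrub / total
  ) |>
    dplyr::arrange(.data$tract_id)
}

#' Classify planting feasibility as high or low
#'
#' Canopy expansion is recommended where planting feasibility is high;
#' tracts with little plantable land get alternative heat-mitigation
#' recommendations instead. "High" defaults to a cohort-relative rule — a
#' tract is high-feasibility when its potential-canopy percentage is at or
#' above the cohort quantile `relative_q` (default 0.5, i.e. the top half of
#' tracts) — which is scale-free across cities; an absolute percentage
#' cutoff is available via `rule = "absolute"`. Ties at the threshold
#' classify as high, biasing toward the planting recommendation.
#'
#' @param summary A canopy summary from [canopy_metrics()].
#' @param rule `"relative"` (default) or `"absolute"`.
#' @param relative_q Cohort quantile defining "high" under the relative rule.
#' @param threshold_pct Absolute potential-canopy percentage cutoff under
#'   the absolute rule (in \[0, 100\]).
#' @return `summary` with a `feasibility` column (`"high"`/`"low"`).
#' @export
classify_feasibility <- function(summary, rule = c("relative", "absolute"),
                                 relative_q = 0.5, threshold_pct = NULL) {
  rule <- match.arg(rule)
  if (rule == "absolute") {
    if (is.null(threshold_pct) || threshold_pct < 0 || threshold_pct > 100) {
      stop("absolute rule needs threshold_pct in [0,100]", call. = FALSE)
    }
    thr <- threshold_pct
  } else {
    stopifnot(relative_q > 0, relative_q < 1)
    thr <- stats::quantile(summary$potential_canopy_pct, relative_q,
                           type = 7, names = FALSE)
  }
  summary$feasibility <- ifelse(summary$potential_canopy_pct >= thr,
                                "high", "low")
  attr(summary, "feasibility_threshold_pct") <- thr
  summary
}

#' Plot tract canopy composition
#'
#' @param object A canopy summary tibble from [canopy_metrics()] (with or
#'   without the feasibility column).
#' @param ... Unused.
#' @return A ggplot object: existing vs potential canopy percentage per
#'   tract.
#' @export
plot_canopy_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[, c("tract_id", "existing_canopy_pct", "potential_canopy_pct")],
    -"tract_id", names_to = "kind", values_to = "pct")
  d$kind <- ifelse(d$kind == "existing_canopy_pct", "existing", "potential")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tract_id, y = .data$pct,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(existing = "#1b7837",
                                          potential = "#a6dba0")) +
    ggplot2::labs(x = "tract", y = "% of tract area", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
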