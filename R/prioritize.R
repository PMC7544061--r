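#' Flag the upper tail of a cohort by quantile
#'
#' A tract is flagged when its value is at or above the empirical
#' `q`-quantile of the cohort, computed with the linear-interpolation
#' convention (`stats::quantile` type 7). The default q = 0.75 flags roughly
#' the top quarter.
#'
#' @param values Numeric vector (one value per tract).
#' @param q Quantile in (0, 1); default 0.75.
#' @return Logical vector, `TRUE` for flagged tracts.
#' @export
quantile_flag <- function(values, q = 0.75) {
  stopifnot(is.numeric(values), length(values) >= 2, q > 0, q < 1)
  if (length(unique(values)) < 2) {
    stop("all values identical; a quantile flag is degenerate — use an ",
         "absolute threshold instead", call. = FALSE)
  }
  values >= stats::quantile(values, q, type = 7, names = FALSE)
}

#' Prioritize tracts for tree planting
#'
#' Implements the region-selection rule of the decision framework: a tract
#' is a planting priority when it has high planting feasibility AND is
#' either highly heat-vulnerable or highly heat-exposed —
#' `priority = high_feasibility & (high_hvi | high_lst)`. Vulnerability
#' (HVI) and exposure (land surface temperature) are flagged separately and
#' never merged into one index: in cities where they anti-correlate, a
#' combined score would obscure two trends that decision-makers may weigh
#' differently. Tracts with low feasibility get
#' `alternative_interventions` (cool roofs, depaving, green roofs) rather
#' than `plant_trees`.
#'
#' @param hvi Tibble with `tract_id` and `hvi` (e.g. `tidy()` of a `uc_hvi`).
#' @param lst Tibble with `tract_id` and `mean_summer_lst`.
#' @param feasibility Tibble with `tract_id` and `feasibility`
#'   (`"high"`/`"low"`), from [classify_feasibility()].
#' @param q_hvi,q_lst Cohort quantiles defining "high" vulnerability and
#'   "high" exposure (default 0.75 each).
#' @return A tibble with `tract_id`, the three boolean flags, `priority`,
#'   and `recommendation`.
#' @export
prioritize_tracts <- function(hvi, lst, feasibility,
                              q_hvi = 0.75, q_lst = 0.75) {
  sets <- list(hvi = hvi$tract_id, lst = lst$tract_id,
               feasibility = feasibility$tract_id)
  all_ids <- sort(unique(unlist(sets)))
  missing <- lapply(sets, function(s) setdiff(all_ids, s))
  if (any(lengths(missing) > 0)) {
    bad <- unlist(lapply(names(missing), function(nm) {
      if (length(missing[[nm]]))
        paste0(nm, " lacks: ", paste(missing[[nm]], collapse = ", "))
    }))
    stop("inputs cover different tract sets — ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  d <- hvi[, c("tract_id", "hvi")] |>
    dplyr::inner_join(lst[, c("tract_id", "mean_summer_lst")],
                      by = "tract_id") |>
    dplyr::inner_join(feasibility[, c("tract_id", "feasibility")],
                      by = "tract_id")
  d$high_hvi <- quantile_flag(d$hvi, q_hvi)
  d$high_lst <- quantile_flag(d$mean_summer_lst, q_lst)
  d$high_feasibility <- d$feasibility == "high"
  d$priority <- d$high_feasibility & (d$high_hvi | d$high_lst)
  d$recommendation <- ifelse(d$high_feasibility, "plant_trees",
                             "alternative_interventions")
  tibble::as_tibble(d[, c("tract_id", "high_hvi", "high_lst",
                          "high_feasibility", "priority",
                          "recommendation")])
}

#' Plot the priority decision per tract
#'
#' @param object A tibble from [prioritize_tracts()].
#' @param ... Unused.
#' @return A ggplot object showing flag combinations and the resulting
#'   priority.
#' @export
plot_priority <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[, c("tract_id", "high_hvi", "high_lst", "high_feasibility",
               "priority")],
    -"tract_id", names_to = "flag", values_to = "value")
  d$flag <- factor(d$flag, levels = c("high_hvi", "high_lst",
                                      "high_feasibility", "priority"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flag, y = .data$tract_id,
                                  fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey95")) +
    ggplot2::labs(x = NULL, y = "tract", fill = "flag") +
    ggplot2::theme_minimal()
}
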