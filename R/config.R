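#' Default run configuration
#'
#' A plain list, serializable as YAML, holding every setting of the
#' end-to-end pipeline: input paths, the variable schema, component
#' retention, the score-standardization reading, bin behaviour is fixed (see
#' [categorize_score()]), "high" quantiles for vulnerability and heat,
#' the feasibility rule, the heat-reduction quantile, the seed and the
#' output directory. Every default is echoed into the run manifest so a run
#' is auditable from its outputs alone.
#'
#' @param input_dir Directory holding `tracts.csv`, `landcover.csv`,
#'   `lst.csv`, `tracts.geojson`, `species.csv` (as written by
#'   [simulate_inputs()]).
#' @param output_dir Where pipeline outputs go; default
#'   `file.path(input_dir, "out")`.
#' @param seed Integer seed recorded for provenance.
#' @return A nested list.
#' @export
default_config <- function(input_dir, output_dir = file.path(input_dir,
                                                             "out"),
                           seed = 1) {
  sch <- default_schema()
  list(
    inputs = list(
      tracts = file.path(input_dir, "tracts.csv"),
      landcover = file.path(input_dir, "landcover.csv"),
      lst = file.path(input_dir, "lst.csv"),
      geometries = file.path(input_dir, "tracts.geojson"),
      species = file.path(input_dir, "species.csv")
    ),
    schema = list(variables = sch$variable, direction = sch$direction,
                  type = sch$type),
    hvi = list(retention = "kaiser", k = NULL, loading_threshold = 0,
               score_standardization = "sum", impute = "none"),
    priority = list(q_hvi = 0.75, q_lst = 0.75),
    feasibility = list(rule = "relative", relative_q = 0.5,
                       threshold_pct = NULL),
    species = list(heat_reduction_q = 0.75),
    seed = as.integer(seed),
    output_dir = output_dir
  )
}

#' Read a run configuration from YAML
#'
#' Missing sections fall back to the defaults of [default_config()].
#'
#' @param path Path to a YAML config.
#' @return A nested config list.
#' @export
read_config <- function(path) {
  assert_file(path)
  cfg <- yaml::read_yaml(path)
  base <- default_config(input_dir = dirname(path))
  merge_config(base, cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

config_schema <- function(cfg) {
  variable_schema(unlist(cfg$schema$variables),
                  unlist(cfg$schema$direction),
                  unlist(cfg$schema$type))
}
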