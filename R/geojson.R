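#' Tract geometries
#'
#' Geometries are carried as a tibble with columns `tract_id`, `area_sqft`
#' and `geometry`, where `geometry` is a list-column: each element is a list
#' with `type` (`"Polygon"` or `"MultiPolygon"`) and `coordinates` following
#' the GeoJSON nesting (rings are n-by-2 matrices of longitude, latitude in
#' WGS84; first and last vertex coincide).
#'
#' @param tract_id Character vector of 11-digit GEOIDs.
#' @param geometry List of geometry elements as described above.
#' @param area_sqft Positive tract areas in square feet.
#' @return A tibble of class `uc_geometry`.
#' @export
tract_geometry <- function(tract_id, geometry, area_sqft) {
  tract_id <- assert_geoid(tract_id, 11L, "tract_id")
  if (anyDuplicated(tract_id)) stop("duplicate tract_id", call. = FALSE)
  stopifnot(length(geometry) == length(tract_id),
            length(area_sqft) == length(tract_id), all(area_sqft > 0))
  for (g in geometry) {
    if (!is.list(g) || !g$type %in% c("Polygon", "MultiPolygon")) {
      stop("geometry elements must be Polygon or MultiPolygon lists",
           call. = FALSE)
    }
    rings <- if (g$type == "Polygon") g$coordinates else
      unlist(g$coordinates, recursive = FALSE)
    for (r in rings) {
      r <- as.matrix(r)
      if (ncol(r) != 2 || nrow(r) < 4 ||
          !isTRUE(all.equal(r[1, ], r[nrow(r), ]))) {
        stop("rings must be closed n-by-2 coordinate matrices (n >= 4)",
             call. = FALSE)
      }
    }
  }
  out <- tibble::tibble(tract_id = tract_id, geometry = geometry,
                        area_sqft = as.numeric(area_sqft))
  class(out) <- c("uc_geometry", class(out))
  out
}

#' Write scored tracts as a GeoJSON FeatureCollection
#'
#' Serializes one Feature per scored tract (RFC 7946, WGS84
#' longitude/latitude), carrying every column of `scores` other than
#' `tract_id` as a Feature property. This is the map layer a web front end
#' would render: HVI, per-component scores, land surface temperature, canopy
#' percentages, feasibility class and the priority flag travel together with
#' the polygon.
#'
#' @param geometries A `uc_geometry` tibble (see [tract_geometry()]).
#' @param scores A data frame keyed by `tract_id`; all other columns become
#'   properties. Every scored tract must have a geometry.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tract_scores_geojson <- function(geometries, scores, path) {
  scores <- tibble::as_tibble(scores)
  stopifnot("tract_id" %in% names(scores))
  orphans <- setdiff(scores$tract_id, geometries$tract_id)
  if (length(orphans)) {
    stop("scored tract(s) without geometry: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  geom_idx <- match(scores$tract_id, geometries$tract_id)
  features <- lapply(seq_len(nrow(scores)), function(i) {
    g <- geometries$geometry[[geom_idx[i]]]
    props <- as.list(scores[i, , drop = FALSE])
    props <- lapply(props, function(x) if (is.list(x)) x[[1]] else x)
    coords <- if (g$type == "Polygon") {
      lapply(g$coordinates, ring_to_list)
    } else {
      lapply(g$coordinates, function(poly) lapply(poly, ring_to_list))
    }
    list(type = "Feature",
         geometry = list(type = g$type, coordinates = coords),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

ring_to_list <- function(r) {
  r <- as.matrix(r)
  lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
}

#' Read a tract-score GeoJSON FeatureCollection
#'
#' Inverse of [write_tract_scores_geojson()]: returns the per-feature
#' properties as a tibble and the geometries as a `geometry` list-column in
#' the same nesting used by [tract_geometry()].
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble of properties with a `geometry` list-column.
#' @export
read_tract_scores_geojson <- function(path) {
  assert_file(path)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  props <- purrr::map(fc$features, function(f) {
    tibble::as_tibble(lapply(f$properties, function(x) {
      if (is.null(x)) NA else x
    }))
  })
  out <- dplyr::bind_rows(props)
  out$geometry <- purrr::map(fc$features, function(f) {
    g <- f$geometry
    coords <- if (g$type == "Polygon") {
      lapply(g$coordinates, list_to_ring)
    } else {
      lapply(g$coordinates, function(poly) lapply(poly, list_to_ring))
    }
    list(type = g$type, coordinates = coords)
  })
  out
}

list_to_ring <- function(ring) {
  do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
}
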