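#' Geometry parameters for market delineation
#'
#' Bundles every tunable of the market constructions with its default. All
#' distances are metres in a planar metric coordinate system; all percentiles
#' are fractions in (0, 1] interpreted with the nearest-rank rule
#' (keep ranks 1..ceiling(p * n) of the ascending distance ordering).
#'
#' @param fixed_radii_m radii of the fixed-radius markets, metres.
#' @param n_polygon_vertices vertex count of fixed-radius polygons (16 gives
#'   the hexadecagon approximation of a circle).
#' @param variable_radius_percentile fraction of a provider's nearest
#'   registered individuals the variable radius must capture.
#' @param outer_trim_percentile first-stage trim of the variable-shape
#'   construction: fraction of nearest registered individuals kept overall.
#' @param sector_trim_percentile second-stage trim: fraction of nearest
#'   individuals kept within each direction sector.
#' @param n_sectors number of equal direction sectors (8 gives 45-degree
#'   sectors with sector 1 spanning north to north-east).
#' @param concavity concavity level of the concave hull; larger values give
#'   simpler, more convex hulls.
#' @param length_threshold_m hull edges shorter than this are never dug
#'   inward, metres.
#' @param buffer_m outward buffer added around the finished variable-shape
#'   polygon so border coordinates fall inside the market, metres.
#' @param n_circle_vertices vertex count used when a variable-radius "circle"
#'   is drawn as a polygon (64 keeps the area error below 0.2%).
#' @return an object of class `geometry_params`.
#' @examples
#' geometry_params()
#' geometry_params(n_sectors = 16)
#' @export
geometry_params <- function(fixed_radii_m = c(1000, 3000),
                            n_polygon_vertices = 16L,
                            variable_radius_percentile = 0.55,
                            outer_trim_percentile = 0.80,
                            sector_trim_percentile = 0.70,
                            n_sectors = 8L,
                            concavity = 3,
                            length_threshold_m = 100,
                            buffer_m = 10,
                            n_circle_vertices = 64L) {
  stopifnot(
    all(fixed_radii_m > 0),
    n_polygon_vertices >= 3,
    n_circle_vertices >= 3,
    n_sectors >= 1, 360 %% n_sectors == 0,
    concavity > 0,
    length_threshold_m >= 0,
    buffer_m >= 0
  )
  for (p in c(variable_radius_percentile, outer_trim_percentile,
              sector_trim_percentile)) {
    if (!(p > 0 && p <= 1)) stop("percentiles must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      fixed_radii_m = as.numeric(fixed_radii_m),
      n_polygon_vertices = as.integer(n_polygon_vertices),
      variable_radius_percentile = variable_radius_percentile,
      outer_trim_percentile = outer_trim_percentile,
      sector_trim_percentile = sector_trim_percentile,
      n_sectors = as.integer(n_sectors),
      concavity = concavity,
      length_threshold_m = length_threshold_m,
      buffer_m = buffer_m,
      n_circle_vertices = as.integer(n_circle_vertices)
    ),
    class = "geometry_params"
  )
}

#' Market definitions
#'
#' The four market definitions handled by the package.
#' @return character vector of definition tags.
#' @export
market_definitions <- function() {
  c("fixed_1km", "fixed_3km", "variable_radius", "variable_shape")
}

#' Construct a market polygon object
#'
#' @param provider_id provider identifier.
#' @param definition one of [market_definitions()].
#' @param boundary vertex matrix (columns x, y), counter-clockwise, not closed.
#' @param degenerate flag set when a fallback geometry was used (too few or
#'   collinear points).
#' @param radius_m radius used, for radius-based definitions.
#' @return an object of class `market_polygon` with fields `provider_id`,
#'   `definition`, `boundary`, `area_km2`, `degenerate` and optionally
#'   `radius_m`.
#' @export
market_polygon <- function(provider_id, definition, boundary,
                           degenerate = FALSE, radius_m = NULL) {
  boundary <- ensure_ccw(as_point_matrix(boundary))
  if (nrow(boundary) < 3) stop("a market polygon needs at least 3 vertices", call. = FALSE)
  area <- polygon_area(boundary)
  if (area <= 0) stop("market polygon must have positive area", call. = FALSE)
  structure(
    list(
      provider_id = provider_id,
      definition = definition,
      boundary = boundary,
      area_km2 = area / 1e6,
      degenerate = isTRUE(degenerate),
      radius_m = radius_m
    ),
    class = "market_polygon"
  )
}

#' @export
print.market_polygon <- function(x, ...) {
  cat(sprintf(
    "<market_polygon> provider %s, %s: %d vertices, %.3f km2%s\n",
    format(x$provider_id), x$definition, nrow(x$boundary), x$area_km2,
    if (x$degenerate) " [degenerate fallback]" else ""
  ))
  invisible(x)
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("<geometry_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
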