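# Quartic-kernel density rasters of registered-individual locations, used to
# visualise a provider's actual catchment against its market polygons.

#' Quartic (biweight) kernel density raster
#'
#' Evaluates a 2-D quartic kernel density on a regular grid. The kernel is
#' `K(u) = (3 / pi) * (1 - u^2)^2` for `u = d / bandwidth <= 1` and zero
#' beyond, so each point contributes unit mass when `normalise = TRUE`
#' (densities integrate to the number of points). With `normalise = FALSE`
#' the raw kernel `(1 - u^2)^2` is accumulated, matching the raw heat values
#' of GIS heatmap tools.
#'
#' @param points point matrix or data frame (metres).
#' @param bandwidth_m kernel radius in metres.
#' @param cell_m raster cell size in metres.
#' @param extent `c(xmin, xmax, ymin, ymax)`; defaults to the point bounding
#'   box padded by one bandwidth.
#' @param normalise scale the kernel to unit mass per point.
#' @return a matrix of class `kde_raster` (rows = y from north to south,
#'   columns = x west to east) with attributes `extent`, `cell_m` and
#'   `bandwidth_m`.
#' @export
kde_heatmap <- function(points, bandwidth_m = 1000, cell_m = 250,
                        extent = NULL, normalise = TRUE) {
  stopifnot(bandwidth_m > 0, cell_m > 0)
  pts <- if (is.null(points) || NROW(points) == 0) {
    matrix(numeric(0), ncol = 2)
  } else {
    as_point_matrix(points)
  }
  if (is.null(extent)) {
    if (nrow(pts) == 0) stop("empty points need an explicit extent", call. = FALSE)
    extent <- c(min(pts[, 1]) - bandwidth_m, max(pts[, 1]) + bandwidth_m,
                min(pts[, 2]) - bandwidth_m, max(pts[, 2]) + bandwidth_m)
  }
  xs <- seq(extent[1] + cell_m / 2, extent[2], by = cell_m)
  ys <- seq(extent[3] + cell_m / 2, extent[4], by = cell_m)
  nx <- length(xs); ny <- length(ys)
  z <- matrix(0, nrow = ny, ncol = nx)
  scale <- if (normalise) 3 / (pi * bandwidth_m^2) else 1
  for (i in seq_len(nrow(pts))) {
    jx <- which(abs(xs - pts[i, 1]) <= bandwidth_m)
    jy <- which(abs(ys - pts[i, 2]) <= bandwidth_m)
    if (length(jx) == 0 || length(jy) == 0) next
    d2 <- outer((ys[jy] - pts[i, 2])^2, (xs[jx] - pts[i, 1])^2, "+")
    u2 <- d2 / bandwidth_m^2
    k <- ifelse(u2 <= 1, (1 - u2)^2, 0)
    z[jy, jx] <- z[jy, jx] + scale * k
  }
  # store rows north-to-south for raster-file conventions
  z <- z[rev(seq_len(ny)), , drop = FALSE]
  structure(z, class = c("kde_raster", "matrix"),
            extent = extent, cell_m = cell_m, bandwidth_m = bandwidth_m)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a `kde_raster` from [kde_heatmap()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(raster, path) {
  ext <- attr(raster, "extent")
  cell <- attr(raster, "cell_m")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(raster)),
    sprintf("nrows %d", nrow(raster)),
    sprintf("xllcorner %s", format(ext[1], scientific = FALSE)),
    sprintf("yllcorner %s", format(ext[3], scientific = FALSE)),
    sprintf("cellsize %s", format(cell, scientific = FALSE)),
    "NODATA_value -9999"
  ), con)
  utils::write.table(format(unclass(raster), digits = 6, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
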