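# Low-level planar polygon helpers shared by the market-delineation code.
# Polygons are numeric matrices with columns x, y, vertices in counter-clockwise
# order, not closed (the last vertex differs from the first). All coordinates
# are metres in a planar metric CRS.

#' Coerce point input to a two-column coordinate matrix
#'
#' Accepts a numeric vector of length 2, a matrix, or a data frame with `x`
#' and `y` columns. Used throughout the geometry layer.
#'
#' @param p points as vector, matrix or data frame.
#' @return a numeric matrix with columns `x` and `y`.
#' @keywords internal
as_point_matrix <- function(p) {
  if (is.data.frame(p)) {
    if (!all(c("x", "y") %in% names(p))) {
      stop("point data frame must have columns 'x' and 'y'", call. = FALSE)
    }
    m <- cbind(x = as.numeric(p$x), y = as.numeric(p$y))
  } else if (is.matrix(p)) {
    if (ncol(p) != 2) stop("point matrix must have two columns", call. = FALSE)
    m <- p
    colnames(m) <- c("x", "y")
    storage.mode(m) <- "double"
  } else if (is.numeric(p) && length(p) == 2) {
    m <- matrix(as.numeric(p), ncol = 2, dimnames = list(NULL, c("x", "y")))
  } else {
    stop("cannot interpret input as planar points", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("coordinates must be finite", call. = FALSE)
  m
}

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly vertex matrix (columns x, y), not closed.
#' @return signed area in square units of the input coordinates.
#' @keywords internal
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Unsigned polygon area
#' @inheritParams polygon_signed_area
#' @return area in square coordinate units.
#' @keywords internal
polygon_area <- function(poly) abs(polygon_signed_area(poly))

#' Force counter-clockwise vertex order
#' @inheritParams polygon_signed_area
#' @keywords internal
ensure_ccw <- function(poly) {
  if (polygon_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Boundary-inclusive point-in-polygon test
#'
#' Vertices and points on edges count as inside, consistent with the
#' convention that market borders belong to the market (the outward buffer
#' added to variable-shape markets exists precisely so border coordinates are
#' included).
#'
#' @param points points (vector, matrix or data frame; see [as_point_matrix]).
#' @param poly polygon vertex matrix.
#' @return logical vector, one element per point.
#' @export
point_in_polygon <- function(points, poly) {
  pts <- as_point_matrix(points)
  if (nrow(pts) == 0) return(logical(0))
  # sp codes: 0 outside, 1 inside, 2 on an edge, 3 on a vertex
  sp::point.in.polygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2]) > 0
}

# Proper-crossing test for segments (a1,a2) x (b1,b2); shared endpoints do not
# count as an intersection. Vectorised over b1/b2 rows.
segments_cross <- function(a1, a2, b1x, b1y, b2x, b2y) {
  orient <- function(px, py, qx, qy, rx, ry) {
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  d1 <- orient(a1[1], a1[2], a2[1], a2[2], b1x, b1y)
  d2 <- orient(a1[1], a1[2], a2[1], a2[2], b2x, b2y)
  d3 <- orient(b1x, b1y, b2x, b2y, a1[1], a1[2])
  d4 <- orient(b1x, b1y, b2x, b2y, a2[1], a2[2])
  shared <- (b1x == a1[1] & b1y == a1[2]) | (b1x == a2[1] & b1y == a2[2]) |
    (b2x == a1[1] & b2y == a1[2]) | (b2x == a2[1] & b2y == a2[2])
  !shared & ((d1 > 0) != (d2 > 0)) & ((d3 > 0) != (d4 > 0))
}

# Squared distance from points (px, py) to segment a-b; vectorised over points.
sq_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) {
    return((px - ax)^2 + (py - ay)^2)
  }
  t <- ((px - ax) * dx + (py - ay) * dy) / l2
  t <- pmin(1, pmax(0, t))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

#' Do two polygons intersect?
#'
#' Boundary contact counts: polygons that merely touch along an edge or at a
#' vertex are treated as intersecting, matching the convention used when
#' competitors are defined through overlapping local markets.
#'
#' @param a,b polygon vertex matrices.
#' @return `TRUE` if the polygons share at least one point.
#' @export
polygons_intersect <- function(a, b) {
  # fast bounding-box reject
  if (max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
      max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2])) {
    return(FALSE)
  }
  # vertex containment covers containment and most touch cases
  if (any(point_in_polygon(a, b)) || any(point_in_polygon(b, a))) return(TRUE)
  # interior overlap without vertex containment (crossing edges)
  inter <- polyclip::polyclip(
    list(list(x = a[, 1], y = a[, 2])),
    list(list(x = b[, 1], y = b[, 2])),
    op = "intersection"
  )
  length(inter) > 0
}

# Convert a polygon matrix to the list(x=, y=) form polyclip expects.
poly_to_list <- function(poly) list(x = poly[, 1], y = poly[, 2])

list_to_poly <- function(pl) {
  ensure_ccw(cbind(x = pl$x, y = pl$y))
}
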