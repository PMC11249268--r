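# Market-delineation geometry. Everything works on planar metric coordinates
# (e.g. SWEREF 99 TM); Euclidean distance is assumed valid throughout.

#' Distance capturing a given fraction of nearest individuals
#'
#' Rank-orders the Euclidean distances from a provider to its registered
#' individuals and returns the distance of the individual at rank
#' `ceiling(p * n)` — the radius needed to capture the `p` nearest share of
#' registrants. Distance ties are broken by stable input order.
#'
#' @param provider provider location (length-2 vector or 1-row matrix).
#' @param registered registered-individual locations (matrix or data frame
#'   with x, y).
#' @param p fraction in (0, 1].
#' @return distance in metres.
#' @examples
#' pts <- cbind(x = seq(100, 1000, by = 100), y = 0)
#' percentile_radius(c(0, 0), pts, 0.55) # 600
#' @export
percentile_radius <- function(provider, registered, p) {
  prov <- as_point_matrix(provider)
  pts <- as_point_matrix(registered)
  if (nrow(pts) == 0) stop("no registered individuals supplied", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1 || !(p > 0 && p <= 1)) {
    stop("p must be a single fraction in (0, 1]", call. = FALSE)
  }
  d <- sqrt((pts[, 1] - prov[1, 1])^2 + (pts[, 2] - prov[1, 2])^2)
  k <- ceiling(p * length(d))
  unname(sort(d, method = "radix")[k])
}

#' Regular polygon inscribed in a circle
#'
#' Vertices lie on the circle of the given radius, the first vertex due north
#' of the centre, ordered counter-clockwise. The enclosed area is
#' `(n / 2) * r^2 * sin(2 * pi / n)`.
#'
#' @param center centre point (length-2 vector or 1-row matrix).
#' @param radius circumradius in metres.
#' @param n_vertices number of vertices (>= 3); 16 gives the hexadecagon used
#'   for fixed-radius markets.
#' @return vertex matrix with columns x, y.
#' @examples
#' hexadecagon <- make_regular_polygon(c(0, 0), 1000, 16)
#' @export
make_regular_polygon <- function(center, radius, n_vertices = 16L) {
  ctr <- as_point_matrix(center)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("radius must be a single positive number", call. = FALSE)
  }
  if (n_vertices < 3) stop("a polygon needs at least 3 vertices", call. = FALSE)
  # bearings run counter-clockwise from due north so orientation is CCW
  theta <- -2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  cbind(x = ctr[1, 1] + radius * sin(theta),
        y = ctr[1, 2] + radius * cos(theta))
}

#' Direction sector of an individual relative to a provider
#'
#' Bearings are measured clockwise from due north; sector `k` covers the
#' half-open arc `[(k - 1) * 360 / n, k * 360 / n)` degrees. With the default
#' 8 sectors, sector 1 is the north-to-north-east wedge. Individuals
#' coincident with the provider have no bearing and get `NA` (callers keep
#' such individuals unconditionally).
#'
#' @param provider provider location.
#' @param individuals individual locations (vectorised).
#' @param n_sectors number of equal sectors dividing the full circle.
#' @return integer vector of sector ids in `1..n_sectors`, `NA` for
#'   coincident points.
#' @examples
#' sector_of(c(0, 0), c(500, 866), 8) # bearing 30 degrees -> sector 1
#' @export
sector_of <- function(provider, individuals, n_sectors = 8L) {
  prov <- as_point_matrix(provider)
  pts <- as_point_matrix(individuals)
  stopifnot(n_sectors >= 1)
  dx <- pts[, 1] - prov[1, 1]
  dy <- pts[, 2] - prov[1, 2]
  coincident <- dx == 0 & dy == 0
  bearing <- (atan2(dx, dy) * 180 / pi) %% 360
  sec <- as.integer(bearing %/% (360 / n_sectors)) + 1L
  sec[sec > n_sectors] <- n_sectors # guard against rounding at 360
  sec[coincident] <- NA_integer_
  sec
}

#' Per-sector trim of registered individuals
#'
#' Within each direction sector, rank-orders individuals by distance to the
#' provider and keeps ranks `1..ceiling(p * n_sector)`. Empty sectors
#' contribute nothing; individuals coincident with the provider are always
#' kept. The input is expected to be the already outer-trimmed subset of a
#' provider's registrants.
#'
#' @param provider provider location.
#' @param registered individual locations.
#' @param params a [geometry_params()] object (uses `n_sectors` and
#'   `sector_trim_percentile`).
#' @return the kept subset of `registered`, as a coordinate matrix.
#' @export
directional_trim <- function(provider, registered, params = geometry_params()) {
  pts <- as_point_matrix(registered)
  if (nrow(pts) == 0) return(pts)
  prov <- as_point_matrix(provider)
  sec <- sector_of(prov, pts, params$n_sectors)
  d <- sqrt((pts[, 1] - prov[1, 1])^2 + (pts[, 2] - prov[1, 2])^2)
  keep <- logical(nrow(pts))
  keep[is.na(sec)] <- TRUE
  for (s in unique(sec[!is.na(sec)])) {
    idx <- which(!is.na(sec) & sec == s)
    k <- ceiling(params$sector_trim_percentile * length(idx))
    keep[idx[order(d[idx])[seq_len(k)]]] <- TRUE
  }
  pts[keep, , drop = FALSE]
}

# Signalled when a point set is too small or collinear for hull construction.
stop_degenerate <- function(msg) {
  stop(structure(
    class = c("caremarkets_degenerate_geometry", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Concave hull of a point set (edge-digging algorithm)
#'
#' Starts from the convex hull and repeatedly digs hull edges inward toward
#' nearby interior points. An edge of squared length `L2` is dug toward the
#' interior point closest to it, provided the point is no closer to the two
#' adjacent hull edges, neither new edge would cross the existing boundary,
#' and the point lies within squared distance `L2 / concavity^2` of one of
#' the edge's endpoints. Edges shorter than `length_threshold` are never dug.
#' Higher concavity values therefore give simpler, more convex hulls; an
#' infinite length threshold reproduces the convex hull exactly.
#'
#' @param points point matrix or data frame (>= 3 non-collinear distinct
#'   points; duplicates are collapsed).
#' @param concavity relative concavity measure (> 0).
#' @param length_threshold edges shorter than this are left alone, metres.
#' @return vertex matrix of a simple polygon containing every input point on
#'   or inside its boundary.
#' @examples
#' set.seed(1)
#' pts <- cbind(x = runif(100, 0, 1000), y = runif(100, 0, 1000))
#' hull <- concave_hull(pts, concavity = 3, length_threshold = 100)
#' @export
concave_hull <- function(points, concavity = 3, length_threshold = 100) {
  stopifnot(concavity > 0, length_threshold >= 0)
  pts <- unique(as_point_matrix(points))
  if (nrow(pts) < 3) stop_degenerate("need at least 3 distinct points")
  hull_idx <- grDevices::chull(pts)
  if (length(hull_idx) < 3) stop_degenerate("points are collinear")
  hull_idx <- rev(hull_idx) # chull is clockwise; we keep CCW

  n <- nrow(pts)
  px <- pts[, 1]; py <- pts[, 2]
  # doubly linked list over point indices; only hull members have links
  nxt <- integer(n); prv <- integer(n)
  h <- length(hull_idx)
  nxt[hull_idx] <- hull_idx[c(2:h, 1)]
  prv[hull_idx] <- hull_idx[c(h, 1:(h - 1))]
  in_hull <- logical(n)
  in_hull[hull_idx] <- TRUE
  cand <- which(!in_hull)

  sq_conc <- concavity^2
  sq_len_thr <- length_threshold^2

  hull_edges <- function() {
    start <- hull_idx[1]
    out <- integer(sum(in_hull))
    i <- start
    for (k in seq_along(out)) {
      out[k] <- i
      i <- nxt[i]
    }
    out
  }

  # no proper crossing between segment (i -> candidate point q) and any hull edge
  no_intersections <- function(i, qx, qy, starts) {
    ax <- px[starts]; ay <- py[starts]
    bx <- px[nxt[starts]]; by <- py[nxt[starts]]
    !any(segments_cross(c(px[i], py[i]), c(qx, qy), ax, ay, bx, by))
  }

  queue <- hull_idx # FIFO of edge start nodes
  head <- 1L
  while (head <= length(queue)) {
    a <- queue[head]
    head <- head + 1L
    b <- nxt[a]
    sq_len <- (px[b] - px[a])^2 + (py[b] - py[a])^2
    if (sq_len < sq_len_thr || length(cand) == 0) next
    max_sq <- sq_len / sq_conc

    d2 <- sq_seg_dist(px[cand], py[cand], px[a], py[a], px[b], py[b])
    ord <- order(d2)
    ord <- ord[d2[ord] <= max_sq]
    chosen <- 0L
    if (length(ord) > 0) {
      starts <- hull_edges()
      pa <- prv[a]; nb <- nxt[b]
      for (j in ord) {
        q <- cand[j]
        # skip candidates closer to one of the adjacent edges
        if (d2[j] >= sq_seg_dist(px[q], py[q], px[pa], py[pa], px[a], py[a])) next
        if (d2[j] >= sq_seg_dist(px[q], py[q], px[b], py[b], px[nb], py[nb])) next
        if (!no_intersections(a, px[q], py[q], starts)) next
        if (!no_intersections(b, px[q], py[q], starts)) next
        chosen <- q
        break
      }
    }
    if (chosen > 0L) {
      da <- (px[chosen] - px[a])^2 + (py[chosen] - py[a])^2
      db <- (px[chosen] - px[b])^2 + (py[chosen] - py[b])^2
      if (min(da, db) <= max_sq) {
        # dig: a -> chosen -> b
        nxt[a] <- chosen
        prv[chosen] <- a
        nxt[chosen] <- b
        prv[b] <- chosen
        in_hull[chosen] <- TRUE
        cand <- cand[cand != chosen]
        queue <- c(queue, a, chosen)
      }
    }
  }

  out <- pts[hull_edges(), , drop = FALSE]
  ensure_ccw(out)
}

#' Buffer a polygon outward
#'
#' Minkowski dilation of a simple polygon by a disc of radius `d`, with round
#' joins (arcs approximated to a small tolerance). Every vertex of the input
#' lies strictly inside the result for `d > 0`.
#'
#' @param poly polygon vertex matrix.
#' @param d buffer distance in metres (>= 0).
#' @return buffered polygon vertex matrix.
#' @export
buffer_polygon <- function(poly, d) {
  if (!is.numeric(d) || length(d) != 1 || d < 0) {
    stop("buffer distance must be a single non-negative number", call. = FALSE)
  }
  poly <- as_point_matrix(poly)
  if (d == 0) return(poly)
  out <- polyclip::polyoffset(list(poly_to_list(poly)), d,
                              jointype = "round", arctol = d * 0.002)
  if (length(out) == 0) stop("buffering produced an empty polygon", call. = FALSE)
  # a simple input dilated outward yields a single outer ring; keep the largest
  areas <- vapply(out, function(p) abs(polygon_signed_area(cbind(p$x, p$y))), 0)
  list_to_poly(out[[which.max(areas)]])
}

#' Fixed-radius market polygon
#'
#' A regular polygon (by default the 16-gon circle approximation) of the given
#' radius around the provider, identical for all providers.
#'
#' @param provider one provider row (`provider_id`, `x`, `y`) or a list with
#'   those fields.
#' @param radius radius in metres.
#' @param params a [geometry_params()] object.
#' @param definition definition tag stored on the result; defaults to
#'   `fixed_<r>km` derived from the radius.
#' @return a [market_polygon()].
#' @export
fixed_radius_market <- function(provider, radius, params = geometry_params(),
                                definition = NULL) {
  loc <- c(provider$x, provider$y)
  if (is.null(definition)) {
    definition <- sprintf("fixed_%gkm", radius / 1000)
  }
  market_polygon(
    provider_id = provider$provider_id,
    definition = definition,
    boundary = make_regular_polygon(loc, radius, params$n_polygon_vertices),
    radius_m = radius
  )
}

#' Variable-radius market polygon
#'
#' The radius is the distance capturing the provider's nearest
#' `variable_radius_percentile` share of registered individuals
#' (see [percentile_radius()]); the circle is drawn as a regular polygon with
#' `n_circle_vertices` vertices.
#'
#' @inheritParams fixed_radius_market
#' @param registered locations of the provider's registered individuals.
#' @return a [market_polygon()] with definition `"variable_radius"`.
#' @export
variable_radius_market <- function(provider, registered,
                                   params = geometry_params()) {
  pts <- as_point_matrix(registered)
  if (nrow(pts) == 0) {
    stop_degenerate("provider has no registered individuals")
  }
  loc <- c(provider$x, provider$y)
  r <- percentile_radius(loc, pts, params$variable_radius_percentile)
  if (r <= 0) {
    # all captured individuals coincide with the provider; use a minimal disc
    return(market_polygon(
      provider$provider_id, "variable_radius",
      make_regular_polygon(loc, params$buffer_m, params$n_circle_vertices),
      degenerate = TRUE, radius_m = params$buffer_m
    ))
  }
  market_polygon(
    provider$provider_id, "variable_radius",
    make_regular_polygon(loc, r, params$n_circle_vertices),
    radius_m = r
  )
}

#' Variable-shape market polygon
#'
#' The two-step construction: keep the provider's nearest
#' `outer_trim_percentile` share of registered individuals; within each
#' direction sector keep the nearest `sector_trim_percentile` share; append
#' the provider's own coordinate; take the concave hull (edge digging with
#' the configured concavity and length threshold); buffer outward by
#' `buffer_m`. If the surviving point set is too small or collinear for a
#' hull, a fallback is used (buffered convex hull of the points plus
#' provider, or a disc of radius `buffer_m` around the provider) and the
#' result is flagged degenerate.
#'
#' @inheritParams variable_radius_market
#' @return a [market_polygon()] with definition `"variable_shape"`.
#' @export
variable_shape_market <- function(provider, registered,
                                  params = geometry_params()) {
  pts <- as_point_matrix(registered)
  if (nrow(pts) == 0) stop_degenerate("provider has no registered individuals")
  loc <- c(provider$x, provider$y)

  # step 1: overall trim to the nearest outer share
  d <- sqrt((pts[, 1] - loc[1])^2 + (pts[, 2] - loc[2])^2)
  k <- ceiling(params$outer_trim_percentile * length(d))
  kept <- pts[order(d)[seq_len(k)], , drop = FALSE]

  # step 2: per-sector trim, then add the provider coordinate
  kept <- directional_trim(loc, kept, params)
  coords <- rbind(kept, matrix(loc, ncol = 2))

  hull <- tryCatch(
    concave_hull(coords, params$concavity, params$length_threshold_m),
    caremarkets_degenerate_geometry = function(e) NULL
  )
  if (!is.null(hull)) {
    return(market_polygon(
      provider$provider_id, "variable_shape",
      buffer_polygon(hull, params$buffer_m)
    ))
  }

  # fallback: buffered convex hull of whatever we have (degenerate sets
  # collapse to a segment or point; polyline/point dilation covers those)
  u <- unique(coords)
  boundary <- if (nrow(u) == 1) {
    make_regular_polygon(u[1, ], params$buffer_m, params$n_circle_vertices)
  } else {
    ch <- grDevices::chull(u)
    if (length(ch) >= 3) {
      buffer_polygon(u[rev(ch), , drop = FALSE], params$buffer_m)
    } else {
      seg <- u[ch, , drop = FALSE]
      out <- polyclip::polylineoffset(
        list(list(x = seg[, 1], y = seg[, 2])), params$buffer_m,
        jointype = "round", endtype = "openround",
        arctol = params$buffer_m * 0.002
      )
      list_to_poly(out[[1]])
    }
  }
  market_polygon(provider$provider_id, "variable_shape", boundary,
                 degenerate = TRUE)
}

#' Delineate market polygons for every provider
#'
#' Builds the requested market definitions for each provider from the
#' provider table and the registered-individual table.
#'
#' @param providers tibble with columns `provider_id`, `x`, `y` (and
#'   optionally `region_id`).
#' @param individuals tibble with columns `serial_id`, `x`, `y`,
#'   `provider_id` (the chosen provider). Only needed for the variable
#'   definitions.
#' @param definitions subset of [market_definitions()].
#' @param params a [geometry_params()] object.
#' @return a list of [market_polygon()] objects, named
#'   `"<provider_id>.<definition>"`.
#' @export
delineate_markets <- function(providers, individuals = NULL,
                              definitions = market_definitions(),
                              params = geometry_params()) {
  definitions <- match.arg(definitions, market_definitions(),
                           several.ok = TRUE)
  needs_ind <- any(definitions %in% c("variable_radius", "variable_shape"))
  if (needs_ind && is.null(individuals)) {
    stop("variable market definitions need the individual table", call. = FALSE)
  }
  reg_split <- if (needs_ind) {
    split(seq_len(nrow(individuals)), individuals$provider_id)
  } else {
    NULL
  }
  markets <- list()
  for (i in seq_len(nrow(providers))) {
    prov <- providers[i, ]
    reg <- if (needs_ind) {
      rows <- reg_split[[as.character(prov$provider_id)]]
      cbind(x = individuals$x[rows], y = individuals$y[rows])
    }
    for (def in definitions) {
      m <- switch(def,
        fixed_1km = fixed_radius_market(prov, params$fixed_radii_m[1], params,
                                        definition = "fixed_1km"),
        fixed_3km = fixed_radius_market(prov, params$fixed_radii_m[2], params,
                                        definition = "fixed_3km"),
        variable_radius = tryCatch(
          variable_radius_market(prov, reg, params),
          caremarkets_degenerate_geometry = function(e) NULL
        ),
        variable_shape = tryCatch(
          variable_shape_market(prov, reg, params),
          caremarkets_degenerate_geometry = function(e) NULL
        )
      )
      if (!is.null(m)) markets[[paste(prov$provider_id, def, sep = ".")]] <- m
    }
  }
  markets
}
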