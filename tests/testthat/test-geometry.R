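# Geometry layer: percentile radii, regular polygons, sectors, trims,
# concave hull, buffering and the three market constructions.

test_that("percentile_radius follows the nearest-rank rule", {
  pts <- cbind(x = seq(100, 1000, by = 100), y = 0)
  expect_equal(percentile_radius(c(0, 0), pts, 0.55), 600)
  expect_equal(percentile_radius(c(0, 0), pts, 1.0), 1000)
  expect_equal(percentile_radius(c(0, 0), cbind(250, 0), 0.01), 250)
  expect_equal(percentile_radius(c(0, 0), cbind(250, 0), 0.99), 250)

  # matches an independent sort-based oracle on random inputs
  for (seed in 1:25) {
    set.seed(seed)
    p <- runif(1, 0.05, 1)
    rnd <- cbind(runif(40, -5000, 5000), runif(40, -5000, 5000))
    expect_equal(percentile_radius(c(0, 0), rnd, p),
                 brute_force_percentile_radius(c(0, 0), rnd, p),
                 tolerance = 1e-12)
  }
})

test_that("percentile_radius is non-decreasing in p and validates input", {
  set.seed(7)
  pts <- cbind(runif(30, -2000, 2000), runif(30, -2000, 2000))
  r <- vapply(seq(0.05, 1, by = 0.05),
              function(p) percentile_radius(c(0, 0), pts, p), 0)
  expect_true(all(diff(r) >= 0))
  expect_error(percentile_radius(c(0, 0), pts[0, , drop = FALSE], 0.5))
  expect_error(percentile_radius(c(0, 0), pts, 0))
  expect_error(percentile_radius(c(0, 0), pts, 1.2))
})

test_that("regular polygons have the closed-form inscribed area", {
  for (n in c(3:10, 16, 32, 64)) {
    for (r in c(1, 1000, 3000)) {
      poly <- make_regular_polygon(c(123, -456), r, n)
      expect_equal(caremarkets:::polygon_area(poly), (n / 2) * r^2 * sin(2 * pi / n),
                   tolerance = 1e-9)
    }
  }
  # hexadecagon areas round to the 3 and 28 km2 of the two fixed markets
  expect_equal(round(caremarkets:::polygon_area(make_regular_polygon(c(0, 0), 1000, 16)) / 1e6), 3)
  expect_equal(round(caremarkets:::polygon_area(make_regular_polygon(c(0, 0), 3000, 16)) / 1e6), 28)
  # many-vertex polygon approaches the circle
  a <- caremarkets:::polygon_area(make_regular_polygon(c(0, 0), 1000, 1024))
  expect_equal(a, pi * 1000^2, tolerance = 1e-4)
  expect_error(make_regular_polygon(c(0, 0), -5, 16))
  expect_error(make_regular_polygon(c(0, 0), 100, 2))
})

test_that("sector assignment is clockwise from north with half-open arcs", {
  prov <- c(0, 0)
  # bearing 30 degrees: north-north-east wedge is sector 1
  expect_equal(sector_of(prov, c(sin(pi / 6), cos(pi / 6)) * 1000, 8), 1L)
  # exact 45-degree boundary belongs to the next sector
  expect_equal(sector_of(prov, c(1000, 1000), 8), 2L)
  # just shy of north wraps to the last sector
  expect_equal(sector_of(prov, c(-0.01, 1000), 8), 8L)
  expect_equal(sector_of(prov, c(0, 1000), 8), 1L)
  # coincident point has no bearing
  expect_true(is.na(sector_of(prov, c(0, 0), 8)))
  # all sectors hit over a full circle of bearings
  ang <- seq(0, 359, by = 1) * pi / 180
  secs <- sector_of(prov, cbind(sin(ang), cos(ang)) * 500, 8)
  expect_equal(sort(unique(secs)), 1:8)
})

test_that("directional trim keeps ceil(p * n) per non-empty sector", {
  params <- geometry_params()
  # one individual per sector: everyone survives
  ang <- (seq(0, 315, by = 45) + 20) * pi / 180
  one_each <- cbind(x = 1000 * sin(ang), y = 1000 * cos(ang))
  expect_equal(nrow(directional_trim(c(0, 0), one_each, params)), 8)
  # ten individuals in a single sector: the 7 nearest survive
  single <- cbind(x = seq(100, 1000, by = 100) * sin(pi / 8),
                  y = seq(100, 1000, by = 100) * cos(pi / 8))
  kept <- directional_trim(c(0, 0), single, params)
  expect_equal(nrow(kept), 7)
  expect_true(all(sqrt(rowSums(kept^2)) <= 700 + 1e-9))
  # empty input passes through
  expect_equal(nrow(directional_trim(c(0, 0), single[0, , drop = FALSE], params)), 0)
  # conservation: output size equals the sum of per-sector ceilings
  set.seed(11)
  for (rep in 1:10) {
    pts <- cbind(runif(60, -3000, 3000), runif(60, -3000, 3000))
    secs <- sector_of(c(0, 0), pts, params$n_sectors)
    expected <- sum(vapply(table(secs), function(m) ceiling(0.7 * m), 0))
    expect_equal(nrow(directional_trim(c(0, 0), pts, params)), expected)
  }
})

test_that("concave hull reduces to the convex hull when digging is disabled", {
  sq <- rbind(c(0, 0), c(50, 0), c(50, 50), c(0, 50))
  hull <- concave_hull(sq, concavity = 3, length_threshold = 100)
  expect_equal(caremarkets:::polygon_area(hull), 2500)
  set.seed(3)
  pts <- cbind(runif(120, 0, 2000), runif(120, 0, 2000))
  hull_inf <- concave_hull(pts, concavity = 3, length_threshold = Inf)
  expect_equal(caremarkets:::polygon_area(hull_inf), convex_hull_area(pts), tolerance = 1e-12)
})

test_that("concave hull digs into a U-shaped notch without losing points", {
  # two 1,000 m arms joined by a base, with a 400 m empty notch between the
  # arms; points scattered at roughly 20 m spacing. With straight scattered
  # walls the digging rule (candidates must be strictly closer to the dug
  # edge than to its neighbours) excavates the notch mouth but stalls before
  # reaching the base, so the frozen expectations come from the brute-force
  # reference implementation: strict area reduction, containment, mouth
  # exclusion, and vertex-for-vertex agreement between implementations.
  set.seed(404)
  u <- rbind(
    cbind(x = runif(750, 0, 300), y = runif(750, 0, 1000)),
    cbind(x = runif(750, 700, 1000), y = runif(750, 0, 1000)),
    cbind(x = runif(100, 300, 700), y = runif(100, 0, 100))
  )
  hull <- concave_hull(u, concavity = 3, length_threshold = 100)
  expect_lt(caremarkets:::polygon_area(hull), convex_hull_area(u))
  expect_true(all(point_in_polygon(u, hull)))
  # the notch mouth (top band of the gap) is excavated
  mouth <- expand.grid(x = seq(380, 620, by = 40), y = seq(850, 980, by = 30))
  expect_false(any(point_in_polygon(as.matrix(mouth), hull)))
  ref <- brute_force_concave_hull(u, 3, 100)
  expect_equal(unname(hull), unname(ref), tolerance = 1e-12)
})

test_that("concave hull fully excavates a tapered notch", {
  # arms whose inner walls slope toward each other going down: the digging
  # rule always finds in-band candidates, so the whole notch is excluded
  set.seed(405)
  t1 <- runif(750); t2 <- runif(750)
  u <- rbind(
    cbind(x = runif(750) * (300 + 150 * (1 - t1)), y = 1000 * t1),
    cbind(x = 1000 - runif(750) * (300 + 150 * (1 - t2)), y = 1000 * t2),
    cbind(x = runif(100, 300, 700), y = runif(100, 0, 80))
  )
  hull <- concave_hull(u, concavity = 3, length_threshold = 100)
  expect_lt(caremarkets:::polygon_area(hull), 0.85 * convex_hull_area(u))
  expect_true(all(point_in_polygon(u, hull)))
  # digging operates at the scale of a third of the edge length, so the notch
  # is guaranteed excavated where the gap is at least 3 x length_threshold:
  # here gap(y) = 100 + 300 * y / 1000 >= 300 for y >= 667
  notch <- expand.grid(x = seq(470, 530, by = 20), y = seq(700, 950, by = 50))
  expect_false(any(point_in_polygon(as.matrix(notch), hull)))
})

test_that("fast and brute-force hull implementations agree on random clouds", {
  for (seed in 1:8) {
    set.seed(100 + seed)
    n <- sample(15:80, 1)
    pts <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
    fast <- concave_hull(pts, 3, 100)
    ref <- brute_force_concave_hull(pts, 3, 100)
    expect_equal(unname(fast), unname(ref), tolerance = 1e-12)
  }
})

test_that("concave hull is sound on random point clouds", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(20:200, 1)
    pts <- cbind(runif(n, 0, 3000), runif(n, 0, 3000))
    hull <- concave_hull(pts, concavity = 3, length_threshold = 100)
    expect_true(all(point_in_polygon(pts, hull)))
    expect_lte(caremarkets:::polygon_area(hull), convex_hull_area(pts) + 1e-9)
    # simple polygon: positive area, no repeated vertices
    expect_gt(caremarkets:::polygon_area(hull), 0)
    expect_equal(anyDuplicated(hull), 0)
  }
})

test_that("concave hull signals degenerate inputs", {
  expect_error(concave_hull(rbind(c(0, 0), c(1, 1))),
               class = "caremarkets_degenerate_geometry")
  collinear <- cbind(x = 1:10, y = 2 * (1:10))
  expect_error(concave_hull(collinear),
               class = "caremarkets_degenerate_geometry")
})

test_that("buffering matches the closed-form dilated-square area", {
  s <- 100; d <- 10
  sq <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  buf <- buffer_polygon(sq, d)
  expect_equal(caremarkets:::polygon_area(buf), s^2 + 4 * s * d + pi * d^2,
               tolerance = 1e-3)
  expect_equal(buffer_polygon(sq, 0), caremarkets:::as_point_matrix(sq))
  expect_error(buffer_polygon(sq, -1))
  # all original boundary points are inside the buffered polygon
  expect_true(all(point_in_polygon(sq, buf)))
  # strict containment of the unbuffered polygon for d > 0
  set.seed(5)
  pts <- cbind(runif(80, 0, 1000), runif(80, 0, 1000))
  hull <- concave_hull(pts, 3, 100)
  buf2 <- buffer_polygon(hull, 10)
  expect_true(all(point_in_polygon(hull, buf2)))
  expect_gt(caremarkets:::polygon_area(buf2), caremarkets:::polygon_area(hull))
})

test_that("fixed-radius markets are congruent hexadecagons that nest", {
  params <- geometry_params()
  p1 <- list(provider_id = "A", x = 1000, y = 2000)
  p2 <- list(provider_id = "B", x = 9000, y = 500)
  m1 <- fixed_radius_market(p1, 1000, params, definition = "fixed_1km")
  m2 <- fixed_radius_market(p2, 1000, params, definition = "fixed_1km")
  expect_equal(m1$area_km2, m2$area_km2, tolerance = 1e-12)
  shift <- sweep(m2$boundary, 2, c(p2$x - p1$x, p2$y - p1$y))
  expect_equal(unname(m1$boundary), unname(shift), tolerance = 1e-9)
  # 1 km market nested in the 3 km market of the same provider
  m3 <- fixed_radius_market(p1, 3000, params, definition = "fixed_3km")
  expect_true(all(point_in_polygon(m1$boundary, m3$boundary)))
  expect_equal(round(m1$area_km2), 3)
  expect_equal(round(m3$area_km2), 28)
})

test_that("variable-radius markets capture the configured share", {
  prov <- list(provider_id = "A", x = 0, y = 0)
  pts <- cbind(x = seq(100, 1000, by = 100), y = 0)
  m <- variable_radius_market(prov, pts)
  expect_equal(m$radius_m, 600)
  # all individuals at one distance
  ring <- cbind(x = 700 * cos(1:12), y = 700 * sin(1:12))
  expect_equal(variable_radius_market(prov, ring)$radius_m, 700, tolerance = 1e-9)
  # a single registrant defines the radius
  expect_equal(variable_radius_market(prov, cbind(300, 0))$radius_m, 300)
  expect_error(variable_radius_market(prov, cbind(0, 0)[0, , drop = FALSE]),
               class = "caremarkets_degenerate_geometry")
})

test_that("variable-shape markets contain the trimmed share and the provider", {
  town <- known_structure_fixture("monopoly_town")
  prov <- town$providers[1, ]
  reg <- as.matrix(town$individuals[, c("x", "y")])
  m <- variable_shape_market(prov, reg)
  expect_false(m$degenerate)
  expect_true(point_in_polygon(c(prov$x, prov$y), m$boundary))
  # the two-stage trim keeps at least 0.8 * 0.7 = 56% of all registrants
  expect_gte(mean(point_in_polygon(reg, m$boundary)), 0.56)
})

test_that("variable-shape markets stay on the side where registrants live", {
  prov <- list(provider_id = "A", x = 0, y = 0)
  set.seed(9)
  nw <- cbind(x = runif(300, -4000, -500), y = runif(300, 500, 4000))
  m <- variable_shape_market(prov, nw)
  b <- m$boundary
  expect_true(all(b[, 1] <= 0 + 10 + 1e-6))
  expect_true(all(b[, 2] >= 0 - 10 - 1e-6))
})

test_that("variable-shape falls back to flagged geometry on tiny inputs", {
  prov <- list(provider_id = "A", x = 0, y = 0)
  two <- rbind(c(100, 100), c(200, 200))
  m <- variable_shape_market(prov, two)
  expect_true(m$degenerate)
  expect_true(point_in_polygon(c(0, 0), m$boundary))
  expect_true(all(point_in_polygon(two, m$boundary)))
  # collinear registrants through the provider
  col3 <- cbind(x = c(100, 200, 300), y = c(100, 200, 300))
  m2 <- variable_shape_market(prov, col3)
  expect_true(m2$degenerate)
  expect_true(all(point_in_polygon(col3, m2$boundary)))
})

test_that("delineate_markets builds every requested definition", {
  sc <- random_scenario(42)
  mk <- delineate_markets(sc$providers, sc$individuals)
  expect_length(mk, nrow(sc$providers) * 4)
  defs <- vapply(mk, function(m) m$definition, "")
  expect_equal(sort(unique(defs)), sort(market_definitions()))
  # every market contains its own provider
  for (m in mk) {
    pr <- sc$providers[sc$providers$provider_id == m$provider_id, ]
    expect_true(point_in_polygon(c(pr$x, pr$y), m$boundary))
  }
})
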