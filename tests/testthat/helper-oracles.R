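# Independent brute-force oracles, deliberately written without reusing the
# package's internals: plain loops and sorts only.

# HHI of a market polygon by direct enumeration over individuals.
brute_force_hhi <- function(boundary, providers, individuals) {
  in_poly <- function(px, py) {
    sp::point.in.polygon(px, py, boundary[, 1], boundary[, 2]) > 0
  }
  prov_in <- character(0)
  for (i in seq_len(nrow(providers))) {
    if (in_poly(providers$x[i], providers$y[i])) {
      prov_in <- c(prov_in, as.character(providers$provider_id[i]))
    }
  }
  counts <- stats::setNames(rep(0, length(prov_in)), prov_in)
  total <- 0
  for (i in seq_len(nrow(individuals))) {
    if (!in_poly(individuals$x[i], individuals$y[i])) next
    pid <- as.character(individuals$provider_id[i])
    if (pid %in% prov_in) {
      counts[pid] <- counts[pid] + 1
      total <- total + 1
    }
  }
  if (total == 0) return(NA_real_)
  s <- 0
  for (pid in prov_in) s <- s + (counts[pid] / total)^2
  unname(s)
}

# Nearest-rank percentile distance by explicit sort.
brute_force_percentile_radius <- function(provider, pts, p) {
  d <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d[i] <- sqrt((pts[i, 1] - provider[1])^2 + (pts[i, 2] - provider[2])^2)
  }
  sort(d)[ceiling(p * length(d))]
}

# Nearest-rank (type-1) quantile by explicit sort.
brute_force_quantile <- function(x, p) {
  sort(x)[pmax(1, ceiling(p * length(x)))]
}

# Convex hull area via chull + shoelace, for hull-soundness comparisons.
convex_hull_area <- function(pts) {
  h <- pts[grDevices::chull(pts), , drop = FALSE]
  x <- h[, 1]; y <- h[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Small random scenario: a few providers in a cluster, individuals around
# them, registrations drawn with mild distance decay.
random_scenario <- function(seed, n_prov = 4, n_ind = 250) {
  set.seed(seed)
  providers <- tibble::tibble(
    provider_id = sprintf("P%d", seq_len(n_prov)),
    x = runif(n_prov, 3000, 7000),
    y = runif(n_prov, 3000, 7000),
    region_id = "R1"
  )
  ix <- runif(n_ind, 0, 10000)
  iy <- runif(n_ind, 0, 10000)
  d <- sqrt(outer(ix, providers$x, "-")^2 + outer(iy, providers$y, "-")^2)
  gumbel <- -log(-log(matrix(runif(n_ind * n_prov), n_ind, n_prov)))
  pick <- max.col(-d / 1500 + gumbel)
  individuals <- tibble::tibble(
    serial_id = sprintf("I%d", seq_len(n_ind)),
    x = (floor(ix / 250) + 0.5) * 250,
    y = (floor(iy / 250) + 0.5) * 250,
    provider_id = providers$provider_id[pick]
  )
  list(providers = providers, individuals = individuals)
}

# Literal, slow reimplementation of the concave-hull edge-digging algorithm:
# plain arrays rebuilt at every step, no linked list, no vectorised candidate
# search. Used to cross-check the package implementation vertex by vertex.
brute_force_concave_hull <- function(points, concavity, length_threshold) {
  pts <- unique(cbind(points[, 1], points[, 2]))
  ch <- grDevices::chull(pts)
  poly <- rev(ch) # counter-clockwise point indices
  interior <- setdiff(seq_len(nrow(pts)), poly)
  sq_conc <- concavity^2
  sq_thr <- length_threshold^2

  seg_d2 <- function(p, a, b) {
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    l2 <- dx^2 + dy^2
    t <- if (l2 == 0) 0 else max(0, min(1, ((p[1] - a[1]) * dx + (p[2] - a[2]) * dy) / l2))
    (p[1] - (a[1] + t * dx))^2 + (p[2] - (a[2] + t * dy))^2
  }
  crosses <- function(p1, q1, p2, q2) {
    if (all(p1 == p2) || all(p1 == q2) || all(q1 == p2) || all(q1 == q2)) return(FALSE)
    o <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    ((o(p1, q1, p2) > 0) != (o(p1, q1, q2) > 0)) &&
      ((o(p2, q2, p1) > 0) != (o(p2, q2, q1) > 0))
  }
  ok_segment <- function(i, q) {
    for (e in seq_along(poly)) {
      a <- pts[poly[e], ]; b <- pts[poly[if (e == length(poly)) 1 else e + 1], ]
      if (crosses(pts[i, ], pts[q, ], a, b)) return(FALSE)
    }
    TRUE
  }

  queue <- poly
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    pos <- match(a, poly)
    b <- poly[if (pos == length(poly)) 1 else pos + 1]
    sq_len <- sum((pts[b, ] - pts[a, ])^2)
    if (sq_len < sq_thr || length(interior) == 0) next
    max_sq <- sq_len / sq_conc
    pa <- poly[if (pos == 1) length(poly) else pos - 1]
    pos_b <- match(b, poly)
    nb <- poly[if (pos_b == length(poly)) 1 else pos_b + 1]
    d2 <- vapply(interior, function(q) seg_d2(pts[q, ], pts[a, ], pts[b, ]), 0)
    chosen <- 0L
    for (j in order(d2)) {
      if (d2[j] > max_sq) break
      q <- interior[j]
      if (d2[j] >= seg_d2(pts[q, ], pts[pa, ], pts[a, ])) next
      if (d2[j] >= seg_d2(pts[q, ], pts[b, ], pts[nb, ])) next
      if (!ok_segment(a, q) || !ok_segment(b, q)) next
      chosen <- q
      break
    }
    if (chosen > 0L) {
      da <- sum((pts[chosen, ] - pts[a, ])^2)
      db <- sum((pts[chosen, ] - pts[b, ])^2)
      if (min(da, db) <= max_sq) {
        poly <- append(poly, chosen, after = pos)
        interior <- interior[interior != chosen]
        queue <- c(queue, a, chosen)
      }
    }
  }
  out <- pts[poly, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}
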