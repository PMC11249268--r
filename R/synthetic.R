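# Synthetic provider / registered-individual populations with the spatial
# structure the market analysis assumes: clustered urban residences around
# towns, scattered rural residences, distance-decay provider choice,
# anonymising grid snapping and a small fraction of stale registrations.

#' Configuration for the synthetic population generator
#'
#' @param seed integer seed; fixes all randomness of the generator.
#' @param towns data frame with one row per town: columns `x`, `y` (centre,
#'   metres), `population` (urban residents), `sd_m` (bivariate-normal spread
#'   of residences), `n_providers`, and optionally `region_id`. The default is
#'   a small three-town landscape (one large, one mid-sized, one small town)
#'   spanning roughly 60 x 60 km.
#' @param rural_fraction overall fraction of individuals living rurally
#'   (default 0.17, matching the share of coarse 1,000 m grid cells in
#'   Swedish residence data).
#' @param rural_extent bounding box `c(xmin, xmax, ymin, ymax)` over which
#'   rural residences are scattered uniformly; defaults to the town bounding
#'   box padded by 20 km.
#' @param choice_decay_lambda distance-decay scale (metres) of provider
#'   choice: an individual picks provider j with probability proportional to
#'   `exp(-d_j / lambda)`. Default 2,000 m, in line with provider-registrant
#'   distances of a few kilometres.
#' @param stale_fraction fraction of individuals whose residence is resampled
#'   far from their provider after choice, emulating movers who never
#'   re-registered (default 0.02).
#' @param urban_cell_m,rural_cell_m grid-snapping cell sides (250 m urban,
#'   1,000 m rural).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             towns = NULL,
                             rural_fraction = 0.17,
                             rural_extent = NULL,
                             choice_decay_lambda = 2000,
                             stale_fraction = 0.02,
                             urban_cell_m = 250,
                             rural_cell_m = 1000) {
  if (is.null(towns)) {
    towns <- data.frame(
      x = c(20000, 55000, 40000),
      y = c(20000, 45000, 70000),
      population = c(12000, 5000, 1500),
      sd_m = c(3000, 2000, 1200),
      n_providers = c(6L, 3L, 1L),
      region_id = c("R1", "R2", "R2")
    )
  }
  stopifnot(
    is.data.frame(towns),
    all(c("x", "y", "population", "sd_m", "n_providers") %in% names(towns)),
    all(towns$population > 0), all(towns$sd_m > 0), all(towns$n_providers >= 1),
    rural_fraction >= 0, rural_fraction < 1,
    choice_decay_lambda > 0,
    stale_fraction >= 0, stale_fraction <= 1,
    urban_cell_m > 0, rural_cell_m > 0
  )
  if (!("region_id" %in% names(towns))) {
    towns$region_id <- paste0("R", seq_len(nrow(towns)))
  }
  if (is.null(rural_extent)) {
    pad <- 20000
    rural_extent <- c(min(towns$x) - pad, max(towns$x) + pad,
                      min(towns$y) - pad, max(towns$y) + pad)
  }
  stopifnot(length(rural_extent) == 4,
            rural_extent[2] > rural_extent[1],
            rural_extent[4] > rural_extent[3])
  structure(
    list(
      seed = as.integer(seed), towns = towns,
      rural_fraction = rural_fraction, rural_extent = rural_extent,
      choice_decay_lambda = choice_decay_lambda,
      stale_fraction = stale_fraction,
      urban_cell_m = urban_cell_m, rural_cell_m = rural_cell_m
    ),
    class = "synthetic_config"
  )
}

#' Snap a point to its grid-cell centroid
#'
#' Returns the centroid of the axis-aligned square cell of side `cell_m`
#' containing the point, emulating the anonymising coarsening applied to
#' residence coordinates. Idempotent: a centroid maps to itself.
#'
#' @param p points (vector, matrix or data frame).
#' @param cell_m cell side in metres.
#' @return snapped coordinate matrix.
#' @examples
#' snap_to_grid(c(130, 470), 250) # centre of cell [0,250) x [250,500)
#' @export
snap_to_grid <- function(p, cell_m) {
  stopifnot(cell_m > 0)
  pts <- as_point_matrix(p)
  cbind(x = (floor(pts[, 1] / cell_m) + 0.5) * cell_m,
        y = (floor(pts[, 2] / cell_m) + 0.5) * cell_m)
}

# Evaluate expr with the given seed without disturbing the caller's RNG.
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic provider and individual population
#'
#' Urban residences are drawn from bivariate normals around the configured
#' town centres and rural residences uniformly over the rural extent, with
#' the rural count chosen so the overall rural share equals
#' `rural_fraction`. Providers are scattered within their town. Each
#' individual chooses a provider with probability proportional to
#' `exp(-d_j / lambda)` over all providers (sampled exactly via the
#' Gumbel-max trick). A `stale_fraction` of individuals then has its
#' residence resampled uniformly over the extent without re-registering.
#' Finally residences are snapped to 250 m (urban) or 1,000 m (rural) grid
#' centroids. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `providers` (tibble: `provider_id`, `x`, `y`,
#'   `region_id`) and `individuals` (tibble: `serial_id`, `x`, `y`,
#'   `provider_id`, plus diagnostic columns `rural`, `stale` and the exact
#'   pre-snap coordinates `x_exact`, `y_exact`).
#' @export
generate_population <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must come from synthetic_config()", call. = FALSE)
  }
  with_fixed_seed(config$seed, {
    towns <- config$towns
    # providers: scattered within each town at about half the residence spread
    pn <- sum(towns$n_providers)
    town_of_prov <- rep(seq_len(nrow(towns)), towns$n_providers)
    prov_xy <- cbind(
      x = towns$x[town_of_prov] + stats::rnorm(pn, 0, towns$sd_m[town_of_prov] / 2),
      y = towns$y[town_of_prov] + stats::rnorm(pn, 0, towns$sd_m[town_of_prov] / 2)
    )
    providers <- tibble::tibble(
      provider_id = sprintf("P%03d", seq_len(pn)),
      x = prov_xy[, 1], y = prov_xy[, 2],
      region_id = towns$region_id[town_of_prov]
    )

    n_urban <- sum(towns$population)
    n_rural <- round(config$rural_fraction / (1 - config$rural_fraction) * n_urban)
    town_of_ind <- rep(seq_len(nrow(towns)), towns$population)
    ux <- towns$x[town_of_ind] + stats::rnorm(n_urban, 0, towns$sd_m[town_of_ind])
    uy <- towns$y[town_of_ind] + stats::rnorm(n_urban, 0, towns$sd_m[town_of_ind])
    ext <- config$rural_extent
    rx <- stats::runif(n_rural, ext[1], ext[2])
    ry <- stats::runif(n_rural, ext[3], ext[4])
    x <- c(ux, rx); y <- c(uy, ry)
    rural <- c(rep(FALSE, n_urban), rep(TRUE, n_rural))
    n <- n_urban + n_rural

    # distance-decay choice over all providers, exact softmax sampling:
    # argmax_j (-d_j / lambda + Gumbel_j) has the softmax distribution
    dx <- outer(x, providers$x, "-")
    dy <- outer(y, providers$y, "-")
    util <- -sqrt(dx^2 + dy^2) / config$choice_decay_lambda
    gumbel <- -log(-log(matrix(stats::runif(n * pn), n, pn)))
    choice <- max.col(util + gumbel, ties.method = "first")

    # stale registrations: residence moves, registration does not
    stale <- rep(FALSE, n)
    n_stale <- round(config$stale_fraction * n)
    if (n_stale > 0) {
      idx <- sample.int(n, n_stale)
      x[idx] <- stats::runif(n_stale, ext[1], ext[2])
      y[idx] <- stats::runif(n_stale, ext[3], ext[4])
      stale[idx] <- TRUE
    }

    cell <- ifelse(rural, config$rural_cell_m, config$urban_cell_m)
    snapped <- cbind((floor(x / cell) + 0.5) * cell,
                     (floor(y / cell) + 0.5) * cell)
    individuals <- tibble::tibble(
      serial_id = sprintf("I%07d", seq_len(n)),
      x = snapped[, 1], y = snapped[, 2],
      provider_id = providers$provider_id[choice],
      rural = rural, stale = stale,
      x_exact = x, y_exact = y
    )
    list(providers = providers, individuals = individuals)
  })
}

#' Small deterministic scenarios with known competition structure
#'
#' Fixtures used throughout the tests and examples:
#' \describe{
#'   \item{monopoly_town}{one provider, one residential cluster; HHI 1 under
#'     every definition.}
#'   \item{duopoly_5050}{two providers 10 m apart whose registrants occupy the
#'     same residential locations in equal numbers; HHI exactly 0.5 under
#'     every definition.}
#'   \item{two_isolated_towns}{two towns 50 km apart with two providers each;
#'     markets of different towns never meet.}
#'   \item{urban_rural_mix}{a town with six providers at varied spacing plus
#'     two isolated rural providers; small fixed markets declare more
#'     monopolies than large ones.}
#'   \item{directional_commuter}{a provider whose registrants live along a
#'     south-west commuter corridor, with a competitor north-east of it; the
#'     variable-shape market excludes the competitor that the variable-radius
#'     circle includes.}
#' }
#'
#' @param name scenario name.
#' @return list with `providers` and `individuals` tibbles as in
#'   [generate_population()].
#' @export
known_structure_fixture <- function(name = c("monopoly_town", "duopoly_5050",
                                             "two_isolated_towns",
                                             "urban_rural_mix",
                                             "directional_commuter")) {
  name <- match.arg(name)
  mk_prov <- function(id, x, y, region = "R1") {
    tibble::tibble(provider_id = id, x = x, y = y, region_id = region)
  }
  mk_ind <- function(xy, provider_id, cell = 250) {
    xy <- snap_to_grid(xy, cell)
    tibble::tibble(
      serial_id = sprintf("I%07d", seq_len(nrow(xy))),
      x = xy[, 1], y = xy[, 2], provider_id = provider_id
    )
  }
  # deterministic cluster: low-discrepancy spiral of n points around a centre
  spiral <- function(cx, cy, n, spread) {
    k <- seq_len(n)
    r <- spread * sqrt(k / n)
    a <- 2 * pi * k * (sqrt(5) - 1) / 2
    cbind(x = cx + r * cos(a), y = cy + r * sin(a))
  }

  switch(name,
    monopoly_town = {
      providers <- mk_prov("P1", 5000, 5000)
      ind <- mk_ind(spiral(5000, 5000, 500, 1800), "P1")
      list(providers = providers, individuals = ind)
    },
    duopoly_5050 = {
      providers <- mk_prov(c("P1", "P2"), c(4995, 5005), c(5000, 5000))
      # same residential locations host one registrant of each provider
      locs <- snap_to_grid(spiral(5000, 5000, 200, 1500), 250)
      ind <- tibble::tibble(
        serial_id = sprintf("I%07d", seq_len(2 * nrow(locs))),
        x = rep(locs[, 1], 2), y = rep(locs[, 2], 2),
        provider_id = rep(c("P1", "P2"), each = nrow(locs))
      )
      list(providers = providers, individuals = ind)
    },
    two_isolated_towns = {
      providers <- mk_prov(c("A1", "A2", "B1", "B2"),
                           c(4000, 6000, 54000, 56000),
                           c(5000, 5000, 5000, 5000),
                           region = c("R1", "R1", "R2", "R2"))
      pa <- spiral(5000, 5000, 300, 2000)
      pb <- spiral(55000, 5000, 300, 2000)
      # within each town, registrants alternate between the two providers
      ind <- mk_ind(rbind(pa, pb),
                    c(rep(c("A1", "A2"), length.out = 300),
                      rep(c("B1", "B2"), length.out = 300)))
      list(providers = providers, individuals = ind)
    },
    urban_rural_mix = {
      providers <- mk_prov(
        c("U1", "U2", "U3", "U4", "U5", "U6", "V1", "V2"),
        c(8500, 11500, 10000, 10000, 9700, 10300, 30000, 5000),
        c(10000, 10000, 11800, 8200, 10000, 10000, 30000, 30000),
        region = c(rep("R1", 6), "R2", "R2")
      )
      with_fixed_seed(20160101, {
        n_u <- 3000
        uxy <- cbind(stats::rnorm(n_u, 10000, 2500), stats::rnorm(n_u, 10000, 2500))
        urb <- providers[1:6, ]
        util <- -sqrt(outer(uxy[, 1], urb$x, "-")^2 +
                        outer(uxy[, 2], urb$y, "-")^2) / 800
        g <- -log(-log(matrix(stats::runif(n_u * 6), n_u, 6)))
        chos <- urb$provider_id[max.col(util + g, ties.method = "first")]
        r1 <- cbind(stats::rnorm(200, 30000, 2500), stats::rnorm(200, 30000, 2500))
        r2 <- cbind(stats::rnorm(200, 5000, 2500), stats::rnorm(200, 30000, 2500))
        ind_u <- mk_ind(uxy, chos, cell = 250)
        ind_r <- mk_ind(rbind(r1, r2), rep(c("V1", "V2"), each = 200), cell = 1000)
        ind_r$serial_id <- sprintf("I%07d", n_u + seq_len(nrow(ind_r)))
        list(providers = providers,
             individuals = rbind(ind_u, ind_r))
      })
    },
    directional_commuter = {
      providers <- mk_prov(c("F", "G"),
                           c(10000, 11400), c(10000, 11400))
      # F's registrants: a south-west commuter corridor out to ~5 km
      t <- seq(0, 1, length.out = 400)
      corridor <- cbind(
        x = 10000 - 200 - 4800 * t + 500 * sin(17 * t),
        y = 10000 - 200 - 4800 * t + 500 * cos(23 * t)
      )
      near <- spiral(9700, 9700, 100, 400) # locals just south-west of F
      g_local <- spiral(11500, 11500, 150, 500)
      ind <- mk_ind(rbind(corridor, near, g_local),
                    c(rep("F", 500), rep("G", 150)))
      list(providers = providers, individuals = ind)
    }
  )
}
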