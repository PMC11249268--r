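# Competition measures within delineated local markets.

signal_no_valid_registrations <- function(provider_id) {
  stop(structure(
    class = c("caremarkets_no_valid_registrations", "error", "condition"),
    list(message = sprintf(
      "no resident of provider %s's market is registered with an in-market provider",
      format(provider_id)
    ), call = NULL)
  ))
}

#' Providers located inside a market
#'
#' Membership is boundary-inclusive, and the focal provider is always a
#' member of its own market (the count measure's minimum is therefore 1).
#'
#' @param market a [market_polygon()].
#' @param providers provider tibble (`provider_id`, `x`, `y`).
#' @return the subset of `providers` located in the market.
#' @export
providers_in_market <- function(market, providers) {
  inside <- point_in_polygon(providers[, c("x", "y")], market$boundary)
  inside <- inside | providers$provider_id == market$provider_id
  providers[inside, , drop = FALSE]
}

#' Market shares of the providers in a market
#'
#' The denominator is the number of individuals who both reside in the market
#' (boundary-inclusive, on their grid-snapped coordinates) and are registered
#' with one of the in-market providers; residents registered with an outside
#' provider are excluded. Each in-market provider's share is its count of
#' in-market registered residents over that denominator, so shares sum to 1.
#'
#' @param market a [market_polygon()].
#' @param providers_in providers located in the market (see
#'   [providers_in_market()]).
#' @param individuals individual tibble (`serial_id`, `x`, `y`,
#'   `provider_id`).
#' @return named numeric vector of shares, one per in-market provider
#'   (zero-share providers included).
#' @export
market_shares <- function(market, providers_in, individuals) {
  if (nrow(providers_in) == 0) {
    stop("providers_in must contain at least the focal provider", call. = FALSE)
  }
  res <- individuals[point_in_polygon(individuals[, c("x", "y")],
                                      market$boundary), , drop = FALSE]
  ids <- as.character(providers_in$provider_id)
  valid <- res[as.character(res$provider_id) %in% ids, , drop = FALSE]
  if (nrow(valid) == 0) signal_no_valid_registrations(market$provider_id)
  counts <- table(factor(as.character(valid$provider_id), levels = ids))
  shares <- as.numeric(counts) / nrow(valid)
  names(shares) <- ids
  shares
}

#' Herfindahl-Hirschman index
#'
#' The sum of squared market shares of the competing providers in a market:
#' `HHI = sum(s_i^2)`. Bounded in (0, 1]; 1 indicates a monopoly and values
#' near 0 a highly competitive market.
#'
#' @param shares numeric vector of market shares summing to 1.
#' @return the index value.
#' @examples
#' hhi(c(0.6, 0.2, 0.2)) # 0.44
#' @export
hhi <- function(shares) {
  if (any(shares < 0 | shares > 1)) {
    stop("shares must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("shares must sum to 1", call. = FALSE)
  }
  sum(shares^2)
}

#' Number of competitors in a market
#'
#' Counts all providers located in the market, the focal provider included,
#' so the minimum is 1.
#'
#' @inheritParams providers_in_market
#' @return integer count.
#' @export
competitor_count <- function(market, providers) {
  nrow(providers_in_market(market, providers))
}

#' HHI with competitors defined by overlapping markets
#'
#' Alternative index in which the competitor set of a focal provider consists
#' of all providers whose own market polygon intersects the focal market
#' (boundary contact included; the focal provider always belongs). Shares are
#' computed over individuals residing in the focal market and registered with
#' any provider in that competitor set; overlapping providers without such
#' registrants carry share zero.
#'
#' @param focal the focal provider's [market_polygon()].
#' @param all_markets list of [market_polygon()] objects for the same
#'   definition, including the focal one.
#' @param individuals individual tibble.
#' @return list with `hhi`, `n_competitors` and the named `shares` vector.
#' @export
overlap_hhi <- function(focal, all_markets, individuals) {
  comp_ids <- unique(vapply(
    all_markets,
    function(m) {
      if (identical(m$provider_id, focal$provider_id) ||
          polygons_intersect(m$boundary, focal$boundary)) {
        as.character(m$provider_id)
      } else {
        NA_character_
      }
    },
    character(1)
  ))
  comp_ids <- comp_ids[!is.na(comp_ids)]
  res <- individuals[point_in_polygon(individuals[, c("x", "y")],
                                      focal$boundary), , drop = FALSE]
  valid <- res[as.character(res$provider_id) %in% comp_ids, , drop = FALSE]
  if (nrow(valid) == 0) signal_no_valid_registrations(focal$provider_id)
  counts <- table(factor(as.character(valid$provider_id), levels = comp_ids))
  shares <- as.numeric(counts) / nrow(valid)
  names(shares) <- comp_ids
  list(hhi = hhi(shares), n_competitors = length(comp_ids), shares = shares)
}

#' Per-provider competition table across market definitions
#'
#' For every provider and every requested market definition, delineates the
#' market, identifies the in-market providers, computes market shares, the
#' HHI, the competitor count and the monopoly flag (HHI = 1 and exactly one
#' provider). Also records market area, total resident population and the
#' count of validly registered residents. Providers whose market could not be
#' computed or holds no validly registered resident get `NA` measures and a
#' degenerate flag instead of aborting the batch.
#'
#' @param providers provider tibble (`provider_id`, `x`, `y`, optionally
#'   `region_id`).
#' @param individuals individual tibble (`serial_id`, `x`, `y`,
#'   `provider_id`).
#' @param params a [geometry_params()] object.
#' @param definitions subset of [market_definitions()].
#' @param markets optional precomputed result of [delineate_markets()] to
#'   reuse.
#' @return a tibble with one row per provider and, per definition `<def>`,
#'   columns `hhi_<def>`, `n_providers_<def>`, `is_monopoly_<def>`,
#'   `area_km2_<def>`, `population_<def>`, `valid_registrants_<def>` and
#'   `degenerate_<def>`.
#' @export
compute_competition_table <- function(providers, individuals,
                                      params = geometry_params(),
                                      definitions = market_definitions(),
                                      markets = NULL) {
  definitions <- match.arg(definitions, market_definitions(), several.ok = TRUE)
  if (is.null(markets)) {
    markets <- delineate_markets(providers, individuals, definitions, params)
  }
  out <- tibble::tibble(provider_id = providers$provider_id)
  if ("region_id" %in% names(providers)) out$region_id <- providers$region_id

  ind_xy <- as.matrix(individuals[, c("x", "y")])
  ind_prov <- as.character(individuals$provider_id)

  for (def in definitions) {
    nh <- rep(NA_real_, nrow(providers))
    nn <- rep(NA_integer_, nrow(providers))
    ar <- rep(NA_real_, nrow(providers))
    pop <- rep(NA_integer_, nrow(providers))
    vr <- rep(NA_integer_, nrow(providers))
    dg <- rep(TRUE, nrow(providers))
    for (i in seq_len(nrow(providers))) {
      m <- markets[[paste(providers$provider_id[i], def, sep = ".")]]
      if (is.null(m)) next
      pin <- providers_in_market(m, providers)
      ar[i] <- m$area_km2
      # bounding-box prefilter keeps point-in-polygon affordable
      bb <- apply(m$boundary, 2, range)
      near <- ind_xy[, 1] >= bb[1, 1] & ind_xy[, 1] <= bb[2, 1] &
        ind_xy[, 2] >= bb[1, 2] & ind_xy[, 2] <= bb[2, 2]
      res_idx <- which(near)[point_in_polygon(ind_xy[near, , drop = FALSE],
                                              m$boundary)]
      pop[i] <- length(res_idx)
      ids <- as.character(pin$provider_id)
      valid <- res_idx[ind_prov[res_idx] %in% ids]
      vr[i] <- length(valid)
      nn[i] <- nrow(pin)
      if (length(valid) > 0) {
        counts <- table(factor(ind_prov[valid], levels = ids))
        nh[i] <- sum((as.numeric(counts) / length(valid))^2)
        dg[i] <- m$degenerate
      }
    }
    out[[paste0("hhi_", def)]] <- nh
    out[[paste0("n_providers_", def)]] <- nn
    out[[paste0("is_monopoly_", def)]] <- !is.na(nh) & nh >= 1 - 1e-9 & nn == 1L
    out[[paste0("area_km2_", def)]] <- ar
    out[[paste0("population_", def)]] <- pop
    out[[paste0("valid_registrants_", def)]] <- vr
    out[[paste0("degenerate_", def)]] <- dg
  }
  out
}
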