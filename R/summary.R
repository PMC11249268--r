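# Descriptive statistics and comparisons of competition measures across
# market definitions. Percentiles use the nearest-rank rule (type-1
# quantiles), matching the rank-based percentile logic of the market
# constructions.

q1 <- function(x, p) unname(stats::quantile(x, p, type = 1, names = FALSE))

measure_stats <- function(x) {
  x <- x[!is.na(x)]
  tibble::tibble(
    mean = mean(x), sd = stats::sd(x), median = stats::median(x),
    min = min(x), max = max(x),
    p10 = q1(x, 0.10), p25 = q1(x, 0.25), p50 = q1(x, 0.50), p75 = q1(x, 0.75)
  )
}

#' Summarise one market definition
#'
#' Descriptive statistics (mean, SD, median, min, max, nearest-rank
#' percentiles 10/25/50/75) of the HHI, the competitor count and — when the
#' columns are present — market area and population, plus the monopoly count
#' and share. A market is a monopoly when its HHI equals 1 and it contains
#' exactly one provider. Rows with missing HHI (degenerate markets) are
#' excluded.
#'
#' @param table competition tibble (wide, with `hhi_<definition>` etc.).
#' @param definition one of [market_definitions()].
#' @return an object of class `definition_summary`: a list with `definition`,
#'   `n`, a `stats` tibble (one row per measure), `monopoly_count` and
#'   `monopoly_share`.
#' @export
summarize_definition <- function(table, definition) {
  definition <- match.arg(definition, market_definitions())
  hcol <- paste0("hhi_", definition)
  if (!(hcol %in% names(table))) {
    stop(sprintf("table has no column %s", hcol), call. = FALSE)
  }
  ok <- !is.na(table[[hcol]])
  if (!any(ok)) stop("no usable rows for this definition", call. = FALSE)
  tab <- table[ok, , drop = FALSE]
  measures <- c(hhi = hcol,
                n_providers = paste0("n_providers_", definition),
                area_km2 = paste0("area_km2_", definition),
                population = paste0("population_", definition))
  measures <- measures[measures %in% names(tab)]
  stats_tbl <- dplyr::bind_rows(lapply(measures, function(cc) measure_stats(tab[[cc]])))
  stats_tbl <- dplyr::bind_cols(tibble::tibble(measure = names(measures)), stats_tbl)
  mono <- tab[[hcol]] >= 1 - 1e-9 & tab[[paste0("n_providers_", definition)]] == 1
  structure(
    list(definition = definition, n = nrow(tab), stats = stats_tbl,
         monopoly_count = sum(mono),
         monopoly_share = sum(mono) / nrow(tab)),
    class = "definition_summary"
  )
}

#' @export
print.definition_summary <- function(x, ...) {
  cat(sprintf("<definition_summary> %s (n = %d)\n", x$definition, x$n))
  print(as.data.frame(x$stats), digits = 4, row.names = FALSE)
  cat(sprintf("monopolies: %d (%.1f%%)\n",
              x$monopoly_count, 100 * x$monopoly_share))
  invisible(x)
}

#' Providers that are monopolies under every definition
#'
#' @param table competition tibble containing all four definitions.
#' @return list with `count` and `share` (share of all providers).
#' @export
all_definition_monopolies <- function(table) {
  cols <- paste0("is_monopoly_", market_definitions())
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    stop(sprintf("table lacks monopoly column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  all_mono <- Reduce(`&`, lapply(cols, function(cc) {
    v <- table[[cc]]
    !is.na(v) & v
  }))
  list(count = sum(all_mono), share = sum(all_mono) / nrow(table))
}

#' Mean HHI per definition, optionally excluding monopolies
#'
#' @param table competition tibble.
#' @param exclude_monopolies drop monopoly markets before averaging.
#' @return tibble with columns `definition`, `mean`, `sd`, `n`.
#' @export
conditional_hhi_means <- function(table, exclude_monopolies = FALSE) {
  defs <- market_definitions()[paste0("hhi_", market_definitions()) %in% names(table)]
  rows <- lapply(defs, function(def) {
    h <- table[[paste0("hhi_", def)]]
    keep <- !is.na(h)
    if (exclude_monopolies) {
      mono <- table[[paste0("is_monopoly_", def)]]
      keep <- keep & !(!is.na(mono) & mono)
    }
    if (!any(keep)) {
      stop(sprintf("no non-monopoly rows for definition %s", def), call. = FALSE)
    }
    tibble::tibble(definition = def, mean = mean(h[keep]),
                   sd = stats::sd(h[keep]), n = sum(keep))
  })
  dplyr::bind_rows(rows)
}

#' Pairwise Pearson correlations of HHI measures across definitions
#'
#' Pearson r with 95% confidence intervals (Fisher z-transform, as in
#' [stats::cor.test()]) for every pair of definitions, computed over
#' providers with non-missing HHI under both. Zero-variance columns yield
#' `NA` for their pairs, with a warning.
#'
#' @param table competition tibble.
#' @return object of class `hhi_correlation`: list of matrices `r`,
#'   `ci_low`, `ci_high` and the pairwise sample-size matrix `n`.
#' @export
hhi_correlation_matrix <- function(table) {
  defs <- market_definitions()[paste0("hhi_", market_definitions()) %in% names(table)]
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  k <- length(defs)
  r <- lo <- hi <- nm <- matrix(NA_real_, k, k, dimnames = list(defs, defs))
  diag(r) <- 1; diag(lo) <- 1; diag(hi) <- 1
  diag(nm) <- vapply(defs, function(d) sum(!is.na(table[[paste0("hhi_", d)]])), 0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- table[[paste0("hhi_", defs[i])]]
      xj <- table[[paste0("hhi_", defs[j])]]
      ok <- !is.na(xi) & !is.na(xj)
      nm[i, j] <- nm[j, i] <- sum(ok)
      if (sum(ok) < 3 || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
        warning(sprintf("correlation undefined for %s vs %s", defs[i], defs[j]))
        next
      }
      ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson",
                            conf.level = 0.95)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      lo[i, j] <- lo[j, i] <- ct$conf.int[1]
      hi[i, j] <- hi[j, i] <- ct$conf.int[2]
    }
  }
  structure(list(r = r, ci_low = lo, ci_high = hi, n = nm),
            class = "hhi_correlation")
}

#' @export
print.hhi_correlation <- function(x, digits = 2, ...) {
  cat("<hhi_correlation> Pearson r (95% CI)\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Per-region summaries of a market definition's competition measures
#'
#' @param table competition tibble.
#' @param regions named vector mapping `provider_id` to region, or `NULL` to
#'   use the table's `region_id` column.
#' @return tibble with one row per region and definition: `n`, `mean_hhi`,
#'   `sd_hhi`, `median_hhi`, `mean_n_providers`, `monopoly_count`,
#'   `monopoly_share`.
#' @export
regional_aggregate <- function(table, regions = NULL) {
  if (is.null(regions)) {
    if (!("region_id" %in% names(table))) {
      stop("supply a provider-to-region mapping or a region_id column",
           call. = FALSE)
    }
    reg <- table$region_id
  } else {
    reg <- unname(regions[as.character(table$provider_id)])
    if (any(is.na(reg))) {
      stop(sprintf("unmapped provider(s): %s",
                   paste(table$provider_id[is.na(reg)], collapse = ", ")),
           call. = FALSE)
    }
  }
  defs <- market_definitions()[paste0("hhi_", market_definitions()) %in% names(table)]
  rows <- list()
  for (rg in sort(unique(reg))) {
    sub <- table[reg == rg, , drop = FALSE]
    for (def in defs) {
      h <- sub[[paste0("hhi_", def)]]
      np <- sub[[paste0("n_providers_", def)]]
      ok <- !is.na(h)
      if (!any(ok)) next
      mono <- h[ok] >= 1 - 1e-9 & np[ok] == 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        region_id = rg, definition = def, n = sum(ok),
        mean_hhi = mean(h[ok]), sd_hhi = stats::sd(h[ok]),
        median_hhi = stats::median(h[ok]),
        mean_n_providers = mean(np[ok]),
        monopoly_count = sum(mono), monopoly_share = mean(mono)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Trimmed provider-registrant distance distribution
#'
#' Computes each individual's distance to their own provider, excludes the
#' furthest `1 - trim` share globally by rank (removing stale and
#' mis-registered records), and returns the mean and median of the
#' remainder. Used to calibrate fixed-radius distances.
#'
#' @param providers provider tibble.
#' @param individuals individual tibble.
#' @param trim fraction of nearest registrations kept (default 0.9).
#' @return list with `mean_m`, `median_m` and the kept `distances_m`.
#' @export
radius_calibration <- function(providers, individuals, trim = 0.9) {
  if (nrow(individuals) == 0) stop("no registrations supplied", call. = FALSE)
  stopifnot(trim > 0, trim <= 1)
  idx <- match(as.character(individuals$provider_id),
               as.character(providers$provider_id))
  if (any(is.na(idx))) {
    stop("individuals registered with unknown providers", call. = FALSE)
  }
  d <- sqrt((individuals$x - providers$x[idx])^2 +
              (individuals$y - providers$y[idx])^2)
  k <- ceiling(trim * length(d))
  kept <- sort(d, method = "radix")[seq_len(k)]
  list(mean_m = mean(kept), median_m = stats::median(kept), distances_m = kept)
}
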