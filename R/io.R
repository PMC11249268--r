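# Readers and writers for the package's tabular and geospatial artefacts.
# All writers are deterministic: fixed column order and fixed float
# formatting (6 significant digits), so identical inputs give byte-identical
# files.

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) format(v, digits = 6, trim = TRUE,
                                                    scientific = FALSE), ""))
}

#' Read a provider table
#'
#' Expects a CSV with columns `provider_id`, `x`, `y` and optionally
#' `region_id` and `ownership`. Rows with missing coordinates and duplicated
#' provider ids are dropped with a message reporting the counts.
#'
#' @param path CSV file path.
#' @return provider tibble.
#' @export
read_provider_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("provider_id", "x", "y")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("provider table %s lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- !is.finite(df$x) | !is.finite(df$y) | is.na(df$provider_id)
  dup <- duplicated(df$provider_id) & !bad
  if (any(bad) || any(dup)) {
    message(sprintf("read_provider_table: dropped %d row(s) with missing data, %d duplicate(s)",
                    sum(bad), sum(dup)))
  }
  tibble::as_tibble(df[!bad & !dup, , drop = FALSE])
}

#' Read an individual registration table
#'
#' Expects a CSV with columns `serial_id`, `x`, `y`, `provider_id` (the
#' chosen provider). Rows with missing coordinates or registration and
#' duplicated serial ids are dropped with a message reporting the counts.
#'
#' @param path CSV file path.
#' @return individual tibble.
#' @export
read_individual_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("serial_id", "x", "y", "provider_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("individual table %s lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- !is.finite(df$x) | !is.finite(df$y) | is.na(df$provider_id) |
    df$provider_id == "" | is.na(df$serial_id)
  dup <- duplicated(df$serial_id) & !bad
  if (any(bad) || any(dup)) {
    message(sprintf("read_individual_table: dropped %d row(s) with missing data, %d duplicate(s)",
                    sum(bad), sum(dup)))
  }
  tibble::as_tibble(df[!bad & !dup, , drop = FALSE])
}

#' Write provider / individual tables
#'
#' Deterministic CSV writers for the tables produced by
#' [generate_population()].
#'
#' @param x tibble to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_provider_table <- function(x, path) {
  df <- as.data.frame(x)[, intersect(c("provider_id", "x", "y", "region_id",
                                       "ownership"), names(x)), drop = FALSE]
  for (cc in c("x", "y")) df[[cc]] <- fmt_num(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_provider_table
#' @export
write_individual_table <- function(x, path) {
  df <- as.data.frame(x)[, intersect(c("serial_id", "x", "y", "provider_id"),
                                     names(x)), drop = FALSE]
  for (cc in c("x", "y")) df[[cc]] <- fmt_num(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

competition_columns <- function(definitions = market_definitions()) {
  c("provider_id",
    paste0("hhi_", definitions),
    paste0("n_providers_", definitions))
}

#' Write a per-provider competition table
#'
#' Native dialect: one row per provider with columns `hhi_<definition>` and
#' `n_providers_<definition>` (plus `provider_id`), HHI written with 6
#' significant digits.
#'
#' @param table competition tibble from [compute_competition_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_competition_csv <- function(table, path) {
  defs <- market_definitions()[paste0("hhi_", market_definitions()) %in% names(table)]
  cols <- competition_columns(defs)
  df <- as.data.frame(table)[, cols, drop = FALSE]
  for (cc in paste0("hhi_", defs)) df[[cc]] <- fmt_num(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-provider competition table
#'
#' Two dialects are supported. `"native"` is what [write_competition_csv()]
#' produces. `"s1"` reads the published supplementary per-provider dataset
#' shape; since the exact published headers can vary, `mapping` translates
#' the file's column names to the native ones (`provider_id`,
#' `hhi_fixed_1km`, ..., `n_providers_variable_shape`). Values are validated:
#' HHI must lie in (0, 1] and provider counts must be integers >= 1.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"s1"`.
#' @param mapping named character vector: names are the file's column names,
#'   values the native column names. Only used for the `"s1"` dialect.
#' @return competition tibble (with `is_monopoly_<definition>` columns
#'   derived from HHI and count).
#' @export
read_competition_csv <- function(path, dialect = c("native", "s1"),
                                 mapping = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "s1") {
    if (is.null(mapping)) {
      stop("the s1 dialect needs a column-name mapping", call. = FALSE)
    }
    hit <- names(df) %in% names(mapping)
    names(df)[hit] <- unname(mapping[names(df)[hit]])
  }
  if (!("provider_id" %in% names(df))) {
    stop("competition table lacks a provider_id column", call. = FALSE)
  }
  defs <- market_definitions()[paste0("hhi_", market_definitions()) %in% names(df)]
  if (length(defs) == 0) {
    stop("competition table holds no hhi_<definition> column", call. = FALSE)
  }
  bad_rows <- integer(0)
  for (def in defs) {
    h <- df[[paste0("hhi_", def)]]
    bad_rows <- union(bad_rows, which(!is.na(h) & (h <= 0 | h > 1)))
    ncol_ <- paste0("n_providers_", def)
    if (ncol_ %in% names(df)) {
      nv <- df[[ncol_]]
      bad_rows <- union(bad_rows,
                        which(!is.na(nv) & (nv < 1 | nv != round(nv))))
    }
  }
  if (length(bad_rows) > 0) {
    stop(sprintf("out-of-range competition values in row(s): %s",
                 paste(sort(bad_rows), collapse = ", ")), call. = FALSE)
  }
  for (def in defs) {
    ncol_ <- paste0("n_providers_", def)
    if (ncol_ %in% names(df)) {
      df[[paste0("is_monopoly_", def)]] <-
        !is.na(df[[paste0("hhi_", def)]]) &
        df[[paste0("hhi_", def)]] >= 1 - 1e-9 & df[[ncol_]] == 1
    }
  }
  tibble::as_tibble(df)
}

#' Write market polygons as GeoJSON
#'
#' One feature per market with properties `provider_id`, `definition` and
#' `area_km2`. Coordinates stay in the planar metric CRS of the input; the
#' CRS note is written to a sidecar `<path>.meta.json` file (GeoJSON itself
#' mandates geographic coordinates, so the planar CRS must travel alongside).
#'
#' @param markets list of [market_polygon()] objects (e.g. from
#'   [delineate_markets()]).
#' @param path output GeoJSON path.
#' @param crs free-text CRS description recorded in the sidecar file.
#' @return `path`, invisibly.
#' @export
write_markets_geojson <- function(markets, path,
                                  crs = "planar metric (e.g. SWEREF 99 TM / EPSG:3006)") {
  features <- lapply(markets, function(m) {
    ring <- rbind(m$boundary, m$boundary[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(
        provider_id = m$provider_id,
        definition = m$definition,
        area_km2 = m$area_km2,
        degenerate = m$degenerate
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  jsonlite::write_json(
    list(crs = crs, units = "metres",
         created_by = "caremarkets", n_features = length(features)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read market polygons from GeoJSON written by [write_markets_geojson()]
#'
#' @param path GeoJSON file path.
#' @return list of [market_polygon()] objects.
#' @export
read_markets_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  out <- lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], as.numeric))
    ring <- ring[-nrow(ring), , drop = FALSE] # drop closing vertex
    market_polygon(f$properties$provider_id, f$properties$definition,
                   ring, degenerate = isTRUE(f$properties$degenerate))
  })
  names(out) <- vapply(out, function(m) paste(m$provider_id, m$definition,
                                              sep = "."), "")
  out
}

#' Read / write scenario configuration files (TOML)
#'
#' Scenario configurations are stored as flat TOML with an optional `[[towns]]`
#' array of tables. `read_scenario_config()` returns a [synthetic_config()];
#' `write_scenario_config()` writes one (covering the flat key/value and
#' towns-array subset of TOML the configs use).
#'
#' @param path TOML file path.
#' @return for the reader, a [synthetic_config()].
#' @export
read_scenario_config <- function(path) {
  tl <- RcppTOML::parseTOML(path)
  towns <- if (!is.null(tl$towns)) {
    do.call(rbind, lapply(tl$towns, function(t) as.data.frame(t, stringsAsFactors = FALSE)))
  }
  args <- tl[setdiff(names(tl), "towns")]
  args$towns <- towns
  do.call(synthetic_config, args)
}

#' @rdname read_scenario_config
#' @param config a [synthetic_config()] to write.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  fmt_val <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (length(v) > 1) sprintf("[%s]", paste(fmt_num(v), collapse = ", "))
    else fmt_num(v)
  }
  lines <- character(0)
  for (nm in c("seed", "rural_fraction", "rural_extent",
               "choice_decay_lambda", "stale_fraction",
               "urban_cell_m", "rural_cell_m")) {
    lines <- c(lines, sprintf("%s = %s", nm, fmt_val(config[[nm]])))
  }
  for (i in seq_len(nrow(config$towns))) {
    lines <- c(lines, "", "[[towns]]")
    for (nm in names(config$towns)) {
      lines <- c(lines, sprintf("%s = %s", nm, fmt_val(config$towns[[nm]][i])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
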