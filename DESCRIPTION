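Package: caremarkets
Title: Local Market Delineation and Spatial Competition in Primary Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates local geographic markets around primary-care providers
    from provider and registered-individual coordinates in a planar metric
    coordinate system, and measures spatial provider competition within them.
    Implements fixed-radius hexadecagon markets, variable-radius markets based
    on the distance capturing a given share of a provider's nearest registered
    individuals, and variable-shape markets built from directionally trimmed
    registrant locations via a concave-hull (edge-digging) construction with an
    outward buffer. Competition is summarised per provider with the
    Herfindahl-Hirschman index, competitor counts and monopoly flags, together
    with descriptive statistics, Pearson correlations between market
    definitions, regional aggregation, radius calibration from trimmed
    provider-registrant distance distributions, and quartic-kernel density
    rasters. A synthetic population generator with clustered urban and
    scattered rural residences, distance-decay provider choice, grid snapping
    and stale-registration noise allows the full pipeline to run and be tested
    without confidential registry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    jsonlite,
    polyclip,
    RcppTOML,
    sp,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
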