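---
title: "Delineating local primary-care markets and measuring spatial competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating local primary-care markets and measuring spatial competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caremarkets)
```

## The problem

In patient-choice systems, primary-care providers compete spatially: people
mostly register with a provider near where they live, so the relevant market
for each provider is a local geographic area, not a national one. Measuring
competition therefore needs two ingredients: a delineation of each
provider's local market, and a concentration measure computed over the
providers and registered residents inside it. This package implements both,
for point data in any planar metric coordinate system (the motivating
setting is Swedish registry data in SWEREF 99 TM, where residence
coordinates are snapped to 250 m grid-cell centroids in urban areas and
1,000 m cells in rural areas, roughly 17% of residents).

Four market definitions are supported for each provider:

* **fixed_1km, fixed_3km** — a circle of identical radius around every
  provider, drawn as an inscribed hexadecagon (16-gon). A regular n-gon of
  circumradius r has area (n/2) r² sin(2π/n), so the 1 km and 3 km
  hexadecagons cover 3.06 km² and 27.55 km².
* **variable_radius** — a circle whose radius is the distance needed to
  capture the nearest 55% of the provider's registered individuals.
* **variable_shape** — a concave polygon built from the registrants'
  locations, so the market can follow commuter corridors, coastlines and
  asymmetric catchments instead of being forced to a disc.

## The variable-shape construction

1. *Outer trim.* Rank the provider's registrants by distance and keep the
   nearest 80%. This removes stale registrations: people who moved without
   re-registering, weekly commuters registered near their workplace, and
   similar artefacts of registration data.
2. *Directional trim.* Assign each remaining registrant to one of 8
   direction sectors of 45°, measured clockwise from due north (sector 1 is
   the north-to-north-east wedge, with half-open boundaries so a bearing of
   exactly 45° falls in sector 2). Within each sector, keep the nearest
   70%. Because sparse directions are trimmed at their own distance scale,
   dense directions keep deeper tails and the market leans toward where
   registrants actually live. The compound keep rate is at least
   0.8 × 0.7 = 56% of all registrants.
3. *Hull.* Add the provider's own coordinate and compute a concave hull of
   the kept points with concavity 3 and length threshold 100 m (below).
4. *Buffer.* Dilate the polygon outward by 10 m (Minkowski sum with a disc,
   round joins) so points lying exactly on the boundary are unambiguously
   inside. All point-in-polygon tests in the package are likewise
   boundary-inclusive, which matters for grid-snapped coordinates that can
   sit exactly on a polygon edge.

### Rank rule

Every "nearest p%" operation uses the same nearest-rank rule: keep ranks
1..⌈p·n⌉ of the ascending distance ordering, ties broken by stable input
order. The ceiling guarantees non-empty selections for any p in (0, 1], and
the same type-1 quantile convention is used for all reported percentiles.

### The concave hull

The hull follows the edge-digging construction: start from the convex hull,
and repeatedly consider each hull edge (a, b) of squared length L². Edges
shorter than the length threshold (100 m) are left alone. Otherwise the
candidate is the interior point closest to the edge, accepted when it is
strictly closer to this edge than to the two adjacent edges, when
connecting it to a and b crosses no existing boundary edge, and when it
lies within squared distance L²/concavity² of one of the edge's endpoints.
Accepted candidates replace the edge by two new edges, which re-enter the
work queue. Higher concavity values make digging harder and the hull more
convex; an infinite length threshold reproduces the convex hull exactly.

Two numerical consequences are worth knowing. First, digging operates at
the scale of a third of the current edge length (concavity 3), so empty
regions narrower than about three times the length threshold may be only
partially excavated; a long straight-walled empty notch can also stall
digging early, because candidates directly past a dug vertex are exactly as
close to the neighbouring edge as to the edge being dug and the strict
acceptance rule rejects them. The test suite pins both behaviours with a
brute-force reimplementation of the same algorithm. Second, duplicate
coordinates (common after grid snapping) are collapsed before hull
construction; containment is unaffected.

Degenerate inputs (fewer than 3 distinct points, or all collinear) fall
back to the buffered convex hull of the points plus provider — or a 10 m
disc around a lone provider — and the resulting market is flagged
`degenerate` rather than aborting a batch run.

## Measuring competition

For a market with N in-market providers (boundary-inclusive membership; the
focal provider always belongs, so the competitor count is at least 1), the
market share s_i of provider i is its number of in-market registered
residents divided by the number of in-market residents registered with
*any* in-market provider; residents registered with an outside provider are
excluded from the denominator, but still counted in the market's population
statistic. The Herfindahl–Hirschman index is

HHI = Σ_{i=1}^{N} s_i²,

bounded by 1/N ≤ HHI ≤ 1 (over providers with nonzero share), equal to 1
exactly for a monopoly. A market is flagged a monopoly when HHI = 1 *and*
N = 1. An alternative index, `overlap_hhi()`, instead defines the
competitor set as all providers whose own market polygon intersects the
focal polygon (boundary contact included); shares are still computed over
residents of the focal market, with overlapping providers lacking
in-market registrants carrying share zero. This interpretation of the
overlapping-competitors variant is the package's own, as published accounts
of the variant leave the share construction open.

`compute_competition_table()` assembles, per provider and definition, the
HHI, competitor count, monopoly flag, market area, resident population and
valid-registrant count; failures for individual providers (no registrants,
degenerate geometry, no validly registered resident) yield flagged `NA`
rows rather than aborting.

## What the synthetic generator emulates

`generate_population()` creates a provider table and an individual table
with the statistical structure the analysis assumes:

* **Residences.** Bivariate-normal clusters around configurable town
  centres, plus a uniform rural scatter sized so the overall rural share
  equals `rural_fraction` (default 0.17, matching the share of
  coarse-gridded residences in the motivating data).
* **Provider choice.** Each individual chooses provider j with probability
  proportional to exp(−d_j/λ). Registration data fit no published choice
  model, so any monotone distance decay suffices for testing; the
  exponential form is chosen for its closed form, sampled exactly with the
  Gumbel-max trick. The default λ = 2,000 m puts typical provider–registrant
  distances at a few kilometres, the scale at which the fixed radii of 1 km
  and 3 km are meaningful.
* **Registration noise.** A `stale_fraction` (default 0.02) of individuals
  has residences resampled uniformly over the extent after choosing,
  emulating movers who never re-registered — precisely the records the 80%
  outer trim and the 90% trim of `radius_calibration()` are designed to
  discard.
* **Anonymisation.** Residences are snapped to 250 m (urban) or 1,000 m
  (rural) cell centroids, so the package always sees coordinates with the
  granularity of the real data.

Everything is reproducible from `seed`, and the generator restores the
caller's RNG state. Five deterministic `known_structure_fixture()`
scenarios with analytically known outcomes (exact monopoly, exact 50/50
duopoly, isolated towns, an urban–rural mix, a commuter corridor) anchor
the tests.

The generator deliberately does **not** emulate: real Swedish population
density or geography, road-network or travel-time distances (all distances
are Euclidean), automatic registration of non-choosers with nearby
providers, or provider capacity constraints. Passing tests on synthetic
data therefore demonstrate correctness of the computations and the
direction of structural effects (e.g. small fixed markets over-declaring
monopolies in mixed landscapes), not calibration to any real market.

## Other numerical choices

* The variable-radius "circle" is drawn as a regular 64-gon (area error
  below 0.2%), keeping all market geometries polygons; fixed markets use
  16 vertices with the first vertex due north, a fixed orientation chosen
  for reproducibility (orientation affects membership only at second
  order).
* Buffering uses round joins with arc tolerance 0.002·d, keeping the
  dilated-square closed-form area identity within 0.1%.
* Monopoly detection compares HHI to 1 at tolerance 1e-9; share vectors
  must sum to 1 within 1e-9.
* Percentiles are nearest-rank (type 1) throughout; CSV floats are written
  with 6 significant digits so files round-trip within test tolerances and
  writers are byte-deterministic.
* Pearson correlations between definitions' HHI columns use Fisher-z 95%
  confidence intervals via `stats::cor.test()`, computed pairwise over
  providers with both measures defined.
* The quartic (biweight) kernel K(u) = (3/π)(1−u²)², u = d/bandwidth ≤ 1,
  is scaled to unit mass per point by default; a raw-count mode matches the
  heat values of GIS tools. The default bandwidth is 1,000 m.

## Problem sizes

The test suite runs on scenarios of roughly 10–30 providers and up to
~40,000 individuals, with 100 randomized brute-force cross-checks of the
HHI and percentile computations; the acceptance script generates an
eight-town landscape of 27 providers and ~42,000 individuals and completes
in seconds. These sizes were chosen so the whole pipeline — including the
pure-R concave hulls — exercises every code path while staying fast enough
to run routinely; the algorithms scale linearly in individuals and roughly
linearly in providers for the fixed definitions, with the concave hull the
most expensive step for providers with many registrants.

## Known limitations

* The geometry is strictly planar; inputs in geographic coordinates
  (longitude/latitude) must be projected first.
* The concave hull's stalling behaviour on long straight empty notches
  (above) means extremely elongated hollow catchments may be bounded less
  tightly than the parameters suggest.
* The overlapping-markets HHI share construction is an interpretation (see
  above).
* Registration data measure listed individuals, not active patients; no
  attempt is made to model utilisation.
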