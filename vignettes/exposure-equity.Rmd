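---
title: "Modelling who benefits from urban greening: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling who benefits from urban greening: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(greenequity)
library(dplyr)
```

## The question the package answers

City greening programmes are usually justified on average benefits: more
trees, less fine particulate matter (PM2.5), better health. But averages hide
distribution. If new trees land where the affluent already live, a programme
that improves air quality for everyone can still widen the exposure gap
between rich and poor. `greenequity` implements the full chain needed to ask
this question quantitatively: edit a land cover toward a greening target,
translate the added canopy into a PM2.5 surface, attach socio-demographic
structure to residential buildings, and compare population-weighted exposure
across subgroups before and after.

## The model chain

**1. Greening scenario.** The '3' and '30' components of the 3-30-300 urban
greening rule are applied as a deterministic land-cover edit
(`apply_330()`): every residential building gets at least two 5 m tree-canopy
cells within 30 m (the raster operationalisation of "three viewable trees"),
and every statistical zone is topped up to at least 30% green and blue space
cover. Only conversions *to* tree canopy are allowed; buildings and water are
never converted.

**2. Air quality.** A reduced-form meta-model maps the woodland fraction
`w` of a 3 km grid cell to a percentage change in PM2.5 concentration.
Two fitted models ship with the package:

* linear (Aarhus): `pcpm(w) = -3.9134 w - 0.1636`
* quadratic (Paris): `pcpm(w) = 6.0425 w^2 - 8.9865 w - 0.8939`

Both are validated at construction to be non-positive on the whole domain:
within these models, adding woodland never worsens air quality. The quadratic
model's removal strength peaks at `w = 8.9865/(2 * 6.0425) ~ 0.744` and
weakens beyond it, a documented artefact of the quadratic fit that matters
only for extremely wooded cells.

The percentage change is converted to an absolute change against a coarse
(3 km) background concentration field, bilinearly resampled to the fine
(1 km) grid, and added to an independent fine-resolution baseline surface —
the delta form of bias correction familiar from climate downscaling
(`scenario_surfaces()`). Both the current-landcover and the scenario deltas
are applied to the same fine baseline; the scientifically meaningful
quantity is their difference, which isolates the effect of the added trees.

**3. Disaggregation.** Zone-level subgroup counts (age, citizenship,
employment, education) are allocated to buildings dasymetrically
(`disaggregate()`): a building's subgroup population is the zone subgroup
proportion times the building's residents. Weights stay fractional end to
end; rounding to whole persons would break the conservation identity
(per-zone building sums equal zone counts) that every run asserts.

**4. Population-weighted exposure.** For each subgroup `a`, exposure is
`sum_u(pop_au * PM_u) / sum_u(pop_au)` over buildings `u`, with the PM2.5
value point-sampled from the fine surface at the building location, and
analogously for tree cover within 300 m of the building (reported in
hectares). Income has no per-person counts — each zone carries a single
median — so zones are ranked by median income, cumulative building
population is cut into fifths, and the class weight is the building's total
population. This reproduces the known consequence that income rows show more
extreme values than categories averaged over the whole city; the package
makes no attempt to smooth it.

**5. Gap report.** `gaps()` reports, per category, the spread of subgroup
exposures at baseline and under the scenario, the top-vs-bottom income
quintile gap, which subgroup benefited most (largest `|delta PM2.5|`), and
whether each gap widened or narrowed. Following the convention of the
published city tables, the headline gaps are computed from values rounded to
2 decimals; unrounded gaps are carried alongside.

## The synthetic city

Real inputs at this resolution (5 m land cover, building-level population,
census zone tables) are large and licence-encumbered, so the package ships a
generator (`generate_city()`) that emulates their structure: a 5 m
categorical land cover, 1 km and 3 km PM2.5 grids, a rectangular zone
tessellation, and buildings with log-normal populations. Three radial
gradients (centre value + slope per metre + Gaussian noise) control baseline
PM2.5, tree probability and zone median income; subgroup composition per
zone follows a softmax link on standardised zone income, so the sign of each
loading plants a recoverable income-composition relationship. Each random
field draws from its own child stream of the root seed, so changing one
gradient leaves the others bit-identical.

Two presets pin the contrasting spatial patterns of interest:
`city_config_paris_like()` (income rises outward, PM2.5 falls outward — the
poor live in the polluted centre) and `city_config_aarhus_like()` (the
affluent live in the polluted centre). At zero noise the pipeline must
recover the planted direction of the income-exposure gap; the test suite
checks this across 20 seeds for each preset.

What the generator does **not** emulate: street networks and traffic
point sources, realistic building footprints (buildings are points on a
single 5 m cell), zone shapes other than rectangles, temporal variation, and
any correlation structure beyond the three radial gradients. Passing tests
on synthetic cities therefore validate the *arithmetic and invariants* of
the pipeline, not the realism of any particular city's results.

## Numerical conventions and edge policies

* **Grids** are north-up, row-major, with half-open cells: a point on an
  interior cell edge belongs to the right/lower neighbour. Point sampling,
  zone membership and building-cell assignment all share this convention,
  so a building is never ambiguous between two cells or zones.
* **Buffer queries** (`cells_within()`) count cells whose *centre* lies
  within the radius, boundary inclusive — standard raster practice, and the
  brute-force oracle is trivial. The 300 m tree-cover buffer is taken from
  the building point (centroid), not a footprint edge; at 5 m resolution the
  difference is a one-cell ring.
* **Bilinear resampling** interpolates between source cell centres and
  clamps to the nearest edge value outside the centre lattice (constant
  extrapolation). City domains are interior crops of larger model domains,
  so reflected or NA edges would invent structure that is not there.
  Constants survive resampling exactly, and output never overshoots the
  local four-neighbour range.
* **Greening placement order** is fully deterministic: buildings ascending
  by id with nearest-first conversion (ties by row then column), then zones
  ascending by id with tree-adjacent cells preferred (ties by scan order).
  No randomness is consumed, so results are reproducible without recording
  a seed, re-application is a fixed point, and the placement log equals the
  raster diff exactly. `greening_params()` accepts a `seed` argument for
  interface stability but does not use it.
* **Eligibility**: grass, bare soil and sealed mineral surfaces can become
  trees; buildings and water cannot. Grass is *not* counted toward the 30%
  green/blue target by default (trees and water are), reflecting the view
  that the canopy target is about trees; the code-set is a parameter for
  users who read the target more inclusively.
* **Degenerate inputs** fail loudly at the right place: non-nesting grids,
  points outside a raster, zones without cell centres, zero-population
  zones containing buildings, all-equal zone incomes (quintiles undefined),
  and subgroups with zero total weight (exposure undefined) are all errors
  naming the offending object, while *infeasible greening targets* are
  reported in the result rather than raised — a zone of pure water and
  buildings is a finding, not a bug.

## Design choices that were genuinely open

* **The background field for the delta.** The percentage change is applied
  to the coarse modelled concentration under current vegetation, for both
  scenarios. An alternative reading uses a bare-soil counterfactual run as
  the background; with the fields available to a desk-scale pipeline the
  current-vegetation field is the defensible choice, and because the same
  background multiplies both scenarios, the scenario-minus-current
  difference — the quantity the equity report uses — is unaffected by a
  proportional rescaling of the background.
* **"Neighbourhood" = statistical zone.** The 30% target needs an areal
  unit; the statistical zone (IRIS/district analogue) is the unit on which
  social data live, and using it keeps the equity and greening geographies
  identical.
* **Income quintile boundaries** are population-weighted (cumulative
  building population cut at 20/40/60/80%), with a zone assigned to the
  quintile containing the midpoint of its population mass and ties in
  income broken by ascending zone id. With equal-population zones this
  reduces to one zone per fifth.
* **Gap arithmetic on rounded values.** Published tables print 2 decimals;
  computing headline gaps on the rounded values makes the package reproduce
  the quoted gap figures exactly, while the exact gaps are also reported.

## Problem sizes

The shipped tests exercise the full pipeline on 3 km cities (600x600
land-cover cells, 9 zones, 60-100 buildings) for property checks across many
seeds, and one 6 km city (1.44M land-cover cells, 25 zones, 2000 buildings)
for the brute-force oracle comparison of the exposure table. These sizes
give stable statistics for every planted-pattern check while keeping a full
`R CMD check` run in minutes.

## A worked example

```{r example, eval = FALSE}
res <- run_equity_pipeline(
  city_config_paris_like(seed = 1, n_buildings = 500),
  model = meta_model_paris()
)
format_exposure_table(res$exposure)
res$gaps |> select(category, gap_baseline, gap_scenario, direction)
res$pattern
```

## Limitations

The meta-models carry no per-cell uncertainty; predictions are deterministic
given woodland fraction. Only PM2.5 removal by deposition is modelled — no
barrier effects, no NO2 or ozone, no emission changes from depaving. The
'300' component of the 3-30-300 rule (a 1 ha green space within 300 m) is
out of scope, as are health-impact translations of exposure differences.
Exposure is residential and annual-average: time-activity patterns and
within-cell variation near traffic sources are invisible at 1 km
resolution.
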