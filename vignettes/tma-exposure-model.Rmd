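---
title: "The dynamic time-microenvironment-activity exposure model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dynamic time-microenvironment-activity exposure model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmaexposure)
```

## The model and its assumptions

`tmaexposure` estimates population exposure to ambient air pollution as the
product of three fields: concentration, population presence, and
outdoor-to-indoor infiltration. Per receptor-grid cell $i$, microenvironment
$j$ and hour $t$,

$$E_i = \sum_{j} F_{\mathrm{inf},j} \sum_{t} C_{i,t}\, P_{i,j,t},
\qquad
\mathrm{PWE}_i = \frac{E_i}{\sum_j \sum_t P_{i,j,t}},$$

with $E$ in µg/m³·persons (the hour weighting is implicit in the sum over an
hourly axis) and PWE in µg/m³. The central modelling assumptions are:

* **Homogeneous microenvironments.** Everyone attributed to an environment in
  a cell experiences the same concentration, namely the ambient receptor
  value attenuated by that environment's infiltration factor. There are no
  indoor sources, no per-building variation, no personal mobility traces.
* **Separable population dynamics.** The *number* of people in each
  environment per hour comes from diurnal activity profiles applied to a
  single total; the *location* of those people comes from static
  environment masks. Temporal and spatial dynamics are decoupled.
* **Well-mixed infiltration.** $F_{\mathrm{inf}} = C_{ai}/C_a$ is an
  averaged, seasonal constant per environment and pollutant — no air-exchange
  or deposition modelling.

Three approaches of increasing detail share this machinery. The **static**
approach has one environment: the full (growth-scaled) residential raster at
every hour. The **dynamic** approach distributes the population over home,
work, other and one aggregate transport environment (masks from land-use
classes; the transport class is "roads and associated land"). The **dynamic
transport** approach replaces the single transport environment with seven
mode environments built from tagged network polylines, with the hourly
transport total divided by a modal split. Home, work and other are identical
between the two dynamic approaches by construction.

## Spatial allocation

Each environment's hourly total is spread over its mask:

* **home** — proportionally to the residential raster. This choice makes the
  static approach an exact degenerate case of the dynamic one (a profile of
  100% home at all hours reproduces the static fields bit-for-bit, which is
  also a regression test), and is more realistic than uniform spreading.
* **work, other, transport and the seven modes** — uniformly over the mask's
  cells. No activity-density weighting is attempted; this deliberately
  matches the equal-distribution assumption stated for transport
  environments and keeps the model free of data that rarely exists city-wide.

Masks may overlap (one street hosts walking, cycling, cars and buses);
environments are tracked independently and no exclusivity is imposed.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| infiltration table | `default_infiltration_table()` | – | per environment × pollutant (NO2, PM2.5) × season; open-air modes fixed at 1; literature-averaged reference values |
| season months | winter = Oct–Mar | – | configurable in `season_of()`; splits a leap year 4392/4392 h |
| activity profiles | `default_activity_profiles()` | – | hourly fractions per day type; every row sums to 1; **generic, non-authoritative** — supply city-specific profiles when available |
| modal split | `hamburg_modal_split()` | – | 27% walk / 15% bike / 36% car / 22% public transport (bus 36, subway 32, suburban 25, regional 6, ferry 1 of the PT share); the negligible ferry share is dropped and the PT sub-shares renormalized so the seven modes sum to 1 |
| commuters | `commuter_spec()` | persons | placed in transport during rush windows (default 07–09, 16–19) and in work during working hours (09–16) on Mon–Fri; windows are configurable because "rush hours" has no canonical definition |
| growth factor | 1 (1.043 in examples) | – | rescales an older census raster to the study year |
| road-type weights | motorway 4 : trunk 3 : primary 2 : secondary 1 | – | stand-ins for generic traffic densities; monotone in expected volume, fully configurable |
| urban-core factor | 3 | – | multiplies road emissions in urban-centre cells to remediate the documented underestimation of regional inventories in dense cores |
| scenario factors | NO2 ×1.3 (ref) / ×1.4 (max); PM2.5 ×1.2 / ×1.3 | – | reference and maximum rescaling of road emissions derived from traffic-station biases; the minimum scenario is the unscaled inventory |
| F_inf band | ±20% on transport modes | – | generated min/max variants when no measured variant table is supplied, capped at the admissible bound 1.5 |

## Numerical choices

* Grids are planar metric, row-major with row 0 at the south edge, 0-based
  indices, half-open cell intervals $[o + k\,s,\ o + (k+1)\,s)$. Geographic
  inputs must be projected upstream; there is no reprojection engine.
* Polyline membership uses the *closed* cell square: any geometric
  intersection counts (Liang–Barsky segment clipping). This is deterministic
  and oracle-checkable against dense point sampling.
* Polygon-to-raster allocation is overlap-area weighted
  (Sutherland–Hodgman clipping + shoelace areas), which conserves counts and
  is resolution-stable. Rings must be simple; self-intersecting rings
  violate the contract.
* Exposure sums run in a fixed order (time innermost), so domain totals are
  bit-reproducible across runs and platforms.
* Differenced (zero-out) fields may be locally negative; values propagate
  unclipped, with a warning when more than 1% of cell-hours are negative.
* FAC2 excludes pairs with zero observations from the ratio count (logged);
  both factor-of-two boundaries are inclusive, as is the FAIRMODE 0.3 gate.
  The index of agreement is the classical Willmott form. Pearson r on a
  constant series is reported missing, never 0.
* Emission disaggregation combines the two weighting factors as a product,
  normalized once per cell: $w_k = \ell_k\,w(\mathrm{type}_k) / \sum_m
  \ell_m\,w(\mathrm{type}_m)$ — the natural reading of combining a length
  weight with a type weight, and the only form that is invariant to
  splitting a link into collinear sub-links. Cells with emissions but no
  intersecting road go to a residual ledger instead of being dropped, so
  mass is auditable: allocated + residual = grid total (to 1e-9 relative).
* The year length is always derived from the time axis (8784 hours for a
  leap year), never hard-coded.

## Decisions on genuinely open points

* **Does the static approach attenuate by the home infiltration factor?**
  Yes, for comparability across approaches — all three apply the same
  infiltration table. Passing `finf_table = NULL` disables infiltration
  entirely (exposure to raw ambient air) for users who want the
  address-based convention.
* **Commuters in the PWE denominator.** Commuters are counted wherever they
  appear in $P_{i,j,t}$; numerator and denominator stay symmetric by
  construction.
* **Ferry mode.** Dropped; its share is returned to the remaining
  public-transport modes by renormalization so that transport population is
  conserved.
* **Land-use and network tag mappings.** `default_lulc_mapping()` and
  `default_mode_queries()` encode the qualitative rules (cars include
  motorways, buses run on major roads but not motorways, walking uses foot
  infrastructure, the three rail modes pick their railway tags). Both are
  editable configuration, not ground truth, and should be adapted to the
  land-use product and network schema in use.

## What the synthetic city emulates — and what it does not

`generate_city()` builds a compact 3 km × 3 km domain at 100 m resolution: a
major-road lattice (all four road types) with foot/cycle infrastructure
alongside, a pedestrian centre, three rail lines, residential/work/leisure
blocks carrying 50,000 residents, an urban-core mask and a road-emission
grid allocated by in-cell road length. `generate_concentration_fields()`
produces a smooth diurnal background with seeded mean-one lognormal noise
(strictly positive by construction) plus a road-traffic increment
$\mathrm{peak}\cdot e^{-d/\lambda}\cdot s(h)$, where $d$ is the cell-centre
distance to the nearest road, $\lambda$ a decay length (default 150 m) and
$s(h)$ a bimodal rush-hour shape. Background levels (NO2 12, PM2.5
8.5 µg/m³) and increment peaks (20 and 4 µg/m³) echo typical European urban
conditions where regional background dominates PM2.5 while traffic dominates
near-road NO2 excess. Distances are computed on cell centres, consistent
with mask semantics.

The zero-out field is the background alone, so the injected increment is a
*constructed ground truth*: the source-contribution path must recover its
exposure exactly (to float tolerance), which validates the entire zero-out
accounting. Emission scenarios scale the increment linearly — a linearity
approximation standing in for re-running a dispersion model with scaled
emissions.

What the generator does **not** emulate: chemistry (no titration or
secondary formation), meteorology-driven advection, street-canyon
enhancement, spatially correlated background errors, activity-density
gradients within environments, or seasonal background cycles. Passing tests
therefore demonstrate the correctness of the exposure *accounting* — mass
conservation, linearity, oracle equivalence, qualitative orderings — not the
realism of any particular concentration field. Results on real cities depend
on the quality of the supplied concentration stacks, land use, profiles and
infiltration factors.

## Problem sizes

The test suite exercises oracle equivalence on 100 randomized instances of
up to 5 × 5 cells × 48 h × 7 environments, population conservation on a
14-day synthetic run, emission-conservation on 50 random grid/network
fixtures, and the qualitative transport ordering across 10 city seeds of
48 h each. The reproduction script (`scripts/acceptance.R`) runs the full
chain on two 14-day windows (January and July) of the default 30 × 30-cell
city — sizes chosen to exercise both seasons and every code path at desk
scale; all quantities are ratios or averages that are stable at these sizes.

## Known limitations

* No routing or origin–destination structure: transport populations are
  presence fields, not flows; inhaled dose (breathing rates per mode) is out
  of scope.
* Uniform in-environment distribution ignores density gradients (a city
  centre footpath counts like a suburban one).
* The aggregate transport environment of the dynamic approach and the seven
  mode environments come from different sources (land-use polygons vs
  network polylines) and are intentionally never reconciled; their exposure
  totals differ accordingly.
* Raster/stack I/O is CSV-based (with GeoJSON for vectors); the formats
  preserve geometry and full double precision but are not compressed —
  year-long full-resolution stacks are better kept in memory or written in
  windows.
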