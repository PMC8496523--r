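---
title: "Network catchments and gridded populations for campaign microplanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network catchments and gridded populations for campaign microplanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcatch)
```

## The problem

Health campaigns — vaccination above all — are planned facility by
facility through *microplans*: operational documents that state, for
each point of care, how many people it must serve, where they are, and
what resources (doses, vials, teams) that implies. Two inputs dominate
the quality of a microplan:

* **Where people are.** Census counts are often a decade old; gridded
  (dasymetric) population products redistribute census totals onto
  ~100 m raster cells using satellite covariates, stratified by age
  band and sex, and are far closer to the present-day distribution.
* **Who can actually reach a facility.** The conventional shortcut is
  a straight-line disc of radius *d* around the facility. People do
  not travel in straight lines; they follow roads, paths and ferries.
  A *network catchment* (service area) is the set of places within a
  travel-distance cutoff of the facility measured **along the
  transport network**, and can be dramatically smaller and
  differently shaped than the disc.

`microcatch` implements the full chain: transport-network
reachability, catchment polygons, zonal overlay with an age/sex
stratified population raster, covered and underserved population
accounting, grouped summary tables, and campaign resource estimates —
plus a seeded synthetic-data generator so the entire pipeline runs and
is testable offline.

## Data model

* `road_network` — undirected planar graph; nodes carry projected
  x/y in meters, edges carry a positive length, a travel-mode set
  (subset of walk/drive/ferry) and a class (road, path, ferry_line,
  railway, river). Lengths may differ from the straight-line endpoint
  distance (a winding road), and missing lengths are filled with it.
* `population_grid` — one non-negative integer raster per
  age-band × sex stratum, north row first (Esri ASCII grid order);
  the total layer is always recomputed from the strata, never trusted
  from disk.
* `catchment` — per facility: the snap location, the covered
  (possibly partial) edge segments within the cutoff, and the
  service-area polygon.
* `coverage_result` — per-facility population totals (overall and by
  stratum) under a stated assignment rule, plus the underserved cell
  mask and totals.

All coordinates are planar meters; geographic rasters must be
projected before use. No coordinate transformations happen inside the
package.

## Reachability and covered segments

A facility is first snapped to the nearest point of a mode-traversable
edge (ties broken by smallest edge id, for reproducibility). The snap
gap — the off-network distance between the facility and the network —
is **not** charged against the travel budget; this matches the usual
service-area semantics, where the cutoff describes travel along the
network. The source edge is split at the snap offset by a temporary
virtual node and single-source shortest paths are truncated at the
cutoff (igraph's Dijkstra under the hood).

An edge $(u, v)$ of length $L$ is then covered from each end with the
leftover budget: from $u$ on $[0, \min(L, c - d(u))]$ and from $v$ on
$[\max(0, L - (c - d(v))), L]$, where $c$ is the cutoff and $d(\cdot)$
the node distances; the source edge also carries the interval around
the snap offset itself. The union of these intervals is the covered
part of the edge — an edge is fully covered exactly when
$(c - d(u)) + (c - d(v)) \ge L$ with both budgets non-negative. These
sub-segments, not the node set, are what the polygon and the exclusive
assignment distance are built from.

```{r chain}
net <- road_network(
  data.frame(node_id = c("A", "B", "C"), x = c(0, 3000, 6000), y = 0),
  data.frame(edge_id = c("eAB", "eBC"), u = c("A", "B"), v = c("B", "C"),
             length_m = 3000, modes = "walk", edge_class = "road"))
src <- snap_facility(net, 0, 0, "walk", 10)
segs <- covered_segments(net, reachability(net, src, cutoff_m = 5000))
segs[[2]]$intervals  # edge B-C covered on [0, 2000] m
```

## From segments to polygons

The catchment polygon is the dissolved union of `buffer_m`-radius
neighbourhoods of all covered segments (plus a disc at the snap
point). Two representations coexist deliberately:

* **Containment is exact.** A point is inside the catchment iff its
  distance to the nearest covered segment is at most `buffer_m`. All
  zonal statistics, underserved masks and case assignment use this
  predicate, so no population number depends on a discretization.
* **The outline is a level set.** For export (GeoJSON), display and
  area, the boundary is extracted by marching squares
  (`grDevices::contourLines`) on the distance field at level
  `buffer_m`, with grid step `buffer_m / 4`. A level set yields the
  *dissolved* union directly and deterministically, with no polygon
  boolean operations; outline areas agree with Monte-Carlo estimates
  of the exact region to well under 2%. Straight-line disc baselines
  use a 128-gon (area error 0.04%).

`buffer_m` defaults to half the population-grid cell size (50 m for a
100 m grid): the polygon is then exactly thick enough that a cell
whose center sits on a covered road is captured, tying polygon
thickness to raster resolution.

Arbitrary polygons (e.g. administrative zones from GeoJSON) are
handled as explicit rings with an even-odd interior; a point exactly
on a boundary counts as inside.

## Zonal rules and conservation

Two inclusion rules are offered because gridded-population practice
uses both and the choice is rarely stated:

* `center` (default): a cell contributes its full count iff its
  center is inside the polygon. Integer-exact, and it **partitions**
  cells, so covered + underserved = grid total holds exactly, as
  integers, for any polygon set. Boundary centers count as inside —
  required for the partition property when polygons tile the plane.
* `fraction`: each cell contributes `count × (overlap area / cell
  area)`, computed by Sutherland–Hodgman clipping of the polygon
  rings against the cell rectangle, rounded only at the final
  per-stratum aggregate. Closer to area-weighted practice, but not
  integer-conservative.

## Assignment rules

Catchments overlap, and what "population of facility X" means then is
a modelling decision, so both semantics are implemented and labelled
in every output:

* `independent` (default): each facility gets the full population of
  its own polygon; people in overlaps are counted once **per
  facility**. This is the natural reading of per-facility summary
  tables, and the right basis for sizing each facility's campaign.
* `exclusive`: every covered cell is credited to exactly one covering
  facility — the one with the smallest cell-to-facility distance,
  ties broken by smallest facility id — so facility populations plus
  the underserved population partition the grid total exactly. The
  distance is the Euclidean hop from the cell center to the nearest
  point of the facility's covered segments plus that point's network
  distance to the source; a center farther than `buffer_m` from every
  segment falls back to the plain Euclidean distance to the snap
  point (a documented approximation — such cells are off-network
  anyway). Exclusive mode requires passing
  `catchment_distance_lookup()` explicitly, so the rule in force is
  always visible at the call site.

`independent` is never smaller than `exclusive` for any facility, and
growing the cutoff never shrinks a facility's independent population
nor grows the underserved total; both properties are exercised in the
test suite.

## Summary tables and pooling

`summarize_by_group()` produces the standard per-group row: number of
facilities, total population, mean, sample SD (divisor $N - 1$),
minimum, maximum. `combine_group_summaries()` pools rows through

$$ s^2 = \frac{\sum_i (n_i - 1)\, s_i^2 + \sum_i n_i (m_i - m)^2}{N - 1}, $$

with group means $m_i$ reconstructed from totals. Two display
conventions are fixed package-wide because they are the ones that make
pooled rows reproduce their member rows in the checkable cells of
published pilot tables: the **sample** SD (not population SD), and
rounding to the nearest integer **half away from zero** (base R's
`round()` would round half to even). All computation is done on
unrounded values; rounding happens once, for display. Rows with
$n = 1$ carry no SD and contribute zero within-group sum of squares.

## Resource estimation

The resource section of a microplan is parameterized minimally: per
facility, `target` is the covered population summed over the
campaign's target strata, and

* doses = ⌈target × doses_per_person⌉
* vials = ⌈doses × (1 + wastage_fraction) / vial_doses⌉
* teams = ⌈doses / (team_daily_throughput × campaign_days)⌉.

These formulas are this package's own minimal parameterization of
resource estimation; the other five microplan sections (cold chain,
operations, supervision, recording, monitoring) are emitted as
template placeholders in `microplan_sections.csv` so the written
report always shows the full structure.

## The synthetic generator

`synth_config()` + the `generate_*()` functions emulate the
*statistical structure* of the real inputs, not any specific product:

* **Population**: cell totals are Poisson with rate
  $\lambda(\text{cell}) = \text{background} + \sum_k A_k
  \exp(-d_k^2 / 2\sigma_k^2)$ over Gaussian settlement kernels —
  settlement-clustered, non-negative integer counts per ~100 m cell.
  Each total is split across an age/sex pyramid (WorldPop-style bands
  0, 1–4, 5–9, …, 80+ × f/m by default, with a stylized declining age
  structure and an even sex split) by a multinomial draw, so strata
  sum to the total in every cell by construction.
* **Network**: a jittered lattice with 10% edge dropout and random
  diagonal shortcuts, rewired (nearest cross-component pairs joined)
  until ≥ 90% of nodes sit in one component. A perturbed lattice was
  chosen over a random geometric graph so that network distances
  differ measurably from straight lines — the very gap catchments
  exist to model. Edge classes: 72% roads (walk|drive), 25% paths
  (walk), plus rare ferry lines and railways.
* **Facilities** are sampled proportional to cell population and
  pulled within `max_snap_m` of the network — facilities cluster
  where people are, as registries show.
* **Cases**: per catchment, Poisson with mean `rate × population /
  1000`, placed uniformly inside the polygon by rejection sampling.

One master seed drives four independent sub-streams (network,
grid, facilities, cases), so regenerating one component never
shifts another. Every generator is a pure function of its config.

What the generator does **not** emulate: satellite covariates and the
AI redistribution behind real gridded products, directed/one-way
roads, transit timetables, facility attribute noise, or spatial
autocorrelation beyond the settlement kernels. Passing tests on
synthetic scenes therefore demonstrates the correctness of the
*pipeline arithmetic* (reachability, overlay, conservation,
pooling) — not the realism of any particular population product.

## Numerical choices

* Snapping ties → smallest edge id; exclusive-assignment ties →
  smallest facility id; both make runs reproducible.
* Covered-interval unions merge at 1e-12 m; containment uses a 1e-9 m
  boundary tolerance.
* Poisson/multinomial draws use R's default RNG under per-component
  seeds; `set.seed` state is always restored afterwards.
* Degenerate inputs: a zero-area extent, a cutoff ≤ 0, an empty
  pyramid, or a facility farther than `max_snap_m` from the network
  raise classed errors (`invalid_config`, `invalid_cutoff`,
  `unreachable_facility`, …); batch building collects per-facility
  failures instead of aborting. A facility coinciding with an
  edgeless node yields a plain `buffer_m` disc.
* Test problem sizes were chosen to make the oracles affordable:
  exhaustive path enumeration on ≤ 8-node graphs (200 draws),
  brute-force cell scans on 30 × 30 grids (100 polygons), 50
  conservation scenes of 20 × 20 cells with 3 facilities, and 200-seed
  Monte-Carlo rate recovery. The full suite runs in well under a
  minute on one core.

## Known limitations

* No reprojection: inputs must already share one planar meter CRS.
* The fraction rule on network catchments clips the discretized
  outline, so its (non-integer) results inherit the outline's small
  approximation; the center rule does not.
* One-way restrictions, congestion, timetable-based transit and
  barrier handling are out of scope; a transit-like mode can only be
  represented as an edge mode label.
* Large rasters are held densely in memory; the package targets
  district-scale scenes, not continental mosaics.
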