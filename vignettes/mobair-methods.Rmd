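---
title: "Models and methods behind mobair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mobair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mobair` quantifies how much the standard practice of assigning long-term
outdoor air-pollution exposure at the residential address diverges from
mobility-integrated exposure estimates. This vignette documents the models,
their assumptions, the tunable parameters and the design choices made where
more than one reasonable convention exists. It states no empirical result;
every number the package reports is computed at run time by the test suite,
the worked example in the README, or `scripts/acceptance.R`.

## 1. Temporal rescaling of annual surfaces

Annual-average concentration surfaces (regular grids in a projected metric
CRS, 100 m cells by default) are rescaled to 48 long-term hourly surfaces —
one per (daytype, hour) with daytype ∈ {weekday = Mon–Fri, weekend =
Sat–Sun} — using diurnal ratios estimated from background monitoring
stations:

$$Ratio_{d,h} = \bar C_{BS}(d,h) \,/\, \bar C_{BS,annual}, \qquad
  C_P(d,h) = C_{P,annual} \cdot Ratio_{d,h}.$$

Conventions, where the estimator admits alternatives:

- **Station pooling is by grand mean** across all stations, in both the
  numerator and the denominator, giving one national ratio set rather than
  per-station ratios that are averaged afterwards. The two differ when
  stations have unequal baseline levels; the grand mean matches a
  denominator defined as the annual average "at all background stations".
- **Ratios are spatially constant scalars** per (daytype, hour): one ratio
  multiplies the whole surface. The hourly set is therefore stored as
  (annual surface, 48 ratios) and member grids are materialised on demand —
  an exact representation, not an approximation.
- **Calendar**: a synthetic year of 364 days = 52 exact weeks, starting on a
  Monday. This makes the weekday/weekend time weights exactly 5/7 and 2/7
  and turns the ratio-conservation identity
  $\tfrac57\,\overline{Ratio}_{wd} + \tfrac27\,\overline{Ratio}_{we} = 1$
  into an algebraic identity (it holds for any station data, noisy or not,
  because both sides are sums over the same 364×24 cells). Real calendars
  would add holiday and leap-day edge cases without changing the science.
- **Missing station hours** are excluded from both the numerator and
  denominator means.
- **Point lookup is nearest-cell** (the containing cell), never bilinear:
  points are overlaid on 100 m rasters in the same way field studies overlay
  address coordinates, and interpolation would silently smooth the exposure
  contrast the comparison is about. A point outside the extent, or on a
  nodata cell, yields a missing value — never an extrapolation.

## 2. The agent-based mobility model

Each agent is mapped to a profile by demographic rule: employed (full- or
part-time) → commuter, with a subcategory from sex × SES (9 subcategories:
all, male, female, male/female × low/mid/high SES; sex recorded as "other"
falls back to the pooled *all* subcategory); homemaker employment →
homemaker with an activity buffer of 1, 5 or 10 km (default 5); everyone
else → residential.

Per commuter realization: a work municipality is drawn from the agent's row
of the subcategory's O-D matrix, a work point uniformly inside that polygon
(rejection sampling); the commuting mode is drawn from P(mode | Euclidean
home–work distance band); the route is the shortest path across the
transport network between the nearest network nodes to home and work; the
weekday diary is home 00:00–08:00, commute, work until 17:00, commute, home
— with commute duration equal to the route travel time at the mode speed,
rounded **up** to whole minutes — and weekends are spent at home. Fifty such
realizations are drawn per commuter; their exposure mean and sample SD form
the ABM record. The known-workplace variant (ABMkWP) replaces the random
work location by the reported one and the random mode by the **modal**
(highest-probability) mode of the distance band, making it fully
deterministic, and uses a single realization.

Choices a maintainer should know about:

- **Default mode table** (fully overridable): < 2 km walk-dominant, 2–10 km
  bike-dominant, 10–40 km and beyond car/public-transport. Band boundaries
  are right-closed upward: a distance exactly on a boundary belongs to the
  upper band. Default speeds: walk 5, bike 15, car 45, public transport
  30 km/h — effective door-to-door urban speeds, not free-flow speeds.
- **Routing ties** are broken by the lexicographically smallest node-id
  sequence among co-optimal paths, so routes are reproducible even on
  symmetric networks. igraph performs the search; the tie-break is applied
  over the full set of shortest paths it returns, and the test suite checks
  the result against an exhaustive all-simple-paths enumeration on small
  graphs.
- **Node snapping**: home and work snap to their nearest network node; the
  off-network stub is ignored in travel exposure. Stationary locations
  dominate time (23 of 24 h for a typical commuter), so the stub's
  contribution is negligible relative to the 1-minute travel discretisation.
- **Homemaker diaries**: two 2-hour excursions (10–12 h and 14–16 h) at
  points uniform in the buffer disc, same pattern on weekdays and weekends,
  redrawn per realization. Residential agents are deterministic and get a
  single realization; homemakers, whose excursion points are their analogue
  of work-location randomness, get the full realization count.
- **Mode is redrawn per realization** together with the work location (the
  mode depends on the drawn distance); fixing it per agent would be the
  other defensible reading.
- **Commuter weekends are spent at home**; shopping/recreation time inside
  the weekday diary is modelled as home time. Multi-leg tours, time-varying
  speeds and transit timetables are out of scope.
- **RNG discipline**: one root seed; every stage and every agent gets a
  substream derived from (seed, name), so batch order and subsetting never
  change per-agent results.

## 3. Exposure aggregation

**Diaries.** A stationary diary entry contributes duration × the hourly
surface value at its point, hour by hour; a travel entry is discretised at
1-minute steps along the route polyline at the mode speed (a step at
36 km/h moves 600 m, about 6 cells of 100 m — finer steps change nothing
appreciable, coarser ones skip cells). The annual value is
(5·weekday-mean + 2·weekend-mean)/7 of the daily time-weighted means. Any
missing lookup makes the whole diary exposure missing, and **one missing
realization voids the agent's ABM record** — exposures averaged over a
censored subset of realizations would be biased toward the interior of the
extent.

**GPS tracks.** App (3–4 min cadence) and tracker (20 s) streams are merged
by timestamp; an app point within 10 s of a tracker point is dropped in
favour of the higher-precision tracker point. Exposure is a time-weighted
mean in which each inter-point interval, capped at 30 min to guard device
gaps, contributes its duration times the mean of its two endpoint
concentrations; intervals are split at clock-hour boundaries so every piece
is scaled by its own (daytype, hour) ratio. For a two-point track this
reduces to the equal-weight mean of the two points, and for a stationary
complete track it reproduces the residential exposure exactly. When the
campaign window is known, leading/trailing stubs are carried at the nearest
point's value (also capped). Intervals with an out-of-extent endpoint leave
both numerator and denominator; a record with less than 50% of its capped
time covered (configurable) is missing.

The SD across ABM realizations uses the sample (n−1) convention. Quantiles
in summary tables use linear interpolation between order statistics (R type
7). Bland-Altman differences are oriented first-argument minus second and
the proportional-bias line is an OLS fit of difference on pair mean.
Agreement categories close each band at its upper bound, with 0.16 itself
counting as moderate — the unique reading consistent with the published
bands and their worked examples (0.77 strong, 0.54 moderately strong, 0.96
very strong).

## 4. What the synthetic world emulates — and what it does not

The generator produces every input the pipeline consumes, so the whole
method is testable without any external data:

- **Pollution fields** = background + Gaussian urban plumes + spatially
  smoothed noise, floored at 0.01 µg/m³. Defaults emulate a 12 × 12 km
  urban region at 100 m resolution with NO2 ~12–35 µg/m³ (63 stations) and
  PM2.5 ~12–19 µg/m³ (9 stations) — the levels and station counts of a
  central-European setting. The urban gradient, not the absolute level, is
  what the metric comparisons depend on.
- **Diurnal shapes**: weekday double rush-hour peaks, weekend single flatter
  midday maximum, jointly normalised to unit (5/7, 2/7) time-weighted mean
  so the ratio estimator can recover them exactly at zero noise; hourly
  station values add multiplicative lognormal noise (sdlog 0.15, unit mean).
- **Municipalities** are axis-aligned rectangles tiling the extent. This
  keeps uniform in-polygon sampling exact while all polygon code paths
  (ray-casting containment, bounding-box rejection sampling) remain
  geometry-agnostic; O-D destination probabilities follow a gravity model,
  P(j | i) ∝ size_j · exp(−d_ij/λ), λ = 5 km scaled per commuter
  subcategory, each row renormalised to 1.
- **The transport network** is a jittered lattice with random diagonals;
  edge lengths are exact Euclidean distances, so the edge-length ≥
  straight-line invariant holds with equality. No real road data are
  imported.
- **PM2.5 modelling extent**: a 900 m corner block of the domain is nodata
  for PM2.5 (but not NO2), emulating a study region that touches the border
  of a national modelling surface. Because a single out-of-extent
  realization voids a record, even a corner holding well under 1% of the
  destination mass excludes a visible minority of commuters over 50 draws —
  the qualitative behaviour of a border city. An all-sides nodata margin
  was rejected: with 50 draws it excludes nearly every commuter.
- **Tracks** sample the ground-truth diary at both cadences with isotropic
  Gaussian positional noise (default 10 m; the mean displacement is then
  σ√(π/2)) and whole-agent tracker dropout with the app stream retained.

Passing tests on this world show that the pipeline's estimators are
internally consistent and reproduce the qualitative phenomena that motivate
the comparison (attenuation of exposure contrast by mobility, the positive
difference-vs-mean slope, the gain from averaging 50 realizations). They do
**not** show that real populations behave like the generator: real diaries
have multi-stop tours and day-to-day variation, real GPS has urban-canyon
multipath rather than isotropic noise, real O-D matrices are survey-based,
and real pollution fields have sources the plume-plus-noise model lacks.
Infiltration indoors and in-vehicle concentration factors are deliberately
out of scope, as is short-term (daily) exposure.

## 5. Problem sizes and numerical tolerances

The default study conditions are 500 agents with 50 realizations each, and
a 14-day GPS campaign; the acceptance script tracks 200 of the 500 agents,
and the bundled `tiny_config.yaml` (20 agents, 50 × 50 grid, 2-day tracks)
exercises the full pipeline in seconds for smoke testing and demos. Exact
identities (ratio conservation, hourly recomposition, RES ≡ ABM for
residential profiles) are asserted at 1e-9 or bit-identity; agreement
statistics are checked against explicit-sum oracles at 1e-10; GPS
ground-truth recovery is asserted at 2% relative error with zero positional
noise (the residual is track-cadence discretisation) and 5% median error at
25 m noise. Degenerate inputs are defined, not patched around: zero-length
commutes produce a diary without travel entries, a zero-variance difference
vector has R² = 0 by convention, and empty rosters or streams raise typed
input errors.
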