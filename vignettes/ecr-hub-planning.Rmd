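---
title: "Siting ECR hubs by travel-time coverage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Siting ECR hubs by travel-time coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrhubs)
```

## The planning problem

Endovascular clot retrieval (ECR) for large-vessel-occlusion stroke is
strongly time-dependent, but a 24/7 ECR service needs accredited
interventional neuroradiologists, dedicated angiography suites and
substantial funding, so a metropolitan area can sustain only a few hub
hospitals. The planning question is therefore: *given a pool of
ECR-capable hospitals, which subset of hubs lets the largest share of the
population reach a hub quickly, and how many hubs are enough?*

`ecrhubs` answers this with a travel-time coverage model. The inputs are

* population units ("suburbs": suburbs, postcodes, or any census unit)
  with a centroid and age-banded headcounts,
* candidate hub hospitals with coordinates,
* a matrix of peak-hour travel times from every centroid to every
  candidate, and
* age-specific annual first-ever stroke incidence rates.

## The coverage model

Write $T_{sh}$ for the travel time (minutes) from suburb $s$ to hospital
$h$, and let $S$ be a candidate hub subset. Each suburb joins the
catchment of its time-nearest selected hub,

$$h(s) = \arg\min_{h \in S} T_{sh}, \qquad t_s = \min_{h \in S} T_{sh},$$

and counts as *covered* when $t_s < \tau$ with threshold $\tau = 30$
minutes by default — a strict inequality, so a suburb at exactly 30.0
minutes is not covered. Thirty minutes is the idealised maximum transport
time used in metropolitan stroke-service redesign; it is a configurable
argument everywhere it appears. Per hub the model reports the catchment
size and the covered count and percentage; the headline score of a subset
is its total covered count $\sum_s \mathbf 1[t_s < \tau]$.

Because every candidate pool of practical size is small (five sites in
the motivating setting), `enumerate_hub_sets()` scores **all**
$\binom{n}{k}$ combinations exactly for each $k$; there is no greedy or
integer-programming approximation to reason about. `rank_models()` orders
models by covered suburbs, breaking ties by covered population at risk
and then lexicographically by hub ids, so rankings are deterministic.
`marginal_gain()` compares the best model at each $k$: when
$\text{best}(k+1) \le \text{best}(k)$, the extra hub is redundant — its
catchment is already absorbed by the others — which is the quantitative
form of the "how many hubs are enough" answer.

Three conventions matter for reproducing published coverage tables:

* **Ties** in travel time go to the hub listed first in the subset; the
  underlying data never justify a finer rule, and determinism is worth
  more than any alternative.
* **Percentages** are printed at one decimal with *half-up* rounding
  (`round_half_up()`), because published rows are only internally
  consistent under that rule; all totals are computed from raw integer
  counts, never by summing rounded percentages.
  `reconstruct_total_from_row()` implements the inverse check
  $\sum_h \mathrm{round}_{0.5\uparrow}(p_h c_h / 100)$ used to validate a
  printed row against its own total.
* **Unassignable suburbs** (no finite time to any selected hub) are
  excluded from the denominator with a warning rather than counted as
  uncovered; mixing "cannot be assigned" into "assigned but slow" would
  make coverage depend on data gaps.

## From coverage to caseload

Expected annual strokes per suburb are a deterministic projection, not a
simulation: $\lambda_s = \sum_b n_{sb} r_b$, with $n_{sb}$ the headcount
of age band $b$ and $r_b$ the band's annual first-ever stroke rate per
person-year. Census bands and incidence-study bands rarely coincide, so
`harmonize_bands()` first maps rates onto the population schema by
overlap-length-weighted averaging over single years of age (a band
labelled 0–64 spans 65 years, both ends inclusive). Open-ended bands are
matched to open-ended bands; for weighting, the open band is closed at a
cap age (default 100, raised automatically if a schema has a higher
finite bound). This is equivalent to assuming a uniform age distribution
within bands up to the cap; the year-by-year expansion used as the test
oracle makes the same assumption, and rates beyond the cap have
negligible population weight in any realistic schema.

A model's *population at risk* is the projected stroke count over covered
suburbs only, per hub and in total. With an ECR eligibility fraction $e$
(default 0.15, the proportion of strokes suitable for clot retrieval in
the motivating analysis) and $k$ hubs, the planning number is the average
annual per-hub caseload

$$\mathrm{round}_{0.5\uparrow}\!\left(\frac{e \sum_{s\,\text{covered}} \lambda_s}{k}\right).$$

Both $e$ and $\tau$ are arguments, not constants, since eligibility
criteria and acceptable transport times both drift as evidence evolves.
The rates shipped with the package (`synthetic_incidence_table()`) are
labelled synthetic: they have the right order of magnitude (about 1 per
10,000 person-years under 45, rising to a few per 100 at 85+) but are
illustrative only, and real planning must substitute the local incidence
study's table via `read_incidence()`.

## The synthetic travel model

Published analyses of this kind query a commercial routing API for
morning-peak drive times; that is neither reproducible nor runnable
offline. `ecrhubs` therefore defines a single provider contract — one
request `(origin, destination, scenario) -> minutes` with a per-session
request quota, default 2500, the familiar daily cap of commercial APIs —
and ships a fully synthetic provider:

$$\text{minutes} = \frac{d_{\text{gc}} \cdot \text{detour}}{v} \cdot 60
  \cdot m + \text{bias} + \varepsilon, \quad \text{truncated at } 0,$$

where $d_{\text{gc}}$ is the haversine great-circle distance (sphere of
radius 6371 km), detour $=1.3$ is a typical road-to-straight-line ratio,
$v = 60$ km/h is free-flow arterial speed, $m = 1.5$ is the morning-peak
congestion multiplier, bias (default 0) is an optional additive offset
such as an observed ambulance-vs-API difference, and $\varepsilon$ is
Gaussian noise with sd 3 minutes. The noise is drawn by inverse-CDF from
a hash of (origin, destination, scenario seed), so a pair's time is
reproducible without consuming the global RNG stream, and a whole matrix
is a deterministic artifact of its inputs and seed. Departure time is
modelled only as a scenario label plus congestion multiplier; the model
has no road network, so it cannot represent rivers, bridges or motorway
asymmetries.

`build_travel_matrix()` caches every result under its
(suburb, hospital, scenario) key in a long-format CSV, written after each
provider session: a warm re-run issues zero requests, an interrupted run
resumes, and a quota-capped provider is never asked more than its limit
per session. A live-API adapter only needs to implement the request
function; no network code exists in the package and none is exercised in
tests.

## The synthetic city generator

`generate_city()` provides complete, validated study data with known
ground truth. Defaults describe the metropolitan setting the pipeline is
aimed at: 226 population units and 5 candidate sites in a disc of 50 km
diameter; suburb totals log-normal (median about 8,000, sdlog 0.6 —
right-skewed, as census unit populations are); age structure
0.60/0.13/0.11/0.09/0.05/0.02 over the bands
0–44/45–54/55–64/65–74/75–84/85+, a typical large-city profile; band
counts split by largest-remainder rounding so they always sum to the
suburb total. Hospitals sit at k-means cluster centres of the centroids,
because real hospitals track population density rather than uniform
space. Everything is deterministic in the single spec seed.

What the generator does *not* emulate: true geography (roads, water,
radial density gradients), spatial autocorrelation of age structure
(retirement belts, young outer growth corridors), and measured travel
times. Tests passing on generated cities therefore demonstrate the
*correctness of the computation* — partitions, counts, rounding,
enumeration, determinism — not the realism of any particular coverage
percentage.

For exactness-critical tests there is a second, deliberately artificial
generator: `generate_known_coverage_city()` plants travel times directly
(covered suburbs at $\tau/2$, uncovered at $\tau + 15$, other hubs
further still) so each hub's catchment recovers a requested covered
fraction exactly. Statistical realism and test determinism are separate
concerns, and keeping two generators keeps both honest.

## Numerical and design choices

* Coordinates are WGS84 decimal degrees; all distances are spherical
  (radius 6371 km). No projected CRS is needed at city scale.
* The age-band schema is always declared (`age_bands()`), never inferred
  from CSV headers; a malformed or unexpected band column is a hard
  error naming the column.
* `validate_city()` reports *all* invariant violations instead of
  stopping at the first, and an empty report guarantees no downstream
  precondition failure; constructors enforce only local invariants, so a
  nonconforming bundle can still be loaded and diagnosed.
* Travel CSVs are written at 2 decimals (sub-second precision is noise);
  the provider cache is written at full precision because a cache hit
  must reproduce the provider value bit for bit.
* Degenerate inputs: empty catchments are legal (a dominated hub scores
  0/0 with an undefined percentage); `threshold = Inf` is legal and
  turns coverage into plain catchment membership, which is how the
  stroke-conservation property is stated; eligibility 0 and 1 are legal
  endpoints.
* The interactive-map layer of a planning study is replaced by static
  GeoJSON export (`export_catchment_geojson()`): one point feature per
  suburb with assigned hub, minutes and covered flag, consumable by any
  mapping front-end, with no hosted-service dependency.

Test problem sizes are chosen for tight feedback: random-instance
oracles run at 50×5, property sweeps use 20 seeded 60-suburb cities, and
full-size checks (226×5) run once through the bundled demo city. The
suite completes in well under a minute on one core.

## Known limitations

* Assignment is purely time-nearest: no hospital capacity constraints,
  no second-nearest fallback, no drip-and-ship vs mothership transport
  modelling.
* Incidence projection is a static expectation; it does not model the
  secular decline in stroke incidence, year-to-year variation, or
  uncertainty intervals.
* The synthetic travel model is monotone in distance by construction
  (up to noise); real road networks are not, and conclusions about any
  *specific* city require measured travel times fed in through
  `read_travel_matrix()`.
* Published tables of this kind are reproduced through their own
  printed per-hub values; rows whose printed totals are inconsistent
  with their own rows cannot be — and are not — forced to agree by
  tuning rounding.
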