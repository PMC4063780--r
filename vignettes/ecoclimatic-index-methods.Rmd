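---
title: "Modelling climate suitability for Miscanthus with an ecoclimatic index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling climate suitability for Miscanthus with an ecoclimatic index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclimex)
```

## The model

`ecoclimex` implements a CLIMEX-style mechanistic bioclimatic envelope model.
The premise is that a location's climate determines whether a species can both
*grow* during a favourable season and *survive* the unfavourable one. Both
aspects are summarized in the ecoclimatic index (EI), a 0–100 score of
year-round climatic suitability for a persistent population:

$$\mathrm{EI} = \mathrm{GI_A} \times \prod_s (1 - X_s),
\qquad \mathrm{EI} = 0 \text{ if } \mathrm{DD} < \mathrm{PDD},$$

where

* $\mathrm{GI_A} = \frac{100}{52}\sum_{w=1}^{52} \mathrm{TI}_w\,\mathrm{MI}_w$
  is the annual growth index, the yearly mean of a weekly temperature response
  $\mathrm{TI}_w$ times a weekly moisture response $\mathrm{MI}_w$;
* $X_s \in [0,1]$ are annual stress accumulations (cold, cold degree-day,
  heat, dry, wet, and optionally hot-wet);
* $\mathrm{DD} = \sum_w 7\,\max(0, \bar T_w - \mathrm{DV0})$ is the annual
  degree-day total above the development threshold, and PDD the minimum needed
  to complete a generation — a population that cannot complete its life cycle
  scores 0 regardless of growth.

An EI of 100 requires optimal temperature and moisture every week of the year
with no stress; in practice only very stable climates approach it. A
commonly used presence rule, adopted here as the default mask threshold, is
EI > 10 ("suitable" or better).

The engine operates on a 52-week year. Monthly climate normals (minimum and
maximum temperature, precipitation, relative humidity at 0900 h and 1500 h)
are anchored at month midpoints of a 365-day year and linearly interpolated to
week midpoints with wrap-around; weekly precipitation totals are rescaled so
the annual water mass is conserved exactly.

The commercial CLIMEX software's internals are not public. This package is a
documented, self-consistent approximation that matches the published
qualitative description of the model: trapezoidal (piecewise-linear) response
functions, a weekly time step, and multiplicative weekly survival for the
"exponential accumulation" of stress. It does not claim bit-for-bit agreement
with CLIMEX outputs, and the bundled reference statistics used for
verification are arithmetic replays of published summary tables, not engine
reproductions (see "What is and is not reproduced" below).

### Response functions

Both growth responses are trapezoids. For temperature, TI is 0 at or below
DV0, rises linearly to 1 at DV1, stays at 1 through DV2, and falls linearly to
0 at DV3. MI does the same on soil moisture with SM0–SM3. Trapezoids keep
every parameter in the published tables directly interpretable as a breakpoint
and make the response exactly testable against an independent piecewise-linear
oracle.

### Soil moisture

Moisture is expressed as a proportion of a soil bucket capacity $C$ (default
100 mm). Weekly:

$$\mathrm{SM}_w = \mathrm{clip}\!\left(\mathrm{SM}_{w-1} +
\frac{P_w - E_w}{C},\; 0,\; \mathrm{sm\_cap}\right), \qquad
E_w = k \,\max(0, \bar T_w)\,\Bigl(1 - \tfrac{\mathrm{RH}_w}{100}\Bigr)\times 7,$$

with evapotranspiration coefficient $k$ = 0.8 mm °C⁻¹ day⁻¹ and RH the mean of
the 0900 h and 1500 h values. The year is repeated from a configurable
starting moisture (default 0.5) until the 52-week cycle is stationary (max
change < 1e-6, at most 10 passes), so the reported cycle is independent of
mid-year transients. The upper clip `sm_cap` = 4 keeps limiting-high-moisture
points above 1 (up to 2.5 for *M. sinensis*) representable; values above 1
stand for transiently waterlogged soil.

A deliberate consequence of this minimal bucket (no explicit drainage term)
is that climates whose precipitation persistently exceeds evaporative demand
ride at the cap, where the high-moisture limit and wet stress dominate. That
emulates the exclusion of species from permanently waterlogged climates, but
it makes the humid end of the moisture axis coarser than a hydrological model
would be; conclusions about wet-margin behaviour should lean on the wet and
hot-wet stress parameters, not on the bucket's saturation detail.

### Stresses

Each stress accumulates weekly population reductions beyond a threshold:

$$i_w = \min(1,\; |\text{rate}| \times \max(0, e_w)), \qquad
X = 1 - \prod_w (1 - i_w),$$

with exceedance $e_w$ measured above or below the threshold depending on the
mechanism. Published parameter tables print some rates with a negative sign to
signal "accumulates below the threshold"; only the magnitude enters the
arithmetic here, the direction being fixed per stress. The weekly reduction is
capped at 1 *before* compounding; whether the original software caps before or
after is not documented, and the choice only matters in already-lethal
climates.

Drivers are chosen by mechanism: cold stress uses the weekly minimum
temperature (its threshold is a lethal minimum, e.g. −5 °C for rhizome kill),
heat stress the weekly maximum, growth and the hot-wet interaction the weekly
mean, and dry/wet stresses the soil-moisture cycle. The degree-day cold
mechanism ("cold stress affecting metabolism", threshold DTCS in °C) is
approximated as a second, milder low-temperature threshold on the weekly mean
with rate DHCS; the exact degree-day accumulator of the original software is
not published, and this approximation is flagged as such rather than claimed
equivalent. The hot-wet stress is a conjunction: it accumulates heat-type
reductions above TTHW only in weeks with soil moisture above MTHW, which is
what restricts *M. sacchariflorus* from warm, permanently wet tropical
climates; *M. sinensis* has no hot-wet block and returns 0 by contract.

### Species parameterizations

`load_species()` ships the two fitted Miscanthus vectors. Highlights (full
values in the object):

| | *M. sacchariflorus* | *M. sinensis* |
|---|---|---|
| DV0–DV3 (°C) | 5, 15, 28, 32 | 5, 15, 30, 35 |
| SM0–SM3 | 0.25, 0.8, 1.2, 1.8 | 0.25, 0.8, 1, 2.5 |
| TTHS / THHS | 32 / 0.06 | 36 / 0.05 |
| hot-wet (TTHW, MTHW, PHW) | 31, 1, 0.01 | — |
| PDD (°D) | 600 | 600 |

## Sensitivity analysis

`run_sensitivity()` implements the one-at-a-time protocol: every parameter is
moved down and up with all others held fixed — temperature-typed parameters by
±1 °C, moisture points, rates and PDD by ±10 % — the engine is rerun over the
grid, and the proportional change in the area of each EI class is compared to
the percent change in the parameter (always expressed relative to the baseline
magnitude, so 1 °C on a 5 °C threshold is 20 %). A parameter is *sensitive*
when any class's area changes proportionally more than the parameter did, in
either direction. A class with zero baseline area yields an undefined (NA)
change that never flags sensitivity on its own — this avoids division-by-zero
artifacts on small synthetic grids.

`sensitivity_replay()` applies the same criterion to the bundled reference
table of published per-class area changes, bypassing the engine. This
separates two claims: the criterion arithmetic (verified exactly against the
published sensitive/not-sensitive markings, 8 of 22 parameters for
*M. sacchariflorus* and 5 of 19 for *M. sinensis*) and the engine behaviour
(verified by properties on synthetic grids, since the original global rasters
are not redistributable).

## Equal-area accounting and classification

EI is classified into five classes, half-open on the right: unsuitable
[0, 1], marginal (1, 10], suitable (10, 20], favourable (20, 30], highly
favourable (30, 100]. Published summaries are ambiguous about whether
0 < EI ≤ 1 is "unsuitable" or "marginal"; the tabulated convention (EI 0–1 as
the lowest class, presence strictly above 10) is adopted and the bounds are
configurable via `ei_classification()`.

Instead of reprojecting rasters to an equal-area projection and resampling,
cell areas are computed analytically on the sphere:
$A(\varphi) = \frac{\pi R^2}{180}\,\Delta\lambda\,
|\sin(\varphi + \tfrac{\Delta\varphi}{2}) - \sin(\varphi - \tfrac{\Delta\varphi}{2})|$
with $R$ = 6371 km. This is exact, dependency-free, and sums to the sphere's
surface area over a global lattice; the GIS step it replaces was only ever a
means to equal-area counting.

## Scenario overlays

`range_change()` overlays a baseline presence mask (EI > threshold) with a
future one: *expansion* (future only), *contraction* (baseline only),
*no change* (present under both — absent-absent cells are not counted, which
is the convention that reproduces the published overlap arithmetic), and
*overlap* = no-change / (no-change + contraction), the fraction of the
baseline range retained. `agreement_index()` compares two projections:
presence-presence area divided by the area where exactly one predicts
presence; agreement about absence is deliberately excluded. Perfect agreement
(no disagreement area) is reported as a marker, not a number, and an empty
baseline makes overlap undefined rather than zero.

`comparison_summary()` returns unrounded group means. The published averages
round half-down in one case (a 2080 model-agreement mean of 0.8125 printed as
0.81), so rounding is left to presentation rather than baked into the
statistic.

## Synthetic climate and occurrences

`generate_grid()` produces a deterministic (per seed) lattice of monthly
climatologies with the structural features of gridded normals: mean annual
temperature falling 0.45 °C per degree of latitude from 28 °C at the equator,
seasonal amplitude growing 0.28 °C per degree (opposite phase in the two
hemispheres), a fixed 8 °C diurnal range, and 30°-wide longitude bands cycling
through humid (85 mm/mo), seasonal (15–105 mm/mo, summer-wet) and arid
(12 mm/mo) precipitation regimes with morning RH of 80/65/40 %. Small per-cell
multiplicative precipitation noise (±10 %) and additive RH noise (±5 points)
are the only stochastic components; temperature is purely functional so the
latitudinal-monotonicity property is exact. The default 2° resolution keeps a
global run in seconds; it is a knob, not a constraint of the method. Scenario
deltas are additive for temperature and multiplicative for precipitation and
RH, the standard downscaling convention.

What the generator does *not* emulate: orography, continentality, realistic
spatial autocorrelation of anomalies, inter-annual variability (grids are
already climatologies), or land/sea masks. Passing tests on synthetic grids
therefore demonstrate the engine's internal correctness and the analysis
pipeline's arithmetic, not predictive skill on real climate data.

`sample_occurrences()` draws presence-only points with probability
proportional to max(EI, noise floor), jittered within the cell, and labels
them native/introduced and given/inferred in fixed proportions — enough
structure to exercise the validation path (`validate_occurrences()`), which
scores each point by the EI class of its nearest cell (ties to the lower
index, no interpolation) and summarizes percentages per record category.

## Numerical choices and degenerate inputs

* Week/month anchoring uses a 365-day year; the 7/364-versus-365 mismatch is
  absorbed by the precipitation rescaling and is irrelevant for temperatures
  (pure interpolation).
* Degenerate trapezoids (equal adjacent breakpoints) become step functions.
* The soil bucket's spin-up tolerance (1e-6) and pass cap (10) make grid runs
  deterministic and independent of the initial transient in all but pathological
  cases; the starting moisture matters only in exactly-balanced climates,
  where it is the user's lever for placing the moisture cycle.
* Perturbing a zero-valued (inert) parameter is recorded as a 0 % move and can
  never flag sensitivity.
* All validation errors name the offending input; lattice mismatches are
  errors, never silent reindexing.

## Problem sizes used in the bundled checks

The test suite runs the engine on lattices between 3×3 and 14×7 cells, and one
full synthetic world at 2° (12,600 cells, both species, baseline plus a
uniform +2 °C delta); the acceptance script repeats the full-world run. These
sizes were chosen as the smallest that exercise every code path (all five EI
classes populated, both range edges inside the lattice); the engine is
vectorized across cells, so far larger grids scale linearly.

## Known limitations

* The engine is an open approximation; absolute EI values will differ from
  the commercial implementation even under identical parameters, which is why
  verification replays published *derived statistics* and engine *properties*
  rather than published absolute areas.
* The bucket model's saturation behaviour (above) coarsens the humid margin.
* One-at-a-time sensitivity ignores parameter interactions by design; it is
  the published protocol, not a global (e.g. variance-based) analysis.
* Occurrence validation here uses synthetic, sampler-generated records; the
  published validation percentages depend on raw occurrence data that are not
  redistributed with the package, so they are not claimed to be reproduced.
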