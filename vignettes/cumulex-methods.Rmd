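---
title: "Methods: cumulative extreme-event mapping with cumulex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative extreme-event mapping with cumulex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Discrete extreme events — marine heatwaves (MHW), land heatwaves (HW),
extreme winds at sea and on land, and extreme precipitation — act on
ecosystems through different channels: intensity relates to abrupt
mortality, duration to prey-field disruption and attrition, frequency to
recovery capacity. Assessing risk to a species that uses both land and
sea (penguins are the motivating case) therefore requires detecting each
event type on daily gridded fields, mapping the *cumulative* burden of
all types per pixel, asking where that burden is *increasing*, and
summarizing both inside the species' distribution hotspots.

`cumulex` implements that chain end to end, and ships a synthetic-data
generator with fully known ground truth so every stage is testable
without downloading observational archives.

## Event detection

An extreme event at a pixel is a maximal run of days whose value
strictly exceeds the *seasonally varying 90th percentile* of that
calendar day, kept when the run lasts at least 5 days (MHW, the marine
convention) or 3 days (atmospheric types). The climatology pools, for
each calendar day `d`, all values within `d ± 5` days (window 11)
across every year of the record, takes the empirical percentile
(type 7), and smooths the 365-day curve with a centred 31-day circular
moving average. The seasonal mean is built identically with the mean in
place of the percentile. Defaults (window 11, smooth 31) follow the
standard marine-heatwave convention and are configurable, as is the
pooling window for atmospheric variables (heatwave indices in the
literature use windows of similar order, e.g. 15 days).

Deliberate choices, each exposed as an argument:

* **Strict exceedance** (`>`). A constant record then has zero events —
  the unambiguous degenerate case.
* **No detrending, full-record baseline.** Trends are part of the signal
  of interest; thresholds and events are computed on the same record.
* **No gap joining** by default (`join_gap = 0`): an event is literally
  a run of consecutive exceedance days. The optional join (e.g. 2-day
  gaps) exists but is off.
* **Minimum duration is inclusive** (`min_rule = "geq"`, runs `>=` 5 or
  3 days are kept). The strictly-greater reading is available as
  `min_rule = "gt"`.
* **Intensity is the anomaly relative to the seasonal mean** averaged
  over event days; anomaly above the threshold is available via
  `intensity_ref = "threshold"`.

Event metrics per pixel: `intensity` (mean of event mean-anomalies,
field units), `duration` (mean event length, days), `frequency` (total
event days per year). Pixels searched but event-free carry frequency 0
and missing intensity/duration.

Coastal `mixed` cells belong to both the sea-role mask (used for MHW and
wind at sea) and the land-role mask (HW, wind on land, precipitation),
so the coast is never silently dropped from either environment.

## Cumulative stacking

Each metric layer is min–max normalized over its environment mask,

x' = (x − x_min) / (x_max − x_min),

so layers with different units become comparable on [0, 1]. The
normalized layers of one environment are summed with equal weights and
the total re-normalized to [0, 1] with the same formula. The formula is
invariant to positive affine transforms of its input, which is what
makes equal-weight stacking meaningful. A spread-free layer
(`x_max == x_min`) maps to all zeros with a warning rather than failing:
the layer carries no ranking information but should not abort a
pipeline. The phrase "re-normalize so the final layer sums to one"
admits a second reading; a field-total normalization is available via
`renorm = "sum"`, but the default is min–max, which is what a 0–1 map
legend implies.

Attribution: for means, the per-pixel *dominant* type (argmax of the
normalized values, ties broken by the fixed canonical order MHW,
wind_sea / HW, wind_land, precip — determinism matters more than the
specific order); for trends, the *set* of retained types (combination
map), since several types can increase at once.

Normalized cumulative values are classified into quartile classes:
[0, 0.25) low, [0.25, 0.5) medium, [0.5, 0.75) high, [0.75, 1] very
high (left-closed bins, top bin closed).

## Trends

Annual series per pixel: events are assigned to the year containing
their start day with their full duration (an event is one biological
disturbance; splitting it across a year boundary would create two
phantom short events). Years without events carry 0 event days and
missing intensity/duration. Ordinary least squares of the annual metric
on the centred year index gives slope and a two-sided t-test p-value;
centring changes nothing statistically but conditions the normal
equations. Pixels with fewer than 10 non-missing years (configurable)
are not fitted — intensity and duration series at rarely-affected pixels
are otherwise dominated by a handful of values. Edge conventions: a
constant series has slope 0 and p 1 (no evidence of change); an exactly
linear non-constant series has p 0.

Only pixels with slope > 0 and p < alpha (default 0.05, the conventional
level; the source method states none) enter cumulative trend maps —
increasing extremes are the ecologically threatening direction. No
multiple-testing correction is applied across pixels, matching the
per-pixel significance convention of the underlying method; serial
correlation of annual metrics is likewise not modelled (plain OLS).
Annual aggregates of daily noise with AR(1) persistence of ~0.5
decorrelate almost completely year to year, so the nominal one-sided
0.025 retention rate on trend-free records is approximately honoured —
this is checked empirically in the test suite.

Area accounting reports, per environment and metric, the percentage of
environment-role cells retaining ≥ 1 type, exactly 1, and ≥ 2
(overlap), broken down by specific combination; single + multiple =
any is an exact partition identity.

## Hotspot exposure

Hotspot polygons are rasterized by *intersection* with grid cells
(default): a colony polygon hugging a cell edge still counts. The
centre-in-polygon rule is available (`rule = "centre"`). Each species
gets a sea-role and a land-role mask; an island polygon smaller than a
grid cell that sits inside a sea-classed cell yields an empty land-role
mask and missing land rows — the real-world case of a species breeding
on islands too small to resolve at 1°.

Mean exposure: per species and event type, the mean metric over the
role mask; the cumulative value is the sum of those means across types
(types with no data inside the mask are excluded from the sum);
contributions are each type's share. Species cumulative values are
normalized by the group maximum within each metric × environment, so
exactly the most-exposed species scores 1 per group.

Trend exposure: mean retained slope per type (0 when no cell is
retained), **divided by the species' total role-mask cell count** — not
the retained count. The divisor choice is what makes the adjustment
shrink values for species whose hotspots are mostly trend-free; dividing
by retained cells would do the opposite. Coverage % is reported per
type and as the union across types (both are emitted because a headline
"share of hotspot with increasing extremes" can reasonably mean either).
A species with no retained cell in any type reports zero cumulative
trend and zero coverage — the "no increasing trends in this hotspot"
outcome is an ordinary value, not an error.

## The synthetic generator

`generate_daily_cube()` realizes: sinusoidal seasonal cycle (period 365,
Southern-Hemisphere peak at calendar day 15, phase flipped north of the
equator) + stationary AR(1) noise (marginal sd `noise_sd`, lag-1
autocorrelation `ar1`) + optional linear level trend + injected episodes
of known pixel/start/duration/amplitude. The calendar has no leap days:
a 365-day year removes February-29 special-casing from climatology
logic (real-data ingestion would drop Feb 29 on load). SST is missing
over land-classed cells, as in observational SST products.

Per-variable defaults are fixed once at field-realistic magnitudes: SST
12 ± 4 °C (noise sd 0.8, AR1 0.8 — ocean temperature is strongly
persistent), air temperature 10 ± 8 °C (sd 3, AR1 0.6), wind components
~3 and ~1 m/s (sd 2.5, AR1 0.5), precipitation ~2 × 10⁻⁴ m/h
(sd 1.5 × 10⁻⁴, AR1 0.3). A 31-year record mirrors a 1993–2023
baseline.

What the generator does *not* emulate: ENSO and other teleconnections,
frontal dynamics, skewed/intermittent precipitation (the noise is
Gaussian, so simulated precipitation can dip below zero — harmless for
threshold exceedance logic, wrong as a physical rain model), spatial
correlation of noise between pixels. Consequently, passing tests
demonstrate the *machinery* (thresholds, run logic, stacking,
regression, masking) is correct under known statistical structure; they
do not validate ecological conclusions drawn from any particular real
data set.

`generate_hotspots()` always produces one coastal polygon spanning land
and sea cells, one strictly marine polygon, and (n ≥ 3) one sub-cell
islet whose land rasterization is empty; further species are seeded
random rectangles, sometimes two per species to exercise the merge of
breeding/non-breeding ranges.

## Numerical and design notes

* Quantiles are empirical type 7 everywhere (R's default), so the
  package and any brute-force check agree to rounding error.
* The circular smoother convolves with ones and divides by the window
  length; `rep(1/k, k)` does not sum to exactly 1 in floating point, and
  that one-ulp slack would make a constant field "exceed" its own
  threshold under strict comparison.
* Min–max re-normalization of an all-equal stack warns and returns
  zeros (information-free, not an error).
* Ties in the dominant-type argmax go to the canonical order; tests
  rely on this determinism.
* Cube files are a one-line JSON header plus CSV with doubles printed
  at 17 significant digits, so values round-trip bit-identically.
* All randomness is seeded explicitly; a pipeline run is a pure function
  of its configuration, and re-runs are byte-identical.

## Validation experiments (sizes and expectations)

The test suite validates the chain on synthetic ground truth at sizes
chosen to finish in minutes on one core:

* Climatology against a brute-force pool-percentile-smooth oracle on a
  3-year, 5 × 5 cube (agreement to 1e-9).
* Episode recovery: 100 replicates of a 31-year single-pixel record,
  one 10-day episode per year at seeded random start days, amplitude
  4 × noise sd on AR(1) = 0.5 noise. Expected: recall ≥ 0.95, ≥ 90 % of
  recovered events within ± 2 days of the true duration. Full-length
  records matter here: on very short records an episode contaminates a
  sizeable share of its own pooled threshold window and clips itself.
* Occurrence-trend recovery: 200 replicates with injected annual event
  days rising ~0.5 days/year (a one-episode-per-year staircase of
  durations 10 + ⌊y/2⌋; the exact OLS slope of that staircase is the
  truth compared against). Expected: mean recovered slope within 10 %.
  Randomized start days keep any single calendar day's pooled window
  clean; injecting at a fixed day every year concentrates contamination
  in late years and biases recovered durations down.
* Type-I: on trend-free replicates the positive-and-significant filter
  (two-sided p < 0.05 plus positivity) retains a fraction compatible
  with the nominal one-sided 0.025 (accepted band 0.025–0.075).
* End-to-end: a 20 × 20-cell, 31-year, 5-variable, 4-species scenario
  completes and re-runs byte-identically.

`scripts/acceptance.R` re-runs scaled versions of these experiments
(40–60 replicates) plus a 14 × 14 pipeline and writes the resulting
quantities as JSON.

## Known limitations

* Plain OLS p-values ignore serial correlation of annual metrics; for
  strongly persistent annual series the filter is anti-conservative.
* No multiple-testing control across pixels (an FDR variant would be a
  natural extension; the area-fraction accounting would then shrink).
* The generator's Gaussian noise under-represents precipitation
  extremes; detection behaviour on heavy-tailed variables is exercised
  only through the percentile mechanism, not through realistic tails.
* Bilinear regridding does not extrapolate: target centres outside the
  source-centre hull, or drawing on any missing source cell, are
  missing. This is intentional at coastlines.
* Compound-event timing (do two types co-occur in time, not just in
  space?) is out of scope; spatial overlap is what is quantified.
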