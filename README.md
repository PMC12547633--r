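# cumulex

Cumulative extreme-event mapping and species exposure on gridded daily
fields.

Ecosystems are increasingly hit by several kinds of extreme event at
once: marine heatwaves (MHW) and extreme winds at sea; land heatwaves
(HW), extreme winds and extreme precipitation on land. For species that
depend on both environments — penguins are the archetype — risk
assessment needs more than one event type on one map: it needs the
*cumulative* burden per pixel, where that burden is *increasing*, and
how both overlap each species' distribution hotspots. `cumulex`
implements that chain for analysts working with daily gridded fields
(SST, 2 m air temperature, 10 m wind components, precipitation) on a
regular latitude/longitude grid.

## The method in brief

1. **Detection.** For each variable and pixel, an extreme event is a
   maximal run of days strictly exceeding the seasonally varying 90th
   percentile (per calendar day: values pooled in an 11-day window
   across all years, percentile taken, 31-day circular smoothing),
   lasting at least 5 days (marine) or 3 days (atmospheric). No
   detrending; trends are part of the signal. Events are summarized per
   pixel into intensity (mean anomaly vs. the seasonal mean, field
   units), duration (mean event length, days) and frequency (event
   days/year).
2. **Cumulative maps.** Each metric layer is min–max normalized,
   x′ = (x − x_min)/(x_max − x_min), over its environment (sea stacks
   MHW + wind; land stacks HW + wind + precipitation), summed with
   equal weights, re-normalized to [0, 1], and attributed to the
   per-pixel dominant event type.
3. **Trends.** Per-pixel ordinary least squares of annual event metrics
   on the year index (slope + two-sided p). Only positive and
   significant slopes (p < 0.05) are kept, stacked like the means, and
   attributed as per-pixel *combinations* of increasing event types,
   with area-fraction accounting.
4. **Hotspot exposure.** Species polygons are rasterized
   (intersection rule; coastal `mixed` cells count as sea for sea
   events and land for land events), mean and trend exposure are
   tabulated per species × environment × event type, normalized by the
   per-group maximum across species, and trend means are adjusted by
   the hotspot's total pixel count, with coverage percentages.

A synthetic-data module (seasonal cycle + AR(1) noise + level trends +
injected episodes of known start/duration/amplitude, plus hotspot
polygons including sub-pixel islets) provides ground truth for every
stage; the whole package runs without any external download.

## Worked example

```r
library(cumulex)

# an 8x8 one-degree grid: three land columns, one mixed coastal column
surf <- matrix("sea", 8, 8); surf[, 1:3] <- "land"; surf[, 4] <- "mixed"
grid <- grid_def(-8, 0, 0, 8, cell_size = 1, surface = surf)

# ten years of daily SST, with a known 12-day, +4 degC episode injected
sst <- generate_daily_cube(field_spec("sst", grid, years = 10, seed = 42))
sst <- inject_episodes(sst, episode_spec(4, 6, start = 1200,
                                         duration = 12, amplitude = 4))

clim <- daily_climatology(sst, window_days = 11, smooth_days = 31,
                          percentile = 90)
mhw <- detect_events(sst, clim, pixel_mask = surface_mask(grid, "sea"))
mhw
#> <event_catalog> MHW: 683 events over 10 yr on 8x8 grid

# the injected episode is recovered at its exact days
subset(mhw$events, lat_idx == 4 & lon_idx == 6 & start == 1200)
#> # A tibble: 1 x 6
#>   lat_idx lon_idx start   end duration mean_intensity
#>     <int>   <int> <int> <int>    <int>          <dbl>
#> 1       4       6  1200  1211       12           3.32

summarize_events(mhw)$frequency
#> <metric_layer> MHW frequency [days/year], 40/64 pixels non-missing

# increasing-event pixels: OLS on annual event days, keep positive p<0.05
tr <- filter_positive_significant(
  ols_trend(annual_metrics(mhw), "frequency"), alpha = 0.05)
sum(tr$retained)
#> [1] 0
```

The 683 background events are ordinary noise exceedances of the 90th
percentile (about 36 days/year before the duration filter); the
injected episode comes back with its exact start, end and duration, and
a mean intensity of 3.32 °C — the +4 °C amplitude averaged against the
noise on those days. On this trend-free record, no pixel passes the
positive-and-significant filter, which is the correct answer.

For the full chain (five event types, cumulative mean and trend maps,
combination attribution, area fractions, species exposure tables) see
`run_pipeline()`:

```r
cfg <- pipeline_config(grid, years = 31, n_species = 4,
                       outdir = "cumulex_out", seed = 1)
res <- run_pipeline(cfg)
res$area_fractions          # % of each environment with increasing extremes
res$mean_tables$sea_intensity  # species ranking, sea intensity
```

Re-running an identical configuration reproduces every product file
byte for byte.

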