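# ecostab

Vegetation resistance and resilience to multi-year dry periods, estimated
per pixel from gridded NDVI time series and station precipitation records,
and summarized along the mean-annual-precipitation (MAP) gradient.

## What it computes

Semi-arid grasslands are shaped not only by single-year droughts but by
*dry periods* — runs of many consecutive below-average precipitation
years. Given a normal / dry / recovery partition of the year axis,
`ecostab` computes for every pixel

```
rain reduction  = (Pnormal    - Pdry)    / Pnormal
NDVI reduction  = (NDVInormal - NDVIdry) / NDVInormal
resistance      = rain reduction / NDVI reduction
resilience      = NDVIpost / NDVInormal
```

where `P*` and `NDVI*` are period means. Resistance normalizes the
vegetation response by the precipitation forcing each pixel actually
experienced (resistance > 1: NDVI declined proportionally less than
rainfall); resilience compares the post-dry-period state to the
pre-dry-period baseline (1 = full recovery; a dry-state denominator is
available via `resilience_denominator = "dry"`). Pixels whose NDVI
reduction is below 1% (likely human-disturbed) or that saw no rain
reduction are excluded, with auditable exclusion reasons.

Around the metrics sit the pipeline stages:

* **raster IO** — ESRI ASCII-grid stacks (one band per year), composite
  aggregation to annual NDVI, bilinear/nearest resampling, masking;
* **interpolation** — per-year thin-plate smoothing splines (via `mgcv`)
  from station CSVs to the analysis grid, penalty fixed or by GCV;
* **periods** — regional anomaly series and explicit or automatic
  detection of the dry run of years;
* **gradient analysis** — 50 mm MAP binning, linear-gate model
  selection over linear / exponential / quadratic / cubic candidates
  with R² comparison, confidence bands, and closed-form curve peaks;
* **synthetic scenes** — a seeded generator with known ground-truth
  resistance/resilience surfaces for end-to-end verification;
* **orchestration** — `run_pipeline()` driven by a YAML config, plus a
  thin CLI at `inst/cli/ecostab.R`.

## Worked example

Synthetic scenes stand in for downloaded archives; everything is
reproducible from one seed.

```r
library(ecostab)

scene <- generate_scene(truth_config(seed = 1))      # 100 x 100 px, 32 yr

anom <- regional_anomaly(scene$precip_cube)
part <- partition_years(anom, "auto")
part
#> <period_partition>
#>   normal:   1982-1998 (17 yr)
#>   dry:      1999-2011 (13 yr)
#>   recovery: 2012-2013 (2 yr)

period_stats(scene$precip_cube, part)
#> <period_stats> regional means:
#>   normal 288.8, dry 243.5, recovery 363.4, all 275
#>   dry-period deficit 11.48% of the all-years mean

metrics <- compute_pixel_metrics(scene$precip_cube, scene$ndvi_cube, part)
metrics
#> <pixel_metrics> 100 x 100 pixels, 9973 valid
#>   exclusions:
#>     none                       9973
#>     nodata                     0
#>     no_rain_reduction          25
#>     ndvi_reduction_below_min   2
#>   resilience denominator: normal; MAP window: all

fit <- fit_candidates(bin_by_map(metrics, "resilience"))
peak_of_fit(fit)
#> [1] 240.6561
#> attr(,"boundary")
#> [1] FALSE
```

The automatic partition finds the injected 13-year dry period exactly;
the regional deficit (11.48% of the whole-series mean) matches the
generator's configured 11.5%; and the fitted resilience curve peaks at
~241 mm MAP, within half a bin of the 250 mm truth. `plot(fit)` draws
the binned profile with the selected curve and its confidence band, and
`write_pixel_metrics()` / `write_fit_json()` export everything as
CSV/ASCII-grid/JSON.

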