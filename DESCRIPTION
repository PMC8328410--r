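Package: ecostab
Title: Vegetation Resistance and Resilience to Multi-Year Dry Periods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies grassland resistance and resilience to decade-long
    dry periods from gridded NDVI time series and station precipitation
    records. Provides raster input/output and temporal aggregation for
    annual NDVI composites, thin-plate smoothing-spline interpolation of
    station precipitation to the analysis grid, detection of multi-year
    below-average dry periods from regional anomaly series, per-pixel
    rain-reduction, NDVI-reduction, resistance and resilience metrics with
    the associated validity filters, precipitation-gradient binning with
    candidate-curve model selection, and a seeded synthetic-scene generator
    with known ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
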