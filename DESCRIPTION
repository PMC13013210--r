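Package: ssimap
Title: Summer Simmer Index Mapping and Heat-Stress Exposure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Summer Simmer Index (SSI), an apparent-temperature
    heat-stress index combining air temperature and relative humidity on the
    Fahrenheit scale, over georeferenced raster grids with strict nodata
    propagation; classifies SSI surfaces into ordered thermal-comfort
    categories; interpolates station observations to continuous surfaces by
    regression-kriging with an elevation covariate (lapse-rate drift plus
    ordinary kriging of residuals); and apportions zone populations across
    SSI classes by areal weighting with exact largest-remainder rounding.
    Includes a deterministic synthetic-scenario generator for a
    Mediterranean-like city (temperature decreasing with elevation, humidity
    negatively correlated with elevation, population concentrated in
    low-elevation zones) and a command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
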