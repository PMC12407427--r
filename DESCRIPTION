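Package: dynexposure
Title: Dynamic Population Exposure to Urban Heat and Cold
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how daily (day/night commuting) and seasonal
    (month-to-month) human mobility modulates urban temperature exposure and
    relative mortality risk. Works on aligned 1-km rasters of daily mean air
    temperature and monthly daytime/nighttime population, with city-specific
    temperature-mortality exposure-response functions and their minimum
    mortality temperatures as exposure thresholds. Includes a synthetic-city
    generator (exponential population density, radially decaying urban heat
    island over a sinusoidal seasonal climate, gravity-law commuter inflow,
    U-shaped exposure-response curves) so the full pipeline runs and is tested
    without external downloads, plus seasonal cosine fitting, mobility scaling
    fits, rescaled radial profiles, and MMT-threshold exposure accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
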