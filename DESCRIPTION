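Package: lakeshape
Title: Line-Height Cyanobacteria Index and Chlorophyll Calibration for
    Inland Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for satellite water-quality monitoring of lakes with
    line-height (spectral-shape) algorithms. Computes the Cyanobacteria
    Index (CI) from Rayleigh-corrected reflectance at the MERIS band set,
    separates cyanobacteria-dominated detections from other blooms via the
    phycocyanin signal at 620 nm, converts CI to chlorophyll-a with linear
    models, filters in situ chlorophyll records with a full audit trail,
    builds same-day satellite-to-in situ match-ups, recalibrates the
    CI-to-chlorophyll relationship by bootstrap resampling with coefficient
    confidence intervals, and validates retrievals with multiplicative
    (log-domain) bias and error metrics and trophic-state confusion
    matrices. Includes simplified Level-3 compositing (daily maximum-CI bin
    selection and multi-day means) and a synthetic-data generator so every
    stage of the pipeline can be exercised without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ncdf4,
    pracma,
    sp,
    stats,
    tibble,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
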