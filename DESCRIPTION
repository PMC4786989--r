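Package: satno2
Title: Satellite-Derived Ground-Level NO2 Records, Exposure Metrics and Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-year ground-level nitrogen dioxide (NO2) exposure
    records from simulated satellite column observations. Provides a synthetic
    world generator (fine-scale surface NO2 truth with urban hotspots, seasonal
    cycles and regional trends; a surrogate chemical-transport model; three
    satellite sensors with distinct footprints, eras and revisit schedules;
    gridded population; monitoring stations), footprint regridding with
    oversampling, cloud and snow quality control, averaging-kernel a-priori
    replacement, multi-sensor harmonization by boxcar smoothing, ratio
    downscaling and long-term cross-calibration, column-to-surface conversion
    with sampling-bias correction, population-weighted exposure metrics
    (means, weighted percentiles, cumulative distributions), and ordinary
    least-squares trend estimation with confidence intervals and relative
    trends in percent per year.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
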