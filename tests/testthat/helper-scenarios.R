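# Shared small scenario builders for fast tests.

# tiny window compatible with a 2-degree surrogate model grid
tiny_config <- function(..., days_per_year = 73, seed = 7L) {
  scenario_config(
    lon_min = 0, lon_max = 4, lat_min = 30, lat_max = 32,
    years = 1996:2012,
    hotspots = tibble::tibble(lon = 1, lat = 31, peak_ppb = 6, decay_deg = 0.4),
    region_trends = c("1" = 5),
    region_layout = "single",
    days_per_year = days_per_year,
    seed = seed,
    ...
  )
}

# a flat, deterministic world: uniform background, no hotspots, no trends,
# no seasonality, (nearly) cloud-free
flat_config <- function(..., background = 2, seed = 11L) {
  scenario_config(
    lon_min = 0, lon_max = 4, lat_min = 30, lat_max = 32,
    years = 1996:2012,
    background_ppb = background,
    hotspots = NULL,
    region_trends = c("1" = 0),
    region_layout = "single",
    seasonal_amplitude = 0,
    days_per_year = 12,
    cloud = list(mean_base = 0.02, seasonal = 0, precision = 50),
    seed = seed,
    ...
  )
}

# noiseless, unbiased three-sensor constellation (same eras as the defaults)
noiseless_sensors <- function(bias3 = 1) {
  list(
    gome = sensor_spec("gome", 3.2, 0.4, c(1995, 2003), 3,
                       noise_sd = 0, kernel_shape = 0),
    sciamachy = sensor_spec("sciamachy", 0.6, 0.3, c(2002, 2011), 6,
                            noise_sd = 0, kernel_shape = 0),
    gome2 = sensor_spec("gome2", 0.8, 0.4, c(2007, 2012), 1,
                        noise_sd = 0, kernel_shape = 0, bias = bias3)
  )
}

# run simulate -> QC -> correct -> annual summary for given sensors, and
# harmonize; mirrors the pipeline but with injectable sensors
harmonize_scenario <- function(config, sensors, cloud_max = 0.5,
                               ratio_gradient = 0, ...) {
  scenario <- make_truth_scenario(config)
  ctm <- make_ctm_surrogate(scenario, ratio_gradient = ratio_gradient)
  doys <- scenario_doys(config)
  season <- seasonal_factor(doys, config$seasonal_amplitude, config$season_peak_doy)
  window <- satno2:::snow_window_from_scenario(scenario)
  annuals <- list()
  for (sensor in sensors) {
    sy <- intersect(config$years, seq(sensor$era[1], sensor$era[2]))
    gran <- simulate_granules(ctm, sensor, sy, doys)
    gran <- apply_cloud_filter(gran, cloud_max)
    gran <- apply_snow_filter(gran, window, scenario$grid)
    gran <- correct_granules(gran, ctm)
    ann <- list()
    for (y in sy) {
      gy <- gran[gran$year == y, , drop = FALSE]
      ann[[as.character(y)]] <- satno2:::sensor_year_summary(
        gy, scenario$grid, doys, season
      )$column
    }
    annuals[[sensor$name]] <- ann
  }
  record <- build_harmonized_record(
    annuals, config$years,
    reference = "sciamachy", downscale = "gome", crosscal = "gome2", ...
  )
  list(scenario = scenario, ctm = ctm, annuals = annuals, record = record)
}

# constant field helper
const_field <- function(spec, value) grid_field(spec, value)

# strip classes recursively for structural equality checks
unclass_deep_test <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep_test) else unclass(x)
}
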