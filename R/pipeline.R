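#' Full pipeline configuration
#'
#' One object holding the scenario plus every threshold of the analysis, all
#' defaulting to the study values: cloud radiance fraction cutoff 0.5,
#' minimum 5 valid days per cell-year, a 3.2 x 0.4 degree smoothing window,
#' downscaling reference period 2003-2005, cross-calibration overlap
#' 2007-2011, trend significance at alpha = 0.01. Round-trips losslessly
#' through JSON (see [write_config()]).
#'
#' @param scenario A `scenario_config`.
#' @param cloud_max Cloud radiance fraction cutoff (strictly greater
#'   rejected).
#' @param min_days Minimum valid observation days per cell-year.
#' @param smooth_window Boxcar window in degrees, `c(lon, lat)`.
#' @param smooth_passes Boxcar passes for the smoothed downscaling
#'   reference (see [build_harmonized_record()]).
#' @param ref_downscale_years,ref_crosscal_years Harmonization reference
#'   periods.
#' @param gome2_bias Multiplicative bias of the late sensor.
#' @param correct_sampling Apply the sampling-bias correction (default
#'   TRUE).
#' @param alpha Trend significance level.
#' @param subperiods Optional list of `c(start, end)` sub-period trends.
#' @param model_cellsize Surrogate model resolution in degrees.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            cloud_max = 0.5,
                            min_days = 5,
                            smooth_window = c(3.2, 0.4),
                            smooth_passes = 2,
                            ref_downscale_years = 2003:2005,
                            ref_crosscal_years = 2007:2011,
                            gome2_bias = 1.1,
                            correct_sampling = TRUE,
                            alpha = 0.01,
                            subperiods = NULL,
                            model_cellsize = 2) {
  structure(
    list(
      scenario = scenario, cloud_max = cloud_max, min_days = min_days,
      smooth_window = smooth_window, smooth_passes = smooth_passes,
      ref_downscale_years = ref_downscale_years,
      ref_crosscal_years = ref_crosscal_years,
      gome2_bias = gome2_bias, correct_sampling = correct_sampling,
      alpha = alpha, subperiods = subperiods, model_cellsize = model_cellsize
    ),
    class = "pipeline_config"
  )
}

#' Run the full exposure pipeline on a synthetic scenario
#'
#' Executes simulate -> ingest (QC + kernel correction + regridding) ->
#' harmonize -> surface conversion with sampling correction -> population
#' weighted metrics -> trends, and returns the full bundle. Deterministic
#' for a fixed configuration (the master seed lives in the scenario config).
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, PWM and trend tables, the
#'   per-year surface fields and a JSON run manifest are written there.
#' @param quiet Suppress stage messages.
#' @return A list of class `pipeline_result` with elements `scenario`,
#'   `ctm`, `regions`, `population`, `annuals_by_sensor`, `record`
#'   (harmonized columns), `surface_fields`, `factors`, `ndays_tbl`,
#'   `pwm`, `trends`, `config`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  scfg <- config$scenario
  years <- scfg$years

  say("stage 1/6: synthetic world")
  scenario <- make_truth_scenario(scfg)
  ctm <- make_ctm_surrogate(scenario, model_cellsize = config$model_cellsize)
  regions <- scenario$regions
  population <- make_population(scenario)

  say("stage 2/6: simulate + ingest sensors")
  sensors <- default_sensors(gome2_bias = config$gome2_bias)
  doys <- scenario_doys(scfg)
  season <- seasonal_factor(doys, scfg$seasonal_amplitude, scfg$season_peak_doy)
  snow_window <- snow_window_from_scenario(scenario)
  ing <- ingest_sensors(scenario, ctm, sensors, years, doys, season,
                        snow_window, config$cloud_max)

  say("stage 3/6: harmonize")
  # the smoothed downscaling reference: the reference-period mean as the
  # coarse sensor's own oversampled record would render it
  fine_ref <- fields_mean(
    lapply(as.character(config$ref_downscale_years), function(y) ing$annuals$sciamachy[[y]])
  )
  gome_years <- intersect(years, seq(sensors$gome$era[1], sensors$gome$era[2]))
  smeared_ref <- sensor_smear(fine_ref, sensors$gome, gome_years, doys,
                              year0 = years[1], master_seed = scfg$seed)
  record <- build_harmonized_record(
    ing$annuals, years,
    reference = "sciamachy", downscale = "gome", crosscal = "gome2",
    ref_downscale_years = config$ref_downscale_years,
    ref_crosscal_years = config$ref_crosscal_years,
    smooth_window = config$smooth_window,
    smooth_passes = config$smooth_passes,
    smoothed_reference = smeared_ref
  )

  say("stage 4/6: surface conversion + sampling correction")
  sf <- surface_from_record(record, ctm, ing$coverage, season,
                            min_days = config$min_days,
                            correct_sampling = config$correct_sampling)

  say("stage 5/6: exposure metrics")
  pwm_tbl <- pwm_series(sf$surface_fields, population, regions)

  say("stage 6/6: trends")
  trends_tbl <- trend_table(pwm_tbl, alpha = config$alpha,
                            subperiods = config$subperiods)

  manifest <- list(
    package_version = as.character(utils::packageVersion("satno2")),
    seed = scfg$seed,
    config_hash = rlang::hash(unclass_deep(config)),
    thresholds = list(cloud_max = config$cloud_max, min_days = config$min_days,
                      alpha = config$alpha),
    years = range(years)
  )
  res <- structure(
    list(
      scenario = scenario, ctm = ctm, regions = regions, population = population,
      annuals_by_sensor = ing$annuals, record = record,
      surface_fields = sf$surface_fields, factors = sf$factors,
      ndays_tbl = ing$ndays_tbl, pwm = pwm_tbl, trends = trends_tbl,
      config = config, manifest = manifest
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# simulate, QC, kernel-correct and summarise every sensor-year
ingest_sensors <- function(scenario, ctm, sensors, years, doys, season,
                           snow_window, cloud_max) {
  grid <- scenario$grid
  annuals <- list()
  coverage <- list()
  ndays_rows <- list()
  for (sensor in sensors) {
    sy <- intersect(years, seq(sensor$era[1], sensor$era[2]))
    if (length(sy) == 0) next
    gran <- simulate_granules(ctm, sensor, sy, doys)
    gran <- apply_cloud_filter(gran, cloud_max)
    gran <- apply_snow_filter(gran, snow_window, grid)
    gran <- correct_granules(gran, ctm)
    ann <- list()
    cov <- list()
    for (y in sy) {
      gy <- gran[gran$year == y, , drop = FALSE]
      s <- sensor_year_summary(gy, grid, doys, season)
      ann[[as.character(y)]] <- s$column
      cov[[as.character(y)]] <- list(ndays = s$ndays, season_sum = s$season_sum)
      idx <- which(s$ndays > 0, arr.ind = TRUE)
      ndays_rows[[paste(sensor$name, y)]] <- tibble::tibble(
        sensor = sensor$name, year = y,
        row = idx[, 1], col = idx[, 2], ndays = s$ndays[idx]
      )
    }
    annuals[[sensor$name]] <- ann
    coverage[[sensor$name]] <- cov
  }
  list(annuals = annuals, coverage = coverage,
       ndays_tbl = dplyr::bind_rows(ndays_rows))
}

# convert harmonized columns to surface ppb, applying the per-sensor-era
# sampling correction and the minimum-days mask
surface_from_record <- function(record, ctm, coverage, season,
                                min_days = 5, correct_sampling = TRUE) {
  ratio_fine <- grid_field(ctm$fine_spec, ctm$ratio_fine)
  season_all_mean <- mean(season)
  surface_fields <- list()
  factors <- list()
  for (i in seq_along(record$years)) {
    y <- record$years[i]
    prov <- record$provenance[record$provenance$year == y, ]
    cov <- coverage[[prov$sensor]][[as.character(y)]]
    obs_mean_season <- ifelse(cov$ndays > 0, cov$season_sum / cov$ndays, NA_real_)
    fac <- if (correct_sampling) season_all_mean / obs_mean_season
           else ifelse(cov$ndays > 0, 1, NA_real_)
    fac[cov$ndays < min_days] <- NA_real_
    surf <- column_to_surface(record$fields[[as.character(y)]], ratio_fine)
    v <- pmax(surf$values * fac, 0)
    surface_fields[[as.character(y)]] <- grid_field(surf$spec, v)
    factors[[as.character(y)]] <- fac
  }
  list(surface_fields = surface_fields, factors = factors)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d-%d, %d regions, seed %d\n",
              min(x$record$years), max(x$record$years),
              length(unique(x$pwm$region_id)), x$manifest$seed))
  print(x$trends[x$trends$period == "full",
                 c("region_id", "mean_ppb", "rel_trend", "rel_ci_lo",
                   "rel_ci_hi", "p_value")])
  invisible(x)
}

# write tables, fields and a manifest for provenance audits
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- res$manifest$config_hash
  write_table(dplyr::mutate(res$pwm, config_hash = hash),
              file.path(out_dir, "pwm.csv"))
  write_table(dplyr::mutate(res$trends, config_hash = hash),
              file.path(out_dir, "trends.csv"))
  for (y in names(res$surface_fields)) {
    write_grid(res$surface_fields[[y]],
               file.path(out_dir, sprintf("surface_%s.csv", y)))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
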