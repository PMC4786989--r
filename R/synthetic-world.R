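#' Scenario configuration for the synthetic world
#'
#' Bundles every knob of the synthetic study conditions: the grid window, the
#' year range, urban hotspots, per-region multiplicative annual trends, the
#' seasonal cycle, the observation-day schedule and the master seed. All
#' downstream generators (truth, surrogate model, sensors, population,
#' stations) read from this one object, so a fixed config + seed pins the
#' whole world.
#'
#' @param lon_min,lon_max,lat_min,lat_max Window edges in degrees.
#' @param cellsize Working resolution in degrees (default 0.1).
#' @param years Inclusive year range of the record.
#' @param background_ppb Rural background surface NO2 in ppb.
#' @param hotspots Tibble with columns `lon`, `lat`, `peak_ppb`, `decay_deg`:
#'   Gaussian urban enhancements (peak amplitude, e-folding scale in degrees).
#' @param region_trends Named numeric vector, region id -> trend in percent
#'   per year, applied multiplicatively: year `t` scales by `(1 + r/100)^t`.
#' @param region_layout `"quadrants"` (2 x 2 split into region ids 1..4) or
#'   `"single"` (whole window is region 1).
#' @param seasonal_amplitude Fractional amplitude of the annual cycle
#'   (wintertime NO2 maximum); must lie in `[0, 1)` so truth stays positive.
#' @param season_peak_doy Day of year of the seasonal maximum (default 15,
#'   mid-January, the northern-hemisphere NO2 peak).
#' @param days_per_year Number of simulated observation days per year, spread
#'   evenly over the calendar (default 73, every fifth day: dense enough that
#'   the slowest-revisit sensor still sees each cell about 12 times per year
#'   before quality control, as the real instruments do at full daily
#'   sampling).
#' @param cloud Cloud model: list with `mean_base` (annual-mean cloud radiance
#'   fraction), `seasonal` (amplitude of its seasonal cycle, peaking with the
#'   NO2 season so winter scenes are cloudier), `precision` (Beta precision).
#' @param snow Snow model: list with `lat_threshold` (degrees; cells poleward
#'   carry seasonal snow), `melt_doy`/`onset_doy` (last spring / first autumn
#'   snow day), `jitter_days` (per-year uniform jitter of both edges).
#' @param population Population model: list with `total` (window total persons
#'   at the first snapshot), `growth_pct_yr` (annual growth, single value or
#'   named per region), `concentration` (how strongly people cluster at
#'   hotspots), `lognormal_sd` (cell-level noise), `subdivide` (integer; counts
#'   are generated at `cellsize/subdivide` then aggregated by summation).
#' @param seed Master seed; all submodule random streams derive from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(lon_min = 0, lon_max = 20, lat_min = 30, lat_max = 40,
                            cellsize = 0.1,
                            years = 1996:2012,
                            background_ppb = 0.5,
                            hotspots = default_hotspots(),
                            region_trends = c("1" = 6.7, "2" = -4.7, "3" = -2.5, "4" = -2.1),
                            region_layout = c("quadrants", "single"),
                            seasonal_amplitude = 0.35,
                            season_peak_doy = 15,
                            days_per_year = 73,
                            cloud = list(mean_base = 0.30, seasonal = 0.15, precision = 5),
                            snow = list(lat_threshold = 55, melt_doy = 80,
                                        onset_doy = 320, jitter_days = 10),
                            population = list(total = 5e7, growth_pct_yr = 1.2,
                                              concentration = 1.0, lognormal_sd = 0.5,
                                              subdivide = 2L),
                            seed = 1L) {
  region_layout <- match.arg(region_layout)
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    if (any(hotspots$peak_ppb < 0)) stop("hotspot peak must be nonnegative", call. = FALSE)
    if (any(hotspots$decay_deg <= 0)) stop("hotspot decay length must be positive", call. = FALSE)
  }
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1) {
    stop("seasonal_amplitude must be in [0, 1) so the surface field stays nonnegative",
         call. = FALSE)
  }
  structure(
    list(
      grid = grid_spec(lon_min, lon_max, lat_min, lat_max, cellsize),
      years = years, background_ppb = background_ppb, hotspots = hotspots,
      region_trends = region_trends, region_layout = region_layout,
      seasonal_amplitude = seasonal_amplitude, season_peak_doy = season_peak_doy,
      days_per_year = as.integer(days_per_year),
      cloud = cloud, snow = snow, population = population,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @rdname scenario_config
#' @export
default_hotspots <- function() {
  # one urban center per quadrant of the default 20 x 10 degree window
  tibble::tibble(
    lon = c(5, 15, 5, 15),
    lat = c(37.5, 37.5, 32.5, 32.5),
    peak_ppb = c(8, 6, 5, 4),
    decay_deg = c(0.5, 0.5, 0.5, 0.5)
  )
}

# deterministic integer stream seed derived from the master seed and a label
stream_seed <- function(master, label) {
  h <- rlang::hash(list(as.integer(master), label))
  strtoi(substr(h, 1, 7), base = 16L)
}

#' Evenly spaced simulated observation days of a year
#'
#' @param config A `scenario_config`.
#' @return Integer days of year.
#' @export
scenario_doys <- function(config) {
  as.integer(round(seq(4, 362, length.out = config$days_per_year)))
}

#' Seasonal modulation factor
#'
#' `1 + A * cos(2 * pi * (doy - peak) / 365.25)`: a wintertime NO2 maximum of
#' fractional amplitude `A`. Its mean over a full uniform year is 1.
#'
#' @param doy Day of year (vector).
#' @param amplitude Fractional amplitude in `[0, 1)`.
#' @param peak_doy Day of the maximum.
#' @export
seasonal_factor <- function(doy, amplitude, peak_doy = 15) {
  1 + amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Generate the true fine-scale scenario
#'
#' Builds the deterministic truth: a time-invariant spatial base (background
#' plus Gaussian hotspots), a region mask, and per-region multiplicative
#' annual trends. The surface field at `(year, day)` is
#' `base * (1 + r_region/100)^(year - year0) * seasonal_factor(day)`, which is
#' nonnegative everywhere and, with seasonality removed, changes the annual
#' regional mean by exactly the configured percent per year (geometric).
#'
#' @param config A `scenario_config`.
#' @return An object of class `truth_scenario`.
#' @export
make_truth_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  spec <- config$grid
  lonc <- grid_lon_centers(spec)
  latc <- grid_lat_centers(spec)
  base <- matrix(config$background_ppb, spec$nlat, spec$nlon)
  hs <- config$hotspots
  if (!is.null(hs) && nrow(hs) > 0) {
    for (k in seq_len(nrow(hs))) {
      d2 <- outer(
        (latc - hs$lat[k])^2,
        (lonc - hs$lon[k])^2,
        "+"
      )
      base <- base + hs$peak_ppb[k] * exp(-d2 / (2 * hs$decay_deg[k]^2))
    }
  }
  regions <- make_regions(config)
  trends <- config$region_trends
  ids <- field_values(regions)
  tf <- matrix(1, spec$nlat, spec$nlon)
  for (id in names(trends)) {
    tf[ids == as.integer(id)] <- 1 + trends[[id]] / 100
  }
  structure(
    list(
      config = config, grid = spec,
      base = base, regions = regions, trend_factor = tf,
      year0 = config$years[1]
    ),
    class = "truth_scenario"
  )
}

#' True surface NO2 field at a given year and day
#'
#' @param scenario A `truth_scenario`.
#' @param year Calendar year.
#' @param doy Day of year.
#' @param seasonal If `FALSE`, drop the seasonal cycle (annual-mean surface).
#' @return A `grid_field` of surface NO2 in ppb.
#' @export
surface_truth <- function(scenario, year, doy = NULL, seasonal = !is.null(doy)) {
  cfg <- scenario$config
  v <- scenario$base * scenario$trend_factor^(year - scenario$year0)
  if (seasonal) {
    v <- v * seasonal_factor(doy, cfg$seasonal_amplitude, cfg$season_peak_doy)
  }
  grid_field(scenario$grid, v)
}

#' Region mask generator
#'
#' Assigns every cell of the window exactly one integer region id (0 is
#' reserved for "no region" and unused by the built-in layouts).
#'
#' @param config A `scenario_config`.
#' @return A `grid_field` of integer region ids with a `region_table`
#'   attribute (tibble `id`, `name`).
#' @export
make_regions <- function(config) {
  spec <- config$grid
  if (config$region_layout == "single") {
    ids <- matrix(1L, spec$nlat, spec$nlon)
    tab <- tibble::tibble(id = 1L, name = "region-1")
  } else {
    lon_mid <- spec$lon0 + spec$nlon * spec$cellsize / 2
    lat_mid <- spec$lat0 + spec$nlat * spec$cellsize / 2
    west <- grid_lon_centers(spec) < lon_mid
    south <- grid_lat_centers(spec) < lat_mid
    # ids: 1 = NW, 2 = NE, 3 = SW, 4 = SE
    ids <- matrix(0L, spec$nlat, spec$nlon)
    ids[!south, west] <- 1L
    ids[!south, !west] <- 2L
    ids[south, west] <- 3L
    ids[south, !west] <- 4L
    tab <- tibble::tibble(
      id = 1:4,
      name = c("northwest", "northeast", "southwest", "southeast")
    )
  }
  out <- grid_field(spec, ids)
  attr(out, "region_table") <- tab
  out
}

#' Surrogate chemical-transport model
#'
#' Stands in for a coarse global model: a square coarse model grid carrying a
#' surface field (the area-weighted block mean of the fine truth), a
#' spatially varying surface-to-column ratio (ppb per 10^15 molec cm-2), the
#' implied tropospheric column (`column = surface / ratio` exactly on the
#' model grid), and a 3-layer partial-column profile whose layers sum to the
#' column. The ratio and the profile shape vary smoothly with latitude and
#' are constant in time; daily variation enters only through the shared
#' seasonal cycle of the surface field.
#'
#' @param scenario A `truth_scenario`.
#' @param model_cellsize Model resolution in degrees; must be a multiple of
#'   the fine cell size and divide the window extent (default 2).
#' @param ratio_base Mean surface-to-column ratio (default 0.5 ppb per 10^15).
#' @param ratio_gradient Relative north-south ratio variation (default 0.3).
#' @return An object of class `ctm_surrogate`.
#' @export
make_ctm_surrogate <- function(scenario, model_cellsize = 2,
                               ratio_base = 0.5, ratio_gradient = 0.3) {
  spec <- scenario$grid
  factor <- model_cellsize / spec$cellsize
  if (abs(factor - round(factor)) > 1e-8 || model_cellsize < spec$cellsize) {
    stop("model resolution must be a whole multiple of the fine cell size", call. = FALSE)
  }
  base_coarse <- block_aggregate(grid_field(spec, scenario$base), round(factor), "mean")
  mspec <- base_coarse$spec
  tf_coarse <- block_aggregate(
    grid_field(spec, scenario$base * scenario$trend_factor),
    round(factor), "mean"
  )
  # effective coarse-cell annual growth factor (area mean of base * tf / mean base)
  growth <- field_values(tf_coarse) / field_values(base_coarse)
  latc <- grid_lat_centers(mspec)
  lat_mid <- mspec$lat0 + mspec$nlat * mspec$cellsize / 2
  half <- mspec$nlat * mspec$cellsize / 2
  rat <- ratio_base * (1 + ratio_gradient * (latc - lat_mid) / half)
  ratio <- matrix(rat, mspec$nlat, mspec$nlon)
  if (any(ratio <= 0)) stop("surrogate ratio must stay positive", call. = FALSE)
  # boundary-layer fraction of the column varies with latitude
  f1 <- 0.5 + 0.1 * (latc - lat_mid) / half
  profile_frac <- cbind(f1, 0.3, 1 - f1 - 0.3)
  structure(
    list(
      scenario = scenario, model_spec = mspec, fine_spec = spec,
      base_coarse = field_values(base_coarse), growth = growth,
      ratio = ratio, profile_frac = profile_frac,
      ratio_fine = field_values(block_replicate(grid_field(mspec, ratio), spec))
    ),
    class = "ctm_surrogate"
  )
}

#' @rdname make_ctm_surrogate
#' @param ctm A `ctm_surrogate`.
#' @param year,doy Time of evaluation; `doy = NULL` drops the seasonal cycle.
#' @param what `"surface"` (ppb), `"column"` (10^15 molec cm-2) or `"ratio"`.
#' @export
ctm_field <- function(ctm, year, doy = NULL, what = c("surface", "column", "ratio")) {
  what <- match.arg(what)
  if (what == "ratio") return(grid_field(ctm$model_spec, ctm$ratio))
  sc <- ctm$scenario
  v <- ctm$base_coarse * ctm$growth^(year - sc$year0)
  if (!is.null(doy)) {
    v <- v * seasonal_factor(doy, sc$config$seasonal_amplitude, sc$config$season_peak_doy)
  }
  if (what == "column") v <- v / ctm$ratio
  grid_field(ctm$model_spec, v)
}

#' @rdname make_ctm_surrogate
#' @details `ctm_profile()` returns the 3-layer partial-column profile
#'   (10^15 molec cm-2) at given model cells; rows sum to the column there.
#' @param row,col Model-grid cell indices (vectors).
#' @export
ctm_profile <- function(ctm, row, col, year, doy = NULL) {
  colf <- field_values(ctm_field(ctm, year, doy, "column"))
  ctm$profile_frac[row, , drop = FALSE] * colf[cbind(row, col)]
}

#' True fine-scale column field
#'
#' The tropospheric column consistent with the truth surface and the
#' surrogate ratio (block-resampled to the fine grid): what a perfect,
#' noise-free instrument of infinitesimal footprint would retrieve.
#'
#' @inheritParams ctm_field
#' @export
true_column_field <- function(ctm, year, doy = NULL) {
  surf <- surface_truth(ctm$scenario, year, doy)
  grid_field(ctm$fine_spec, field_values(surf) / ctm$ratio_fine)
}

#' Satellite sensor specification
#'
#' @param name Sensor name.
#' @param footprint_lon,footprint_lat Footprint size in degrees (along x
#'   across). The three defaults follow the historical instruments: 3.2 x 0.4
#'   (GOME-like, 320 km x 40 km), 0.6 x 0.3 (SCIAMACHY-like, 60 km x 30 km),
#'   0.8 x 0.4 (GOME-2-like, 80 km x 40 km) at ~111 km per degree.
#' @param era Inclusive first and last observation year.
#' @param revisit_days Days needed for full coverage (3, 6 and 1 for the
#'   defaults).
#' @param noise_sd Relative (multiplicative Gaussian) column noise standard
#'   deviation, truncated at -90%.
#' @param kernel_shape Averaging-kernel shape parameter `s`; the 3-layer
#'   kernel is `(1 - s, 1, 1)` (reduced near-surface sensitivity).
#' @param bias Multiplicative inter-sensor calibration bias (1 = unbiased).
#' @param overpass Local-time window of the overpass, hours.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(name, footprint_lon, footprint_lat, era, revisit_days,
                        noise_sd = 0.25, kernel_shape = 0.3, bias = 1,
                        overpass = c(10, 12)) {
  stopifnot(footprint_lon > 0, footprint_lat > 0, length(era) == 2, era[1] <= era[2],
            revisit_days >= 1, noise_sd >= 0, bias > 0)
  structure(
    list(
      name = name, footprint_lon = footprint_lon, footprint_lat = footprint_lat,
      era = as.integer(era), revisit_days = as.integer(revisit_days),
      noise_sd = noise_sd, kernel_shape = kernel_shape, bias = bias,
      overpass = overpass
    ),
    class = "sensor_spec"
  )
}

#' @rdname sensor_spec
#' @param gome2_bias Multiplicative bias of the third sensor relative to the
#'   reference (the cross-calibration step exists to remove it).
#' @details `default_sensors()` returns the three-instrument constellation
#'   with overlapping eras (1995-2003, 2002-2011, 2007-2012), mirroring the
#'   GOME / SCIAMACHY / GOME-2 succession.
#' @export
default_sensors <- function(gome2_bias = 1.1) {
  list(
    gome = sensor_spec("gome", 3.2, 0.4, c(1995, 2003), 3,
                       noise_sd = 0.30, kernel_shape = 0.35),
    sciamachy = sensor_spec("sciamachy", 0.6, 0.3, c(2002, 2011), 6,
                            noise_sd = 0.25, kernel_shape = 0.25),
    gome2 = sensor_spec("gome2", 0.8, 0.4, c(2007, 2012), 1,
                        noise_sd = 0.25, kernel_shape = 0.30, bias = gome2_bias)
  )
}

# kernel vector of a sensor (3 retrieval layers)
sensor_kernel <- function(sensor) c(1 - sensor$kernel_shape, 1, 1)

# footprint rectangles for one day: grid-aligned tiling whose phase is a
# uniform draw keyed on the master seed (so repeated overpasses dither
# across the footprint and long-term oversampling accumulates
# sub-footprint structure, while the exact pattern stays reproducible by
# the smearing operator). The across-track phase is fixed within a year and
# the swath schedule rotates daily, so any run of `revisit` consecutive
# days within a year covers every cell at least once — also under
# subsampled observation-day schedules.
day_footprints <- function(sensor, spec, abs_day, master_seed = 0L) {
  cs <- spec$cellsize
  fw <- max(1L, as.integer(round(sensor$footprint_lon / cs)))
  fh <- max(1L, as.integer(round(sensor$footprint_lat / cs)))
  year_idx <- abs_day %/% 366L
  off_x <- stream_seed(master_seed, paste0("phx:", sensor$name, ":", year_idx)) %% fw
  off_y <- stream_seed(master_seed, paste0("phy:", sensor$name, ":", abs_day)) %% fh
  x_edges <- seq(-off_x, spec$nlon, by = fw)
  y_edges <- seq(-off_y, spec$nlat, by = fh)
  x0 <- pmax(x_edges, 0L)
  x1 <- pmin(x_edges + fw, spec$nlon)
  y0 <- pmax(y_edges, 0L)
  y1 <- pmin(y_edges + fh, spec$nlat)
  keep_x <- which(x1 - x0 > 0)
  keep_y <- which(y1 - y0 > 0)
  # swath schedule: a fraction 1/revisit of footprint columns per day
  keep_x <- keep_x[(keep_x + abs_day) %% sensor$revisit_days == 0]
  if (length(keep_x) == 0 || length(keep_y) == 0) {
    return(matrix(numeric(0), 0, 4))
  }
  g <- expand.grid(ix = keep_x, iy = keep_y)
  cbind(
    spec$lon0 + x0[g$ix] * cs, spec$lon0 + x1[g$ix] * cs,
    spec$lat0 + y0[g$iy] * cs, spec$lat0 + y1[g$iy] * cs
  )
}

# snow window edges (day of year) for one year; list(melt, onset) or NULL
snow_edges <- function(snow_model, year, master_seed) {
  j <- snow_model$jitter_days
  if (j > 0) {
    withr::with_seed(stream_seed(master_seed, paste0("snow:", year)), {
      jit <- round(stats::runif(2, -j, j))
    })
  } else {
    jit <- c(0, 0)
  }
  list(melt = snow_model$melt_doy + jit[1], onset = snow_model$onset_doy + jit[2])
}

#' Simulate one sensor's footprint observations
#'
#' Tiles the window with grid-aligned rectangular footprints on a revisit
#' schedule (a fraction `1/revisit` of swaths per day, with a deterministic
#' day-dependent phase so long-term oversampling reveals sub-footprint
#' structure), and retrieves for each footprint the area-weighted mean true
#' column over its rectangle, distorted by the sensor's averaging-kernel
#' a-priori mismatch, the sensor's calibration bias, and multiplicative
#' Gaussian noise truncated at -90%. Each footprint carries a cloud radiance
#' fraction drawn from a seasonally modulated Beta distribution and a snow
#' flag from the latitude/day-of-year snow model.
#'
#' @param ctm A `ctm_surrogate` (carries the truth scenario).
#' @param sensor A `sensor_spec`.
#' @param years Years to simulate; must lie within the sensor era (error
#'   otherwise, stating the era).
#' @param doys Days of year to simulate (default: the scenario schedule).
#' @param seed Seed for this stream (default: derived from the scenario
#'   master seed and the sensor name).
#' @return A tibble of class `no2_granules`: one row per footprint with
#'   `sensor`, `year`, `doy`, rectangle bounds `lon_lo`, `lon_hi`, `lat_lo`,
#'   `lat_hi`, retrieved `column` (10^15 molec cm-2), `cloud_frac`, `snow`.
#'   The sensor spec and grid ride along as attributes.
#' @export
simulate_granules <- function(ctm, sensor, years, doys = NULL, seed = NULL) {
  scenario <- ctm$scenario
  cfg <- scenario$config
  spec <- scenario$grid
  if (any(years < sensor$era[1] | years > sensor$era[2])) {
    stop(sprintf(
      "requested years outside the %s era (%d-%d)",
      sensor$name, sensor$era[1], sensor$era[2]
    ), call. = FALSE)
  }
  if (is.null(doys)) doys <- scenario_doys(cfg)
  if (is.null(seed)) seed <- stream_seed(cfg$seed, paste0("granules:", sensor$name))
  kernel <- sensor_kernel(sensor)
  snow_m <- cfg$snow
  cloud_m <- cfg$cloud
  out <- vector("list", length(years) * length(doys))
  i <- 0L
  withr::with_seed(seed, {
    for (year in years) {
      se <- snow_edges(snow_m, year, cfg$seed)
      for (doy in doys) {
        abs_day <- (year - scenario$year0) * 366L + doy
        rects <- day_footprints(sensor, spec, abs_day, cfg$seed)
        n <- nrow(rects)
        if (n == 0) next
        colf <- true_column_field(ctm, year, doy)
        col_true <- cpp_rect_means(field_values(colf), rects,
                                   spec$lon0, spec$lat0, spec$cellsize)
        # averaging-kernel distortion from the model profile at footprint centers
        cen <- grid_locate(ctm$model_spec,
                           (rects[, 1] + rects[, 2]) / 2,
                           (rects[, 3] + rects[, 4]) / 2)
        prof <- ctm_profile(ctm, cen$row, cen$col, year, doy)
        distort <- as.vector(prof %*% kernel) / rowSums(prof)
        noise <- pmax(stats::rnorm(n, 0, sensor$noise_sd), -0.9)
        # seasonally modulated cloudiness (cloudier in the NO2-peak season)
        cmean <- min(max(cloud_m$mean_base + cloud_m$seasonal *
                           cos(2 * pi * (doy - cfg$season_peak_doy) / 365.25), 0.02), 0.95)
        cloud <- stats::rbeta(n, cmean * cloud_m$precision,
                              (1 - cmean) * cloud_m$precision)
        lat_c <- (rects[, 3] + rects[, 4]) / 2
        snow <- lat_c > snow_m$lat_threshold & (doy <= se$melt | doy >= se$onset)
        obs_column <- col_true * distort * sensor$bias * (1 + noise)
        i <- i + 1L
        out[[i]] <- tibble::tibble(
          sensor = sensor$name, year = year, doy = doy,
          lon_lo = rects[, 1], lon_hi = rects[, 2],
          lat_lo = rects[, 3], lat_hi = rects[, 4],
          column = obs_column,
          cloud_frac = cloud, snow = snow
        )
      }
    }
  })
  g <- dplyr::bind_rows(out[seq_len(i)])
  attr(g, "sensor") <- sensor
  attr(g, "grid") <- spec
  class(g) <- c("no2_granules", class(g))
  g
}

#' Gridded population snapshots
#'
#' Generates population counts at 5-year snapshots. Counts are drawn at a
#' finer subdivision of the working grid (log-normal cell noise around a
#' density that decays away from the hotspots) and then aggregated to the
#' working resolution by summation, so totals are conserved exactly.
#' Snapshots share one spatial draw and differ only by per-region geometric
#' growth, emulating slowly evolving census rasters.
#'
#' @param scenario A `truth_scenario`.
#' @param snapshot_years Snapshot years (default 1995, 2000, ..., 2015).
#' @param seed Stream seed (default derived from the master seed).
#' @return An object of class `population_series`: list with `years` and
#'   `fields` (one `grid_field` of persons per snapshot).
#' @export
make_population <- function(scenario, snapshot_years = seq(1995, 2015, by = 5),
                            seed = NULL) {
  cfg <- scenario$config
  pm <- cfg$population
  spec <- scenario$grid
  sub <- as.integer(pm$subdivide %||% 1L)
  fine <- grid_spec(
    spec$lon0, spec$lon0 + spec$nlon * spec$cellsize,
    spec$lat0, spec$lat0 + spec$nlat * spec$cellsize,
    cellsize = spec$cellsize / sub
  )
  if (is.null(seed)) seed <- stream_seed(cfg$seed, "population")
  # density shaped by the (time-invariant) hotspot pattern of the truth
  shape <- field_values(block_replicate(grid_field(spec, scenario$base), fine))
  dens <- (shape / max(shape))^pm$concentration
  withr::with_seed(seed, {
    noise <- exp(stats::rnorm(length(dens), -pm$lognormal_sd^2 / 2, pm$lognormal_sd))
  })
  base_counts <- dens * matrix(noise, fine$nlat, fine$nlon)
  base_counts <- base_counts * (pm$total / sum(base_counts))
  growth <- pm$growth_pct_yr
  rid_fine <- field_values(block_replicate(scenario$regions, fine))
  gmat <- matrix(1 + (if (length(growth) == 1) growth else 0) / 100,
                 fine$nlat, fine$nlon)
  if (length(growth) > 1) {
    for (id in names(growth)) gmat[rid_fine == as.integer(id)] <- 1 + growth[[id]] / 100
  }
  y0 <- snapshot_years[1]
  fields <- lapply(snapshot_years, function(y) {
    f <- grid_field(fine, base_counts * gmat^(y - y0))
    block_aggregate(f, sub, "sum")
  })
  structure(
    list(years = snapshot_years, fields = fields, native_cellsize = fine$cellsize),
    class = "population_series"
  )
}

#' Synthetic ground-monitoring stations
#'
#' Draws station locations (population-weighted, so stations sit where people
#' are, as real networks do), assigns site classes and a multiplicative local
#' bias factor (log-normal around 1; larger for "traffic" sites, which real
#' networks flag for exclusion).
#'
#' @param scenario A `truth_scenario`.
#' @param n Number of stations (> 0).
#' @param population Optional `population_series` used as the sampling weight.
#' @param n_traffic How many of the `n` stations are traffic sites.
#' @param bias_sd Log-scale standard deviation of the local bias factor.
#' @param seed Stream seed.
#' @return Tibble with `station_id`, `lon`, `lat`, `row`, `col`, `class`,
#'   `bias`.
#' @export
make_stations <- function(scenario, n = 20, population = NULL, n_traffic = 0,
                          bias_sd = 0.2, seed = NULL) {
  if (n <= 0) stop("number of stations must be positive", call. = FALSE)
  cfg <- scenario$config
  spec <- scenario$grid
  if (is.null(seed)) seed <- stream_seed(cfg$seed, "stations")
  w <- if (!is.null(population)) {
    as.vector(field_values(population$fields[[1]]))
  } else {
    as.vector(scenario$base)
  }
  withr::with_seed(seed, {
    cells <- sample.int(length(w), n, replace = FALSE, prob = w / sum(w))
    bias <- exp(stats::rnorm(n, 0, bias_sd))
    cls <- sample(c("rural", "suburban", "urban"), n, replace = TRUE)
  })
  if (n_traffic > 0) {
    idx <- seq_len(min(n_traffic, n))
    cls[idx] <- "traffic"
    bias[idx] <- bias[idx] * 1.5 # roadside enhancement
  }
  row <- ((cells - 1L) %% spec$nlat) + 1L
  col <- ((cells - 1L) %/% spec$nlat) + 1L
  tibble::tibble(
    station_id = sprintf("st%02d", seq_len(n)),
    lon = grid_lon_centers(spec)[col],
    lat = grid_lat_centers(spec)[row],
    row = row, col = col, class = cls, bias = bias
  )
}

#' Daily midmorning station observations
#'
#' Samples the truth surface field at each station's cell on the scenario's
#' observation days and applies the station's multiplicative local bias:
#' the synthetic analogue of 1000-1200 h averages from hourly monitors.
#'
#' @param scenario A `truth_scenario`.
#' @param stations Tibble from [make_stations()].
#' @param years Years to sample (default: scenario years).
#' @return Tibble with `station_id`, `year`, `doy`, `value_ppb`.
#' @export
station_observations <- function(scenario, stations, years = NULL) {
  cfg <- scenario$config
  if (is.null(years)) years <- cfg$years
  doys <- scenario_doys(cfg)
  cell_base <- scenario$base[cbind(stations$row, stations$col)]
  cell_tf <- scenario$trend_factor[cbind(stations$row, stations$col)]
  grid_ <- tidyr::expand_grid(
    i = seq_len(nrow(stations)), year = years, doy = doys
  )
  dplyr::mutate(
    grid_,
    station_id = stations$station_id[.data$i],
    value_ppb = cell_base[.data$i] * cell_tf[.data$i]^(.data$year - scenario$year0) *
      seasonal_factor(.data$doy, cfg$seasonal_amplitude, cfg$season_peak_doy) *
      stations$bias[.data$i],
    i = NULL
  )[, c("station_id", "year", "doy", "value_ppb")]
}
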