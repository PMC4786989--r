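#' Read and write gridded fields as plain-text CSV
#'
#' Gridded fields are serialized as long-format CSV (`lon`, `lat`, `value`)
#' with the grid geometry in commented header lines, so files are
#' self-describing, diffable and round-trip to numeric precision. Masked
#' cells are written as empty values and come back as `NA`.
#'
#' @param field A `grid_field`.
#' @param path Output file.
#' @export
write_grid <- function(field, path) {
  spec <- field$spec
  header <- sprintf(
    "# grid_spec lon0=%.10g lat0=%.10g nlon=%d nlat=%d cellsize=%.10g",
    spec$lon0, spec$lat0, spec$nlon, spec$nlat, spec$cellsize
  )
  writeLines(header, path)
  readr::write_csv(as_tibble(field), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_grid
#' @return `read_grid()` returns the `grid_field`.
#' @export
read_grid <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec(
    "^# grid_spec lon0=([-0-9.eE+]+) lat0=([-0-9.eE+]+) nlon=([0-9]+) nlat=([0-9]+) cellsize=([-0-9.eE+]+)$",
    first
  ))[[1]]
  if (length(m) != 6) {
    stop("malformed grid file (missing '# grid_spec' header line): ", path, call. = FALSE)
  }
  nlon <- as.integer(m[4])
  nlat <- as.integer(m[5])
  cs <- as.numeric(m[6])
  spec <- grid_spec(
    as.numeric(m[2]), as.numeric(m[2]) + nlon * cs,
    as.numeric(m[3]), as.numeric(m[3]) + nlat * cs, cs
  )
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("lon", "lat", "value") %in% names(tb)) || nrow(tb) != nlat * nlon) {
    stop("malformed grid file (expected ", nlat * nlon, " lon/lat/value rows): ",
         path, call. = FALSE)
  }
  loc <- grid_locate(spec, tb$lon, tb$lat)
  v <- matrix(NA_real_, nlat, nlon)
  v[cbind(loc$row, loc$col)] <- tb$value
  grid_field(spec, v)
}

#' Read and write tabular results as CSV
#'
#' Thin wrappers with a header row and strict parsing: malformed rows and
#' missing required columns raise descriptive errors.
#'
#' @param tbl A data frame.
#' @param path File path.
#' @param required Column names that must be present on read.
#' @export
write_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, required = NULL) {
  tb <- readr::read_csv(path, show_col_types = FALSE, lazy = FALSE)
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed table %s: e.g. row %d, %s", path,
                 probs$row[1], probs$expected[1]), call. = FALSE)
  }
  if (!is.null(required)) {
    miss <- setdiff(required, names(tb))
    if (length(miss) > 0) {
      stop("table ", path, " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (col in required) {
      bad <- which(is.na(tb[[col]]))
      if (length(bad) > 0) {
        stop(sprintf("table %s: missing value for '%s' in row %d",
                     path, col, bad[1]), call. = FALSE)
      }
    }
  }
  tb
}

#' Serialize a pipeline configuration to JSON and back
#'
#' The configuration (scenario plus thresholds) round-trips losslessly:
#' `read_config(write_config(cfg, path))` reproduces `cfg`.
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass_deep(config)
  x$scenario$grid <- NULL # derived from the extent fields below
  # keep names of short named vectors through auto_unbox
  x$scenario$region_trends <- as.list(x$scenario$region_trends)
  if (length(x$scenario$population$growth_pct_yr) > 1) {
    x$scenario$population$growth_pct_yr <- as.list(x$scenario$population$growth_pct_yr)
  }
  sp <- config$scenario$grid
  x$scenario$extent <- list(
    lon_min = sp$lon0, lon_max = sp$lon0 + sp$nlon * sp$cellsize,
    lat_min = sp$lat0, lat_max = sp$lat0 + sp$nlat * sp$cellsize,
    cellsize = sp$cellsize
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- x$scenario
  ext <- s$extent
  hotspots <- if (is.null(s$hotspots) || length(s$hotspots) == 0) NULL
              else tibble::as_tibble(s$hotspots)
  scen <- scenario_config(
    lon_min = ext$lon_min, lon_max = ext$lon_max,
    lat_min = ext$lat_min, lat_max = ext$lat_max,
    cellsize = ext$cellsize,
    years = s$years, background_ppb = s$background_ppb,
    hotspots = hotspots,
    region_trends = unlist(s$region_trends),
    region_layout = s$region_layout,
    seasonal_amplitude = s$seasonal_amplitude,
    season_peak_doy = s$season_peak_doy,
    days_per_year = s$days_per_year,
    cloud = s$cloud, snow = s$snow,
    population = s$population,
    seed = s$seed
  )
  pipeline_config(
    scenario = scen,
    cloud_max = x$cloud_max, min_days = x$min_days,
    smooth_window = x$smooth_window,
    smooth_passes = x$smooth_passes %||% 2,
    ref_downscale_years = x$ref_downscale_years,
    ref_crosscal_years = x$ref_crosscal_years,
    gome2_bias = x$gome2_bias, correct_sampling = x$correct_sampling,
    alpha = x$alpha,
    subperiods = if (is.null(x$subperiods)) NULL
      else if (is.matrix(x$subperiods))
        lapply(seq_len(nrow(x$subperiods)), function(i) as.numeric(x$subperiods[i, ]))
      else lapply(x$subperiods, as.numeric),
    model_cellsize = x$model_cellsize
  )
}
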