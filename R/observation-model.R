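#' Cloud quality-control filter
#'
#' Removes footprints whose cloud radiance fraction exceeds 0.5 (strictly
#' greater than: a fraction of exactly 0.5 is kept). Footprints with a
#' missing fraction are also rejected and counted separately. Rejection
#' counts are attached as the `qc_log` attribute.
#'
#' @param granules A granule tibble (from [simulate_granules()] or with the
#'   same columns).
#' @param max_cloud_frac Threshold (default 0.5).
#' @return The filtered granule tibble.
#' @export
apply_cloud_filter <- function(granules, max_cloud_frac = 0.5) {
  missing_frac <- is.na(granules$cloud_frac)
  cloudy <- !missing_frac & granules$cloud_frac > max_cloud_frac
  out <- granules[!missing_frac & !cloudy, , drop = FALSE]
  attr(out, "qc_log") <- c(
    attr(granules, "qc_log"),
    list(cloud = list(
      removed_cloudy = sum(cloudy), removed_missing = sum(missing_frac),
      kept = nrow(out), threshold = max_cloud_frac
    ))
  )
  out
}

#' Shortest snow-free season per cell
#'
#' For every year the snow-free interval is (last spring snow day + 1, first
#' autumn snow day - 1); the window returned is the intersection over all
#' years — the shortest snow-free season — applied identically to every year
#' so seasonal sampling is the same across sensor eras. A cell snow-covered
#' all year in any year gets an empty window (`NA` edges) and is excluded.
#'
#' @param snow_flags A list (one element per year) of logical arrays with
#'   dimension `n_days x n_cells` (`TRUE` = snow cover on that day).
#' @param doys Integer day-of-year labels of the day axis.
#' @param per_year If `TRUE`, return the per-year windows (list of matrices)
#'   instead of their intersection.
#' @return A list of class `snow_free_window` with vectors `start` and `end`
#'   (day of year, inclusive) per cell; `NA` where a cell has no snow-free
#'   season. Cells that never see snow get `[1, 366]`.
#' @export
snow_free_window <- function(snow_flags, doys, per_year = FALSE) {
  stopifnot(is.list(snow_flags), length(snow_flags) >= 1)
  n_cells <- ncol(snow_flags[[1]])
  windows <- lapply(snow_flags, function(fl) {
    stopifnot(nrow(fl) == length(doys))
    st <- rep(1L, n_cells)
    en <- rep(366L, n_cells)
    for (cell in seq_len(n_cells)) {
      sd <- doys[fl[, cell]]
      if (length(sd) == 0) next
      mid <- 366 / 2
      spring <- sd[sd <= mid]
      autumn <- sd[sd > mid]
      if (length(spring) > 0) st[cell] <- max(spring) + 1L
      if (length(autumn) > 0) en[cell] <- min(autumn) - 1L
      if (st[cell] > en[cell]) st[cell] <- en[cell] <- NA_integer_
    }
    cbind(start = st, end = en)
  })
  if (per_year) return(windows)
  start <- do.call(pmax, lapply(windows, function(w) w[, "start"]))
  end <- do.call(pmin, lapply(windows, function(w) w[, "end"]))
  bad <- !is.na(start) & !is.na(end) & start > end
  start[bad] <- NA_integer_
  end[bad] <- NA_integer_
  structure(list(start = start, end = end), class = "snow_free_window")
}

# snow-free window implied by the parametric snow model of a scenario:
# per-year windows from the (jittered) melt and onset days, intersected
snow_window_from_scenario <- function(scenario) {
  cfg <- scenario$config
  sm <- cfg$snow
  spec <- scenario$grid
  lat <- grid_lat_centers(spec)
  polar <- lat > sm$lat_threshold
  start <- 1L
  end <- 366L
  for (year in cfg$years) {
    se <- snow_edges(sm, year, cfg$seed)
    start <- max(start, se$melt + 1L)
    end <- min(end, se$onset - 1L)
  }
  st <- ifelse(polar, start, 1L)
  en <- ifelse(polar, end, 366L)
  empty <- st > en
  st[empty] <- NA_integer_
  en[empty] <- NA_integer_
  structure(
    list(start = rep(st, spec$nlon), end = rep(en, spec$nlon), spec = spec,
         by_lat_row = TRUE),
    class = "snow_free_window"
  )
}

#' Snow quality-control filter
#'
#' Drops observations that fall outside the snow-free window of the cell at
#' the footprint center (and any footprint carrying a raised snow flag).
#' With a `[1, 366]` window everywhere and no snow flags this is the
#' identity.
#'
#' @param granules A granule tibble.
#' @param window A `snow_free_window` for the target grid (per-cell vectors
#'   in column-major cell order), or `NULL` to filter on the snow flag alone.
#' @param grid The `grid_spec` the window refers to (defaults to the granule
#'   attribute).
#' @return The filtered granule tibble; removal count appended to `qc_log`.
#' @export
apply_snow_filter <- function(granules, window = NULL, grid = attr(granules, "grid")) {
  drop <- isTRUE_v(granules$snow)
  if (!is.null(window)) {
    stopifnot(inherits(window, "snow_free_window"))
    loc <- grid_locate(grid,
                       (granules$lon_lo + granules$lon_hi) / 2,
                       (granules$lat_lo + granules$lat_hi) / 2)
    cell <- loc$row + (loc$col - 1L) * grid$nlat
    st <- window$start[cell]
    en <- window$end[cell]
    outside <- is.na(st) | granules$doy < st | granules$doy > en
    drop <- drop | outside
  }
  out <- granules[!drop, , drop = FALSE]
  attr(out, "qc_log") <- c(
    attr(granules, "qc_log"),
    list(snow = list(removed = sum(drop), kept = nrow(out)))
  )
  out
}

isTRUE_v <- function(x) !is.na(x) & x

#' Averaging-kernel a-priori replacement
#'
#' Replaces the a-priori profile assumed in a retrieval with a model profile:
#' the corrected column is `column * sum(x) / sum(A * x)` with `x` the model
#' partial-column profile and `A` the averaging kernel. A unit kernel gives
#' the identity; the factor is invariant to rescaling of `x`. Observations
#' where `sum(A * x) <= 0` are flagged invalid (`NA`).
#'
#' @param column Retrieved column(s), numeric vector.
#' @param kernel Averaging kernel, one vector of layer sensitivities (length
#'   `L`) shared by all observations, or a matrix with one row per
#'   observation.
#' @param model_profile Model partial-column profile: vector of length `L`
#'   or matrix with one row per observation.
#' @return Corrected column(s); `NA` where invalid.
#' @export
apply_averaging_kernel_correction <- function(column, kernel, model_profile) {
  x <- if (is.matrix(model_profile)) model_profile else
    matrix(model_profile, nrow = length(column), ncol = length(model_profile), byrow = TRUE)
  a <- if (is.matrix(kernel)) kernel else
    matrix(kernel, nrow = nrow(x), ncol = length(kernel), byrow = TRUE)
  stopifnot(ncol(a) == ncol(x), nrow(x) == length(column))
  denom <- rowSums(a * x)
  fac <- ifelse(denom > 0, rowSums(x) / denom, NA_real_)
  column * fac
}

#' Apply the kernel correction to a granule table
#'
#' Convenience wrapper: looks up the surrogate-model midmorning profile at
#' each footprint center and applies
#' [apply_averaging_kernel_correction()] with the sensor's kernel.
#'
#' @param granules A granule tibble (carries its `sensor_spec` attribute).
#' @param ctm A `ctm_surrogate`.
#' @return The granule tibble with corrected `column`; invalid rows dropped.
#' @export
correct_granules <- function(granules, ctm) {
  if (nrow(granules) == 0) return(granules)
  sensor <- attr(granules, "sensor")
  kernel <- sensor_kernel(sensor)
  cen <- grid_locate(ctm$model_spec,
                     (granules$lon_lo + granules$lon_hi) / 2,
                     (granules$lat_lo + granules$lat_hi) / 2)
  # profile shape is constant in time; evaluate per (year, doy) group
  key <- paste(granules$year, granules$doy)
  out <- granules
  for (k in unique(key)) {
    idx <- which(key == k)
    prof <- ctm_profile(ctm, cen$row[idx], cen$col[idx],
                        granules$year[idx][1], granules$doy[idx][1])
    out$column[idx] <- apply_averaging_kernel_correction(
      granules$column[idx], kernel, prof
    )
  }
  keep <- !is.na(out$column)
  res <- out[keep, , drop = FALSE]
  attr(res, "qc_log") <- c(
    attr(granules, "qc_log"),
    list(kernel = list(removed_invalid = sum(!keep)))
  )
  res
}

#' Regrid a granule to the working grid by overlap-area weighting
#'
#' Every cell receives the overlap-area-weighted mean of all footprints that
#' cover it (areas are planar rectangle intersections scaled by the cosine of
#' the cell-center latitude); the cell weight is the total overlap area.
#' Cells with no overlap — or a total overlap below 1% of the cell area —
#' are masked. Negative columns (possible under retrieval noise) are
#' retained: clipping would bias low-signal means.
#'
#' @param granules A granule tibble (QC-filtered and kernel-corrected).
#' @param grid Target `grid_spec` (defaults to the granule attribute).
#' @return A list of class `daily_column_field` with `column` and `weight`
#'   `grid_field`s (masked cells `NA` in `column`, weight 0).
#' @export
regrid_granule <- function(granules, grid = attr(granules, "grid")) {
  stopifnot(inherits(grid, "grid_spec"))
  rects <- cbind(granules$lon_lo, granules$lon_hi, granules$lat_lo, granules$lat_hi)
  dep <- cpp_rect_deposit(rects, granules$column, grid$nlat, grid$nlon,
                          grid$lon0, grid$lat0, grid$cellsize)
  w <- dep$sum_w
  v <- ifelse(w > 0, dep$sum_wv / w, NA_real_)
  structure(
    list(
      column = grid_field(grid, v),
      weight = grid_field(grid, w),
      date = if (nrow(granules) > 0) c(granules$year[1], granules$doy[1]) else NULL,
      sensor = attr(granules, "sensor")$name
    ),
    class = "daily_column_field"
  )
}
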