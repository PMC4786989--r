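#' Convert a column field to ground-level concentrations
#'
#' Multiplies a tropospheric column field (10^15 molec cm-2) by the model
#' surface-to-column ratio (ppb per 10^15 molec cm-2), cellwise. The ratio
#' field may live on the coarse model grid, in which case it is resampled to
#' the column grid by nearest-neighbour (block) assignment — fine spatial
#' texture comes from the satellite, not the model. Masks propagate.
#'
#' @param column_field A `grid_field` of columns.
#' @param ctm_ratio_field A `grid_field` of ratios, on the same grid or on a
#'   coarser model grid that nests it.
#' @return A `grid_field` of surface NO2 in ppb.
#' @export
column_to_surface <- function(column_field, ctm_ratio_field) {
  if (!identical(dim(ctm_ratio_field$values), dim(column_field$values))) {
    ctm_ratio_field <- block_replicate(ctm_ratio_field, column_field$spec)
  }
  r <- ctm_ratio_field$values
  if (any(r < 0, na.rm = TRUE)) {
    stop("negative surface-to-column ratio: surrogate model construction violated",
         call. = FALSE)
  }
  grid_field(column_field$spec, column_field$values * r)
}

#' Sampling-bias correction factor
#'
#' Incomplete satellite sampling biases annual means where concentrations
#' correlate with season or cloudiness. The per-cell correction factor is
#' the annual ratio of the model surface field sampled on every day to the
#' model surface sampled only on days with a successful retrieval:
#' `factor = mean(model, all days) / mean(model, retrieval days)`. The
#' factor is 1 when every day is sampled; a cell-year with zero retrieval
#' days gets `NA` (masked, not corrected).
#'
#' @param ctm_surface_daily Numeric matrix of model surface values,
#'   `n_days x n_cells` (columns in cell order).
#' @param retrieval_day_mask Logical matrix of the same shape; `TRUE` marks
#'   days with a valid quality-controlled observation for that cell.
#' @return Numeric vector of per-cell factors.
#' @export
sampling_correction_factor <- function(ctm_surface_daily, retrieval_day_mask) {
  stopifnot(identical(dim(ctm_surface_daily), dim(retrieval_day_mask)))
  all_mean <- colMeans(ctm_surface_daily)
  n_ret <- colSums(retrieval_day_mask)
  ret_mean <- colSums(ctm_surface_daily * retrieval_day_mask) / n_ret
  ifelse(n_ret > 0, all_mean / ret_mean, NA_real_)
}

#' Annual mean of daily surface fields with sampling correction
#'
#' The annual mean per cell is the observation-weight-weighted mean of the
#' valid daily values, multiplied by the sampling-correction factor; cells
#' with fewer valid days than `min_days` are masked, and the result is
#' floored at 0 (negative noise retained through daily averaging is clipped
#' only here, on output).
#'
#' @param daily_fields List of `daily_column_field`-like lists, each with a
#'   value `grid_field` (`$column` or `$surface`) and a `$weight`
#'   `grid_field`.
#' @param factors `grid_field` (or matrix) of per-cell correction factors;
#'   1 applies no correction.
#' @param min_days Minimum number of valid days per cell-year (default 5).
#' @return A list with `mean` (`grid_field`), `ndays` (matrix), `factor`
#'   applied.
#' @export
annual_surface_mean <- function(daily_fields, factors = 1, min_days = 5) {
  stopifnot(length(daily_fields) >= 1, min_days >= 1)
  first <- daily_fields[[1]]
  val_of <- function(d) (d$surface %||% d$column)$values
  spec <- (first$surface %||% first$column)$spec
  sv <- matrix(0, spec$nlat, spec$nlon)
  sw <- matrix(0, spec$nlat, spec$nlon)
  nd <- matrix(0L, spec$nlat, spec$nlon)
  for (d in daily_fields) {
    v <- val_of(d)
    w <- d$weight$values
    ok <- !is.na(v) & w > 0
    sv[ok] <- sv[ok] + (w * v)[ok]
    sw[ok] <- sw[ok] + w[ok]
    nd[ok] <- nd[ok] + 1L
  }
  f <- if (inherits(factors, "grid_field")) factors$values else factors
  m <- ifelse(sw > 0 & nd >= min_days, sv / sw, NA_real_) * f
  m <- pmax(m, 0)
  list(mean = grid_field(spec, m), ndays = nd, factor = f)
}

# Fused per-sensor-year summary used by the pipeline: deposits every QC'd
# footprint of the year at once (equivalent to averaging the daily regridded
# fields with their observation weights, since both reduce to one pooled
# overlap-area-weighted mean) and tracks per-cell day coverage together with
# the summed seasonal factor on observed days (the sufficient statistic for
# the sampling correction when the model surface is separable in space and
# season, as the surrogate model is).
sensor_year_summary <- function(granules, grid, doys, season_by_doy) {
  rects <- cbind(granules$lon_lo, granules$lon_hi, granules$lat_lo, granules$lat_hi)
  dep <- cpp_rect_deposit(rects, granules$column, grid$nlat, grid$nlon,
                          grid$lon0, grid$lat0, grid$cellsize)
  day_idx <- match(granules$doy, doys)
  cov <- cpp_rect_coverage(rects[order(day_idx), , drop = FALSE],
                           sort(day_idx), season_by_doy,
                           grid$nlat, grid$nlon,
                           grid$lon0, grid$lat0, grid$cellsize)
  mean_col <- ifelse(dep$sum_w > 0, dep$sum_wv / dep$sum_w, NA_real_)
  list(
    column = grid_field(grid, mean_col),
    weight = grid_field(grid, dep$sum_w),
    ndays = cov$ndays,
    season_sum = cov$factor_sum
  )
}
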