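#' Two-dimensional boxcar smoothing
#'
#' Replaces each cell by the unweighted mean of the unmasked cells inside a
#' centered rectangular window, truncated at the grid edges. Used to degrade
#' a fine-resolution field to the horizontal smearing of a coarse sensor
#' (e.g. a 3.2 x 0.4 degree window mimics a 320 km x 40 km footprint).
#' Window sizes in degrees are converted to cell counts and rounded up to
#' the next odd number of cells.
#'
#' @param field A `grid_field`.
#' @param window_lon_deg,window_lat_deg Window extent in degrees (positive).
#' @return The smoothed `grid_field`; cells whose window holds no unmasked
#'   cell stay masked.
#' @export
boxcar_smooth <- function(field, window_lon_deg, window_lat_deg) {
  spec <- field$spec
  if (window_lon_deg < spec$cellsize || window_lat_deg < spec$cellsize) {
    stop("smoothing window must be at least one cell in both axes", call. = FALSE)
  }
  to_odd <- function(w) {
    k <- ceiling(w / spec$cellsize - 1e-9)
    as.integer(if (k %% 2 == 0) k + 1 else k)
  }
  kx <- to_odd(window_lon_deg)
  ky <- to_odd(window_lat_deg)
  v <- field$values
  valid <- !is.na(v)
  v0 <- ifelse(valid, v, 0)
  sv <- slide_sum_rows(slide_sum_cols(v0, (kx - 1L) %/% 2L), (ky - 1L) %/% 2L)
  sn <- slide_sum_rows(slide_sum_cols(valid + 0, (kx - 1L) %/% 2L), (ky - 1L) %/% 2L)
  out <- ifelse(sn > 0, sv / sn, NA_real_)
  grid_field(spec, out)
}

# sliding window sums with edge truncation, via cumulative sums
slide_sum_cols <- function(m, half) {
  n <- ncol(m)
  if (n == 1L || half == 0L) return(m)
  cs <- cbind(0, matrix(t(apply(m, 1, cumsum)), nrow(m), n))
  hi <- pmin(seq_len(n) + half, n) + 1L
  lo <- pmax(seq_len(n) - half, 1L)
  cs[, hi, drop = FALSE] - cs[, lo, drop = FALSE]
}

slide_sum_rows <- function(m, half) {
  t(slide_sum_cols(t(m), half))
}

#' Ratio downscaling of a coarse-resolution annual field
#'
#' Transfers fine spatial texture onto a coarse sensor's annual mean by
#' multiplying it with the ratio of a temporally averaged fine-resolution
#' reference to its boxcar-smoothed version:
#' `out = coarse * fine_ref / max(smoothed_ref, floor)`. Where the smoothed
#' reference falls below the floor the ratio is set to 1 (near-zero
#' denominators carry no usable spatial structure).
#'
#' @param coarse_annual Annual mean field of the coarse sensor.
#' @param fine_reference_mean Multi-year mean of the fine-resolution
#'   reference sensor over the reference period.
#' @param smoothed_reference_mean Its boxcar-smoothed counterpart.
#' @param floor Denominator floor; default 5% of the area-weighted global
#'   mean of the smoothed reference.
#' @return The downscaled `grid_field`.
#' @export
ratio_downscale <- function(coarse_annual, fine_reference_mean,
                            smoothed_reference_mean, floor = NULL) {
  stopifnot(
    identical(dim(coarse_annual$values), dim(fine_reference_mean$values)),
    identical(dim(coarse_annual$values), dim(smoothed_reference_mean$values))
  )
  sm <- smoothed_reference_mean$values
  if (is.null(floor)) floor <- 0.05 * field_area_mean(smoothed_reference_mean)
  ratio <- ifelse(!is.na(sm) & sm >= floor, fine_reference_mean$values / sm, 1)
  grid_field(coarse_annual$spec, coarse_annual$values * ratio)
}

#' Cross-calibration by long-term overlap ratio
#'
#' Scales a sensor's annual mean by the per-cell ratio of the reference
#' sensor's long-term mean to the target sensor's long-term mean over a
#' common overlap window, removing a multiplicative inter-sensor bias.
#' The ratio is clipped to `[0.1, 10]` and set to 1 where the target
#' long-term mean falls below the floor.
#'
#' @param target_annual Annual mean field of the sensor being calibrated.
#' @param reference_longterm_mean,target_longterm_mean Long-term means of
#'   reference and target over the same overlap window.
#' @param floor Denominator floor; default 5% of the area-weighted global
#'   mean of the target long-term mean.
#' @return The scaled `grid_field`.
#' @export
crosscal_scale <- function(target_annual, reference_longterm_mean,
                           target_longterm_mean, floor = NULL) {
  stopifnot(
    identical(dim(target_annual$values), dim(reference_longterm_mean$values)),
    identical(dim(target_annual$values), dim(target_longterm_mean$values))
  )
  tl <- target_longterm_mean$values
  if (is.null(floor)) floor <- 0.05 * field_area_mean(target_longterm_mean)
  ratio <- ifelse(!is.na(tl) & tl >= floor, reference_longterm_mean$values / tl, 1)
  ratio <- pmin(pmax(ratio, 0.1), 10)
  grid_field(target_annual$spec, target_annual$values * ratio)
}

# area-weighted mean over unmasked cells
field_area_mean <- function(field) {
  w <- grid_cell_area(field$spec)
  v <- field$values
  keep <- !is.na(v)
  sum(w[keep] * v[keep]) / sum(w[keep])
}

# cellwise multi-year mean of a list of fields (mask-aware)
fields_mean <- function(fields) {
  stopifnot(length(fields) >= 1)
  spec <- fields[[1]]$spec
  sv <- matrix(0, spec$nlat, spec$nlon)
  sn <- matrix(0, spec$nlat, spec$nlon)
  for (f in fields) {
    v <- f$values
    ok <- !is.na(v)
    sv[ok] <- sv[ok] + v[ok]
    sn[ok] <- sn[ok] + 1
  }
  grid_field(spec, ifelse(sn > 0, sv / sn, NA_real_))
}

#' Build a resolution-consistent multi-sensor annual record
#'
#' Assembles one annual mean column field per year at the effective fine
#' resolution of the reference sensor: years observed by the coarse early
#' sensor are ratio-downscaled using the reference period; reference-era
#' years pass through unchanged; years carried by the late sensor are scaled
#' by the long-term overlap ratio. Overlap years are assigned to a single
#' sensor (coarse sensor up to its era end, reference through its era end,
#' late sensor afterwards) unless `assignment` is given explicitly.
#'
#' @param annuals_by_sensor Named list: sensor name -> named list of annual
#'   mean `grid_field`s keyed by year (as character).
#' @param years Years the record must cover (error listing any gap).
#' @param reference,downscale,crosscal Sensor names playing the fine
#'   reference, the coarse early sensor and the late sensor. `downscale` and
#'   `crosscal` may be `NULL` when the record is single- or two-sensor.
#' @param ref_downscale_years Reference-period years for the downscaling
#'   ratio (default 2003:2005).
#' @param ref_crosscal_years Overlap years for the cross-calibration ratio
#'   (default 2007:2011).
#' @param assignment Optional named list sensor -> years overriding the
#'   default year assignment.
#' @param smoothed_reference Optional `grid_field` to use directly as the
#'   smoothed downscaling reference (e.g. the reference mean passed through
#'   the coarse sensor's own sampling operator, see [sensor_smear()]); when
#'   given, `smooth_window`/`smooth_passes` are ignored.
#' @param smooth_window Boxcar window in degrees matching the coarse
#'   sensor's footprint (default `c(3.2, 0.4)`).
#' @param smooth_passes Number of boxcar passes building the smoothed
#'   reference (default 2). A long-term mean oversampled from uniformly
#'   dithered rectangular footprints is smeared by the footprint boxcar
#'   convolved with the offset distribution — well approximated by the
#'   boxcar self-convolution (a triangular kernel), i.e. two passes; one
#'   pass reproduces a single non-dithered footprint average.
#' @param floor_frac Ratio floors as a fraction of the area-weighted global
#'   mean of the respective denominator (default 0.05).
#' @return An object of class `harmonized_record`: list with `years`,
#'   `fields` (per-year `grid_field`s, values floored at 0), `provenance`
#'   tibble (`year`, `sensor`, `transform`).
#' @export
build_harmonized_record <- function(annuals_by_sensor, years,
                                    reference, downscale = NULL, crosscal = NULL,
                                    ref_downscale_years = 2003:2005,
                                    ref_crosscal_years = 2007:2011,
                                    assignment = NULL,
                                    smooth_window = c(3.2, 0.4),
                                    smooth_passes = 2,
                                    smoothed_reference = NULL,
                                    floor_frac = 0.05) {
  sensors <- names(annuals_by_sensor)
  stopifnot(reference %in% sensors)
  have_years <- function(s) as.integer(names(annuals_by_sensor[[s]]))
  if (is.null(assignment)) {
    assignment <- list()
    remaining <- years
    if (!is.null(downscale)) {
      ds_years <- intersect(remaining[remaining <= max(have_years(downscale))],
                            have_years(downscale))
      assignment[[downscale]] <- ds_years
      remaining <- setdiff(remaining, ds_years)
    }
    ref_years <- remaining[remaining <= max(have_years(reference))]
    assignment[[reference]] <- intersect(ref_years, have_years(reference))
    remaining <- setdiff(remaining, assignment[[reference]])
    if (!is.null(crosscal)) {
      assignment[[crosscal]] <- intersect(remaining, have_years(crosscal))
      remaining <- setdiff(remaining, assignment[[crosscal]])
    }
    if (length(remaining) > 0) {
      stop("no sensor covers year(s): ", paste(remaining, collapse = ", "), call. = FALSE)
    }
  }
  covered <- sort(unlist(assignment, use.names = FALSE))
  if (!setequal(covered, years)) {
    stop("year assignment does not cover the record: missing ",
         paste(setdiff(years, covered), collapse = ", "), call. = FALSE)
  }

  get_annual <- function(s, y) {
    f <- annuals_by_sensor[[s]][[as.character(y)]]
    if (is.null(f)) stop(sprintf("no %s annual mean for %d", s, y), call. = FALSE)
    f
  }

  ds_ratio_args <- NULL
  if (!is.null(downscale)) {
    fine_ref <- fields_mean(lapply(ref_downscale_years, get_annual, s = reference))
    smoothed_ref <- smoothed_reference
    if (is.null(smoothed_ref)) {
      smoothed_ref <- fine_ref
      for (pass in seq_len(smooth_passes)) {
        smoothed_ref <- boxcar_smooth(smoothed_ref, smooth_window[1], smooth_window[2])
      }
    }
    ds_ratio_args <- list(
      fine = fine_ref, smoothed = smoothed_ref,
      floor = floor_frac * field_area_mean(smoothed_ref)
    )
  }
  cc_args <- NULL
  if (!is.null(crosscal)) {
    if (length(intersect(have_years(reference), ref_crosscal_years)) == 0 ||
        length(intersect(have_years(crosscal), ref_crosscal_years)) == 0) {
      stop("empty cross-calibration overlap window", call. = FALSE)
    }
    ref_lt <- fields_mean(lapply(ref_crosscal_years, get_annual, s = reference))
    tgt_lt <- fields_mean(lapply(ref_crosscal_years, get_annual, s = crosscal))
    cc_args <- list(
      ref = ref_lt, tgt = tgt_lt,
      floor = floor_frac * field_area_mean(tgt_lt)
    )
  }

  fields <- list()
  prov <- list()
  for (y in years) {
    s <- sensors[vapply(sensors, function(ss) y %in% assignment[[ss]], logical(1))][1]
    f <- get_annual(s, y)
    transform <- "passthrough"
    if (!is.null(downscale) && s == downscale) {
      f <- ratio_downscale(f, ds_ratio_args$fine, ds_ratio_args$smoothed,
                           floor = ds_ratio_args$floor)
      transform <- "ratio_downscale"
    } else if (!is.null(crosscal) && s == crosscal) {
      f <- crosscal_scale(f, cc_args$ref, cc_args$tgt, floor = cc_args$floor)
      transform <- "crosscal_scale"
    }
    fields[[as.character(y)]] <- grid_field(f$spec, pmax(f$values, 0))
    prov[[as.character(y)]] <- tibble::tibble(year = y, sensor = s, transform = transform)
  }
  structure(
    list(years = years, fields = fields, provenance = dplyr::bind_rows(prov)),
    class = "harmonized_record"
  )
}

#' @export
print.harmonized_record <- function(x, ...) {
  cat(sprintf("<harmonized_record> %d years (%d-%d)\n",
              length(x$years), min(x$years), max(x$years)))
  print(dplyr::count(x$provenance, .data$sensor, .data$transform))
  invisible(x)
}

#' Inter-sensor continuity z-scores
#'
#' For each pixel series, computes the consecutive-year differences `d_t`,
#' and for each sensor-boundary pair the score
#' `z = (d_boundary - mean(d)) / sd(d)` with the sample standard deviation
#' taken over all of the pixel's consecutive-year differences. A series with
#' constant differences (sd = 0) gets `z = 0`. Reports per-pixel `|z|` and
#' the fraction of pixel-boundary cases within the threshold.
#'
#' @param series Numeric matrix, years in rows (ordered), pixels in columns.
#' @param years Integer year labels of the rows.
#' @param boundary_years Years `y` whose boundary pair is `(y, y + 1)`.
#' @param threshold Continuity threshold on `|z|` (default 1.5).
#' @return List of class `boundary_zscores`: tibble `scores` (`pixel`,
#'   `boundary`, `z`), `fraction_within`, `threshold`.
#' @export
boundary_zscores <- function(series, years, boundary_years, threshold = 1.5) {
  series <- as.matrix(series)
  stopifnot(nrow(series) == length(years), nrow(series) >= 4)
  stopifnot(all(boundary_years %in% years[-length(years)]))
  d <- diff(series)
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  rows <- match(boundary_years, years[-length(years)])
  out <- list()
  for (i in seq_along(rows)) {
    z <- (d[rows[i], ] - mu) / ifelse(sdv > 0, sdv, Inf)
    out[[i]] <- tibble::tibble(
      pixel = seq_len(ncol(series)),
      boundary = sprintf("%d-%d", boundary_years[i], boundary_years[i] + 1L),
      z = z
    )
  }
  scores <- dplyr::bind_rows(out)
  structure(
    list(
      scores = scores,
      fraction_within = mean(abs(scores$z) <= threshold),
      threshold = threshold
    ),
    class = "boundary_zscores"
  )
}

#' Apply a sensor's effective sampling smear to a static field
#'
#' Observes a static field with a sensor's footprint tiling and revisit
#' schedule over a set of days (no noise, no quality-control losses) and
#' regrids the resulting footprints by overlap area. The output is the
#' field as the sensor's long-term oversampled mean would render it — the
#' exact smoothing operator to use as the downscaling denominator, of which
#' a boxcar window is the analytic approximation.
#'
#' @param field A `grid_field`.
#' @param sensor A `sensor_spec`.
#' @param years,doys Days whose footprint phases to accumulate.
#' @param year0 First year of the record (anchors the day counter).
#' @param master_seed Seed keying the footprint phases; must match the
#'   scenario seed used to simulate the sensor's granules.
#' @return The smeared `grid_field`.
#' @export
sensor_smear <- function(field, sensor, years, doys, year0 = min(years),
                         master_seed = 0L) {
  spec <- field$spec
  sum_wv <- matrix(0, spec$nlat, spec$nlon)
  sum_w <- matrix(0, spec$nlat, spec$nlon)
  for (year in years) {
    for (doy in doys) {
      abs_day <- (year - year0) * 366L + doy
      rects <- day_footprints(sensor, spec, abs_day, master_seed)
      if (nrow(rects) == 0) next
      vals <- cpp_rect_means(field$values, rects,
                             spec$lon0, spec$lat0, spec$cellsize)
      dep <- cpp_rect_deposit(rects, vals, spec$nlat, spec$nlon,
                              spec$lon0, spec$lat0, spec$cellsize)
      sum_wv <- sum_wv + dep$sum_wv
      sum_w <- sum_w + dep$sum_w
    }
  }
  grid_field(spec, ifelse(sum_w > 0, sum_wv / sum_w, NA_real_))
}
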