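#' Regular latitude-longitude grid specification
#'
#' Defines a regular lat/lon raster with half-open cells `[lo, hi)` in both
#' axes. Cell centers sit at `origin + (index - 0.5) * cellsize`; the number of
#' cells times the cell size spans the stated extent exactly (the extent is
#' required to be a whole multiple of the cell size).
#'
#' @param lon_min,lon_max West and east edges in degrees.
#' @param lat_min,lat_max South and north edges in degrees.
#' @param cellsize Cell size in degrees (default 0.1, the working resolution
#'   of the pipeline).
#' @return An object of class `grid_spec` with fields `lon0`, `lat0`, `nlon`,
#'   `nlat`, `cellsize`.
#' @examples
#' gs <- grid_spec(0, 2, 30, 31)
#' gs$nlon # 20 cells of 0.1 degrees
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cellsize = 0.1) {
  stopifnot(is.numeric(cellsize), cellsize > 0, lon_max > lon_min, lat_max > lat_min)
  nlon <- (lon_max - lon_min) / cellsize
  nlat <- (lat_max - lat_min) / cellsize
  if (abs(nlon - round(nlon)) > 1e-8 || abs(nlat - round(nlat)) > 1e-8) {
    stop("grid extent must be a whole multiple of the cell size", call. = FALSE)
  }
  structure(
    list(
      lon0 = lon_min, lat0 = lat_min,
      nlon = as.integer(round(nlon)), nlat = as.integer(round(nlat)),
      cellsize = cellsize
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %g x %g deg cells, %d lon x %d lat, lon [%g, %g), lat [%g, %g)\n",
    x$cellsize, x$cellsize, x$nlon, x$nlat,
    x$lon0, x$lon0 + x$nlon * x$cellsize,
    x$lat0, x$lat0 + x$nlat * x$cellsize
  ))
  invisible(x)
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @export
grid_lon_centers <- function(spec) spec$lon0 + (seq_len(spec$nlon) - 0.5) * spec$cellsize

#' @rdname grid_spec
#' @export
grid_lat_centers <- function(spec) spec$lat0 + (seq_len(spec$nlat) - 0.5) * spec$cellsize

#' Per-cell area weights
#'
#' Planar cell area scaled by the cosine of the cell-center latitude, the
#' spherical-area approximation used throughout the overlap arithmetic.
#' Returned as an `nlat x nlon` matrix (constant along rows of longitude).
#'
#' @param spec A `grid_spec`.
#' @export
grid_cell_area <- function(spec) {
  coslat <- cos(grid_lat_centers(spec) * pi / 180)
  matrix(coslat * spec$cellsize^2, nrow = spec$nlat, ncol = spec$nlon)
}

#' Gridded scalar field
#'
#' A `grid_field` couples a `grid_spec` with an `nlat x nlon` numeric matrix
#' (rows run south to north, columns west to east). Missing data are `NA`;
#' the mask is simply `is.na(values)`.
#'
#' @param spec A `grid_spec`.
#' @param values A numeric matrix of dimension `nlat x nlon`, or a single
#'   number recycled to the full grid.
#' @return An object of class `grid_field`.
#' @examples
#' f <- grid_field(grid_spec(0, 1, 0, 1), 2)
#' mean(field_values(f))
#' @export
grid_field <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L) values <- matrix(values, spec$nlat, spec$nlon)
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$nlat, spec$nlon))) {
    stop(sprintf(
      "values must be %d x %d (nlat x nlon), got %d x %d",
      spec$nlat, spec$nlon, nrow(values), ncol(values)
    ), call. = FALSE)
  }
  structure(list(spec = spec, values = values), class = "grid_field")
}

#' @rdname grid_field
#' @param x A `grid_field`.
#' @export
field_values <- function(x) {
  stopifnot(inherits(x, "grid_field"))
  x$values
}

#' @export
print.grid_field <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<grid_field> %d x %d cells, %d masked; range [%s, %s]\n",
    x$spec$nlat, x$spec$nlon, sum(is.na(v)),
    format(suppressWarnings(min(v, na.rm = TRUE)), digits = 4),
    format(suppressWarnings(max(v, na.rm = TRUE)), digits = 4)
  ))
  invisible(x)
}

#' @export
as_tibble.grid_field <- function(x, ...) {
  spec <- x$spec
  tibble::tibble(
    lon = rep(grid_lon_centers(spec), each = spec$nlat),
    lat = rep(grid_lat_centers(spec), times = spec$nlon),
    value = as.vector(x$values)
  )
}

#' Locate points on a grid
#'
#' @param spec A `grid_spec`.
#' @param lon,lat Point coordinates in degrees.
#' @return A tibble with integer cell indices `row` (latitude) and `col`
#'   (longitude); `NA` for points outside the grid extent.
#' @export
grid_locate <- function(spec, lon, lat) {
  col <- floor((lon - spec$lon0) / spec$cellsize) + 1
  row <- floor((lat - spec$lat0) / spec$cellsize) + 1
  col[col < 1 | col > spec$nlon] <- NA_integer_
  row[row < 1 | row > spec$nlat] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Block-aggregate or block-replicate a field between nested resolutions
#'
#' `block_aggregate()` collapses `factor x factor` blocks of fine cells to one
#' coarse cell by area-weighted mean (`fun = "mean"`) or plain sum
#' (`fun = "sum"`, used for population counts so totals are conserved).
#' `block_replicate()` is the inverse resampling: every coarse value is
#' assigned to all enclosed fine cells (nearest-neighbour/block resampling).
#'
#' @param field A `grid_field`.
#' @param factor Integer number of fine cells per coarse cell along each axis.
#' @param fun `"mean"` (cosine-latitude area-weighted) or `"sum"`.
#' @export
block_aggregate <- function(field, factor, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  spec <- field$spec
  factor <- as.integer(factor)
  stopifnot(factor >= 1, spec$nlat %% factor == 0, spec$nlon %% factor == 0)
  coarse <- grid_spec(
    spec$lon0, spec$lon0 + spec$nlon * spec$cellsize,
    spec$lat0, spec$lat0 + spec$nlat * spec$cellsize,
    cellsize = spec$cellsize * factor
  )
  v <- field$values
  ri <- (seq_len(spec$nlat) - 1L) %/% factor + 1L
  ci <- (seq_len(spec$nlon) - 1L) %/% factor + 1L
  idx <- ri[row(v)] + (ci[col(v)] - 1L) * coarse$nlat
  if (fun == "sum") {
    out <- rowsum(as.vector(v), idx, na.rm = FALSE)
    m <- matrix(NA_real_, coarse$nlat, coarse$nlon)
    m[as.integer(rownames(out))] <- out[, 1]
  } else {
    w <- grid_cell_area(spec)
    valid <- !is.na(v)
    sw <- rowsum(as.vector(w * valid), idx)
    swv <- rowsum(as.vector(ifelse(valid, w * v, 0)), idx)
    m <- matrix(NA_real_, coarse$nlat, coarse$nlon)
    ok <- sw[, 1] > 0
    m[as.integer(rownames(sw))[ok]] <- swv[ok, 1] / sw[ok, 1]
  }
  grid_field(coarse, m)
}

#' @rdname block_aggregate
#' @param fine_spec Target `grid_spec`; must nest exactly inside `field`'s grid.
#' @export
block_replicate <- function(field, fine_spec) {
  cs <- field$spec
  factor <- cs$cellsize / fine_spec$cellsize
  if (abs(factor - round(factor)) > 1e-8) {
    stop("fine grid cell size must divide the coarse cell size exactly", call. = FALSE)
  }
  factor <- as.integer(round(factor))
  # map each fine cell center to its enclosing coarse cell
  loc <- grid_locate(
    cs,
    rep(grid_lon_centers(fine_spec), each = fine_spec$nlat),
    rep(grid_lat_centers(fine_spec), times = fine_spec$nlon)
  )
  if (anyNA(loc$row) || anyNA(loc$col)) {
    stop("fine grid extends beyond the coarse grid extent", call. = FALSE)
  }
  m <- matrix(field$values[cbind(loc$row, loc$col)], fine_spec$nlat, fine_spec$nlon)
  grid_field(fine_spec, m)
}

#' Pearson correlation between two fields over jointly unmasked cells
#'
#' Used to quantify agreement between sensor records during overlap periods
#' and between downscaled fields and fine-scale references.
#'
#' @param field_a,field_b `grid_field`s on the same grid.
#' @param mask Optional logical matrix; only `TRUE` cells enter.
#' @return Pearson r.
#' @export
overlap_correlation <- function(field_a, field_b, mask = NULL) {
  stopifnot(identical(dim(field_a$values), dim(field_b$values)))
  a <- field_a$values
  b <- field_b$values
  keep <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) keep <- keep & mask
  if (sum(keep) < 3) {
    stop("overlap correlation undefined: fewer than 3 jointly unmasked cells", call. = FALSE)
  }
  stats::cor(a[keep], b[keep])
}
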