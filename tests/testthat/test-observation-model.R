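fake_granules <- function(cloud_frac, doy = 150, snow = FALSE,
                          rect = c(0, 0.2, 30, 30.2), column = 1) {
  n <- length(cloud_frac)
  g <- tibble::tibble(
    sensor = "test", year = 2000, doy = doy,
    lon_lo = rect[1], lon_hi = rect[2], lat_lo = rect[3], lat_hi = rect[4],
    column = column, cloud_frac = cloud_frac,
    snow = rep_len(snow, n)
  )
  attr(g, "grid") <- grid_spec(0, 1, 30, 31)
  g
}

test_that("cloud filter rejects strictly above 0.5 and counts missing fractions", {
  g <- fake_granules(c(0.4, 0.5, 0.6))
  out <- apply_cloud_filter(g)
  expect_equal(nrow(out), 2L) # 0.5 kept under strict >
  expect_equal(attr(out, "qc_log")$cloud$removed_cloudy, 1L)

  g2 <- fake_granules((0:99) / 100)
  expect_equal(nrow(apply_cloud_filter(g2)), 51L)

  g3 <- fake_granules(rep(0, 10))
  expect_equal(nrow(apply_cloud_filter(g3)), 10L)

  g4 <- fake_granules(c(0.2, NA, 0.7))
  out4 <- apply_cloud_filter(g4)
  expect_equal(nrow(out4), 1L)
  expect_equal(attr(out4, "qc_log")$cloud$removed_missing, 1L)
})

test_that("snow-free window is the across-year intersection of snow-free seasons", {
  doys <- 1:366
  mk <- function(free_lo, free_hi) {
    fl <- matrix(FALSE, 366, 2)
    fl[doys < free_lo | doys > free_hi, 1] <- TRUE # cell 1 seasonal snow
    fl # cell 2 never snow
  }
  w <- snow_free_window(list(mk(100, 300), mk(120, 280)), doys)
  expect_equal(w$start[1], 120L)
  expect_equal(w$end[1], 280L)
  expect_equal(w$start[2], 1L)
  expect_equal(w$end[2], 366L)

  w3 <- snow_free_window(list(mk(90, 310), mk(100, 300), mk(110, 290)), doys)
  expect_equal(unname(c(w3$start[1], w3$end[1])), c(110L, 290L))

  # cell snow-covered all year in one year -> empty window
  all_snow <- matrix(TRUE, 366, 2)
  w4 <- snow_free_window(list(mk(100, 300), all_snow), doys)
  expect_true(is.na(w4$start[1]) && is.na(w4$end[1]))
})

test_that("snow filter drops observations outside the cell window and is the identity otherwise", {
  spec <- grid_spec(0, 1, 30, 31)
  open_window <- structure(
    list(start = rep(1L, 100), end = rep(366L, 100)),
    class = "snow_free_window"
  )
  g <- fake_granules(rep(0, 4), doy = 50)
  expect_equal(nrow(apply_snow_filter(g, open_window, spec)), 4L)

  narrow <- structure(
    list(start = rep(110L, 100), end = rep(290L, 100)),
    class = "snow_free_window"
  )
  expect_equal(nrow(apply_snow_filter(g, narrow, spec)), 0L)

  # 2-cell, 4-day fixture counted by enumeration: cell A open, cell B [110, 290]
  win <- structure(
    list(start = c(1L, 110L, rep(1L, 98)), end = c(366L, 290L, rep(366L, 98))),
    class = "snow_free_window"
  ) # cells in column-major order: (row 1, col 1) open, (row 2, col 1) narrow
  rows <- dplyr::bind_rows(
    fake_granules(rep(0, 4), doy = 50, rect = c(0.0, 0.1, 30.0, 30.1)),
    fake_granules(rep(0, 4), doy = 50, rect = c(0.0, 0.1, 30.1, 30.2)),
    fake_granules(rep(0, 4), doy = 150, rect = c(0.0, 0.1, 30.1, 30.2))
  )
  attr(rows, "grid") <- spec
  # surviving: 4 (cell A day 50) + 0 (cell B day 50) + 4 (cell B day 150)
  expect_equal(nrow(apply_snow_filter(rows, win, spec)), 8L)

  # raised snow flags are dropped even without a window
  gf <- fake_granules(rep(0, 3), snow = c(FALSE, TRUE, FALSE))
  expect_equal(nrow(apply_snow_filter(gf, NULL)), 2L)
})

test_that("cloud and snow filters commute", {
  set.seed(5)
  spec <- grid_spec(0, 1, 30, 31)
  g <- fake_granules(runif(40), doy = sample(c(50, 150), 40, TRUE),
                     snow = sample(c(TRUE, FALSE), 40, TRUE))
  win <- structure(
    list(start = rep(100L, 100), end = rep(300L, 100)),
    class = "snow_free_window"
  )
  a <- apply_snow_filter(apply_cloud_filter(g), win, spec)
  b <- apply_cloud_filter(apply_snow_filter(g, win, spec))
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "qc_log") <- NULL
    attr(x, "grid") <- NULL
    rownames(x) <- NULL
    x
  }
  expect_equal(strip(a), strip(b))
})

test_that("averaging-kernel correction follows the a-priori replacement factor", {
  # unit kernel -> identity
  expect_equal(apply_averaging_kernel_correction(3, c(1, 1, 1), c(5, 1, 2)), 3)
  # x = (2,1,1), A = (0.5,1,1): factor = 4 / 3
  expect_equal(apply_averaging_kernel_correction(3, c(0.5, 1, 1), c(2, 1, 1)), 4)
  # x = (1,0,0), A = (2,1,1): factor = 1/2
  expect_equal(apply_averaging_kernel_correction(2, c(2, 1, 1), c(1, 0, 0)), 1)
  # scale equivariance: doubling the profile leaves the factor unchanged
  expect_equal(
    apply_averaging_kernel_correction(3, c(0.5, 1, 1), c(4, 2, 2)), 4
  )
  # nonpositive weighted profile -> flagged invalid
  expect_true(is.na(apply_averaging_kernel_correction(3, c(-1, 0, 0), c(1, 0, 0))))
})

test_that("kernel distortion applied by the simulator is exactly inverted by the correction", {
  cfg <- flat_config(background = 2)
  sc <- make_truth_scenario(cfg)
  ctm <- make_ctm_surrogate(sc, ratio_gradient = 0)
  sensor <- sensor_spec("k", 0.6, 0.3, c(2002, 2011), 6,
                        noise_sd = 0, kernel_shape = 0.4)
  g <- simulate_granules(ctm, sensor, 2005, doys = 100)
  truth_col <- field_values(true_column_field(ctm, 2005, 100))[1, 1]
  expect_gt(max(abs(g$column - truth_col)), 0.01) # distorted as retrieved
  corrected <- correct_granules(g, ctm)
  expect_equal(corrected$column, rep(truth_col, nrow(corrected)), tolerance = 1e-12)
})

test_that("regridding distributes footprints by overlap area", {
  spec <- grid_spec(0, 1, 30, 31)
  # one footprint exactly covering 4 cells
  g <- fake_granules(0, rect = c(0.2, 0.4, 30.2, 30.4), column = 5)
  attr(g, "grid") <- spec
  day <- regrid_granule(g)
  v <- field_values(day$column)
  expect_equal(unname(v[3:4, 3:4]), matrix(5, 2, 2))
  expect_equal(sum(!is.na(v)), 4L)
  w <- field_values(day$weight)
  expect_equal(w[3, 3], 0.01 * cos(30.25 * pi / 180), tolerance = 1e-12)

  # two overlapping footprints with overlap areas a and 3a in the same cell:
  # weighted mean (2a + 18a) / 4a = 5
  g2 <- dplyr::bind_rows(
    fake_granules(0, rect = c(0.0, 0.1, 30.0, 30.025), column = 2),
    fake_granules(0, rect = c(0.0, 0.1, 30.0, 30.075), column = 6)
  )
  attr(g2, "grid") <- spec
  v2 <- field_values(regrid_granule(g2)$column)
  expect_equal(v2[1, 1], 5)

  # footprint covering half a cell: value preserved, weight half the cell area
  g3 <- fake_granules(0, rect = c(0.0, 0.05, 30.0, 30.1), column = 7)
  attr(g3, "grid") <- spec
  day3 <- regrid_granule(g3)
  expect_equal(field_values(day3$column)[1, 1], 7)
  expect_equal(field_values(day3$weight)[1, 1], 0.005 * cos(30.05 * pi / 180),
               tolerance = 1e-12)
})

test_that("regridding matches the brute-force per-cell loop on random footprints", {
  spec <- grid_spec(0, 2, 40, 41)
  set.seed(9)
  n <- 60
  x0 <- runif(n, -0.3, 1.9)
  y0 <- runif(n, 39.8, 40.9)
  rects <- cbind(x0, x0 + runif(n, 0.05, 0.8), y0, y0 + runif(n, 0.05, 0.4))
  vals <- runif(n, 1, 10)
  g <- tibble::tibble(
    sensor = "r", year = 2000, doy = 1,
    lon_lo = rects[, 1], lon_hi = rects[, 2],
    lat_lo = rects[, 3], lat_hi = rects[, 4],
    column = vals, cloud_frac = 0, snow = FALSE
  )
  attr(g, "grid") <- spec
  day <- regrid_granule(g)
  oracle <- oracle_regrid(rects, vals, spec)
  expect_equal(field_values(day$column), oracle$values, tolerance = 1e-10)
  expect_equal(field_values(day$weight), oracle$weight, tolerance = 1e-10)
})

test_that("regridding a uniform granule preserves the value exactly over covered cells", {
  spec <- grid_spec(0, 2, 40, 41)
  set.seed(10)
  x0 <- runif(30, 0, 1.5)
  y0 <- runif(30, 40, 40.8)
  g <- tibble::tibble(
    sensor = "u", year = 2000, doy = 1,
    lon_lo = x0, lon_hi = x0 + 0.5, lat_lo = y0, lat_hi = y0 + 0.2,
    column = 3.25, cloud_frac = 0, snow = FALSE
  )
  attr(g, "grid") <- spec
  v <- field_values(regrid_granule(g)$column)
  expect_true(all(abs(v[!is.na(v)] - 3.25) < 1e-12))
})
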