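test_that("flat configuration yields a time-invariant uniform truth", {
  cfg <- flat_config(background = 1)
  sc <- make_truth_scenario(cfg)
  for (y in c(1996, 2004, 2012)) {
    f <- surface_truth(sc, y, doy = 100)
    expect_equal(field_values(f), matrix(1, sc$grid$nlat, sc$grid$nlon))
  }
})

test_that("regional annual means grow geometrically at the configured rate", {
  cfg <- scenario_config(
    lon_min = 0, lon_max = 4, lat_min = 30, lat_max = 32,
    years = 1996:2012, hotspots = default_hotspots()[1, ],
    region_trends = c("1" = 6.7), region_layout = "single",
    seasonal_amplitude = 0
  )
  sc <- make_truth_scenario(cfg)
  first <- mean(field_values(surface_truth(sc, 1996, seasonal = FALSE)))
  last <- mean(field_values(surface_truth(sc, 2012, seasonal = FALSE)))
  expect_equal(last, first * 1.067^16, tolerance = 1e-12)
})

test_that("negative peaks and nonpositive decay lengths are configuration errors", {
  bad_peak <- tibble::tibble(lon = 1, lat = 31, peak_ppb = -2, decay_deg = 0.5)
  bad_decay <- tibble::tibble(lon = 1, lat = 31, peak_ppb = 2, decay_deg = 0)
  expect_error(scenario_config(hotspots = bad_peak), "peak")
  expect_error(scenario_config(hotspots = bad_decay), "decay")
  expect_error(scenario_config(seasonal_amplitude = 1.2), "seasonal_amplitude")
})

test_that("surface truth is nonnegative across seasons and trends", {
  cfg <- tiny_config(seasonal_amplitude = 0.9)
  sc <- make_truth_scenario(cfg)
  for (doy in c(1, 100, 200, 350)) {
    expect_true(all(field_values(surface_truth(sc, 2012, doy)) >= 0))
  }
})

test_that("surrogate model satisfies surface = ratio x column and profiles sum to columns", {
  sc <- make_truth_scenario(tiny_config())
  ctm <- make_ctm_surrogate(sc)
  surf <- field_values(ctm_field(ctm, 2000, 150, "surface"))
  colm <- field_values(ctm_field(ctm, 2000, 150, "column"))
  rat <- field_values(ctm_field(ctm, 2000, what = "ratio"))
  expect_equal(surf, rat * colm, tolerance = 1e-12)
  ms <- ctm$model_spec
  idx <- expand.grid(row = seq_len(ms$nlat), col = seq_len(ms$nlon))
  prof <- ctm_profile(ctm, idx$row, idx$col, 2000, 150)
  expect_equal(rowSums(prof), colm[cbind(idx$row, idx$col)], tolerance = 1e-12)
})

test_that("uniform surface with uniform ratio implies the uniform column", {
  cfg <- flat_config(background = 2)
  sc <- make_truth_scenario(cfg)
  ctm <- make_ctm_surrogate(sc, ratio_base = 0.5, ratio_gradient = 0)
  colm <- field_values(ctm_field(ctm, 2000, what = "column"))
  expect_equal(colm, matrix(4, ctm$model_spec$nlat, ctm$model_spec$nlon),
               tolerance = 1e-12)
})

test_that("coarse model surface equals the area mean of enclosed fine truth cells", {
  sc <- make_truth_scenario(tiny_config())
  ctm <- make_ctm_surrogate(sc)
  spec <- sc$grid
  w <- grid_cell_area(spec)
  v <- field_values(surface_truth(sc, 1996, seasonal = FALSE))
  # model cell (1,1) encloses fine rows/cols 1:20
  direct <- sum((w * v)[1:20, 1:20]) / sum(w[1:20, 1:20])
  expect_equal(field_values(ctm_field(ctm, 1996))[1, 1], direct, tolerance = 1e-10)
})

test_that("granule simulation is deterministic and refuses out-of-era dates", {
  sc <- make_truth_scenario(tiny_config())
  ctm <- make_ctm_surrogate(sc)
  sensor <- default_sensors()$sciamachy
  g1 <- simulate_granules(ctm, sensor, 2003, doys = c(50, 150))
  g2 <- simulate_granules(ctm, sensor, 2003, doys = c(50, 150))
  expect_identical(g1$column, g2$column)
  expect_identical(g1$cloud_frac, g2$cloud_frac)
  expect_error(simulate_granules(ctm, sensor, 2013), "era \\(2002-2011\\)")
})

test_that("footprint columns equal the uniform column for a flat noiseless world", {
  cfg <- flat_config(background = 2)
  sc <- make_truth_scenario(cfg)
  ctm <- make_ctm_surrogate(sc, ratio_base = 0.5, ratio_gradient = 0)
  sensor <- noiseless_sensors()$sciamachy
  g <- simulate_granules(ctm, sensor, 2005, doys = c(100))
  expect_gt(nrow(g), 0)
  expect_equal(g$column, rep(4, nrow(g)), tolerance = 1e-12)
})

test_that("footprint means agree with brute-force rectangle integration; coarse < fine at a hotspot", {
  cfg <- tiny_config()
  sc <- make_truth_scenario(cfg)
  ctm <- make_ctm_surrogate(sc)
  colf <- true_column_field(ctm, 2000, 150)
  spec <- sc$grid
  # GOME-like and SCIAMACHY-like footprints centered on the hotspot (1, 31)
  coarse_rect <- c(1 - 1.6, 1 + 1.6, 31 - 0.2, 31 + 0.2)
  fine_rect <- c(1 - 0.3, 1 + 0.3, 31 - 0.15, 31 + 0.15)
  rects <- rbind(coarse_rect, fine_rect)
  got <- satno2:::cpp_rect_means(field_values(colf), rects,
                                 spec$lon0, spec$lat0, spec$cellsize)
  expect_equal(got[1], oracle_rect_mean(colf, coarse_rect), tolerance = 1e-10)
  expect_equal(got[2], oracle_rect_mean(colf, fine_rect), tolerance = 1e-10)
  expect_lt(got[1], got[2]) # the wide footprint dilutes the hotspot
})

test_that("a revisit-3 schedule observes every cell within a cycle of 3 days", {
  cfg <- flat_config()
  sc <- make_truth_scenario(cfg)
  ctm <- make_ctm_surrogate(sc)
  sensor <- noiseless_sensors()$gome
  spec <- sc$grid
  # cycle-aligned window: absolute days 3k, 3k+1, 3k+2 for doys 30:32 of 1996
  g <- simulate_granules(ctm, sensor, 1996, doys = 30:32)
  covered <- matrix(FALSE, spec$nlat, spec$nlon)
  for (k in seq_len(nrow(g))) {
    loc0 <- grid_locate(spec, g$lon_lo[k] + 1e-9, g$lat_lo[k] + 1e-9)
    loc1 <- grid_locate(spec, g$lon_hi[k] - 1e-9, g$lat_hi[k] - 1e-9)
    covered[loc0$row:loc1$row, loc0$col:loc1$col] <- TRUE
  }
  expect_true(all(covered))
  # a single day leaves unobserved swaths
  g1 <- simulate_granules(ctm, sensor, 1996, doys = 30)
  area1 <- if (nrow(g1) > 0) sum((g1$lon_hi - g1$lon_lo) * (g1$lat_hi - g1$lat_lo)) else 0
  expect_lt(area1, 0.9 * 4 * 2)
})

test_that("population aggregation conserves totals and snapshots are deterministic", {
  sc <- make_truth_scenario(tiny_config())
  p1 <- make_population(sc)
  p2 <- make_population(sc)
  expect_identical(field_values(p1$fields[[1]]), field_values(p2$fields[[1]]))
  expect_equal(sum(field_values(p1$fields[[1]])),
               sc$config$population$total, tolerance = 1e-6)
  # growth between snapshots follows the configured rate
  g <- 1 + sc$config$population$growth_pct_yr / 100
  expect_equal(sum(field_values(p1$fields[[2]])),
               sum(field_values(p1$fields[[1]])) * g^5, tolerance = 1e-9)
})

test_that("stations sample the truth with their bias factor", {
  cfg <- tiny_config(seasonal_amplitude = 0.3)
  sc <- make_truth_scenario(cfg)
  st <- make_stations(sc, n = 4, seed = 3)
  st$bias[1] <- 1 # unbiased station
  obs <- station_observations(sc, st, years = 2000)
  doys <- scenario_doys(cfg)
  truth_mean <- mean(
    sc$base[st$row[1], st$col[1]] * sc$trend_factor[st$row[1], st$col[1]]^4 *
      seasonal_factor(doys, cfg$seasonal_amplitude, cfg$season_peak_doy)
  )
  got <- mean(obs$value_ppb[obs$station_id == st$station_id[1]])
  expect_equal(got, truth_mean, tolerance = 1e-12)
  expect_error(make_stations(sc, n = 0), "positive")
})
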