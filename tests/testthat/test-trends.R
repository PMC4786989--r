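test_that("OLS trend matches the closed-form 3-point example", {
  tr <- ols_trend(c(0, 1, 2), c(1, 2, 4))
  expect_equal(tr$slope, 1.5, tolerance = 1e-12)
  expect_equal(tr$longterm_mean, 7 / 3, tolerance = 1e-12)
  expect_equal(tr$rel_trend, 100 * 1.5 / (7 / 3), tolerance = 1e-10) # 64.29 %/yr
  expect_equal(round(tr$rel_trend, 1), 64.3)
})

test_that("OLS trend agrees with textbook sum-formula OLS on random fixtures", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    x <- sort(sample(1990:2020, n))
    x <- x - mean(x) # center so the sum-formula oracle is well conditioned
    y <- 3 + 0.1 * x + rnorm(n, 0, 2)
    tr <- ols_trend(x, y)
    o <- oracle_ols(x, y)
    expect_equal(tr$slope, o$slope, tolerance = 1e-10)
    expect_equal(tr$se, o$se, tolerance = 1e-10)
    tcrit <- qt(0.975, n - 2)
    expect_equal(tr$ci_lo, o$slope - tcrit * o$se, tolerance = 1e-10)
    expect_equal(tr$ci_hi, o$slope + tcrit * o$se, tolerance = 1e-10)
  }
})

test_that("degenerate series follow the stated contracts", {
  # perfectly linear: zero SE, zero CI width
  y <- 2 + 0.1 * (0:9)
  tr <- ols_trend(2000:2009, y)
  expect_equal(tr$slope, 0.1, tolerance = 1e-10)
  expect_equal(tr$se, 0)
  expect_equal(tr$ci_hi - tr$ci_lo, 0)
  expect_equal(tr$p_value, 0)
  # constant series: slope 0, p = 1 by convention
  trc <- ols_trend(2000:2009, rep(3, 10))
  expect_equal(trc$slope, 0)
  expect_equal(trc$p_value, 1)
  expect_false(trc$significant)
  expect_error(ols_trend(c(2000, 2001), c(1, 2)), "fewer than 3")
})

test_that("relative trend is invariant to positive scaling and the CI transforms alike", {
  set.seed(7)
  x <- 1996:2012
  y <- 5 * exp(-0.02 * (x - 1996)) * (1 + rnorm(17, 0, 0.05))
  a <- ols_trend(x, y)
  b <- ols_trend(x, 13 * y)
  expect_equal(a$rel_trend, b$rel_trend, tolerance = 1e-10)
  expect_equal(a$rel_ci_lo, b$rel_ci_lo, tolerance = 1e-10)
  expect_equal(a$rel_trend - a$rel_ci_lo, a$rel_ci_hi - a$rel_trend,
               tolerance = 1e-10) # symmetric in the relative scale too
})

test_that("significance classification is inclusive at the alpha boundary", {
  # construct a series whose p-value is then used at alpha equal to it
  set.seed(1)
  x <- 1:10
  y <- 0.3 * x + rnorm(10)
  tr <- ols_trend(x, y)
  expect_true(ols_trend(x, y, alpha = tr$p_value)$significant)
  expect_false(ols_trend(x, y, alpha = tr$p_value * 0.999)$significant)
})

test_that("95% CI covers a known slope at the nominal rate over seeded replicates", {
  set.seed(123)
  slope_true <- 0.05
  hits <- 0L
  n_rep <- 250L
  for (r in seq_len(n_rep)) {
    x <- 1996:2012
    y <- 1 + slope_true * (x - 1996) + rnorm(17, 0, 0.15)
    tr <- ols_trend(x, y)
    hits <- hits + (tr$ci_lo <= slope_true && slope_true <= tr$ci_hi)
  }
  expect_gte(hits / n_rep, 0.91)
  expect_lte(hits / n_rep, 0.99)
})

test_that("sub-period trends divide by the full-period long-term mean", {
  x <- 1996:2012
  # piecewise linear: flat then declining
  y <- c(rep(10, 8), 10 - 0.5 * (1:9))
  sub <- subperiod_trend(x, y, 2004, 2012)
  direct <- oracle_ols(2004:2012, y[x >= 2004])
  expect_equal(sub$slope, direct$slope, tolerance = 1e-10)
  expect_equal(sub$longterm_mean, mean(y), tolerance = 1e-12)
  expect_equal(sub$rel_trend, 100 * direct$slope / mean(y), tolerance = 1e-10)
  # sub-period equal to the full period reproduces ols_trend
  full <- subperiod_trend(x, y, 1996, 2012)
  ref <- ols_trend(x, y)
  expect_equal(full$slope, ref$slope)
  expect_equal(full$rel_trend, ref$rel_trend)
  expect_error(subperiod_trend(x, y, 2020, 2022), "empty")
})

test_that("normalization to the long-term mean has unit mean and preserves relative trends", {
  y <- c(1, 3)
  expect_equal(normalize_to_longterm_mean(y), c(0.5, 1.5))
  expect_equal(normalize_to_longterm_mean(rep(4, 5)), rep(1, 5))
  set.seed(2)
  x <- 1996:2012
  z <- 4 * exp(0.03 * (x - 1996)) * (1 + rnorm(17, 0, 0.03))
  expect_equal(mean(normalize_to_longterm_mean(z)), 1, tolerance = 1e-12)
  expect_equal(ols_trend(x, normalize_to_longterm_mean(z))$rel_trend,
               ols_trend(x, z)$rel_trend, tolerance = 1e-10)
  expect_error(normalize_to_longterm_mean(c(-2, 0)), "not positive")
})

test_that("trend difference is the absolute difference in percent per year", {
  expect_equal(trend_difference(-4.4, -3.7), 0.7)
  expect_equal(trend_difference(-2.2, -1.9), 0.3, tolerance = 1e-12)
  expect_equal(trend_difference(1.5, 1.5), 0)
})

test_that("tidy and glance return one-row tibbles with the fit summaries", {
  tr <- ols_trend(2000:2010, 1 + 0.1 * (0:10) + c(0, 0.05, -0.03, rep(0, 8)))
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate, tr$slope)
  gl <- glance(tr)
  expect_equal(gl$nobs, 11L)
  expect_equal(gl$longterm.mean, tr$longterm_mean)
})

test_that("station comparison applies selection rules, pixel averaging and bias cancellation", {
  cfg <- tiny_config(seasonal_amplitude = 0.2)
  sc <- make_truth_scenario(cfg)
  years <- cfg$years
  # satellite record = exact truth annual means (midmorning, all days)
  doys <- scenario_doys(cfg)
  smean <- mean(seasonal_factor(doys, cfg$seasonal_amplitude, cfg$season_peak_doy))
  fields <- lapply(years, function(y) {
    grid_field(sc$grid, field_values(surface_truth(sc, y, seasonal = FALSE)) * smean)
  })
  names(fields) <- years

  st <- make_stations(sc, n = 10, n_traffic = 3, seed = 5)
  st$bias[4] <- 1.3 # biased but proportional station
  obs <- station_observations(sc, st)
  cmp <- compare_with_stations(fields, st, obs, min_years = 15)
  # traffic stations excluded: 7 remain
  expect_equal(cmp$n_excluded, 3L)
  expect_equal(sum(cmp$pixels$n_stations), 7L)
  # multiplicative bias cancels under normalization: trend difference ~ 0
  expect_lt(max(cmp$pixels$trend_difference), 1e-8)
  expect_equal(max(abs(cmp$series$satellite - cmp$series$ground)), 0,
               tolerance = 1e-10)

  # a station with only 14 years of data is excluded
  obs14 <- dplyr::filter(obs, !(station_id == st$station_id[5] & year > 2009))
  cmp14 <- compare_with_stations(fields, st, obs14, min_years = 15)
  expect_equal(sum(cmp14$pixels$n_stations), 6L)

  # stations sharing a pixel are averaged before comparison
  st3 <- st[4:6, ]
  st3$row <- st$row[4]
  st3$col <- st$col[4]
  st3$lon <- st$lon[4]
  st3$lat <- st$lat[4]
  obs3 <- station_observations(sc, st3)
  cmp3 <- compare_with_stations(fields, st3, obs3, min_years = 15)
  expect_equal(nrow(cmp3$pixels), 1L)
  expect_equal(cmp3$pixels$n_stations, 3L)
  ann_direct <- obs3 |>
    dplyr::group_by(.data$station_id, .data$year) |>
    dplyr::summarise(v = mean(.data$value_ppb), .groups = "drop") |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(v = mean(.data$v))
  expect_equal(
    cmp3$series$ground,
    unname(normalize_to_longterm_mean(ann_direct$v)),
    tolerance = 1e-10
  )

  # the coincidence rule excludes stations without enough qualifying years
  cd <- tibble::tibble(row = st$row[4], col = st$col[4],
                       year = years, ndays = 10)
  cmp_cd <- compare_with_stations(fields, st, obs, coincident_days = cd,
                                  min_years = 15)
  expect_equal(sum(cmp_cd$pixels$n_stations), 1L) # only station 4 qualifies
  expect_warning(
    compare_with_stations(fields, st, obs,
                          coincident_days = cd[0, ], min_years = 15),
    "no station passes"
  )
})

test_that("Newey-West standard errors are available for sensitivity analysis", {
  set.seed(9)
  x <- 1996:2012
  e <- as.numeric(stats::filter(rnorm(17, 0, 0.2), 0.6, method = "recursive"))
  y <- 2 + 0.05 * (x - 1996) + e
  plain <- ols_trend(x, y)
  robust <- ols_trend(x, y, robust_se = TRUE)
  expect_equal(robust$slope, plain$slope) # point estimate unchanged
  expect_false(isTRUE(all.equal(robust$se, plain$se)))
  expect_gt(robust$se, 0)
})

test_that("default sensor eras overlap by at least one year in succession", {
  s <- default_sensors()
  expect_gte(s$gome$era[2], s$sciamachy$era[1])
  expect_gte(s$sciamachy$era[2], s$gome2$era[1])
})

test_that("trend_table reports full-period and sub-period rows per region", {
  pwm_tbl <- tibble::tibble(
    region_id = rep(1:2, each = 17), year = rep(1996:2012, 2),
    pwm_ppb = c(10 * 0.97^(0:16), 2 * 1.03^(0:16)) * rep(c(1, 1.001), 17)
  )
  class(pwm_tbl) <- c("pwm_series", class(pwm_tbl))
  tt <- trend_table(pwm_tbl, subperiods = list(c(1996, 2003), c(2004, 2010)))
  expect_equal(nrow(tt), 2 * 3)
  expect_setequal(unique(tt$period), c("full", "1996-2003", "2004-2010"))
  y1 <- pwm_tbl$pwm_ppb[pwm_tbl$region_id == 1]
  direct <- subperiod_trend(1996:2012, y1, 2004, 2010)
  row <- tt[tt$region_id == 1 & tt$period == "2004-2010", ]
  expect_equal(row$rel_trend, direct$rel_trend, tolerance = 1e-12)
  expect_equal(row$mean_ppb, mean(y1), tolerance = 1e-12)
})
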