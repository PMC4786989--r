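#' Ordinary least-squares trend with 95% CI and relative trend
#'
#' Fits `value ~ year` by OLS (years centered for numerical stability; the
#' slope is unchanged), with the 95% confidence interval
#' `slope +/- t(0.975, n - 2) * SE` and the two-sided t-test p-value on the
#' slope. The relative trend expresses the slope in percent per year of the
#' series' long-term mean, with the same transform applied to the CI ends.
#' Missing years are dropped, not imputed. Degenerate contracts: an exactly
#' linear series has SE 0 and zero CI width (p-value 0 unless the slope is
#' also 0, in which case p = 1).
#'
#' @param years Numeric years.
#' @param values Series values (same length; `NA` dropped).
#' @param period Optional `c(start, end)` restricting the fit.
#' @param longterm_mean Mean used for the relative trend; defaults to the
#'   mean of the fitted values' own years. Sub-period fits pass the
#'   full-period mean here.
#' @param alpha Significance level for the `significant` flag (`p <= alpha`;
#'   default 0.01).
#' @param robust_se Use Newey-West (heteroskedasticity- and
#'   autocorrelation-consistent) standard errors instead of the plain OLS
#'   ones. Off by default — the reporting convention is plain OLS — and
#'   intended for sensitivity analyses of serially correlated residuals.
#' @return An object of class `no2_trend`: slope (per year), `ci_lo`,
#'   `ci_hi`, `p_value`, `longterm_mean`, `rel_trend`, `rel_ci_lo`,
#'   `rel_ci_hi` (percent/year), `n`, `period`, `significant`.
#' @export
ols_trend <- function(years, values, period = NULL, longterm_mean = NULL,
                      alpha = 0.01, robust_se = FALSE) {
  stopifnot(length(years) == length(values))
  keep <- !is.na(values) & !is.na(years)
  if (!is.null(period)) keep <- keep & years >= period[1] & years <= period[2]
  x <- years[keep]
  y <- values[keep]
  n <- length(x)
  if (n < 3) {
    stop("trend undefined: fewer than 3 non-missing years in period", call. = FALSE)
  }
  fit <- stats::lm(y ~ I(x - mean(x)))
  slope <- unname(stats::coef(fit)[2])
  vc <- suppressWarnings(if (robust_se) {
    # Newey-West (1994) plug-in bandwidth for short annual series
    sandwich::NeweyWest(fit, lag = max(1L, floor(4 * (n / 100)^(2 / 9))),
                        prewhite = FALSE)
  } else {
    stats::vcov(fit)
  })
  se <- unname(sqrt(diag(vc))[2])
  sigma2 <- sum(stats::residuals(fit)^2)
  if (sigma2 < 1e-24 * max(1, mean(y)^2)) { # numerically exact fit
    se <- 0
    p <- if (abs(slope) <= 1e-12 * max(1, abs(mean(y)))) 1 else 0
  } else {
    p <- 2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  }
  tcrit <- stats::qt(0.975, df = n - 2)
  lo <- slope - tcrit * se
  hi <- slope + tcrit * se
  ltm <- longterm_mean %||% mean(y)
  rel <- if (ltm > 0) 100 * c(slope, lo, hi) / ltm else rep(NA_real_, 3)
  structure(
    list(
      slope = slope, ci_lo = lo, ci_hi = hi, se = se, p_value = p,
      longterm_mean = ltm,
      rel_trend = rel[1], rel_ci_lo = rel[2], rel_ci_hi = rel[3],
      n = n, period = c(min(x), max(x)),
      alpha = alpha, significant = p <= alpha
    ),
    class = "no2_trend"
  )
}

#' @export
print.no2_trend <- function(x, ...) {
  cat(sprintf(
    "<no2_trend> slope %.4g/yr (95%% CI %.4g, %.4g), p = %.3g\n  relative: %.2f %%/yr (95%% CI %.2f, %.2f) of long-term mean %.3g; n = %d (%d-%d)\n",
    x$slope, x$ci_lo, x$ci_hi, x$p_value,
    x$rel_trend, x$rel_ci_lo, x$rel_ci_hi, x$longterm_mean,
    x$n, x$period[1], x$period[2]
  ))
  invisible(x)
}

#' @export
tidy.no2_trend <- function(x, ...) {
  tibble::tibble(
    term = "year",
    estimate = x$slope, std.error = x$se,
    conf.low = x$ci_lo, conf.high = x$ci_hi, p.value = x$p_value,
    rel.trend = x$rel_trend, rel.conf.low = x$rel_ci_lo, rel.conf.high = x$rel_ci_hi
  )
}

#' @export
glance.no2_trend <- function(x, ...) {
  tibble::tibble(
    longterm.mean = x$longterm_mean, p.value = x$p_value,
    nobs = x$n, significant = x$significant,
    period.start = x$period[1], period.end = x$period[2]
  )
}

#' Sub-period trend relative to the full-period mean
#'
#' Fits the slope on the sub-period years only, but expresses the relative
#' trend in percent per year of the full series' long-term mean — the
#' convention used when quoting, e.g., a steeper mid-record decline against
#' the 17-year mean.
#'
#' @param years,values Full series.
#' @param start,end Sub-period bounds (inclusive), within the series period.
#' @inheritParams ols_trend
#' @return An `no2_trend`.
#' @export
subperiod_trend <- function(years, values, start, end, alpha = 0.01) {
  keep <- !is.na(values)
  if (!any(years[keep] >= start & years[keep] <= end)) {
    stop("empty sub-period", call. = FALSE)
  }
  ols_trend(years, values, period = c(start, end),
            longterm_mean = mean(values[keep]), alpha = alpha)
}

#' Normalize a series to its long-term mean
#'
#' Each value divided by the mean over the series' own non-missing years;
#' the normalized series has mean 1 and is dimensionless, so records with
#' different absolute calibrations (e.g. a biased monitor and an area-mean
#' satellite pixel) can be compared through their relative changes.
#'
#' @param values Series values.
#' @return Normalized values.
#' @export
normalize_to_longterm_mean <- function(values) {
  m <- mean(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("normalization undefined: long-term mean is not positive", call. = FALSE)
  }
  values / m
}

#' Absolute difference between two relative trends
#'
#' @param rel_trend_a,rel_trend_b Relative trends in percent per year.
#' @return `|a - b|` in percent per year.
#' @examples
#' trend_difference(-4.4, -3.7) # 0.7
#' @export
trend_difference <- function(rel_trend_a, rel_trend_b) {
  abs(rel_trend_a - rel_trend_b)
}

#' Per-region trend table from a PWM series
#'
#' @param pwm_tbl A `pwm_series` tibble (`region_id`, `year`, `pwm_ppb`).
#' @param alpha Significance level (default 0.01; `p <= alpha` significant).
#' @param subperiods Optional list of `c(start, end)` sub-periods, reported
#'   relative to each region's full-period mean.
#' @return Tibble: `region_id`, `period`, `slope_ppb_yr`, `ci_lo`, `ci_hi`,
#'   `p_value`, `mean_ppb`, `rel_trend`, `rel_ci_lo`, `rel_ci_hi`,
#'   `significant`.
#' @export
trend_table <- function(pwm_tbl, alpha = 0.01, subperiods = NULL) {
  one <- function(df, per, lab) {
    tr <- if (is.null(per)) {
      ols_trend(df$year, df$pwm_ppb, alpha = alpha)
    } else {
      subperiod_trend(df$year, df$pwm_ppb, per[1], per[2], alpha = alpha)
    }
    tibble::tibble(
      region_id = df$region_id[1], period = lab,
      slope_ppb_yr = tr$slope, ci_lo = tr$ci_lo, ci_hi = tr$ci_hi,
      p_value = tr$p_value, mean_ppb = tr$longterm_mean,
      rel_trend = tr$rel_trend, rel_ci_lo = tr$rel_ci_lo, rel_ci_hi = tr$rel_ci_hi,
      significant = tr$significant
    )
  }
  pwm_tbl |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_map(function(df, key) {
      df$region_id <- key$region_id
      full <- one(df, NULL, "full")
      subs <- lapply(subperiods, function(p) one(df, p, sprintf("%d-%d", p[1], p[2])))
      dplyr::bind_rows(c(list(full), subs))
    }) |>
    dplyr::bind_rows()
}

#' Compare the satellite record with ground stations through relative trends
#'
#' Applies the station-network selection rules (a minimum number of
#' satellite-coincident observations per year, a minimum number of years,
#' optional exclusion of traffic sites), averages stations sharing a pixel,
#' normalizes both the station series and the collocated satellite pixel
#' series to their long-term means, and reports both trends and their
#' absolute difference.
#'
#' @param surface_fields Named list (by year) of annual surface
#'   `grid_field`s (the satellite-derived record).
#' @param stations Station tibble from [make_stations()].
#' @param station_obs Daily observations from [station_observations()].
#' @param coincident_days Optional tibble `row`, `col`, `year`, `ndays` of
#'   valid satellite retrieval days per cell-year; stations require
#'   `ndays >= min_coincident` in at least `min_years` years. When `NULL`,
#'   the coincidence rule is taken as satisfied.
#' @param min_coincident Minimum satellite-coincident observations per year
#'   (default 5).
#' @param min_years Minimum qualifying years (default 15).
#' @param exclude_traffic Drop stations of class `"traffic"` (default TRUE).
#' @param alpha Significance level passed through to the trend fits.
#' @return A list of class `station_comparison`: `pixels` tibble (`row`,
#'   `col`, `n_stations`, `sat_rel_trend`, `ground_rel_trend`,
#'   `trend_difference`, CIs), `series` tibble of paired normalized annual
#'   series, and `n_excluded`.
#' @export
compare_with_stations <- function(surface_fields, stations, station_obs,
                                  coincident_days = NULL,
                                  min_coincident = 5, min_years = 15,
                                  exclude_traffic = TRUE, alpha = 0.01) {
  years <- as.integer(names(surface_fields))
  n0 <- nrow(stations)
  if (exclude_traffic) stations <- dplyr::filter(stations, .data$class != "traffic")
  # station annual means from their completely sampled daily series
  ann <- station_obs |>
    dplyr::filter(.data$station_id %in% stations$station_id, .data$year %in% years) |>
    dplyr::group_by(.data$station_id, .data$year) |>
    dplyr::summarise(value = mean(.data$value_ppb), .groups = "drop")
  yrs_per_st <- dplyr::count(ann, .data$station_id)
  ok_years <- yrs_per_st$station_id[yrs_per_st$n >= min_years]
  stations <- dplyr::filter(stations, .data$station_id %in% ok_years)
  if (!is.null(coincident_days)) {
    qualifies <- vapply(seq_len(nrow(stations)), function(i) {
      nd <- coincident_days |>
        dplyr::filter(.data$row == stations$row[i], .data$col == stations$col[i],
                      .data$ndays >= min_coincident)
      nrow(nd) >= min_years
    }, logical(1))
    stations <- stations[qualifies, , drop = FALSE]
  }
  if (nrow(stations) == 0) {
    warning("no station passes the selection rules", call. = FALSE)
    return(structure(
      list(pixels = tibble::tibble(), series = tibble::tibble(),
           n_excluded = n0),
      class = "station_comparison"
    ))
  }
  # average stations sharing a pixel, then pair with the satellite cell series
  ann <- dplyr::inner_join(ann, stations[, c("station_id", "row", "col")],
                           by = "station_id")
  pix_ground <- ann |>
    dplyr::group_by(.data$row, .data$col, .data$year) |>
    dplyr::summarise(ground = mean(.data$value), .groups = "drop")
  sat_at <- function(row, col) {
    vapply(years, function(y) surface_fields[[as.character(y)]]$values[row, col],
           numeric(1))
  }
  pix_keys <- dplyr::distinct(pix_ground, .data$row, .data$col)
  pixels <- list()
  series <- list()
  for (i in seq_len(nrow(pix_keys))) {
    r <- pix_keys$row[i]
    cc <- pix_keys$col[i]
    g <- dplyr::filter(pix_ground, .data$row == r, .data$col == cc)
    sat <- sat_at(r, cc)
    keep <- !is.na(sat) & years %in% g$year
    if (sum(keep) < 3) next
    yv <- years[keep]
    sat_n <- normalize_to_longterm_mean(sat[keep])
    gr_n <- normalize_to_longterm_mean(g$ground[match(yv, g$year)])
    t_sat <- ols_trend(yv, sat_n, alpha = alpha)
    t_gr <- ols_trend(yv, gr_n, alpha = alpha)
    pixels[[i]] <- tibble::tibble(
      row = r, col = cc,
      n_stations = sum(stations$row == r & stations$col == cc),
      sat_rel_trend = t_sat$rel_trend, sat_rel_ci_lo = t_sat$rel_ci_lo,
      sat_rel_ci_hi = t_sat$rel_ci_hi,
      ground_rel_trend = t_gr$rel_trend, ground_rel_ci_lo = t_gr$rel_ci_lo,
      ground_rel_ci_hi = t_gr$rel_ci_hi,
      trend_difference = trend_difference(t_sat$rel_trend, t_gr$rel_trend)
    )
    series[[i]] <- tibble::tibble(
      row = r, col = cc, year = yv, satellite = sat_n, ground = gr_n
    )
  }
  structure(
    list(
      pixels = dplyr::bind_rows(pixels),
      series = dplyr::bind_rows(series),
      n_excluded = n0 - nrow(stations)
    ),
    class = "station_comparison"
  )
}
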