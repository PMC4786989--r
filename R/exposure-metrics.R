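#' Interpolate population between snapshots
#'
#' Cellwise linear interpolation between the bracketing 5-year snapshots;
#' years outside the snapshot range clamp to the nearest snapshot.
#'
#' @param series A `population_series`.
#' @param year Target year.
#' @return A `grid_field` of persons.
#' @export
interpolate_population <- function(series, year) {
  ys <- series$years
  if (year <= ys[1]) return(series$fields[[1]])
  if (year >= ys[length(ys)]) return(series$fields[[length(ys)]])
  hit <- match(year, ys)
  if (!is.na(hit)) return(series$fields[[hit]])
  i <- findInterval(year, ys)
  w <- (year - ys[i]) / (ys[i + 1] - ys[i])
  a <- series$fields[[i]]
  b <- series$fields[[i + 1]]
  grid_field(a$spec, (1 - w) * a$values + w * b$values)
}

#' Population-weighted mean over a region
#'
#' `sum(pop_i * C_i) / sum(pop_i)` over the region's unmasked cells; masked
#' cells drop out of both sums (weight renormalization).
#'
#' @param field `grid_field` of concentrations.
#' @param population `grid_field` of persons on the same grid.
#' @param region_mask `grid_field` of integer region ids, or `NULL` to use
#'   the whole grid.
#' @param region_id Region to evaluate (ignored when `region_mask` is
#'   `NULL`).
#' @return Scalar PWM in the field's units.
#' @export
pwm <- function(field, population, region_mask = NULL, region_id = NULL) {
  sel <- region_cells(field, population, region_mask, region_id)
  sum(sel$pop * sel$conc) / sum(sel$pop)
}

region_cells <- function(field, population, region_mask, region_id) {
  stopifnot(identical(dim(field$values), dim(population$values)))
  keep <- !is.na(field$values) & !is.na(population$values)
  if (!is.null(region_mask)) {
    stopifnot(!is.null(region_id))
    keep <- keep & region_mask$values == region_id
  }
  pop <- population$values[keep]
  conc <- field$values[keep]
  if (sum(pop) <= 0) {
    stop("population-weighted statistic undefined: zero total population in region",
         call. = FALSE)
  }
  list(conc = conc, pop = pop)
}

#' Population-weighted percentile and cumulative distribution
#'
#' Sorts the region's cells by concentration and accumulates population
#' fraction; the `q`th percentile is the concentration at which the
#' cumulative fraction first reaches `q/100`, with linear interpolation
#' between adjacent cell boundaries in cumulative-population space.
#'
#' @inheritParams pwm
#' @param q Percentile(s) in (0, 100).
#' @return `pw_percentile()`: concentration(s); `pw_cdf()`: a tibble of
#'   class `weighted_cdf` with sorted `conc` and nondecreasing cumulative
#'   population fraction `cum_frac` from its first positive mass to 1.
#' @export
pw_percentile <- function(field, population, region_mask = NULL, region_id = NULL, q) {
  stopifnot(all(q > 0 & q < 100))
  cdf <- pw_cdf(field, population, region_mask, region_id)
  stats::approx(
    x = cdf$cum_frac, y = cdf$conc, xout = q / 100,
    method = "linear", rule = 2, ties = "ordered"
  )$y
}

#' @rdname pw_percentile
#' @export
pw_cdf <- function(field, population, region_mask = NULL, region_id = NULL) {
  sel <- region_cells(field, population, region_mask, region_id)
  ord <- order(sel$conc)
  conc <- sel$conc[ord]
  cf <- cumsum(sel$pop[ord]) / sum(sel$pop)
  out <- tibble::tibble(conc = conc, cum_frac = cf)
  class(out) <- c("weighted_cdf", class(out))
  out
}

#' Percent change between two values
#'
#' `100 * (v_end - v_start) / v_start`, with the reported integer rounded
#' half away from zero; the unrounded value is preserved alongside.
#'
#' @param v_start,v_end Start and end values; `v_start` must be positive.
#' @return A tibble with `percent` (unrounded) and `percent_rounded`.
#' @examples
#' percent_change(15.9, 13.4) # -16%
#' percent_change(1.2, 1.6)   # +33%
#' @export
percent_change <- function(v_start, v_end) {
  if (any(v_start <= 0)) {
    stop("percent change undefined for nonpositive start value", call. = FALSE)
  }
  p <- 100 * (v_end - v_start) / v_start
  tibble::tibble(percent = p, percent_rounded = round_half_away(p))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Population living under significant trends
#'
#' Sums population over regions whose trend is statistically significant
#' (`p <= alpha`, so a p-value exactly at the threshold counts), split by
#' trend sign.
#'
#' @param trend_table Tibble with columns `region_id`, `p_value` and a slope
#'   or relative-trend column named by `slope_col`.
#' @param population `grid_field` of persons.
#' @param region_mask `grid_field` of integer region ids.
#' @param alpha Significance level (default 0.01).
#' @param slope_col Column giving the trend sign (default `rel_trend`).
#' @return Tibble with `direction` (`"increase"`/`"decrease"`) and `persons`.
#' @export
population_under_trend <- function(trend_table, population, region_mask,
                                   alpha = 0.01, slope_col = "rel_trend") {
  pops <- vapply(trend_table$region_id, function(id) {
    keep <- region_mask$values == id & !is.na(population$values)
    sum(population$values[keep])
  }, numeric(1))
  sig <- !is.na(trend_table$p_value) & trend_table$p_value <= alpha
  slope <- trend_table[[slope_col]]
  tibble::tibble(
    direction = c("increase", "decrease"),
    persons = c(sum(pops[sig & slope > 0]), sum(pops[sig & slope < 0]))
  )
}

#' Population-weighted mean time series per region
#'
#' Convenience builder: interpolates population to each record year and
#' computes per-region PWM over the unmasked cells of each annual surface
#' field.
#'
#' @param surface_fields Named list (by year) of surface `grid_field`s.
#' @param population A `population_series`.
#' @param region_mask `grid_field` of region ids (with a `region_table`
#'   attribute, optional).
#' @param region_ids Regions to report (default: all positive ids present).
#' @return Tibble of class `pwm_series`: `region_id`, `year`, `pwm_ppb`,
#'   `population`.
#' @export
pwm_series <- function(surface_fields, population, region_mask, region_ids = NULL) {
  years <- as.integer(names(surface_fields))
  if (is.null(region_ids)) {
    region_ids <- sort(setdiff(unique(as.vector(region_mask$values)), 0L))
  }
  rows <- list()
  for (y in years) {
    pop_y <- interpolate_population(population, y)
    f <- surface_fields[[as.character(y)]]
    for (id in region_ids) {
      keep <- region_mask$values == id & !is.na(f$values) & !is.na(pop_y$values)
      val <- if (any(keep) && sum(pop_y$values[keep]) > 0) {
        pwm(f, pop_y, region_mask, id)
      } else {
        NA_real_ # region-year with no valid populated cell
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        region_id = id, year = y,
        pwm_ppb = val,
        population = sum(pop_y$values[keep])
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pwm_series", class(out))
  out
}
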