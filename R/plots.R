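#' Plot a population-weighted mean time series
#'
#' One line per region of annual population-weighted mean NO2.
#'
#' @param object A `pwm_series` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwm_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$year, y = .data$pwm_ppb,
    colour = factor(.data$region_id), group = .data$region_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "year", y = expression("population-weighted mean" ~ NO[2] ~ "(ppb)"),
      colour = "region"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a population-weighted cumulative distribution
#'
#' @param object A `weighted_cdf` tibble.
#' @param ... Unused.
#' @export
autoplot.weighted_cdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$conc, y = .data$cum_frac)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = expression(NO[2] ~ "(ppb)"),
      y = "cumulative population fraction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a gridded field as a raster map
#'
#' @param object A `grid_field`.
#' @param ... Unused.
#' @export
autoplot.grid_field <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$lon, y = .data$lat, fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Plot paired normalized satellite and station series
#'
#' @param object A `station_comparison`.
#' @param ... Unused.
#' @export
autoplot.station_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series, c("satellite", "ground"),
                              names_to = "source", values_to = "normalized")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$year, y = .data$normalized,
    colour = .data$source, linetype = .data$source
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ paste0("pixel (", row, ",", col, ")")) +
    ggplot2::labs(x = "year", y = "normalized to long-term mean") +
    ggplot2::theme_minimal()
}
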