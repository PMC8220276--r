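# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted covariance model
#'
#' @param x A [covariance_model()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`.
#' @export
tidy.covariance_model <- function(x, ...) {
  tibble::tibble(
    term = c("sill", "nugget", "range_space", "range_time"),
    estimate = c(x$sill, x$nugget, x$range_space, x$range_time),
    unit = c("var(transformed)", "var(transformed)", "km", "hours"))
}

#' @rdname tidy.covariance_model
#' @return For `glance()`: one row with the fit summary (`family`,
#'   `transform`, WLS objective, convergence flag, pair counts; `NA`
#'   when the model was specified rather than fitted).
#' @export
glance.covariance_model <- function(x, ...) {
  f <- attr(x, "fit")
  tibble::tibble(family = x$family, transform = x$transform,
                 objective = f$objective %||% NA_real_,
                 convergence = f$convergence %||% NA_integer_,
                 n_bins = f$n_bins %||% NA_integer_,
                 n_pairs = f$n_pairs %||% NA_real_)
}

# Long tibble from a (lat, lon, time[, realization]) array
field_long <- function(a, grid, value_name) {
  dn <- dim(a)
  df <- tidyr::expand_grid(
    r = if (length(dn) == 4) seq_len(dn[4]) else 1L,
    t = seq_len(dn[3]), j = seq_len(dn[2]), i = seq_len(dn[1]))
  df[[value_name]] <- as.vector(a)
  df <- df[!is.na(df[[value_name]]), , drop = FALSE]
  out <- tibble::tibble(
    lat = grid$lat[df$i], lon = grid$lon[df$j],
    time = grid$times[df$t], i = df$i, j = df$j)
  out[[value_name]] <- df[[value_name]]
  if (length(dn) == 4) out$realization <- df$r
  out
}

#' Tidy gridded fields into long tibbles
#'
#' @param x A `density_field`, `density_ensemble`, `velocity_field` or
#'   `flow_result`.
#' @param ... Unused.
#' @return A long tibble with `lat`, `lon`, `time` and the field values;
#'   masked cells are dropped.
#' @export
tidy.density_field <- function(x, ...) field_long(x$estimate, x$grid, "density")

#' @rdname tidy.density_field
#' @export
tidy.density_ensemble <- function(x, ...) field_long(x$fields, x$grid, "density")

#' @rdname tidy.density_field
#' @export
tidy.velocity_field <- function(x, ...) {
  a <- field_long(x$v_lon, x$grid, "v_lon")
  b <- field_long(x$v_lat, x$grid, "v_lat")
  dplyr::inner_join(a, b, by = c("lat", "lon", "time", "i", "j"))
}

#' @rdname tidy.density_field
#' @export
tidy.flow_result <- function(x, ...) {
  grid <- x$grid
  out <- field_long(x$W, grid_spec_steps(grid), "W")
  out$takeoff <- pmax(out$W, 0)
  out$landing <- -pmin(out$W, 0)
  out
}

# A grid whose time axis is the W step axis (first n_t - 1 instants).
grid_spec_steps <- function(grid) {
  g <- grid
  g$times <- grid$times[-grid$n_t]
  g$n_t <- grid$n_t - 1L
  g
}

#' Health summary of a flow-model run
#'
#' @param x A `flow_result`.
#' @param ... Unused.
#' @return One row: total take-off and landing (birds), net boundary flux
#'   (birds), worst absolute and relative mass-balance residuals.
#' @export
glance.flow_result <- function(x, ...) {
  gm <- grid_metrics(x$grid)
  area <- matrix(gm$area_km2, x$grid$n_lat, x$grid$n_lon)
  dt <- x$grid$d_t_hours
  sum_field <- function(f) {
    tot <- 0
    for (t in seq_len(dim(f)[3])) {
      sl <- f[, , t]
      tot <- tot + sum(sl[!is.na(sl)] * area[!is.na(sl)]) * dt
    }
    tot
  }
  tibble::tibble(
    takeoff_birds = sum_field(x$takeoff),
    landing_birds = sum_field(x$landing),
    net_boundary_birds = sum(x$boundary$flux) * dt,
    max_residual = max(x$residual$residual, na.rm = TRUE),
    max_rel_residual = max(x$residual$rel_residual, na.rm = TRUE))
}

#' Map the nightly take-off and landing pulses
#'
#' One raster panel per (night, phase), the visual used to follow a
#' migration wave from night to night.
#'
#' @param object A [nightly_pulses()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nightly_pulses <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("takeoff_km2", "landing_km2"),
                        names_to = "phase", values_to = "birds_km2") |>
    dplyr::mutate(phase = dplyr::recode(.data$phase,
                                        takeoff_km2 = "take-off",
                                        landing_km2 = "landing"))
  ggplot2::ggplot(long, ggplot2::aes(.data$lon, .data$lat,
                                     fill = .data$birds_km2)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(phase ~ night) +
    ggplot2::scale_fill_viridis_c(name = "birds/km²") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' Plot the year-round accumulation of birds on the ground
#'
#' Nightly change (landing minus take-off) as bars with the cumulative
#' number of birds on the ground as a line, zeroed at the series start.
#'
#' @param object An [ground_accumulation()] series.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accumulation_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$night)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$delta_ground),
                      fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "brown") +
    ggplot2::labs(x = NULL, y = "birds",
                  title = "Nightly change and cumulative birds on the ground")
}

#' Plot seasonal transect flows
#'
#' @param object A [seasonal_transect_flows()] summary.
#' @param ... Unused.
#' @return A ggplot object with entering/leaving totals per transect and
#'   season.
#' @export
autoplot.transect_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("entering", "leaving"),
                              names_to = "direction", values_to = "birds")
  ggplot2::ggplot(long, ggplot2::aes(.data$transect, .data$birds,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~season) +
    ggplot2::labs(x = NULL, y = "birds")
}

#' Plot an empirical variogram with its fitted model
#'
#' @param cov A fitted [covariance_model()] (from [fit_covariance()]).
#' @return A ggplot object: empirical points by time lag with fitted
#'   curves over distance.
#' @export
plot_variogram <- function(cov) {
  ev <- attr(cov, "variogram")
  if (is.null(ev)) stop("model carries no empirical variogram", call. = FALSE)
  hh <- seq(0, max(ev$h_km), length.out = 60)
  fit <- tidyr::expand_grid(h_km = hh, u_hours = unique(ev$u_hours)) |>
    dplyr::mutate(gamma = vario_st(.data$h_km, .data$u_hours, cov))
  ggplot2::ggplot(ev, ggplot2::aes(.data$h_km, .data$gamma,
                                   colour = factor(.data$u_hours))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_line(data = fit) +
    ggplot2::scale_size_area(guide = "none") +
    ggplot2::labs(x = "distance [km]", y = "semivariance",
                  colour = "lag [h]")
}
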