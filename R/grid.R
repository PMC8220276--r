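#' Kilometres per degree of latitude
#'
#' Conversion constant used throughout for the metric size of grid cells.
#' @keywords internal
KM_PER_DEG <- 111.32

#' Define the space-time lattice
#'
#' Builds the regular latitude-longitude-time grid on which densities,
#' velocities and fluxes live. Cell centres sit half a step inside the
#' domain edges; time instants run from `t_start` to `t_end` inclusive at
#' step `d_t_hours`. Indices are `i` for latitude (south to north), `j` for
#' longitude (west to east) and `t` for time.
#'
#' @param lat_min,lat_max,lon_min,lon_max Domain edges in degrees.
#' @param d_lat,d_lon Cell size in degrees.
#' @param t_start,t_end POSIXct (UTC) period covered, `t_end` inclusive.
#' @param d_t_hours Time step in hours; must divide 24 evenly.
#' @return A `grid_spec` object: cell-centre coordinate vectors `lat`, `lon`,
#'   time instants `times`, sizes `n_lat`, `n_lon`, `n_t` and the steps.
#' @examples
#' g <- grid_spec(44, 49, 0, 6, t_start = as.POSIXct("2018-04-06", tz = "UTC"),
#'                t_end = as.POSIXct("2018-04-07", tz = "UTC"))
#' g$n_lat
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max,
                      d_lat = 0.25, d_lon = 0.25,
                      t_start, t_end, d_t_hours = 0.25) {
  stopifnot(d_lat > 0, d_lon > 0, d_t_hours > 0,
            lat_max > lat_min, lon_max > lon_min)
  if (abs(24 / d_t_hours - round(24 / d_t_hours)) > 1e-9)
    stop("`d_t_hours` must divide one day evenly", call. = FALSE)
  n_lat <- (lat_max - lat_min) / d_lat
  n_lon <- (lon_max - lon_min) / d_lon
  if (abs(n_lat - round(n_lat)) > 1e-6 || abs(n_lon - round(n_lon)) > 1e-6)
    stop("domain extent must be an integer number of cells", call. = FALSE)
  n_lat <- as.integer(round(n_lat)); n_lon <- as.integer(round(n_lon))
  t_start <- as.POSIXct(t_start, tz = "UTC")
  t_end <- as.POSIXct(t_end, tz = "UTC")
  n_steps <- as.numeric(difftime(t_end, t_start, units = "hours")) / d_t_hours
  if (n_steps < 1 || abs(n_steps - round(n_steps)) > 1e-6)
    stop("period must be a positive integer number of time steps", call. = FALSE)
  times <- t_start + 3600 * d_t_hours * seq(0L, round(n_steps))
  structure(list(
    lat_min = lat_min, lat_max = lat_max, lon_min = lon_min, lon_max = lon_max,
    d_lat = d_lat, d_lon = d_lon, d_t_hours = d_t_hours,
    n_lat = n_lat, n_lon = n_lon, n_t = length(times),
    lat = lat_min + d_lat * (seq_len(n_lat) - 0.5),
    lon = lon_min + d_lon * (seq_len(n_lon) - 0.5),
    times = times
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells (%.2f deg), %d time instants (%.2f h)\n  lat [%g, %g]  lon [%g, %g]\n  %s .. %s UTC\n",
    x$n_lat, x$n_lon, x$d_lat, x$n_t, x$d_t_hours,
    x$lat_min, x$lat_max, x$lon_min, x$lon_max,
    format(x$times[1]), format(x$times[x$n_t])))
  invisible(x)
}

#' Metric cell geometry of a latitude-longitude grid
#'
#' The latitudinal extent of a cell is constant in kilometres while the
#' longitudinal extent shrinks with the cosine of latitude; both, and the
#' resulting cell areas, are needed to discretize the continuity equation
#' on the lattice.
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per latitude row: `i`, `lat`, `dlat_km`,
#'   `dlon_km` and `area_km2`.
#' @examples
#' g <- grid_spec(44, 49, 0, 6, t_start = as.POSIXct("2018-04-06", tz = "UTC"),
#'                t_end = as.POSIXct("2018-04-07", tz = "UTC"))
#' cell_geometry(g)
#' @export
cell_geometry <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  g <- grid_metrics(grid)
  tibble::tibble(
    i = seq_len(grid$n_lat), lat = grid$lat,
    dlat_km = g$dlat_km, dlon_km = g$dlon_km, area_km2 = g$area_km2)
}

# Internal metric bundle: per-row widths/areas plus interface lengths.
# Latitude-interface lengths are evaluated at the *edge* latitude so that
# the flux-form divergence telescopes exactly over any set of cells.
grid_metrics <- function(grid) {
  dlat_km <- grid$d_lat * KM_PER_DEG
  dlon_km <- grid$d_lon * KM_PER_DEG * cos(grid$lat * pi / 180)
  lat_edges <- grid$lat_min + grid$d_lat * seq(0L, grid$n_lat)
  list(
    dlat_km = dlat_km,
    dlon_km = dlon_km,
    area_km2 = dlat_km * dlon_km,
    # length of the interface between rows i and i+1 (n_lat + 1 values)
    len_lat_if_km = grid$d_lon * KM_PER_DEG * cos(lat_edges * pi / 180),
    # length of an east-west interface (constant)
    len_lon_if_km = dlat_km)
}

# Map POSIXct times onto grid time indices; error on misalignment.
time_index <- function(grid, times) {
  idx <- as.numeric(difftime(times, grid$times[1], units = "hours")) / grid$d_t_hours
  if (any(abs(idx - round(idx)) > 1e-6, na.rm = TRUE))
    stop("times are not aligned on the grid time step", call. = FALSE)
  out <- as.integer(round(idx)) + 1L
  out[out < 1L | out > grid$n_t] <- NA_integer_
  out
}
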