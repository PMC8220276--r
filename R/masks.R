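#' Build the static and dynamic validity masks of the model domain
#'
#' A cell is statically valid when it is on land, at or below the elevation
#' ceiling, and within surveillance range of at least one radar
#' (great-circle distance). A (cell, step) is dynamically valid when the
#' cell is statically valid, the step is nocturnal there, rain stays at or
#' below `rain_max`, and the night is not on the excluded list.
#'
#' @param grid A [grid_spec()].
#' @param dem List with matrices `elevation_m` and logical `water`, both
#'   `n_lat x n_lon`. See [flat_dem()] for an all-land default.
#' @param radars List of [radar_site()] objects (or a data frame with
#'   `lat`, `lon` columns).
#' @param nights A [assign_nights()] index on the same grid.
#' @param rain Array `n_lat x n_lon x n_t` of rain intensity in mm/h, or
#'   `NULL` for a rain-free run. `NA` rain over a statically valid cell is
#'   a configuration error.
#' @param max_elev_m Elevation ceiling, m a.s.l. (default 2000).
#' @param max_radar_dist_km Maximum distance to the nearest radar (default 150).
#' @param rain_max Rain threshold in mm/h (default 1).
#' @param excluded_nights `Date` vector of no-data nights to blank out.
#' @return A `mask_stack`: logical matrix `static` and logical array
#'   `dynamic` (`dynamic` implies `static` everywhere).
#' @export
build_masks <- function(grid, dem, radars, nights, rain = NULL,
                        max_elev_m = 2000, max_radar_dist_km = 150,
                        rain_max = 1, excluded_nights = NULL) {
  stopifnot(inherits(grid, "grid_spec"), inherits(nights, "night_index"))
  nl <- grid$n_lat; nc <- grid$n_lon; nt <- grid$n_t
  stopifnot(all(dim(dem$elevation_m) == c(nl, nc)),
            all(dim(dem$water) == c(nl, nc)))
  if (inherits(radars, "radar_site")) radars <- list(radars)
  if (is.data.frame(radars)) {
    rlat <- radars$lat; rlon <- radars$lon
  } else {
    rlat <- vapply(radars, `[[`, numeric(1), "lat")
    rlon <- vapply(radars, `[[`, numeric(1), "lon")
  }
  cells <- cbind(lon = rep(grid$lon, each = nl), lat = rep(grid$lat, nc))
  dmin <- rep(Inf, nl * nc)
  for (r in seq_along(rlat)) {
    d <- geosphere::distHaversine(cells, c(rlon[r], rlat[r])) / 1000
    dmin <- pmin(dmin, d)
  }
  static <- !dem$water & dem$elevation_m <= max_elev_m &
    matrix(dmin <= max_radar_dist_km, nl, nc)
  if (is.null(rain)) rain <- array(0, c(nl, nc, nt))
  stopifnot(all(dim(rain) == c(nl, nc, nt)))
  if (any(is.na(rain[array(static, c(nl, nc, nt))])))
    stop("rain grid is missing over statically valid cells", call. = FALSE)
  dynamic <- array(static, c(nl, nc, nt)) & nights$is_night &
    (is.na(rain) | rain <= rain_max)
  if (length(excluded_nights)) {
    excl <- as.integer(as.Date(excluded_nights))
    dynamic <- dynamic & !array(nights$night_date %in% excl, c(nl, nc, nt))
  }
  structure(list(grid = grid, static = static, dynamic = dynamic,
                 params = list(max_elev_m = max_elev_m,
                               max_radar_dist_km = max_radar_dist_km,
                               rain_max = rain_max,
                               excluded_nights = as.Date(excluded_nights %||% as.Date(character())))),
            class = "mask_stack")
}

#' All-land, sea-level elevation model for a grid
#'
#' Convenience input for [build_masks()] on synthetic scenarios.
#' @param grid A [grid_spec()].
#' @return List with `elevation_m` (zeros) and `water` (all `FALSE`).
#' @export
flat_dem <- function(grid) {
  list(elevation_m = matrix(0, grid$n_lat, grid$n_lon),
       water = matrix(FALSE, grid$n_lat, grid$n_lon))
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("<mask_stack> %d/%d cells statically valid; %.1f%% of (cell,step) pairs dynamically valid\n",
              sum(x$static), length(x$static), 100 * mean(x$dynamic)))
  invisible(x)
}
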