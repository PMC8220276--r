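# Nightly, seasonal and year-round aggregation of flow-model output.

# Long per-(cell, step) view of the source/sink arrays with night labels.
ssf_long <- function(flow, nights) {
  grid <- flow$grid
  gm <- grid_metrics(grid)
  nl <- grid$n_lat; nc <- grid$n_lon
  out <- vector("list", dim(flow$W)[3])
  for (t in seq_len(dim(flow$W)[3])) {
    idx <- which(!is.na(flow$W[, , t]))
    if (!length(idx)) next
    i <- ((idx - 1) %% nl) + 1
    j <- ((idx - 1) %/% nl) + 1
    out[[t]] <- tibble::tibble(
      t = t, i = i, j = j,
      night = nights$night_date[cbind(i, j, t)],
      takeoff = flow$takeoff[, , t][idx],
      landing = flow$landing[, , t][idx],
      area_km2 = gm$area_km2[i])
  }
  dplyr::bind_rows(out)
}

#' Nightly take-off and landing maps
#'
#' Sums the take-off and landing rates separately over each night, per
#' cell: the map pairs that let one track a migration wave, the landing
#' of one night lining up with the take-off of the next.
#'
#' @param flow A [flow_model()] result (one realization).
#' @param nights An [assign_nights()] index on the same grid.
#' @return A `nightly_pulses` tibble: `night`, `i`, `j`, `lat`, `lon`,
#'   `takeoff_km2`, `landing_km2` (birds/km^2 summed over the night) and
#'   `takeoff_birds`, `landing_birds` (scaled by cell area).
#' @export
nightly_pulses <- function(flow, nights) {
  grid <- flow$grid
  long <- ssf_long(flow, nights)
  if (!nrow(long))
    return(structure(tibble::tibble(
      night = as.Date(character()), i = integer(), j = integer(),
      lat = numeric(), lon = numeric(), takeoff_km2 = numeric(),
      landing_km2 = numeric(), takeoff_birds = numeric(),
      landing_birds = numeric()), class = c("nightly_pulses", class(tibble::tibble()))))
  out <- long |>
    dplyr::filter(!is.na(.data$night)) |>
    dplyr::group_by(.data$night, .data$i, .data$j) |>
    dplyr::summarise(
      takeoff_km2 = sum(.data$takeoff) * grid$d_t_hours,
      landing_km2 = sum(.data$landing) * grid$d_t_hours,
      area_km2 = .data$area_km2[1], .groups = "drop") |>
    dplyr::mutate(night = as.Date(.data$night, origin = "1970-01-01"),
                  lat = grid$lat[.data$i], lon = grid$lon[.data$j],
                  takeoff_birds = .data$takeoff_km2 * .data$area_km2,
                  landing_birds = .data$landing_km2 * .data$area_km2) |>
    dplyr::select("night", "i", "j", "lat", "lon", "takeoff_km2",
                  "landing_km2", "takeoff_birds", "landing_birds")
  structure(out, class = c("nightly_pulses", class(tibble::tibble())))
}

# Night label of boundary rows (evening civil date in local solar time).
boundary_nights <- function(boundary) {
  as.Date(night_of(boundary$time, boundary$lon), origin = "1970-01-01")
}

#' Year-round accumulation of birds on the ground
#'
#' Aggregates take-off, landing, entering and leaving over each night for
#' the whole study area. The nightly change in the number of birds on the
#' ground is landing minus take-off -- equivalently, when no birds are
#' aloft at dusk and dawn, entering minus leaving -- and its cumulative
#' sum, started arbitrarily at zero, is the number of birds that remained
#' on the ground. The conservation identity
#' `landing - takeoff = entering - leaving - aloft_change` is checked per
#' night; nights violating `tol` are flagged invalid.
#'
#' @param flow A [flow_model()] result.
#' @param nights An [assign_nights()] index.
#' @param tol Relative tolerance of the identity check.
#' @return An `accumulation_series` tibble, one row per night between the
#'   first and last observed night: `takeoff`, `landing`, `entering`,
#'   `leaving` (all birds, positive), `delta_ground`, `aloft_change`,
#'   `cumulative`, `has_data`, `identity_gap`, `identity_ok`.
#' @export
ground_accumulation <- function(flow, nights, tol = 1e-6) {
  grid <- flow$grid
  gm <- grid_metrics(grid)
  long <- ssf_long(flow, nights)
  if (!nrow(long)) stop("flow result contains no valid steps", call. = FALSE)
  ssf <- long |>
    dplyr::filter(!is.na(.data$night)) |>
    dplyr::group_by(night = .data$night) |>
    dplyr::summarise(
      takeoff = sum(.data$takeoff * .data$area_km2) * grid$d_t_hours,
      landing = sum(.data$landing * .data$area_km2) * grid$d_t_hours,
      .groups = "drop")
  # change of birds aloft per night over the same step cell-sets as W
  area <- matrix(gm$area_km2, grid$n_lat, grid$n_lon)
  aloft <- long |>
    dplyr::mutate(drho = flow$rho[cbind(.data$i, .data$j, .data$t + 1L)] -
                    flow$rho[cbind(.data$i, .data$j, .data$t)]) |>
    dplyr::group_by(night = .data$night) |>
    dplyr::summarise(aloft_change = sum(.data$drho * .data$area_km2),
                     .groups = "drop")
  bnd <- flow$boundary
  bn <- if (nrow(bnd)) {
    bnd$night <- as.integer(boundary_nights(bnd))
    bnd |>
      dplyr::group_by(night = .data$night) |>
      dplyr::summarise(entering = sum(pmax(.data$flux, 0)) * grid$d_t_hours,
                       leaving = -sum(pmin(.data$flux, 0)) * grid$d_t_hours,
                       .groups = "drop")
  } else tibble::tibble(night = integer(), entering = numeric(), leaving = numeric())
  all_nights <- seq(min(ssf$night), max(ssf$night))
  out <- tibble::tibble(night_int = all_nights) |>
    dplyr::left_join(ssf, by = c(night_int = "night")) |>
    dplyr::left_join(bn, by = c(night_int = "night")) |>
    dplyr::left_join(aloft, by = c(night_int = "night")) |>
    dplyr::mutate(
      has_data = !is.na(.data$takeoff),
      dplyr::across(c("takeoff", "landing", "entering", "leaving",
                      "aloft_change"), ~ dplyr::coalesce(.x, 0)),
      delta_ground = .data$landing - .data$takeoff,
      cumulative = cumsum(.data$delta_ground),
      identity_gap = abs(.data$delta_ground -
                           (.data$entering - .data$leaving - .data$aloft_change)),
      scale = pmax(.data$takeoff + .data$landing +
                     .data$entering + .data$leaving, 1e-12),
      identity_ok = .data$identity_gap <= tol * .data$scale | !.data$has_data,
      night = as.Date(.data$night_int, origin = "1970-01-01")) |>
    dplyr::select("night", "takeoff", "landing", "entering", "leaving",
                  "delta_ground", "aloft_change", "cumulative", "has_data",
                  "identity_gap", "identity_ok")
  if (!all(out$identity_ok))
    warning("conservation identity violated on ",
            sum(!out$identity_ok), " night(s); result flagged invalid",
            call. = FALSE)
  structure(out, class = c("accumulation_series", class(tibble::tibble())))
}

#' Default six-transect partition of a rectangular domain boundary
#'
#' Splits the boundary into six contiguous arcs named after the major
#' flyways around Western Europe: the whole northern edge (North), the
#' eastern edge (East), the southern edge split at mid-longitude into
#' Spain (west) and Alps (east), and the western edge split at
#' mid-latitude into UK (north) and Atlantic (south). Geometry is data: a
#' user can supply any tibble of the same shape.
#'
#' @param grid A [grid_spec()].
#' @return Transect definition tibble: `name`, `side`, `lat_lo`, `lat_hi`,
#'   `lon_lo`, `lon_hi` (half-open on the upper ends).
#' @export
default_transects <- function(grid) {
  mid_lat <- (grid$lat_min + grid$lat_max) / 2
  mid_lon <- (grid$lon_min + grid$lon_max) / 2
  big <- 1e6
  tibble::tibble(
    name = c("North", "East", "Spain", "Alps", "UK", "Atlantic"),
    side = c("N", "E", "S", "S", "W", "W"),
    lat_lo = c(-big, -big, -big, -big, mid_lat, -big),
    lat_hi = c(big, big, big, big, big, mid_lat),
    lon_lo = c(-big, -big, -big, mid_lon, -big, -big),
    lon_hi = c(big, big, mid_lon, big, big, big))
}

# Assign each external boundary interface to exactly one transect.
assign_transects <- function(boundary, transects) {
  n <- nrow(boundary)
  name <- rep(NA_character_, n)
  hits <- integer(n)
  for (k in seq_len(nrow(transects))) {
    m <- boundary$side == transects$side[k] &
      boundary$lat >= transects$lat_lo[k] & boundary$lat < transects$lat_hi[k] &
      boundary$lon >= transects$lon_lo[k] & boundary$lon < transects$lon_hi[k]
    hits <- hits + m
    name[m & is.na(name)] <- transects$name[k]
  }
  if (any(hits > 1))
    stop("transect definitions overlap: some interfaces match two transects",
         call. = FALSE)
  if (any(is.na(name)))
    stop("transect definitions do not cover the whole boundary", call. = FALSE)
  name
}

#' Default season windows
#'
#' Spring is February through June, autumn August through December, by
#' the civil date of the night.
#' @return Named list of month vectors.
#' @export
default_seasons <- function() list(spring = 2:6, autumn = 8:12)

#' Seasonal flows of birds through named boundary transects
#'
#' Totals the birds entering and leaving the study area through each
#' transect over each season, from the signed boundary fluxes. Only
#' `external` interfaces count (internal rain/day boundaries are not part
#' of the study-area rim). The six transects partition the boundary, so
#' their totals sum exactly to the whole-boundary totals.
#'
#' @param boundary Boundary-flux tibble from [flow_model()] or
#'   [extract_boundary_fluxes()].
#' @param grid A [grid_spec()].
#' @param transects Transect definition tibble ([default_transects()]).
#' @param seasons Named list of month vectors ([default_seasons()]);
#'   nights in no season are dropped.
#' @param d_t_hours Step length in hours (taken from `grid`).
#' @return A `transect_summary` tibble: `transect`, `season`, `entering`,
#'   `leaving` (birds, positive), `net` (entering - leaving).
#' @export
seasonal_transect_flows <- function(boundary, grid,
                                    transects = default_transects(grid),
                                    seasons = default_seasons(),
                                    d_t_hours = grid$d_t_hours) {
  b <- boundary[boundary$tag == "external", , drop = FALSE]
  if (!nrow(b))
    return(structure(tibble::tibble(transect = character(), season = character(),
                                    entering = numeric(), leaving = numeric(),
                                    net = numeric()),
                     class = c("transect_summary", class(tibble::tibble()))))
  b$transect <- assign_transects(b, transects)
  month <- as.integer(format(boundary_nights(b), "%m"))
  b$season <- NA_character_
  for (s in names(seasons)) b$season[month %in% seasons[[s]]] <- s
  out <- b |>
    dplyr::filter(!is.na(.data$season)) |>
    dplyr::group_by(.data$transect, .data$season) |>
    dplyr::summarise(entering = sum(pmax(.data$flux, 0)) * d_t_hours,
                     leaving = -sum(pmin(.data$flux, 0)) * d_t_hours,
                     .groups = "drop") |>
    dplyr::mutate(net = .data$entering - .data$leaving)
  full <- tidyr::expand_grid(transect = transects$name, season = names(seasons))
  out <- full |>
    dplyr::left_join(out, by = c("transect", "season")) |>
    dplyr::mutate(dplyr::across(c("entering", "leaving", "net"),
                                ~ dplyr::coalesce(.x, 0)))
  structure(out, class = c("transect_summary", class(tibble::tibble())))
}

# Dominant-direction crossing magnitude of one transect and season.
dominant_flow <- function(ts, transect, season) {
  r <- ts[ts$transect %in% transect & ts$season == season, , drop = FALSE]
  if (!nrow(r)) stop("no ", season, " totals for transect ",
                     paste(transect, collapse = "+"), call. = FALSE)
  max(sum(r$entering), sum(r$leaving))
}

#' Autumn-to-spring route ratio of a transect
#'
#' Ratio of the autumn crossing magnitude to the spring crossing
#' magnitude for one transect, where the crossing magnitude of a season
#' is the dominant direction's total (entering or leaving, whichever is
#' larger). Values above 1 mean proportionally more birds use the route
#' in autumn.
#'
#' @param ts A `transect_summary` tibble.
#' @param transect Transect name.
#' @return The ratio, a bare number.
#' @export
route_ratio <- function(ts, transect) {
  sp <- dominant_flow(ts, transect, "spring")
  if (sp == 0) stop("spring flow through ", transect,
                    " is zero; ratio undefined", call. = FALSE)
  dominant_flow(ts, transect, "autumn") / sp
}

#' Net recruitment index from seasonal flows
#'
#' The autumn/spring flux ratio proxies net population change
#' (reproduction minus mortality). `transect_ratio` divides the dominant
#' autumn flow through a transect group by the dominant spring flow
#' through the same group; `area_net_ratio` divides the whole-area autumn
#' deficit (leaving minus entering) by the spring surplus (entering minus
#' leaving), which is robust to routes shifting between seasons.
#'
#' @param ts A `transect_summary` tibble.
#' @param mode `"transect_ratio"` or `"area_net_ratio"`.
#' @param transects Transect names forming the group (for
#'   `transect_ratio`), e.g. the three southern transects.
#' @return The index, a bare number.
#' @export
recruitment_index <- function(ts, mode = c("transect_ratio", "area_net_ratio"),
                              transects = NULL) {
  mode <- match.arg(mode)
  if (mode == "transect_ratio") {
    if (is.null(transects)) stop("`transects` group required", call. = FALSE)
    sp <- dominant_flow(ts, transects, "spring")
    if (sp == 0) stop("spring flow is zero; index undefined", call. = FALSE)
    dominant_flow(ts, transects, "autumn") / sp
  } else {
    spring_surplus <- sum(ts$net[ts$season == "spring"])
    autumn_deficit <- -sum(ts$net[ts$season == "autumn"])
    if (spring_surplus == 0)
      stop("spring surplus is zero; index undefined", call. = FALSE)
    autumn_deficit / spring_surplus
  }
}

#' Ensemble mean and quantile envelope of per-realization results
#'
#' Summarises any per-realization tidy table into the reporting style of
#' the ensemble analyses: mean, Q5 and Q95 (empirical quantiles with
#' linear interpolation between order statistics) per group.
#'
#' @param df Tibble with a `realization` column.
#' @param values Names of the value columns to summarise.
#' @param by Grouping columns (e.g. `"night"`, or
#'   `c("transect", "season")`).
#' @param q Two probabilities for the envelope, default `c(0.05, 0.95)`.
#' @return Tibble with, per group and value, `<value>_mean`, `<value>_q5`,
#'   `<value>_q95`.
#' @export
ensemble_quantiles <- function(df, values, by = NULL, q = c(0.05, 0.95)) {
  stopifnot("realization" %in% names(df))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(values),
      list(mean = ~ mean(.x),
           q5 = ~ unname(stats::quantile(.x, q[1], type = 7)),
           q95 = ~ unname(stats::quantile(.x, q[2], type = 7))),
      .names = "{.col}_{.fn}"), .groups = "drop")
}
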