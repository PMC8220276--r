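#' Describe a weather-radar site
#'
#' @param id Short station code.
#' @param lat,lon Position in degrees.
#' @param ground_alt Ground elevation at the site, m a.s.l.
#' @param antenna_alt Antenna elevation, m a.s.l.; defaults to the ground.
#' @return A `radar_site` list.
#' @export
radar_site <- function(id, lat, lon, ground_alt = 0, antenna_alt = ground_alt) {
  stopifnot(lat >= -90, lat <= 90, lon >= -180, lon <= 180,
            ground_alt <= antenna_alt)
  structure(list(id = as.character(id), lat = lat, lon = lon,
                 ground_alt = ground_alt, antenna_alt = antenna_alt),
            class = "radar_site")
}

#' Read a vertical-profile time series (VPTS) file
#'
#' Reads the community CSV dialect for altitude-binned radar retrievals of
#' birds: one row per (timestamp, 200-m altitude bin) with volumetric bird
#' density, ground speed, track direction and the standard deviation of
#' radial velocity, optionally air speed. Rows that cannot be parsed are
#' reported with a warning, never silently dropped.
#'
#' @param path CSV file with columns `radar, datetime, height, dens, ff,
#'   dd, sd_vvp` and optionally `airspeed`.
#' @param site The [radar_site()] the file belongs to.
#' @return A `profile_series` tibble (columns `time`, `height`, `density`,
#'   `speed`, `direction`, `sd_vr`[, `airspeed`]) with the site attached as
#'   an attribute.
#' @export
parse_vpts <- function(path, site) {
  stopifnot(inherits(site, "radar_site"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("radar", "datetime", "height", "dens", "ff", "dd", "sd_vvp")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("VPTS file lacks mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  p <- tibble::tibble(
    time = as.POSIXct(raw$datetime, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%d %H:%M:%S",
                                     "%Y-%m-%dT%H:%M:%S")),
    height = num(raw$height),
    density = num(raw$dens),
    speed = num(raw$ff),
    direction = num(raw$dd) %% 360,
    sd_vr = num(raw$sd_vvp))
  if ("airspeed" %in% names(raw)) p$airspeed <- num(raw$airspeed)
  bad <- is.na(p$time) | is.na(p$height)
  if (any(bad))
    warning(sum(bad), " row(s) with unparseable time or height dropped",
            call. = FALSE)
  p <- p[!bad, , drop = FALSE]
  hh <- sort(unique(p$height))
  if (length(hh) > 1 && any(abs(diff(hh) - 200) > 1e-6))
    stop("inconsistent altitude bin widths (expected 200 m)", call. = FALSE)
  if (any(p$density < 0, na.rm = TRUE))
    stop("negative bird densities in VPTS file", call. = FALSE)
  p <- dplyr::arrange(p, .data$time, .data$height)
  new_profile_series(p, site)
}

new_profile_series <- function(p, site) {
  structure(p, site = site, class = c("profile_series", class(tibble::tibble())))
}

#' Write a profile series back to VPTS CSV
#'
#' Inverse of [parse_vpts()]; a written file re-parses to an identical
#' `profile_series`.
#' @param p A `profile_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vpts <- function(p, path) {
  site <- attr(p, "site")
  out <- tibble::tibble(
    radar = site$id,
    datetime = format(p$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    height = p$height, dens = p$density, ff = p$speed, dd = p$direction,
    sd_vvp = p$sd_vr)
  if ("airspeed" %in% names(p)) out$airspeed <- p$airspeed
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Remove slow, weak scatterers (insects, snow) from a profile series
#'
#' Cells whose standard deviation of radial velocity or whose air speed
#' falls below the thresholds are treated as non-bird contamination and
#' their density is set to missing; everything else is untouched.
#'
#' @param p A `profile_series`.
#' @param sd_vr_min Minimum standard deviation of radial velocity, m/s.
#' @param airspeed_min Minimum air speed, m/s. Requires an `airspeed`
#'   column (ground speed minus wind); set 0 to disable the criterion when
#'   no wind data are available.
#' @return The filtered `profile_series`; the number of removed cells is
#'   attached as attribute `n_removed` and reported via `message()`.
#' @export
filter_contamination <- function(p, sd_vr_min = 2, airspeed_min = 5) {
  stopifnot(inherits(p, "profile_series"), sd_vr_min >= 0, airspeed_min >= 0)
  if (airspeed_min > 0 && !("airspeed" %in% names(p)))
    stop("`airspeed_min` > 0 but the series has no airspeed column; ",
         "supply wind-corrected speeds or set airspeed_min = 0", call. = FALSE)
  air_hit <- if (airspeed_min > 0)
    !is.na(p$airspeed) & p$airspeed < airspeed_min else FALSE
  hit <- !is.na(p$density) &
    ((!is.na(p$sd_vr) & p$sd_vr < sd_vr_min) | air_hit)
  p$density[hit] <- NA_real_
  message(sum(hit), " contaminated profile cell(s) removed")
  attr(p, "n_removed") <- sum(hit)
  p
}

#' Vertically integrate a profile series to areal density and velocity
#'
#' Collapses the 200-m altitude bins into a single column value per time:
#' areal density (birds/km^2) is volumetric density times the height of
#' each bin that lies above the ground and below 5000 m a.s.l., and the
#' velocity is the density-weighted mean over contributing bins, converted
#' to km/h and resolved into eastward (`v_lon`) and northward (`v_lat`)
#' components from speed and direction (degrees clockwise from north).
#' The unobserved layer between the ground and the lowest bin with data is
#' filled according to `below_beam`.
#'
#' @param p A `profile_series`.
#' @param below_beam `"extend_lowest"` copies the lowest valid bin's
#'   density into the unobserved layer below it (adds low-altitude birds);
#'   `"zero"` assumes the layer is empty.
#' @return A point-series tibble: `site_id`, `lat`, `lon`, `time`,
#'   `areal_density`, `v_lon`, `v_lat`, `quality_flag` (`ok`/`missing`).
#'   Times are still at radar cadence; see [resample_to_step()].
#' @export
vertically_integrate <- function(p, below_beam = c("extend_lowest", "zero")) {
  below_beam <- match.arg(below_beam)
  site <- attr(p, "site")
  ground_km <- site$ground_alt / 1000
  per_time <- function(d) {
    lo <- pmax(d$height / 1000, ground_km)
    hi <- pmin(d$height / 1000 + 0.2, 5)
    thick <- pmax(0, hi - lo)                       # km of surveyed air per bin
    ok <- !is.na(d$density)
    if (!any(ok))
      return(tibble::tibble(areal_density = NA_real_, v_lon = NA_real_,
                            v_lat = NA_real_, quality_flag = "missing"))
    w <- ifelse(ok, d$density, 0) * thick
    # unobserved layer between ground and the lowest bin carrying data
    k0 <- which(ok & thick > 0)
    if (length(k0)) {
      k0 <- k0[1]
      gap <- max(0, d$height[k0] / 1000 - ground_km)
      if (below_beam == "extend_lowest" && gap > 0) w[k0] <- w[k0] + d$density[k0] * gap
    }
    vl <- d$speed * 3.6 * sin(d$direction * pi / 180)
    vb <- d$speed * 3.6 * cos(d$direction * pi / 180)
    wv <- ifelse(ok & !is.na(vl), w, 0)
    if (sum(wv) > 0) {
      v_lon <- sum(wv * vl, na.rm = TRUE) / sum(wv)
      v_lat <- sum(wv * vb, na.rm = TRUE) / sum(wv)
    } else {
      v_lon <- 0; v_lat <- 0                        # no birds aloft, no motion
    }
    tibble::tibble(areal_density = sum(w), v_lon = v_lon, v_lat = v_lat,
                   quality_flag = "ok")
  }
  out <- p |>
    dplyr::group_by(time = .data$time) |>
    dplyr::group_modify(~ per_time(.x)) |>
    dplyr::ungroup()
  tibble::tibble(site_id = site$id, lat = site$lat, lon = site$lon, out)
}

#' Average a point series onto the model time step
#'
#' Time-averages areal density and vector-averages the velocity components
#' within each step; steps covered by the series but containing no valid
#' profile are kept and flagged `missing`.
#'
#' @param ps A point-series tibble from [vertically_integrate()].
#' @param step_hours Model step in hours; must divide one day evenly.
#' @return A point-series tibble on the regular step, same columns.
#' @export
resample_to_step <- function(ps, step_hours = 0.25) {
  stopifnot(step_hours > 0, abs(24 / step_hours - round(24 / step_hours)) < 1e-9)
  sec <- step_hours * 3600
  ps$step <- as.POSIXct(floor(as.numeric(ps$time) / sec) * sec,
                        origin = "1970-01-01", tz = "UTC")
  agg <- ps |>
    dplyr::filter(.data$quality_flag != "missing") |>
    dplyr::group_by(.data$site_id, .data$lat, .data$lon, time = .data$step) |>
    dplyr::summarise(areal_density = mean(.data$areal_density),
                     v_lon = mean(.data$v_lon), v_lat = mean(.data$v_lat),
                     .groups = "drop") |>
    dplyr::mutate(quality_flag = "ok")
  full <- tidyr::expand_grid(
    dplyr::distinct(ps, .data$site_id, .data$lat, .data$lon),
    time = seq(min(ps$step), max(ps$step), by = sec))
  full |>
    dplyr::left_join(agg, by = c("site_id", "lat", "lon", "time")) |>
    dplyr::mutate(quality_flag = dplyr::coalesce(.data$quality_flag, "missing")) |>
    dplyr::arrange(.data$site_id, .data$time)
}
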