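#' Solar elevation angle
#'
#' Elevation of the sun above the horizon for vectors of positions and
#' times: geocentric ecliptic longitude from the mean anomaly with the
#' equation-of-centre series, apparent longitude corrected for nutation
#' and aberration, then right ascension/declination and the hour angle
#' from Greenwich mean sidereal time. Accuracy is about 0.01 degrees,
#' a few seconds of time at sunrise/sunset.
#'
#' @param lat,lon Degrees (longitude east-positive). Recycled against `time`.
#' @param time POSIXct, UTC.
#' @return Elevation in degrees (geometric, no refraction).
#' @export
solar_elevation <- function(lat, lon, time) {
  time <- as.POSIXct(time, tz = "UTC")
  jd <- as.numeric(time) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  d2r <- pi / 180
  L0 <- 280.46646 + 36000.76983 * T + 0.0003032 * T^2   # mean longitude
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) * d2r
  C <- (1.914602 - 0.004817 * T) * sin(M) +             # equation of centre
    (0.019993 - 0.000101 * T) * sin(2 * M) + 0.000289 * sin(3 * M)
  Om <- (125.04 - 1934.136 * T) * d2r                   # lunar node
  lam <- (L0 + C - 0.00569 - 0.00478 * sin(Om)) * d2r   # apparent longitude
  eps <- (23.4392911 - 46.815 * T / 3600 + 0.00256 * cos(Om)) * d2r
  alpha <- atan2(cos(eps) * sin(lam), cos(lam))
  delta <- asin(sin(eps) * sin(lam))
  gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545)) %% 360
  ha <- (gmst + lon) * d2r - alpha
  lat_r <- lat * d2r
  sin_el <- sin(lat_r) * sin(delta) + cos(lat_r) * cos(delta) * cos(ha)
  asin(pmin(1, pmax(-1, sin_el))) / d2r
}

#' Sunset and sunrise bracketing one night
#'
#' Finds, by root-finding on [solar_elevation()], the evening crossing below
#' `threshold` on `date` and the following morning crossing above it. The
#' night is labelled by the civil date of its evening in local solar time.
#'
#' @param lat,lon Position in degrees.
#' @param date A `Date`: the evening's civil date (local solar time).
#' @param threshold Solar elevation in degrees separating day from night;
#'   0 is geometric sunset, -6 civil twilight.
#' @return Tibble with `date`, `sunset`, `sunrise` (POSIXct UTC).
#' @export
sun_rise_set <- function(lat, lon, date, threshold = 0) {
  date <- as.Date(date)
  out <- purrr::map(seq_along(date), function(k) {
    # local solar noon of the labelling date, then search +/- half a day
    noon <- as.POSIXct(paste(date[k], "12:00:00"), tz = "UTC") - lon * 240
    f <- function(s) solar_elevation(lat, lon, noon + s) - threshold
    if (f(0) <= 0 || f(86400) <= 0)
      stop("sun never rises above the threshold on ", date[k],
           " (polar night?)", call. = FALSE)
    if (f(43200) >= 0)
      stop("sun never sets below the threshold on ", date[k],
           " (polar day?)", call. = FALSE)
    ss <- stats::uniroot(f, c(0, 43200), tol = 1)$root
    sr <- stats::uniroot(f, c(43200, 86400), tol = 1)$root
    tibble::tibble(date = date[k], sunset = noon + ss, sunrise = noon + sr)
  })
  dplyr::bind_rows(out)
}

#' Assign each grid step to a night or to day
#'
#' Every (cell, time) pair with solar elevation below `day_threshold` is
#' nocturnal and is labelled with the civil date of its evening in local
#' solar time (so a 02:00 step on 2 April belongs to the night of 1 April);
#' steps at or above the threshold are day and excluded from the flow model.
#'
#' @param grid A [grid_spec()].
#' @param day_threshold Solar elevation in degrees; default 0 (geometric
#'   sunrise/sunset), set -6 for civil twilight.
#' @return A `night_index`: logical array `is_night` and integer array
#'   `night_date` (days since epoch, `NA` by day), both `n_lat x n_lon x n_t`,
#'   plus the vector of night labels.
#' @export
assign_nights <- function(grid, day_threshold = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(abs(grid$lat) > 66))
    stop("polar latitudes are not supported by the night labelling", call. = FALSE)
  nl <- grid$n_lat; nc <- grid$n_lon; nt <- grid$n_t
  lat_m <- matrix(rep(grid$lat, nc), nl, nc)
  lon_m <- matrix(rep(grid$lon, each = nl), nl, nc)
  is_night <- array(FALSE, c(nl, nc, nt))
  night_date <- array(NA_integer_, c(nl, nc, nt))
  for (t in seq_len(nt)) {
    el <- solar_elevation(as.vector(lat_m), as.vector(lon_m), grid$times[t])
    night <- el < day_threshold
    # evening civil date in local solar time: date of (local time - 12 h)
    local <- grid$times[t] + as.vector(lon_m) * 240
    lab <- as.integer(floor((as.numeric(local) - 43200) / 86400))
    is_night[, , t] <- night
    nd <- ifelse(night, lab, NA_integer_)
    night_date[, , t] <- nd
  }
  structure(list(grid = grid, is_night = is_night, night_date = night_date,
                 day_threshold = day_threshold,
                 nights = sort(unique(stats::na.omit(as.vector(night_date))))),
            class = "night_index")
}

#' @export
print.night_index <- function(x, ...) {
  cat(sprintf("<night_index> %d nights over %d steps (threshold %g deg)\n",
              length(x$nights), x$grid$n_t, x$day_threshold))
  invisible(x)
}

# Date labels of a night_index as Date vector
night_labels <- function(nights) as.Date(nights$nights, origin = "1970-01-01")
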