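# Shared fixtures, built in code. Heavy truth bundles are memoised per
# session so several test files can share one forward simulation.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Small all-valid grid with explicit masks (bypasses solar masking so the
# flow stencil can be exercised on arbitrary fields).
tiny_grid <- function(nl = 4, nc = 5, nt_steps = 4, d = 0.25, d_t = 0.25,
                      lat0 = 45, lon0 = 2) {
  grid_spec(lat0, lat0 + nl * d, lon0, lon0 + nc * d, d_lat = d, d_lon = d,
            t_start = utc("2018-04-06 20:00:00"),
            t_end = utc("2018-04-06 20:00:00") + nt_steps * d_t * 3600,
            d_t_hours = d_t)
}

all_valid_masks <- function(grid, static = NULL) {
  if (is.null(static)) static <- matrix(TRUE, grid$n_lat, grid$n_lon)
  structure(list(grid = grid, static = static,
                 dynamic = array(static, c(grid$n_lat, grid$n_lon, grid$n_t))),
            class = "mask_stack")
}

const_velocity <- function(grid, v_lon, v_lat) {
  list(v_lon = array(v_lon, c(grid$n_lat, grid$n_lon, grid$n_t)),
       v_lat = array(v_lat, c(grid$n_lat, grid$n_lon, grid$n_t)))
}

# Fake single-night index covering every step of a grid (for aggregation
# unit tests that do not need real solar geometry).
fake_nights <- function(grid, night = as.Date("2018-04-06")) {
  structure(list(
    grid = grid,
    is_night = array(TRUE, c(grid$n_lat, grid$n_lon, grid$n_t)),
    night_date = array(as.integer(night), c(grid$n_lat, grid$n_lon, grid$n_t)),
    day_threshold = 0, nights = as.integer(night)),
    class = "night_index")
}

# A 25-bin profile series tibble shaped like parse_vpts() output.
make_profile <- function(site, times, density_fun = function(h) rep(10, length(h)),
                         speed = 10, direction = 45, sd_vr = 4, airspeed = NULL) {
  h <- seq(0, 4800, by = 200)
  rows <- tidyr::expand_grid(time = times, height = h)
  rows$density <- density_fun(rows$height)
  rows$speed <- speed
  rows$direction <- direction
  rows$sd_vr <- sd_vr
  if (!is.null(airspeed)) rows$airspeed <- airspeed
  structure(rows, site = site,
            class = c("profile_series", class(tibble::tibble())))
}

# Memoised truth bundles: one default and one dense scenario per session.
.fixture_env <- new.env(parent = emptyenv())

default_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    .fixture_env$sc <- wave_scenario(seed = 7L)
    .fixture_env$truth <- forward_simulate(.fixture_env$sc)
  }
  .fixture_env$truth
}

default_scenario <- function() { default_truth(); .fixture_env$sc }

dense_truth <- function() {
  if (is.null(.fixture_env$dense_truth)) {
    .fixture_env$dense_sc <- dense_wave_scenario(seed = 11L)
    .fixture_env$dense_truth <- forward_simulate(.fixture_env$dense_sc)
  }
  .fixture_env$dense_truth
}

dense_scenario <- function() { dense_truth(); .fixture_env$dense_sc }
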