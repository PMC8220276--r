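#' Separable spatio-temporal covariance model for bird density
#'
#' The transformed density field is modelled as second-order stationary
#' with covariance `sill * f(h / range_space) * f(u / range_time)` plus a
#' nugget at zero lag, where `f` is the chosen correlation family, `h` a
#' great-circle distance in km and `u` a time lag in hours. The nugget
#' absorbs measurement error and micro-scale variability, letting the
#' interpolation diverge from noisy observations.
#'
#' @param sill Partial sill (variance of the correlated component) in
#'   units of the transformed density.
#' @param nugget Nugget variance, same units.
#' @param range_space Spatial scale parameter, km.
#' @param range_time Temporal scale parameter, hours.
#' @param family Correlation family: exponential `exp(-d)`, gaussian
#'   `exp(-d^2)` or spherical.
#' @param transform Density transform under which the model lives:
#'   `"log"` for `log(1 + rho)` (default; densities are skewed and
#'   non-negative) or `"none"` (used for velocity components).
#' @param trend `"none"` or `"nightly_mean"` (remove each night's mean
#'   before kriging and restore it after).
#' @return A `covariance_model` object.
#' @export
covariance_model <- function(sill, nugget = 0, range_space, range_time,
                             family = c("exponential", "gaussian", "spherical"),
                             transform = c("log", "none"),
                             trend = c("none", "nightly_mean")) {
  family <- match.arg(family)
  stopifnot(sill >= 0, nugget >= 0, range_space > 0, range_time > 0)
  structure(list(sill = sill, nugget = nugget,
                 range_space = range_space, range_time = range_time,
                 family = family, transform = match.arg(transform),
                 trend = match.arg(trend)),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf(
    "<covariance_model> %s, transform=%s\n  sill %.4g  nugget %.4g  range_space %.4g km  range_time %.4g h\n",
    x$family, x$transform, x$sill, x$nugget, x$range_space, x$range_time))
  invisible(x)
}

cor_family <- function(d, family) {
  switch(family,
         exponential = exp(-d),
         gaussian = exp(-d^2),
         spherical = ifelse(d < 1, 1 - 1.5 * d + 0.5 * d^3, 0))
}

# Covariance between points at space lag h [km] and time lag u [h],
# excluding the nugget (which only acts at exactly coincident points).
cov_st <- function(h_km, u_hours, cm) {
  cm$sill * cor_family(h_km / cm$range_space, cm$family) *
    cor_family(abs(u_hours) / cm$range_time, cm$family)
}

# Semivariogram implied by the model (nugget active off the origin).
vario_st <- function(h_km, u_hours, cm) {
  at0 <- h_km == 0 & u_hours == 0
  cm$nugget * (!at0) + cm$sill - cov_st(h_km, u_hours, cm)
}

transform_density <- function(x, cm) if (cm$transform == "log") log1p(x) else x
back_transform_density <- function(z, cm) {
  if (cm$transform != "log") return(z)
  out <- expm1(z)
  out[!is.na(out) & out < 0] <- 0   # in place, preserving dim
  out
}

# Point series list/tibble -> one tibble with site metadata
bind_obs <- function(obs) {
  if (is.data.frame(obs)) obs else dplyr::bind_rows(obs)
}

# Wide matrices of observations on a common time sequence:
# list(times, sites (tibble id/lat/lon), z = [n_time, n_site] matrix, ...)
obs_matrix <- function(obs, value = "areal_density", step_hours = NULL) {
  obs <- bind_obs(obs)
  obs <- obs[!is.na(obs[[value]]), , drop = FALSE]
  if (!nrow(obs)) stop("no valid observations", call. = FALSE)
  sites <- dplyr::distinct(obs, .data$site_id, .data$lat, .data$lon)
  times <- sort(unique(obs$time))
  if (is.null(step_hours)) {
    dh <- as.numeric(diff(times), units = "secs") / 3600
    step_hours <- if (length(dh)) min(dh) else 0.25
  }
  ti <- round(as.numeric(difftime(obs$time, times[1], units = "hours")) / step_hours) + 1
  si <- match(obs$site_id, sites$site_id)
  nt <- max(ti)
  z <- matrix(NA_real_, nt, nrow(sites))
  z[cbind(ti, si)] <- obs[[value]]
  full_times <- times[1] + 3600 * step_hours * (seq_len(nt) - 1)
  list(times = full_times, step_hours = step_hours, sites = sites, z = z)
}

site_dist_km <- function(sites) {
  n <- nrow(sites)
  m <- matrix(0, n, n)
  for (a in seq_len(n)) {
    m[a, ] <- geosphere::distHaversine(
      cbind(sites$lon, sites$lat), c(sites$lon[a], sites$lat[a])) / 1000
  }
  (m + t(m)) / 2
}

#' Empirical spatio-temporal variogram of transformed densities
#'
#' Half mean squared differences of the transformed observations, pooled
#' over site pairs into great-circle distance classes and over time into
#' integer step lags.
#'
#' @param obs A point-series tibble (or list of them) as produced by
#'   [resample_to_step()] or [sample_radars()].
#' @param transform `"log"` or `"none"`.
#' @param n_space_bins Number of distance classes (zero distance is always
#'   its own class).
#' @param max_tlag_steps Largest time lag, in model steps.
#' @param value Column to use (default `areal_density`).
#' @return Tibble with `h_km` (class midpoint), `u_hours`, `gamma`, `n`.
#' @export
empirical_variogram <- function(obs, transform = "log", n_space_bins = 8,
                                max_tlag_steps = 8, value = "areal_density") {
  cm0 <- list(transform = transform)
  om <- obs_matrix(obs, value = value)
  z <- if (transform == "log") log1p(om$z) else om$z
  ns <- nrow(om$sites); nt <- nrow(z)
  dmat <- site_dist_km(om$sites)
  rows <- list()
  for (u in 0:min(max_tlag_steps, nt - 1)) {
    for (a in seq_len(ns)) {
      bs <- if (u == 0) seq_len(ns)[-seq_len(a)] else seq_len(ns)
      for (b in bs) {
        d2 <- (z[seq_len(nt - u), a] - z[seq_len(nt - u) + u, b])^2
        n <- sum(!is.na(d2))
        if (n > 0)
          rows[[length(rows) + 1L]] <- c(dmat[a, b], u, sum(d2, na.rm = TRUE) / 2, n)
      }
    }
  }
  if (!length(rows)) stop("no observation pairs for the variogram", call. = FALSE)
  m <- do.call(rbind, rows)
  df <- tibble::tibble(h = m[, 1], u_steps = m[, 2], ss = m[, 3], n = m[, 4])
  hmax <- max(df$h)
  brk <- if (hmax > 0) seq(0, hmax, length.out = n_space_bins + 1) else c(0, 1)
  # distance class 0 = coincident sites; classes 1..K by upper edge
  df$bin <- ifelse(df$h == 0, 0L, pmax(1L, findInterval(df$h, brk, rightmost.closed = TRUE)))
  df |>
    dplyr::group_by(.data$bin, .data$u_steps) |>
    dplyr::summarise(h_km = stats::weighted.mean(.data$h, .data$n),
                     gamma = sum(.data$ss) / sum(.data$n),
                     n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(u_hours = .data$u_steps * om$step_hours) |>
    dplyr::filter(!(.data$h_km == 0 & .data$u_hours == 0)) |>
    dplyr::select("h_km", "u_hours", "gamma", "n")
}

#' Fit the covariance model to observations by weighted least squares
#'
#' Computes the empirical spatio-temporal variogram of the transformed
#' observations and fits sill, nugget and the two range parameters by
#' weighted least squares with Cressie weights `n / gamma_model^2`.
#'
#' @param obs Point-series tibble or list of them (needs at least two
#'   radars with overlapping valid times).
#' @param model0 A [covariance_model()] holding the starting values and
#'   the transform/family/trend choices to keep.
#' @param n_space_bins,max_tlag_steps Passed to [empirical_variogram()].
#' @param value Observation column to fit on.
#' @return A fitted `covariance_model`; `tidy()` gives the parameters,
#'   `glance()` the fit summary, and the empirical variogram is attached
#'   as attribute `variogram`.
#' @export
fit_covariance <- function(obs, model0 = NULL, n_space_bins = 8,
                           max_tlag_steps = 8, value = "areal_density") {
  obs <- bind_obs(obs)
  if (all(is.na(obs[[value]]))) stop("all observations missing", call. = FALSE)
  if (dplyr::n_distinct(obs$site_id) < 2)
    stop("need at least two radars to fit a spatial model", call. = FALSE)
  if (is.null(model0))
    model0 <- covariance_model(sill = 1, nugget = 0.1, range_space = 100,
                               range_time = 2)
  ev <- empirical_variogram(obs, transform = model0$transform,
                            n_space_bins = n_space_bins,
                            max_tlag_steps = max_tlag_steps, value = value)
  zvar <- stats::var(transform_density(obs[[value]], model0), na.rm = TRUE)
  if (!is.finite(zvar) || zvar == 0) zvar <- 1e-8
  lower <- c(sill = 1e-9, nugget = 0, range_space = 1, range_time = 0.05)
  upper <- c(sill = 10 * zvar + 1e-6, nugget = 10 * zvar + 1e-6,
             range_space = 5 * max(ev$h_km, 10), range_time = 5 * max(ev$u_hours, 1))
  start <- pmin(pmax(c(model0$sill, model0$nugget,
                       model0$range_space, model0$range_time), lower), upper)
  # weights fixed at n / gamma_hat^2 (model-dependent weights inside the
  # objective would reward inflating the model variogram)
  w <- ev$n / (ev$gamma + 1e-8 * max(ev$gamma, 1e-8))^2
  obj <- function(p) {
    cm <- covariance_model(p[1], p[2], p[3], p[4], family = model0$family,
                           transform = model0$transform, trend = model0$trend)
    gm <- vario_st(ev$h_km, ev$u_hours, cm)
    sum(w * (ev$gamma - gm)^2)
  }
  fit <- stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500))
  out <- covariance_model(fit$par[1], fit$par[2], fit$par[3], fit$par[4],
                          family = model0$family, transform = model0$transform,
                          trend = model0$trend)
  attr(out, "variogram") <- ev
  attr(out, "fit") <- list(objective = fit$value, convergence = fit$convergence,
                           n_bins = nrow(ev), n_pairs = sum(ev$n))
  out
}
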