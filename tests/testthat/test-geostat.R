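test_that("static and dynamic masks encode the exclusion rules", {
  g <- tiny_grid(nl = 4, nc = 5, nt_steps = 3)
  dem <- flat_dem(g)
  dem$elevation_m[2, 2] <- 2500                 # above the ceiling
  dem$water[3, 4] <- TRUE                       # a lake
  radars <- list(radar_site("A", g$lat[1], g$lon[1]))
  nights <- fake_nights(g)
  ms <- build_masks(g, dem, radars, nights)
  expect_false(ms$static[2, 2])
  expect_false(ms$static[3, 4])
  expect_true(ms$static[1, 1])
  # a far-away radar leaves everything out of range
  far <- list(radar_site("far", 50, 10))        # > 150 km from this grid
  ms2 <- build_masks(g, flat_dem(g), far, nights)
  expect_false(any(ms2$static))
  # planted rain excludes exactly those (cell, step) pairs
  rain <- array(0, c(4, 5, g$n_t))
  hit <- rbind(c(1, 2, 2), c(4, 5, 2), c(2, 3, 3))
  rain[hit] <- 2
  near <- list(radar_site("A", g$lat[2], g$lon[3]))
  ms3 <- build_masks(g, flat_dem(g), near, nights, rain = rain)
  expect_equal(sum(ms3$dynamic[, , 2] != ms3$static), 2)
  expect_false(ms3$dynamic[1, 2, 2])
  expect_false(ms3$dynamic[2, 3, 3])
  # dynamic implies static
  expect_true(all(!ms3$dynamic | array(ms3$static, dim(ms3$dynamic))))
  # an excluded night is blanked out entirely
  ms4 <- build_masks(g, flat_dem(g), near, nights,
                     excluded_nights = as.Date("2018-04-06"))
  expect_false(any(ms4$dynamic))
})

test_that("missing rain over valid cells is a configuration error", {
  g <- tiny_grid()
  nights <- fake_nights(g)
  rain <- array(NA_real_, c(g$n_lat, g$n_lon, g$n_t))
  expect_error(build_masks(g, flat_dem(g), list(radar_site("A", g$lat[1], g$lon[1])),
                           nights, rain = rain), "rain")
})

# --- variogram fitting ------------------------------------------------------

sim_separable_obs <- function(sites, nt, cm, step_hours = 0.25, seed = 1) {
  # test-owned simulator: direct Kronecker Cholesky of the separable model
  dmat <- matrix(0, nrow(sites), nrow(sites))
  for (a in seq_len(nrow(sites)))
    dmat[a, ] <- geosphere::distHaversine(cbind(sites$lon, sites$lat),
                                          c(sites$lon[a], sites$lat[a])) / 1000
  Cs <- cm$sill * exp(-dmat / cm$range_space)
  ut <- abs(outer(seq_len(nt), seq_len(nt), "-")) * step_hours
  Ct <- exp(-ut / cm$range_time)
  set.seed(seed)
  Z <- t(chol(Cs + diag(1e-10, nrow(Cs)))) %*%
    matrix(rnorm(nrow(sites) * nt), nrow(sites)) %*%
    chol(Ct + diag(1e-10, nt))
  Z <- Z + matrix(rnorm(length(Z), 0, sqrt(cm$nugget)), nrow(Z))
  t0 <- utc("2018-04-06 00:00:00")
  tidyr::expand_grid(s = seq_len(nrow(sites)), t = seq_len(nt)) |>
    dplyr::mutate(site_id = sites$id[s], lat = sites$lat[s], lon = sites$lon[s],
                  time = t0 + (t - 1) * step_hours * 3600,
                  areal_density = Z[cbind(s, t)], quality_flag = "ok") |>
    dplyr::select(-s, -t)
}

test_that("covariance parameters are recovered from synthetic fields", {
  sites <- tidyr::expand_grid(a = 1:6, b = 1:6) |>
    dplyr::mutate(id = paste0("S", a, b), lat = 44 + a * 0.5, lon = 1 + b * 0.5)
  truth <- covariance_model(sill = 1, nugget = 0.1, range_space = 80,
                            range_time = 2, transform = "none")
  obs <- sim_separable_obs(sites, nt = 240, truth, seed = 5)
  fit <- fit_covariance(obs, covariance_model(0.5, 0.05, 150, 4,
                                              transform = "none"),
                        max_tlag_steps = 12)
  expect_equal(fit$range_space, 80, tolerance = 0.25)
  expect_equal(fit$sill, 1, tolerance = 0.35)
  expect_equal(fit$nugget, 0.1, tolerance = 0.5)
})

test_that("white noise fits as pure nugget", {
  set.seed(9)
  sites <- tibble::tibble(id = paste0("W", 1:15),
                          lat = runif(15, 44, 46), lon = runif(15, 1, 4))
  t0 <- utc("2018-04-06 00:00:00")
  obs <- tidyr::expand_grid(k = 1:15, t = 1:150) |>
    dplyr::mutate(site_id = sites$id[k], lat = sites$lat[k], lon = sites$lon[k],
                  time = t0 + (t - 1) * 900,
                  areal_density = rnorm(dplyr::n(), 0, 2),
                  quality_flag = "ok")
  fit <- fit_covariance(obs, covariance_model(1, 1, 100, 2, transform = "none"))
  expect_equal(fit$nugget, 4, tolerance = 0.25)
  expect_lt(fit$sill, 0.3 * 4)
})

test_that("a constant field fits with (almost) no variance", {
  t0 <- utc("2018-04-06 00:00:00")
  obs <- tidyr::expand_grid(k = 1:4, t = 1:50) |>
    dplyr::mutate(site_id = paste0("C", k), lat = 44 + k / 2, lon = 2,
                  time = t0 + (t - 1) * 900, areal_density = 7,
                  quality_flag = "ok")
  fit <- fit_covariance(obs, covariance_model(1, 0.5, 100, 2,
                                              transform = "none"))
  expect_lt(fit$sill + fit$nugget, 1e-4)
})

# --- kriging ----------------------------------------------------------------

test_that("kriging with zero nugget interpolates observations exactly", {
  g <- tiny_grid(nl = 4, nc = 5, nt_steps = 4)
  masks <- all_valid_masks(g)
  # radars sitting exactly on cell centres, observations on grid times
  sites <- list(radar_site("K1", g$lat[2], g$lon[2]),
                radar_site("K2", g$lat[3], g$lon[4]))
  t0 <- g$times[1]
  obs <- tidyr::expand_grid(k = 1:2, t = seq_len(g$n_t)) |>
    dplyr::mutate(site_id = c("K1", "K2")[k],
                  lat = c(g$lat[2], g$lat[3])[k],
                  lon = c(g$lon[2], g$lon[4])[k],
                  time = g$times[t],
                  areal_density = 10 + 5 * k + t, quality_flag = "ok")
  cm <- covariance_model(sill = 1, nugget = 0, range_space = 100, range_time = 2)
  df <- krige_density(obs, cm, g, masks, max_tlag_steps = 3)
  for (t in seq_len(g$n_t)) {
    expect_equal(df$z[2, 2, t], log1p(obs$areal_density[obs$k == 1][t]),
                 tolerance = 1e-9)
    expect_equal(df$z[3, 4, t], log1p(obs$areal_density[obs$k == 2][t]),
                 tolerance = 1e-9)
  }
  expect_true(all(df$estimate >= 0, na.rm = TRUE))
})

test_that("a pure-nugget model predicts the neighbourhood mean", {
  g <- tiny_grid(nl = 3, nc = 3, nt_steps = 2)
  masks <- all_valid_masks(g)
  obs <- tibble::tibble(site_id = c("a", "b", "c"),
                        lat = g$lat[c(1, 2, 3)], lon = g$lon[c(1, 2, 3)],
                        time = g$times[1],
                        areal_density = c(2, 4, 9), quality_flag = "ok")
  cm <- covariance_model(sill = 1e-9, nugget = 1, range_space = 50,
                         range_time = 1, transform = "none")
  df <- krige_density(obs, cm, g, masks, max_tlag_steps = 0)
  expect_equal(df$estimate[1, 1, 1], mean(c(2, 4, 9)), tolerance = 1e-6)
  expect_equal(df$estimate[3, 3, 1], mean(c(2, 4, 9)), tolerance = 1e-6)
})

test_that("gridded kriging matches a direct dense solve of the OK system", {
  g <- tiny_grid(nl = 4, nc = 4, nt_steps = 3)
  masks <- all_valid_masks(g)
  set.seed(11)
  sites <- tibble::tibble(id = paste0("B", 1:5),
                          lat = runif(5, g$lat_min, g$lat_max),
                          lon = runif(5, g$lon_min, g$lon_max))
  obs <- tidyr::expand_grid(k = 1:5, t = 1:3) |>
    dplyr::mutate(site_id = sites$id[k], lat = sites$lat[k], lon = sites$lon[k],
                  time = g$times[t], areal_density = exp(rnorm(dplyr::n())),
                  quality_flag = "ok")
  cm <- covariance_model(sill = 0.8, nugget = 0.2, range_space = 60,
                         range_time = 1.5)
  df <- krige_density(obs, cm, g, masks, max_tlag_steps = 10)
  # independent dense solve, built from scratch in the test
  z <- log1p(obs$areal_density)
  n <- nrow(obs)
  pts <- cbind(obs$lon, obs$lat)
  K <- matrix(0, n, n)
  for (a in seq_len(n)) {
    h <- geosphere::distHaversine(pts, pts[a, ]) / 1000
    u <- abs(as.numeric(difftime(obs$time, obs$time[a], units = "hours")))
    K[a, ] <- 0.8 * exp(-h / 60) * exp(-u / 1.5)
  }
  K <- K + 0.2 * diag(n)
  Kaug <- rbind(cbind(K, 1), c(rep(1, n), 0))
  for (cell in list(c(1, 1, 1), c(2, 3, 2), c(4, 4, 3))) {
    h0 <- geosphere::distHaversine(pts, c(g$lon[cell[2]], g$lat[cell[1]])) / 1000
    u0 <- abs(as.numeric(difftime(obs$time, g$times[cell[3]], units = "hours")))
    rhs <- c(0.8 * exp(-h0 / 60) * exp(-u0 / 1.5), 1)
    lam <- solve(Kaug, rhs)
    expect_equal(df$z[cell[1], cell[2], cell[3]], sum(lam[1:n] * z),
                 tolerance = 1e-8)
  }
})

test_that("velocity interpolation is component-wise scalar kriging", {
  g <- tiny_grid(nl = 3, nc = 4, nt_steps = 3)
  masks <- all_valid_masks(g)
  set.seed(12)
  obs <- tidyr::expand_grid(k = 1:4, t = 1:3) |>
    dplyr::mutate(site_id = paste0("V", k),
                  lat = 45.1 + k * 0.15, lon = 2.1 + k * 0.2,
                  time = g$times[t],
                  v_lon = rnorm(dplyr::n(), 20, 5),
                  v_lat = rnorm(dplyr::n(), -5, 5),
                  areal_density = 1, quality_flag = "ok")
  cmv <- covariance_model(sill = 25, nugget = 1, range_space = 80,
                          range_time = 2, transform = "none")
  vf <- interpolate_velocity(obs, cmv, g, masks)
  # same answer as running the scalar path on each component
  o1 <- dplyr::mutate(obs, areal_density = v_lon)
  o2 <- dplyr::mutate(obs, areal_density = v_lat)
  e1 <- krige_density(o1, cmv, g, masks)$estimate
  e2 <- krige_density(o2, cmv, g, masks)$estimate
  expect_equal(vf$v_lon, e1, tolerance = 1e-12)
  expect_equal(vf$v_lat, e2, tolerance = 1e-12)
  # constant observations give a constant field
  oc <- dplyr::mutate(obs, v_lon = 36, v_lat = 0)
  vfc <- interpolate_velocity(oc, cmv, g, masks)
  expect_equal(max(abs(vfc$v_lon - 36), na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(max(abs(vfc$v_lat), na.rm = TRUE), 0, tolerance = 1e-8)
})

# --- conditional simulation -------------------------------------------------

test_that("simulation conditions on the data and reproduces under a seed", {
  g <- tiny_grid(nl = 4, nc = 4, nt_steps = 3)
  masks <- all_valid_masks(g)
  obs <- tibble::tibble(site_id = c("a", "b"),
                        lat = g$lat[c(1, 3)], lon = g$lon[c(2, 4)],
                        time = g$times[2],
                        areal_density = c(5, 12), quality_flag = "ok")
  cm <- covariance_model(sill = 0.5, nugget = 0, range_space = 60,
                         range_time = 2)
  ens <- simulate_ensemble(obs, cm, g, masks, n_real = 3, seed = 42)
  for (r in 1:3) {
    expect_equal(ens$fields[1, 2, 2, r], 5, tolerance = 1e-6)
    expect_equal(ens$fields[3, 4, 2, r], 12, tolerance = 1e-6)
  }
  ens2 <- simulate_ensemble(obs, cm, g, masks, n_real = 3, seed = 42)
  expect_identical(ens$fields, ens2$fields)
  ens3 <- simulate_ensemble(obs, cm, g, masks, n_real = 3, seed = 43)
  expect_false(identical(ens$fields, ens3$fields))
  expect_true(all(ens$fields >= 0, na.rm = TRUE))
})

test_that("the ensemble mean tracks the kriging estimate and keeps its texture", {
  g <- tiny_grid(nl = 5, nc = 5, nt_steps = 2)
  masks <- all_valid_masks(g)
  set.seed(31)
  obs <- tibble::tibble(site_id = paste0("m", 1:6),
                        lat = runif(6, g$lat_min, g$lat_max),
                        lon = runif(6, g$lon_min, g$lon_max),
                        time = g$times[1],
                        areal_density = rnorm(6, 10, 3), quality_flag = "ok")
  cm <- covariance_model(sill = 4, nugget = 0.5, range_space = 40,
                         range_time = 2, transform = "none")
  ens <- simulate_ensemble(obs, cm, g, masks, n_real = 200, seed = 9)
  est <- krige_density(obs, cm, g, masks)
  # transformed space is the identity here; Monte-Carlo error bars at 3 SE
  pts <- rbind(c(1, 1, 1), c(3, 3, 1), c(5, 2, 2), c(2, 5, 2), c(4, 4, 1))
  for (k in seq_len(nrow(pts))) {
    v <- ens$fields[pts[k, 1], pts[k, 2], pts[k, 3], ]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - est$estimate[pts[k, 1], pts[k, 2], pts[k, 3]]),
              3 * se + 1e-9)
  }
  # smoothing inequality: the kriging map is smoother than any realization
  var_est <- var(as.vector(est$estimate[, , 1]))
  var_real <- mean(apply(ens$fields[, , 1, ], 3, function(m) var(as.vector(m))))
  expect_lt(var_est, var_real)
})
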