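# Spatio-temporal ordinary kriging and conditional Gaussian simulation on
# the model lattice. Observations live at radar sites on grid time steps;
# targets are the dynamically valid (cell, step) pairs. Per time step the
# neighbourhood is every observation within `max_tlag_steps` steps, so one
# factorization serves all cells of that step.

# Night label of a timestamp at longitude `lon`: civil date of the evening
# in local solar time (used by the optional nightly-mean trend).
night_of <- function(time, lon) {
  as.integer(floor((as.numeric(time) + lon * 240 - 43200) / 86400))
}

# Prepare observations for kriging: one row per (site, step) with grid
# time index `ti` and the (transformed) observed values in matrix `z`.
prep_obs <- function(obs, grid, cov, values) {
  obs <- bind_obs(obs)
  if ("quality_flag" %in% names(obs))
    obs <- obs[obs$quality_flag != "missing", , drop = FALSE]
  keep <- rep(TRUE, nrow(obs))
  for (v in values) keep <- keep & is.finite(obs[[v]])
  obs <- obs[keep, , drop = FALSE]
  ti <- time_index(grid, obs$time)
  obs <- obs[!is.na(ti), , drop = FALSE]
  ti <- ti[!is.na(ti)]
  if (!nrow(obs)) stop("no usable observations on the grid", call. = FALSE)
  z <- sapply(values, function(v) transform_density(obs[[v]], cov))
  z <- matrix(z, nrow = nrow(obs))
  sites <- dplyr::distinct(obs, .data$site_id, .data$lat, .data$lon)
  list(site = match(obs$site_id, sites$site_id), ti = ti, z = z,
       sites = sites, night = night_of(obs$time, obs$lon))
}

# Distances [km] from every grid cell (column-major cell id) to each site.
cell_site_dist <- function(grid, sites) {
  cells <- cbind(lon = rep(grid$lon, each = grid$n_lat),
                 lat = rep(grid$lat, grid$n_lon))
  m <- matrix(0, nrow(cells), nrow(sites))
  for (s in seq_len(nrow(sites)))
    m[, s] <- geosphere::distHaversine(cells, c(sites$lon[s], sites$lat[s])) / 1000
  m
}

# Shared engine. Returns transformed-space estimates (one array per value
# column), the ordinary-kriging variance, and optionally the per-step
# systems for reuse by the conditional simulation.
krige_engine <- function(po, cov, grid, masks, max_tlag_steps = 4,
                         keep_systems = FALSE) {
  nl <- grid$n_lat; nc <- grid$n_lon; nt <- grid$n_t
  p <- ncol(po$z)
  dsite <- site_dist_km(po$sites)
  dcell <- cell_site_dist(grid, po$sites)
  est <- replicate(p, array(NA_real_, c(nl, nc, nt)), simplify = FALSE)
  kvar <- array(NA_real_, c(nl, nc, nt))
  systems <- if (keep_systems) vector("list", nt) else NULL
  # nightly-mean trend: scalar mean of transformed obs per night
  trend_tab <- NULL
  zc <- po$z
  if (cov$trend == "nightly_mean") {
    trend_tab <- rowsum(po$z, po$night) / as.vector(table(po$night))
    zc <- po$z - trend_tab[match(po$night, as.integer(rownames(trend_tab))), ,
                           drop = FALSE]
  }
  cell_lon <- rep(grid$lon, each = nl)
  for (t in seq_len(nt)) {
    tgt <- which(masks$dynamic[, , t])
    if (!length(tgt)) next
    nb <- which(abs(po$ti - t) <= max_tlag_steps)
    if (!length(nb)) next
    n <- length(nb)
    u <- abs(outer(po$ti[nb], po$ti[nb], "-")) * grid$d_t_hours
    K <- cov_st(dsite[po$site[nb], po$site[nb]], u, cov)
    coincident <- outer(po$site[nb], po$site[nb], "==") &
      outer(po$ti[nb], po$ti[nb], "==")
    K <- K + cov$nugget * coincident
    u0 <- abs(po$ti[nb] - t) * grid$d_t_hours
    rhs <- cov_st(t(dcell[tgt, po$site[nb], drop = FALSE]),
                  matrix(u0, n, length(tgt)), cov)
    Kaug <- rbind(cbind(K, 1), c(rep(1, n), 0))
    lam <- tryCatch(solve(Kaug, rbind(rhs, 1)),
                    error = function(e) NULL)
    if (is.null(lam))
      lam <- tryCatch(solve(Kaug + diag(1e-8, n + 1), rbind(rhs, 1)),
                      error = function(e) NULL)
    if (is.null(lam)) {
      warning("singular kriging system at step ", t,
              "; falling back to the neighbourhood mean", call. = FALSE)
      lam <- rbind(matrix(1 / n, n, length(tgt)), 0)
    }
    zhat <- crossprod(lam[seq_len(n), , drop = FALSE], zc[nb, , drop = FALSE])
    if (!is.null(trend_tab)) {
      tn <- night_of(grid$times[t], cell_lon[tgt])
      idx <- match(tn, as.integer(rownames(trend_tab)))
      tr <- trend_tab[idx, , drop = FALSE]
      tr[is.na(idx), ] <- colMeans(po$z)[col(tr)][is.na(idx)]
      zhat <- zhat + tr
    }
    for (k in seq_len(p)) {
      sl <- est[[k]][, , t]
      sl[tgt] <- zhat[, k]
      est[[k]][, , t] <- sl
    }
    sv <- kvar[, , t]
    sv[tgt] <- pmax(0, cov$sill - colSums(lam[seq_len(n), , drop = FALSE] * rhs) -
                      lam[n + 1, ])
    kvar[, , t] <- sv
    if (keep_systems) systems[[t]] <- list(tgt = tgt, nb = nb, lam = lam)
  }
  list(est = est, kvar = kvar, systems = systems, trend_tab = trend_tab)
}

#' Krige bird density onto the grid
#'
#' Ordinary kriging of the transformed areal densities on every
#' dynamically valid (cell, step), using all observations within
#' `max_tlag_steps` steps as the neighbourhood. Estimates are
#' back-transformed and non-negative; masked cells stay missing. With a
#' zero nugget the map interpolates the observations exactly.
#'
#' @param obs Point-series tibble or list of tibbles.
#' @param cov A [covariance_model()] (typically from [fit_covariance()]).
#' @param grid A [grid_spec()].
#' @param masks A [build_masks()] stack.
#' @param max_tlag_steps Temporal half-width of the kriging neighbourhood,
#'   in steps.
#' @return A `density_field`: back-transformed `estimate` array
#'   (`n_lat x n_lon x n_t`, birds/km^2), transformed-space `z` and
#'   kriging variance `variance`.
#' @export
krige_density <- function(obs, cov, grid, masks, max_tlag_steps = 4) {
  po <- prep_obs(obs, grid, cov, "areal_density")
  ke <- krige_engine(po, cov, grid, masks, max_tlag_steps)
  structure(list(grid = grid, estimate = back_transform_density(ke$est[[1]], cov),
                 z = ke$est[[1]], variance = ke$kvar, cov = cov),
            class = "density_field")
}

#' Interpolate the bird velocity field component-wise
#'
#' Each of the eastward and northward velocity components is kriged
#' independently with the supplied covariance model (no transform, no
#' clipping), exactly as the scalar density is.
#'
#' @param obs Point series with `v_lon`, `v_lat` columns (km/h).
#' @param cov_v A [covariance_model()] with `transform = "none"`.
#' @inheritParams krige_density
#' @return A `velocity_field` with arrays `v_lon` and `v_lat`.
#' @export
interpolate_velocity <- function(obs, cov_v, grid, masks, max_tlag_steps = 4) {
  stopifnot(cov_v$transform == "none")
  po <- prep_obs(obs, grid, cov_v, c("v_lon", "v_lat"))
  ke <- krige_engine(po, cov_v, grid, masks, max_tlag_steps)
  structure(list(grid = grid, v_lon = ke$est[[1]], v_lat = ke$est[[2]]),
            class = "velocity_field")
}

#' Conditional Gaussian simulation of the density field
#'
#' Draws an ensemble of equally probable density fields that honour the
#' observations (up to the nugget) and the covariance model, by
#' conditioning unconditional Gaussian realizations with the same kriging
#' operator used for the estimate: `z_cond = z_hat + (z_unc - z_hat_unc)`.
#' Aggregates (sums, totals) computed per realization are unbiased where
#' the smooth kriging map is not, which is the point of simulating.
#'
#' @inheritParams krige_density
#' @param n_real Number of realizations (the study default is 500; desk
#'   examples use tens).
#' @param seed Integer seed; identical inputs and seed give an identical
#'   ensemble. The caller's RNG state is left untouched.
#' @return A `density_ensemble` with `fields`
#'   (`n_lat x n_lon x n_t x n_real`, birds/km^2, `NA` off-mask) and the
#'   kriging `estimate` used for conditioning.
#' @export
simulate_ensemble <- function(obs, cov, grid, masks, n_real = 500, seed = 1,
                              max_tlag_steps = 4) {
  stopifnot(n_real >= 1)
  po <- prep_obs(obs, grid, cov, "areal_density")
  ke <- krige_engine(po, cov, grid, masks, max_tlag_steps, keep_systems = TRUE)
  nl <- grid$n_lat; nc <- grid$n_lon; nt <- grid$n_t
  n_cell <- nl * nc; n_site <- nrow(po$sites)
  # joint spatial locations: grid cells plus radar sites, with sites that
  # coincide with a cell centre aliased onto that cell (keeps the joint
  # covariance non-singular and the conditioning exact at data points)
  dcell <- cell_site_dist(grid, po$sites)
  cells <- cbind(lon = rep(grid$lon, each = nl), lat = rep(grid$lat, nc))
  Dcc <- matrix(0, n_cell, n_cell)
  for (a in seq_len(n_cell))
    Dcc[, a] <- geosphere::distHaversine(cells, cells[a, ]) / 1000
  Dss <- site_dist_km(po$sites)
  nearest <- apply(dcell, 2, which.min)
  ndist <- dcell[cbind(nearest, seq_len(n_site))]
  extra <- which(ndist >= 1e-3)
  site_row <- ifelse(ndist < 1e-3, nearest,
                     n_cell + match(seq_len(n_site), extra))
  D <- rbind(cbind(Dcc, dcell[, extra, drop = FALSE]),
             cbind(t(dcell[, extra, drop = FALSE]),
                   Dss[extra, extra, drop = FALSE]))
  Cs <- cov$sill * cor_family(D / cov$range_space, cov$family)
  # time instants that carry any valid target or observation
  t_use <- sort(unique(c(which(apply(masks$dynamic, 3, any)), po$ti)))
  ut <- abs(outer(t_use, t_use, "-")) * grid$d_t_hours
  Ct <- cor_family(ut / cov$range_time, cov$family)
  Ls <- t(chol(Cs + diag(1e-8 * max(cov$sill, 1), nrow(Cs))))
  Lt <- t(chol(Ct + diag(1e-10, nrow(Ct))))
  fields <- array(NA_real_, c(nl, nc, nt, n_real))
  with_preserved_seed(seed, {
    for (r in seq_len(n_real)) {
      E <- matrix(stats::rnorm(nrow(Cs) * length(t_use)), nrow(Cs))
      Z <- Ls %*% E %*% t(Lt)                    # locations x t_use
      obs_col <- match(po$ti, t_use)
      z_unc_obs <- Z[cbind(site_row[po$site], obs_col)] +
        stats::rnorm(length(po$ti), 0, sqrt(cov$nugget))
      for (tk in seq_along(t_use)) {
        t <- t_use[tk]
        sys <- ke$systems[[t]]
        if (is.null(sys)) next
        n <- length(sys$nb)
        # kriging of the unconditional draw at the data points, with the
        # same weights as the estimate: z_cond = z_hat + (z_unc - z_hat_unc)
        zhat_unc <- crossprod(sys$lam[seq_len(n), , drop = FALSE],
                              z_unc_obs[sys$nb])
        sl <- matrix(NA_real_, nl, nc)
        sl[sys$tgt] <- ke$est[[1]][, , t][sys$tgt] + Z[sys$tgt, tk] - zhat_unc
        fields[, , t, r] <- back_transform_density(sl, cov)
      }
    }
  })
  structure(list(grid = grid, n_real = n_real, fields = fields,
                 estimate = back_transform_density(ke$est[[1]], cov),
                 z_estimate = ke$est[[1]], cov = cov, seed = seed),
            class = "density_ensemble")
}
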