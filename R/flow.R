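# Continuity-equation flow model on the staggered lattice.
#
# Bird density rho [birds/km^2] and velocity v [km/h] live at cell
# centres; fluxes Phi = rho v [birds/km/h] are interpolated to the cell
# interfaces (arithmetic mean of the two adjacent centred values,
# one-sided at boundaries). The source/sink inversion realizes the
# centred-space divergence in flux form -- interface flux times interface
# length, the latitude-interface length taken at the edge latitude -- so
# that interior contributions telescope and the discrete mass balance
# closes to machine precision on any masked geometry.

as_slices <- function(x) if (length(dim(x)) == 2) array(x, c(dim(x), 1)) else x

# Slice a 3-d array at time t without dropping singleton dimensions.
slice2 <- function(a, t) matrix(a[, , t], dim(a)[1], dim(a)[2])

#' Interpolate cell-centred fluxes to the cell interfaces
#'
#' Computes `Phi = rho * v` at cell centres and averages adjacent cells
#' onto the staggered interfaces; a domain- or mask-edge interface takes
#' the one-sided centred value of its single valid neighbour. Positive
#' `phi_lon` is eastward, positive `phi_lat` northward.
#'
#' @param rho Density array (`n_lat x n_lon[ x n_t]`, birds/km^2) or a
#'   `density_field` estimate.
#' @param v A `velocity_field` (or list with `v_lon`, `v_lat` arrays of
#'   matching shape, km/h).
#' @param grid A [grid_spec()].
#' @param valid Optional logical array of the same shape marking valid
#'   cells; invalid cells carry no flux.
#' @return A `flux_field`: `phi_lon` (`n_lat x (n_lon+1) x n_t`) and
#'   `phi_lat` (`(n_lat+1) x n_lon x n_t`) in birds/km/h, `NA` where both
#'   adjacent cells are invalid.
#' @export
compute_interface_fluxes <- function(rho, v, grid, valid = NULL) {
  if (inherits(rho, "density_field")) rho <- rho$estimate
  rho <- as_slices(rho)
  vlon <- as_slices(v$v_lon); vlat <- as_slices(v$v_lat)
  stopifnot(all(dim(rho) == dim(vlon)), all(dim(rho) == dim(vlat)))
  nl <- dim(rho)[1]; nc <- dim(rho)[2]; nt <- dim(rho)[3]
  stopifnot(nl == grid$n_lat, nc == grid$n_lon)
  if (is.null(valid)) valid <- !is.na(rho) else valid <- as_slices(valid) & !is.na(rho)
  phi_lon <- array(NA_real_, c(nl, nc + 1, nt))
  phi_lat <- array(NA_real_, c(nl + 1, nc, nt))
  pair_mean <- function(L, R) {
    out <- ifelse(!is.na(L) & !is.na(R), (L + R) / 2, NA_real_)
    out[is.na(L) & !is.na(R)] <- R[is.na(L) & !is.na(R)]
    out[!is.na(L) & is.na(R)] <- L[!is.na(L) & is.na(R)]
    out
  }
  for (t in seq_len(nt)) {
    vt <- slice2(valid, t)
    Pc_lon <- ifelse(vt, slice2(rho, t) * slice2(vlon, t), NA_real_)
    Pc_lat <- ifelse(vt, slice2(rho, t) * slice2(vlat, t), NA_real_)
    padNA_col <- matrix(NA_real_, nl, 1)
    L <- cbind(padNA_col, Pc_lon); R <- cbind(Pc_lon, padNA_col)
    phi_lon[, , t] <- pair_mean(L, R)
    padNA_row <- matrix(NA_real_, 1, nc)
    B <- rbind(padNA_row, Pc_lat); U <- rbind(Pc_lat, padNA_row)
    phi_lat[, , t] <- pair_mean(B, U)
  }
  structure(list(grid = grid, phi_lon = phi_lon, phi_lat = phi_lat),
            class = "flux_field")
}

# Flux-form divergence [birds/h/km^2] of one flux slice over `valid` cells.
divergence_slice <- function(phi_lon_t, phi_lat_t, grid, valid) {
  gm <- grid_metrics(grid)
  nl <- grid$n_lat; nc <- grid$n_lon
  pl <- phi_lon_t; pl[is.na(pl)] <- 0
  pb <- phi_lat_t; pb[is.na(pb)] <- 0
  flow_lon <- (pl[, 2:(nc + 1), drop = FALSE] - pl[, 1:nc, drop = FALSE]) *
    gm$len_lon_if_km
  flow_lat <- pb[2:(nl + 1), , drop = FALSE] * gm$len_lat_if_km[2:(nl + 1)] -
    pb[1:nl, , drop = FALSE] * gm$len_lat_if_km[1:nl]
  div <- (flow_lon + flow_lat) / gm$area_km2
  div[!valid] <- NA_real_
  div
}

#' Invert the discretized continuity equation for the source/sink term
#'
#' `W = d rho / dt + div(Phi)`: the rate of birds appearing in (take-off,
#' `W > 0`) or disappearing from (landing, `W < 0`) the air column of each
#' cell over one forward-time step, in birds/h/km^2. The divergence uses
#' the centred-space interface fluxes of [compute_interface_fluxes()]; the
#' inversion is algebraic, so no stability constraint applies.
#'
#' @param rho_t,rho_t1 Density matrices at steps `t` and `t+1`.
#' @param flux A `flux_field` slice list (`phi_lon`, `phi_lat` matrices)
#'   computed from `rho_t`.
#' @param grid A [grid_spec()].
#' @param valid Logical matrix of cells valid at both steps; `W` is `NA`
#'   elsewhere.
#' @return Matrix of `W` values, birds/h/km^2, attributed to step `t`.
#' @export
infer_source_sink <- function(rho_t, rho_t1, flux, grid, valid = NULL) {
  stopifnot(grid$d_t_hours > 0)
  if (is.null(valid)) valid <- !is.na(rho_t) & !is.na(rho_t1)
  pl <- flux$phi_lon
  if (length(dim(pl)) == 3) pl <- slice2(pl, 1)
  pl <- matrix(pl, grid$n_lat, grid$n_lon + 1)
  pb <- flux$phi_lat
  if (length(dim(pb)) == 3) pb <- slice2(pb, 1)
  pb <- matrix(pb, grid$n_lat + 1, grid$n_lon)
  div <- divergence_slice(pl, pb, grid, valid)
  W <- (rho_t1 - rho_t) / grid$d_t_hours + div
  W[!valid] <- NA_real_
  W
}

#' Split the source/sink term into take-off and landing
#'
#' Positive `W` is birds taking off, negative `W` is birds landing; both
#' are reported positive, in birds/h/km^2, and reassemble `W` exactly as
#' `takeoff - landing`. Multiplying by cell area and the step length
#' converts to birds per cell per step.
#'
#' @param W Source/sink array or matrix.
#' @return List with `takeoff` and `landing` of the same shape.
#' @export
split_source_sink <- function(W) {
  list(takeoff = pmax(W, 0), landing = -pmin(W, 0))
}

# Enumerate boundary interfaces of the valid set of one step.
# Returns a tibble keyed by (i, j, side) with geometry and tags.
boundary_interfaces <- function(valid_t, static_valid, grid) {
  gm <- grid_metrics(grid)
  nl <- grid$n_lat; nc <- grid$n_lon
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, nl, nc)
    si <- seq_len(nl) + di; sj <- seq_len(nc) + dj
    ok_i <- si >= 1 & si <= nl; ok_j <- sj >= 1 & sj <= nc
    out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    out
  }
  rows <- list()
  sides <- list(
    list(side = "S", di = -1L, dj = 0L), list(side = "N", di = 1L, dj = 0L),
    list(side = "W", di = 0L, dj = -1L), list(side = "E", di = 0L, dj = 1L))
  for (s in sides) {
    nb_valid <- pad(valid_t, s$di, s$dj)
    hit <- which(valid_t & !nb_valid, arr.ind = TRUE)
    if (!nrow(hit)) next
    i <- hit[, 1]; j <- hit[, 2]
    ni <- i + s$di; nj <- j + s$dj
    inside <- ni >= 1 & ni <= nl & nj >= 1 & nj <= nc
    nb_static <- rep(FALSE, length(i))
    nb_static[inside] <- static_valid[cbind(ni[inside], nj[inside])]
    len <- switch(s$side,
                  S = gm$len_lat_if_km[i], N = gm$len_lat_if_km[i + 1],
                  W = rep(gm$len_lon_if_km, length(i)),
                  E = rep(gm$len_lon_if_km, length(i)))
    lat <- switch(s$side,
                  S = grid$lat[i] - grid$d_lat / 2, N = grid$lat[i] + grid$d_lat / 2,
                  W = grid$lat[i], E = grid$lat[i])
    lon <- switch(s$side,
                  S = grid$lon[j], N = grid$lon[j],
                  W = grid$lon[j] - grid$d_lon / 2, E = grid$lon[j] + grid$d_lon / 2)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      i = i, j = j, side = s$side, lat = lat, lon = lon, length_km = len,
      tag = ifelse(nb_static, "internal_boundary", "external"))
  }
  dplyr::bind_rows(rows)
}

# Cells participating in step t -> t+1: dynamically valid and carrying a
# finite density at both instants. W, the boundary fluxes and the balance
# check all refer to this one set, which is what makes the identity close.
step_valid_set <- function(rho, masks, t) {
  slice2(masks$dynamic, t) & slice2(masks$dynamic, t + 1) &
    !is.na(slice2(rho, t)) & !is.na(slice2(rho, t + 1))
}

empty_boundary <- function() {
  tibble::tibble(t = integer(), time = as.POSIXct(character(), tz = "UTC"),
                 i = integer(), j = integer(), side = character(),
                 lat = numeric(), lon = numeric(), length_km = numeric(),
                 flux = numeric(), tag = character())
}

boundary_slice <- function(flux_lon, flux_lat, vt, static_valid, grid, t) {
  bi <- boundary_interfaces(vt, static_valid, grid)
  if (!nrow(bi)) return(NULL)
  phi <- numeric(nrow(bi))
  for (k in seq_len(nrow(bi))) {
    phi[k] <- switch(bi$side[k],
                     S = flux_lat[bi$i[k], bi$j[k]],
                     N = -flux_lat[bi$i[k] + 1, bi$j[k]],
                     W = flux_lon[bi$i[k], bi$j[k]],
                     E = -flux_lon[bi$i[k], bi$j[k] + 1])
  }
  bi$flux <- phi * bi$length_km
  bi$t <- t
  bi$time <- grid$times[t]
  bi
}

#' Extract signed fluxes through the boundary of the valid domain
#'
#' Every edge of a valid cell not shared with another valid cell is a
#' boundary interface; the flux through it is the interface flux component
#' normal to the edge times the interface length, in birds/h, signed
#' inward-positive (birds entering the study area are positive, birds
#' leaving are negative). Interfaces whose far side is a statically valid
#' but dynamically masked cell (rain, daytime) are tagged
#' `internal_boundary`; the rest are `external`. The valid set of step `t`
#' is the one the source/sink inversion uses (cells valid at both `t` and
#' `t+1`), so that the reported fluxes are exactly those entering the mass
#' balance.
#'
#' @inheritParams compute_interface_fluxes
#' @param masks A [build_masks()] stack (or a list with `static` matrix
#'   and `dynamic` array).
#' @return Tibble with one row per (step, interface): `t`, `time`, `i`,
#'   `j`, `side`, `lat`, `lon`, `length_km`, `flux` (birds/h,
#'   inward-positive) and `tag`.
#' @export
extract_boundary_fluxes <- function(rho, v, grid, masks) {
  if (inherits(rho, "density_field")) rho <- rho$estimate
  rho <- as_slices(rho)
  nt <- dim(rho)[3]
  out <- vector("list", nt - 1)
  for (t in seq_len(nt - 1)) {
    vt <- step_valid_set(rho, masks, t)
    if (!any(vt)) next
    fl <- compute_interface_fluxes(
      slice2(rho, t), list(v_lon = slice2(v$v_lon, t), v_lat = slice2(v$v_lat, t)),
      grid, vt)
    out[[t]] <- boundary_slice(slice2(fl$phi_lon, 1), slice2(fl$phi_lat, 1), vt,
                               masks$static, grid, t)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(empty_boundary())
  dplyr::select(res, "t", "time", "i", "j", "side", "lat", "lon",
                "length_km", "flux", "tag")
}

#' Discrete mass-balance residual per step
#'
#' Any change of the number of birds aloft must be explained by the
#' source/sink term and the boundary fluxes:
#' `sum(drho * area) = sum(W * area) * dt + sum(boundary flux) * dt`.
#' The absolute residual of this identity, per step, is the health metric
#' of a flow-model run; with consistent fields it sits at rounding error.
#'
#' @param rho Density array (`n_lat x n_lon x n_t`).
#' @param W Source/sink array (`n_lat x n_lon x (n_t - 1)`).
#' @param boundary Boundary-flux tibble from [extract_boundary_fluxes()].
#' @param grid A [grid_spec()].
#' @param masks A [build_masks()] stack.
#' @return Tibble per step: `t`, `residual` (birds), `aloft` (birds at
#'   `t`), `rel_residual` (residual over birds aloft, 0 when none).
#' @export
mass_balance_residual <- function(rho, W, boundary, grid, masks) {
  if (inherits(rho, "density_field")) rho <- rho$estimate
  rho <- as_slices(rho); W <- as_slices(W)
  gm <- grid_metrics(grid)
  area <- matrix(gm$area_km2, grid$n_lat, grid$n_lon)
  nt <- dim(rho)[3]
  bnd <- boundary |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(flux = sum(.data$flux), .groups = "drop")
  out <- tibble::tibble(t = seq_len(nt - 1), residual = NA_real_,
                        aloft = NA_real_, rel_residual = NA_real_)
  for (t in seq_len(nt - 1)) {
    valid <- step_valid_set(rho, masks, t) & !is.na(slice2(W, t))
    if (!any(valid)) next
    dmass <- sum((slice2(rho, t + 1) - slice2(rho, t))[valid] * area[valid])
    src <- sum(slice2(W, t)[valid] * area[valid]) * grid$d_t_hours
    bf <- bnd$flux[match(t, bnd$t)]
    bf <- if (is.na(bf)) 0 else bf * grid$d_t_hours
    out$residual[t] <- abs(dmass - src - bf)
    out$aloft[t] <- sum(rho[, , t][valid] * area[valid])
    out$rel_residual[t] <- if (out$aloft[t] > 0) out$residual[t] / out$aloft[t] else 0
  }
  out
}

#' Run the flow model on one density realization
#'
#' Convenience wrapper: interface fluxes, source/sink inversion and
#' boundary-flux extraction for a full density/velocity time series, with
#' the mass-balance residual as a health check. `W` over `[t, t+1)` is
#' computed on cells valid at both steps and attributed to step `t`.
#'
#' @param rho Density array (`n_lat x n_lon x n_t`) or `density_field`,
#'   birds/km^2.
#' @param v A `velocity_field`.
#' @param grid A [grid_spec()].
#' @param masks A [build_masks()] stack.
#' @return A `flow_result`: arrays `W`, `takeoff`, `landing`
#'   (`n_lat x n_lon x (n_t-1)`, birds/h/km^2), the `boundary` flux tibble
#'   and the `residual` tibble.
#' @export
flow_model <- function(rho, v, grid, masks) {
  if (inherits(rho, "density_field")) rho <- rho$estimate
  rho <- as_slices(rho)
  nl <- grid$n_lat; nc <- grid$n_lon; nt <- dim(rho)[3]
  W <- array(NA_real_, c(nl, nc, nt - 1))
  bnd <- vector("list", nt - 1)
  for (t in seq_len(nt - 1)) {
    vt <- step_valid_set(rho, masks, t)
    if (!any(vt)) next
    fl <- compute_interface_fluxes(
      slice2(rho, t), list(v_lon = slice2(v$v_lon, t), v_lat = slice2(v$v_lat, t)),
      grid, vt)
    fl_slice <- list(phi_lon = slice2(fl$phi_lon, 1), phi_lat = slice2(fl$phi_lat, 1))
    W[, , t] <- infer_source_sink(slice2(rho, t), slice2(rho, t + 1), fl_slice, grid, vt)
    bnd[[t]] <- boundary_slice(fl_slice$phi_lon, fl_slice$phi_lat, vt,
                               masks$static, grid, t)
  }
  parts <- split_source_sink(W)
  boundary <- dplyr::bind_rows(bnd)
  boundary <- if (nrow(boundary))
    dplyr::select(boundary, "t", "time", "i", "j", "side", "lat", "lon",
                  "length_km", "flux", "tag")
  else empty_boundary()
  structure(list(grid = grid, W = W, takeoff = parts$takeoff,
                 landing = parts$landing, boundary = boundary,
                 residual = mass_balance_residual(rho, W, boundary, grid, masks),
                 rho = rho, v = v, masks = masks),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf(
    "<flow_result> %d steps; max |mass-balance residual| %.3g birds (rel %.3g)\n",
    dim(x$W)[3], max(x$residual$residual, na.rm = TRUE),
    max(x$residual$rel_residual, na.rm = TRUE)))
  invisible(x)
}
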