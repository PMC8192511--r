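# HMM state space: the discretised ocean and the daily movement kernel.

#' Build the HMM state grid
#'
#' Two discretisations of the ocean are supported. `latlon` places one state
#' per (possibly coarsened) lat/lon cell, so the physical cell width shrinks
#' polewards. `distance` keeps rows at the same latitude spacing but widens
#' the longitudinal spacing by `1/cos(lat)` so cell centers are
#' approximately equidistant in km. Land cells are excluded in both.
#'
#' @param env an [env_grid()].
#' @param resolution grid resolution in degrees latitude; must be an
#'   integer multiple of the environment resolution.
#' @param flavour `"latlon"` or `"distance"`.
#' @return object of class `state_grid`: per-state center coordinates, cell
#'   areas (km^2), bathymetry, and the environment cell index of each state.
#' @export
build_grid <- function(env, resolution = 1, flavour = c("latlon", "distance")) {
  flavour <- match.arg(flavour)
  env_res <- abs(stats::median(diff(env$lat)))
  k <- resolution / env_res
  if (abs(k - round(k)) > 1e-8)
    psat_stop("resolution must be an integer multiple of the environment resolution",
              "psat_grid_error")
  lat_lo <- min(env$lat) - env_res / 2
  lat_hi <- max(env$lat) + env_res / 2
  lon_lo <- min(env$lon) - env_res / 2
  lon_hi <- max(env$lon) + env_res / 2
  lat_c <- seq(lat_lo + resolution / 2, lat_hi - resolution / 2 + 1e-9,
               by = resolution)

  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  if (flavour == "latlon") {
    lon_c <- seq(lon_lo + resolution / 2, lon_hi - resolution / 2 + 1e-9,
                 by = resolution)
    lat_all <- rep(lat_c, times = length(lon_c))
    lon_all <- rep(lon_c, each = length(lat_c))
    area <- (km_per_deg * resolution)^2 * cos(deg2rad(lat_all))
  } else {
    pts <- lapply(lat_c, function(phi) {
      sp <- resolution / max(cos(deg2rad(phi)), 1e-6)
      lon_row <- seq(lon_lo + sp / 2, lon_hi, by = sp)
      lon_row <- lon_row[lon_row <= lon_hi - sp / 2 + 1e-9]
      if (!length(lon_row)) lon_row <- (lon_lo + lon_hi) / 2
      cbind(phi, lon_row)
    })
    pts <- do.call(rbind, pts)
    lat_all <- pts[, 1]; lon_all <- pts[, 2]
    area <- rep((km_per_deg * resolution)^2, length(lat_all))
  }

  ij <- env_cell_index(env, lat_all, lon_all)
  ocean <- !env$land_mask[ij]
  if (!any(ocean))
    psat_stop("domain is entirely land; no ocean states", "psat_grid_error")
  structure(list(lat = lat_all[ocean], lon = lon_all[ocean],
                 area_km2 = area[ocean],
                 bathy = env$bathymetry[ij][ocean],
                 env_i = ij[ocean, 1], env_j = ij[ocean, 2],
                 n = sum(ocean), resolution = resolution, flavour = flavour),
            class = "state_grid")
}

#' @export
print.state_grid <- function(x, ...) {
  cat(sprintf("<state_grid> %d ocean states, %s flavour, %g deg resolution\n",
              x$n, x$flavour, x$resolution))
  invisible(x)
}

# SST value of every state for a calendar month
grid_sst <- function(grid, env, month) {
  env$sst[cbind(rep(as.integer(month), grid$n), grid$env_i, grid$env_j)]
}

#' Daily movement kernel
#'
#' One-day transition weights of an isotropic diffusion with coefficient `D`
#' (km^2/day): `w(s -> d) = exp(-dist^2 / (4 D))` in great-circle km,
#' truncated to exactly zero beyond `truncation_sds * sqrt(2 D)` km, and
#' renormalised over ocean destinations so each source row sums to 1 (land
#' and truncated mass is reflected back, never absorbed).
#'
#' @param grid a [build_grid()] result.
#' @param D diffusion coefficient, km^2/day; `D = 0` gives the identity.
#' @param truncation_sds truncation radius in per-axis standard deviations
#'   (`sqrt(2 D)` km) of the one-day displacement; default 4.
#' @return object of class `movement_kernel` holding a sparse row-stochastic
#'   matrix.
#' @export
movement_kernel <- function(grid, D, truncation_sds = 4) {
  if (D < 0) stop_input("diffusion coefficient D must be >= 0")
  K <- grid$n
  if (D == 0) {
    W <- Matrix::Diagonal(K)
    return(structure(list(W = methods::as(W, "CsparseMatrix"), D = 0,
                          radius_km = 0, n = K),
                     class = "movement_kernel"))
  }
  radius <- truncation_sds * sqrt(2 * D)
  phi <- deg2rad(grid$lat); lam <- deg2rad(grid$lon)
  X <- cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  # chord -> arc distance via the dot product, blockwise to bound memory
  block <- max(1L, floor(2e7 / K))
  trips <- vector("list", ceiling(K / block))
  b <- 1L
  for (start in seq(1L, K, by = block)) {
    rows <- start:min(K, start + block - 1L)
    dot <- X[rows, , drop = FALSE] %*% t(X)
    d <- EARTH_RADIUS_KM * acos(pmin(pmax(dot, -1), 1))
    w <- exp(-d^2 / (4 * D))
    w[d > radius] <- 0
    idx <- which(w > 0, arr.ind = TRUE)
    trips[[b]] <- cbind(rows[idx[, 1]], idx[, 2], w[idx])
    b <- b + 1L
  }
  trips <- do.call(rbind, trips)
  W <- Matrix::sparseMatrix(i = trips[, 1], j = trips[, 2], x = trips[, 3],
                            dims = c(K, K))
  rs <- Matrix::rowSums(W)
  W <- Matrix::Diagonal(x = 1 / rs) %*% W
  structure(list(W = methods::as(W, "CsparseMatrix"), D = D,
                 radius_km = radius, n = K),
            class = "movement_kernel")
}

#' @export
print.movement_kernel <- function(x, ...) {
  cat(sprintf("<movement_kernel> %d states, D = %g km^2/day, radius %g km, %.2f%% nonzero\n",
              x$n, x$D, x$radius_km,
              100 * length(x$W@x) / as.numeric(x$n)^2))
  invisible(x)
}

#' Push a probability surface through the movement kernel
#'
#' The prediction step of the recursion: `out(d) = sum_s p(s) w(s -> d)`.
#'
#' @param kernel a [movement_kernel()].
#' @param p normalised probability vector on the same grid.
#' @return normalised probability vector.
#' @export
apply_kernel <- function(kernel, p) {
  if (length(p) != kernel$n)
    psat_stop("probability surface does not match the kernel grid",
              "psat_shape_error")
  if (abs(sum(p) - 1) > 1e-6)
    stop_validation("input surface must be normalised")
  out <- as.numeric(Matrix::crossprod(kernel$W, p))
  out / sum(out)
}
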