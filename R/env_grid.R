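# Environment grid: monthly SST climatology, bathymetry and a land mask on
# a regular lat/lon lattice of cell centers.

#' Construct and validate an environment grid
#'
#' @param lat,lon strictly monotone vectors of cell-center coordinates
#'   (degrees); longitude in [-180, 180).
#' @param sst numeric array `[12, nlat, nlon]`, monthly sea-surface
#'   temperature in degrees C.
#' @param bathymetry numeric matrix `[nlat, nlon]`, sea depth in m,
#'   positive wherever the cell is ocean.
#' @param land_mask logical matrix `[nlat, nlon]`, `TRUE` on land.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(lat, lon, sst, bathymetry, land_mask) {
  if (length(lat) < 2 || length(lon) < 2)
    stop_validation("environment grid needs at least 2 cells per axis")
  if (any(diff(lat) <= 0) && any(diff(lat) >= 0))
    stop_validation("lat axis must be strictly monotone")
  if (any(diff(lon) <= 0) && any(diff(lon) >= 0))
    stop_validation("lon axis must be strictly monotone")
  if (any(abs(lat) > 90)) stop_validation("lat out of [-90, 90]")
  if (any(lon < -180 | lon >= 180)) stop_validation("lon out of [-180, 180)")
  nlat <- length(lat); nlon <- length(lon)
  if (!identical(dim(sst), c(12L, nlat, nlon)))
    stop_validation("sst must be a [12, nlat, nlon] array")
  if (!identical(dim(bathymetry), c(nlat, nlon)))
    stop_validation("bathymetry must be a [nlat, nlon] matrix")
  if (!is.logical(land_mask) || !identical(dim(land_mask), c(nlat, nlon)))
    stop_validation("land_mask must be a logical [nlat, nlon] matrix")
  if (any(bathymetry[!land_mask] <= 0))
    stop_validation("bathymetry must be > 0 on every ocean cell")
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 sst = sst, bathymetry = bathymetry, land_mask = land_mask),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells, lat [%g, %g], lon [%g, %g], %d%% land\n",
              length(x$lat), length(x$lon), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon), round(100 * mean(x$land_mask))))
  invisible(x)
}

# nearest cell indices on each axis for a point (vectorised over points)
env_cell_index <- function(env, lat, lon) {
  i <- pmax(1L, pmin(length(env$lat),
                     round(stats::approx(env$lat, seq_along(env$lat),
                                         xout = lat, rule = 2)$y)))
  j <- pmax(1L, pmin(length(env$lon),
                     round(stats::approx(env$lon, seq_along(env$lon),
                                         xout = lon, rule = 2)$y)))
  cbind(i = as.integer(i), j = as.integer(j))
}

# SST at point(s) for a calendar month (1-12), nearest-cell lookup
env_sst_at <- function(env, lat, lon, month) {
  ij <- env_cell_index(env, lat, lon)
  env$sst[cbind(as.integer(month), ij[, 1], ij[, 2])]
}

env_is_land_at <- function(env, lat, lon) {
  ij <- env_cell_index(env, lat, lon)
  env$land_mask[ij]
}

env_bathy_at <- function(env, lat, lon) {
  ij <- env_cell_index(env, lat, lon)
  env$bathymetry[ij]
}

env_in_domain <- function(env, lat, lon) {
  res_lat <- abs(stats::median(diff(env$lat)))
  res_lon <- abs(stats::median(diff(env$lon)))
  lat >= min(env$lat) - res_lat / 2 & lat <= max(env$lat) + res_lat / 2 &
    lon >= min(env$lon) - res_lon / 2 & lon <= max(env$lon) + res_lon / 2
}

#' Generate a synthetic North-Atlantic-like environment
#'
#' Builds an idealised high-latitude ocean: SST decreases linearly from the
#' southern edge polewards (the meridional gradient), oscillates seasonally
#' as a cosine peaking in July, and carries a time-invariant spatial noise
#' field (seeded) that gives each location a persistent thermal fingerprint.
#' A land strip of configurable width occupies the western edge, with a
#' linear shelf dropping to the basin depth.
#'
#' @param config a [sim_config()] list; uses its grid, SST, bathymetry and
#'   seed entries.
#' @return an [env_grid()].
#' @export
generate_environment <- function(config) {
  config <- as_sim_config(config)
  res <- config$res_deg
  nlat <- floor(diff(config$lat_range) / res + 1e-9)
  nlon <- floor(diff(config$lon_range) / res + 1e-9)
  if (nlat < 2 || nlon < 2)
    psat_stop("grid degenerate: fewer than 2 cells on an axis",
              "psat_config_error")
  lat <- config$lat_range[1] + res / 2 + (seq_len(nlat) - 1) * res
  lon <- config$lon_range[1] + res / 2 + (seq_len(nlon) - 1) * res

  set.seed(config$seed %% .Machine$integer.max)
  noise <- matrix(rnorm(nlat * nlon, 0, config$sst_noise_sd_c), nlat, nlon)

  sst <- array(NA_real_, c(12L, nlat, nlon))
  for (m in 1:12) {
    seasonal <- config$sst_seasonal_amp_c * cos(2 * pi * (m - 7) / 12)
    base <- config$sst_ref_c -
      config$sst_gradient_c_per_deg * (lat - config$lat_range[1])
    sst[m, , ] <- matrix(base, nlat, nlon) + seasonal + noise
  }

  land_cols <- lon < (config$lon_range[1] + config$land_width_deg)
  land <- matrix(rep(land_cols, each = nlat), nlat, nlon)
  coast_lon <- config$lon_range[1] + config$land_width_deg
  dist_deg <- pmax(0, lon - coast_lon) + config$res_deg / 2
  depth_col <- pmin(1, dist_deg / max(config$shelf_width_deg, config$res_deg)) *
    config$basin_depth_m
  bathy <- matrix(rep(pmax(depth_col, 20), each = nlat), nlat, nlon)
  bathy[land] <- 0

  env_grid(lat, lon, sst, bathy, land)
}
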