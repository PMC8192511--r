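# Daily observations and likelihood surfaces.

#' Likelihood/observation model parameters
#'
#' @param sigma_lon_deg Gaussian sd of the light-based longitude, degrees.
#' @param sigma_lat_deg Gaussian sd of the light-based latitude, degrees.
#' @param sigma_sst_c Gaussian sd of the SST match, degrees C.
#' @param equinox_window_days latitude blackout half-width around equinoxes.
#' @param bathy_tol_m slack added to bathymetry before the maximum-depth
#'   feasibility cut (absorbs tag pressure-sensor error).
#' @param popup_sd_km Gaussian sd of the Argos pop-up anchor, km.
#' @return classed parameter list.
#' @export
obs_params <- function(sigma_lon_deg = 0.5, sigma_lat_deg = 1.5,
                       sigma_sst_c = 0.7, equinox_window_days = 10,
                       bathy_tol_m = 10, popup_sd_km = 10) {
  structure(list(sigma_lon_deg = sigma_lon_deg, sigma_lat_deg = sigma_lat_deg,
                 sigma_sst_c = sigma_sst_c,
                 equinox_window_days = equinox_window_days,
                 bathy_tol_m = bathy_tol_m, popup_sd_km = popup_sd_km),
            class = "obs_params")
}

#' Collapse a tag series to daily observations
#'
#' One row per UTC calendar day with at least one retained sample: the
#' day's maximum depth, the mean temperature over samples shallower than
#' 20 m (the SST proxy; missing if no such sample), and the light-based
#' position estimate when a twilight pair is available.
#'
#' @param series a [tag_series()].
#' @param equinox_window_days passed to [light_position()].
#' @return data.frame with columns `date`, `max_depth_m`, `sst_c`,
#'   `light_lon`, `light_lat`, `lat_usable`.
#' @export
daily_observations <- function(series, equinox_window_days = 10) {
  s <- series$samples
  empty <- data.frame(date = as.Date(character()), max_depth_m = numeric(),
                      sst_c = numeric(), light_lon = numeric(),
                      light_lat = numeric(), lat_usable = logical())
  if (!nrow(s)) return(empty)
  day <- as.Date(s$timestamp, tz = "UTC")
  days <- sort(unique(day))
  rows <- lapply(days, function(d) {
    i <- day == d
    shallow <- i & s$depth_m < 20
    data.frame(date = d,
               max_depth_m = max(s$depth_m[i]),
               sst_c = if (any(shallow)) mean(s$temperature_c[shallow])
                       else NA_real_,
               light_lon = NA_real_, light_lat = NA_real_,
               lat_usable = FALSE)
  })
  obs <- do.call(rbind, rows)
  tw <- series$twilights
  if (!is.null(tw) && nrow(tw)) {
    m <- match(obs$date, tw$date)
    for (r in which(!is.na(m))) {
      lp <- light_position(tw$sunrise_utc[m[r]], tw$sunset_utc[m[r]],
                           obs$date[r], equinox_window_days)
      obs$light_lon[r] <- lp$lon
      obs$light_lat[r] <- lp$lat
      obs$lat_usable[r] <- lp$lat_usable
    }
  }
  obs
}

new_likelihood_surface <- function(date, values, components) {
  structure(list(date = date, values = values, components = components,
                 degenerate = all(values <= 0)),
            class = "likelihood_surface")
}

#' Daily likelihood surface over the state grid
#'
#' Cellwise product of the available components: a Gaussian in longitude
#' (and, when the day length carries latitude information, in latitude)
#' around the light-based position; a Gaussian comparing the day's surface
#' temperature to the monthly SST field; and a hard feasibility indicator
#' requiring the water depth (plus tolerance) to cover the day's maximum
#' depth. Missing components contribute uniformly. An all-zero product is
#' flagged degenerate; the filter then uses the prediction alone.
#'
#' @param obs one row of [daily_observations()] (or an equivalent list).
#' @param grid a [build_grid()] result.
#' @param env the [env_grid()].
#' @param params an [obs_params()] list.
#' @return object of class `likelihood_surface`.
#' @export
daily_likelihood <- function(obs, grid, env, params = obs_params()) {
  if (max(grid$env_i) > length(env$lat) || max(grid$env_j) > length(env$lon))
    psat_stop("state grid does not match the environment grid",
              "psat_shape_error")
  v <- rep(1, grid$n)
  comps <- character()
  month <- as.integer(format(as.Date(obs$date), "%m"))
  if (!is.na(obs$light_lon)) {
    dlon <- wrap_lon(grid$lon - obs$light_lon)
    v <- v * dnorm(dlon, 0, params$sigma_lon_deg)
    comps <- c(comps, "light_lon")
    if (isTRUE(obs$lat_usable) && !is.na(obs$light_lat)) {
      v <- v * dnorm(grid$lat - obs$light_lat, 0, params$sigma_lat_deg)
      comps <- c(comps, "light_lat")
    }
  }
  if (!is.null(obs$sst_c) && !is.na(obs$sst_c)) {
    v <- v * dnorm(obs$sst_c, grid_sst(grid, env, month), params$sigma_sst_c)
    comps <- c(comps, "sst")
  }
  if (!is.null(obs$max_depth_m) && !is.na(obs$max_depth_m)) {
    v[grid$bathy + params$bathy_tol_m < obs$max_depth_m] <- 0
    comps <- c(comps, "depth")
  }
  new_likelihood_surface(as.Date(obs$date), v, comps)
}

#' Anchor surface at a known position
#'
#' Gaussian (in great-circle km) likelihood pinning the track to a known
#' location: the release site (`sd_km = 0`, a point mass at the nearest
#' ocean state) or the Argos pop-up position (Argos-scale sd).
#'
#' @param grid a [build_grid()] result.
#' @param lat,lon the anchor position, degrees.
#' @param sd_km Gaussian sd in km; 0 collapses to the nearest ocean state.
#' @return a `likelihood_surface`.
#' @export
anchor_surface <- function(grid, lat, lon, sd_km = 0) {
  d <- great_circle_distance(lat, lon, grid$lat, grid$lon)
  res_km <- grid$resolution * pi * EARTH_RADIUS_KM / 180
  if (min(d) > max(3 * sd_km, 3 * res_km))
    psat_stop("anchor location too far from any ocean state",
              "psat_anchor_error")
  v <- numeric(grid$n)
  if (sd_km <= 0) {
    v[which.min(d)] <- 1
  } else {
    v <- exp(-d^2 / (2 * sd_km^2))
    if (sum(v) == 0) v[which.min(d)] <- 1
  }
  new_likelihood_surface(NULL, v, "anchor")
}
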