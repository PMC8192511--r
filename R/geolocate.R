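# The user-facing model fit: one call per tag, returning a classed object.

#' Geolocate a tagged fish
#'
#' Fits the grid-based hidden Markov model to one tag record. Daily
#' likelihood surfaces are assembled from the light-based position, the
#' mean surface (< 20 m) temperature matched against the monthly SST field,
#' and the maximum-depth bathymetry cut; the track is pinned to the release
#' site on day 0 and to the Argos pop-up position (Gaussian,
#' `params$popup_sd_km`) on the final day. The movement kernel is an
#' isotropic diffusion whose coefficient `D` is either supplied or fitted
#' by maximum likelihood. The route estimate is the per-day spherical mean
#' of `n_tracks` forward-filter backward-sampled trajectories.
#'
#' @param series a [tag_series()] with pop-up metadata.
#' @param env the [env_grid()] of monthly SST, bathymetry and land.
#' @param resolution state-grid resolution, degrees (default 1).
#' @param flavour grid discretisation, `"latlon"` or `"distance"`.
#' @param D diffusion coefficient km^2/day, or `NULL` to estimate.
#' @param D_bounds search interval when `D` is estimated.
#' @param n_tracks number of sampled trajectories for the route mean
#'   (default 1000).
#' @param seed RNG seed for trajectory sampling.
#' @param params an [obs_params()] list.
#' @return an object of class `psat_fit`.
#' @examples
#' cfg <- sim_config(deployment_days = 20, lat_range = c(50, 62),
#'                   lon_range = c(-10, 12))
#' env <- generate_environment(cfg)
#' trk <- simulate_track(env, cfg)
#' tag <- simulate_tag_series(trk, env, cfg)
#' fit <- geolocate(tag, env, D = 500, n_tracks = 100)
#' fit
#' @export
geolocate <- function(series, env, resolution = 1,
                      flavour = c("latlon", "distance"),
                      D = NULL, D_bounds = c(50, 5000), n_tracks = 1000,
                      seed = 1, params = obs_params()) {
  flavour <- match.arg(flavour)
  dep <- series$deployment
  if (is.null(dep$popup_date))
    stop_input("deployment must carry a pop-up date")
  grid <- build_grid(env, resolution, flavour)

  dates <- seq(dep$release_date, dep$popup_date, by = "day")
  obs <- daily_observations(series, params$equinox_window_days)
  anchor0 <- anchor_surface(grid, dep$release_lat, dep$release_lon, 0)

  liks <- vector("list", length(dates) - 1)
  for (t in seq_along(liks)) {
    r <- which(obs$date == dates[t + 1])
    if (length(r))
      liks[[t]] <- daily_likelihood(obs[r, ], grid, env, params)
  }
  if (length(liks) && !is.null(dep$popup_lat)) {
    pa <- anchor_surface(grid, dep$popup_lat, dep$popup_lon,
                         params$popup_sd_km)
    T_ <- length(liks)
    if (is.null(liks[[T_]])) {
      liks[[T_]] <- pa
    } else {
      liks[[T_]]$values <- liks[[T_]]$values * pa$values
      liks[[T_]]$components <- c(liks[[T_]]$components, "anchor")
      liks[[T_]]$degenerate <- all(liks[[T_]]$values <= 0)
    }
  }

  if (is.null(D))
    D <- as.numeric(estimate_diffusion(anchor0, liks, grid, D_bounds))
  kernel <- movement_kernel(grid, D)
  ff <- forward_filter(anchor0, kernel, liks)
  sm <- backward_smooth(ff, kernel)
  samples <- sample_tracks(ff, kernel, n = n_tracks, seed = seed,
                           grid = grid, dates = dates)
  track <- mean_track(samples)

  structure(list(deployment = dep, grid = grid, env_dim = dim(env$bathymetry),
                 dates = dates, D = D, kernel = kernel,
                 filtered = ff$filtered, smoothed = sm,
                 log_lik = ff$log_lik,
                 degenerate_days = ff$degenerate_days,
                 n_obs_days = sum(!vapply(liks, is.null, logical(1))),
                 samples = samples, track = track,
                 params = params, seed = seed, n_tracks = n_tracks),
            class = "psat_fit")
}

#' @export
print.psat_fit <- function(x, ...) {
  cat(sprintf("Hidden Markov geolocation fit: tag %s (%s)\n",
              x$deployment$tag_id, x$deployment$population))
  cat(sprintf("  %d days, %d ocean states (%s grid, %g deg)\n",
              length(x$dates) - 1, x$grid$n, x$grid$flavour,
              x$grid$resolution))
  cat(sprintf("  D = %.1f km^2/day, log-likelihood %.2f\n", x$D, x$log_lik))
  cat(sprintf("  route = mean of %d sampled tracks; %d degenerate day(s)\n",
              x$n_tracks, length(x$degenerate_days)))
  invisible(x)
}

#' @export
summary.psat_fit <- function(object, ...) {
  trk <- object$track
  dep <- object$deployment
  mig <- great_circle_distance(dep$release_lat, dep$release_lon,
                               trk$mean_lat[nrow(trk)],
                               trk$mean_lon[nrow(trk)])
  daily <- great_circle_distance(trk$mean_lat[-1], trk$mean_lon[-1],
                                 trk$mean_lat[-nrow(trk)],
                                 trk$mean_lon[-nrow(trk)])
  out <- list(deployment = dep, n_days = length(object$dates) - 1,
              D = object$D, log_lik = object$log_lik,
              n_obs_days = object$n_obs_days,
              degenerate_days = object$degenerate_days,
              migration_km = mig, mean_daily_km = mean(daily),
              mean_angular_sd_deg = mean(trk$angular_sd_deg))
  class(out) <- "summary.psat_fit"
  out
}

#' @export
print.summary.psat_fit <- function(x, ...) {
  cat(sprintf("Tag %s (%s), %d tracked days (%d with data)\n",
              x$deployment$tag_id, x$deployment$population, x$n_days,
              x$n_obs_days))
  cat(sprintf("  diffusion D: %.1f km^2/day   log-likelihood: %.2f\n",
              x$D, x$log_lik))
  cat(sprintf("  straight-line migration distance: %.0f km\n", x$migration_km))
  cat(sprintf("  mean daily displacement of the route: %.1f km\n",
              x$mean_daily_km))
  cat(sprintf("  mean posterior angular sd: %.2f deg; degenerate days: %d\n",
              x$mean_angular_sd_deg, length(x$degenerate_days)))
  invisible(x)
}

#' @export
coef.psat_fit <- function(object, ...) c(D = object$D)

#' @export
logLik.psat_fit <- function(object, ...) {
  structure(object$log_lik, df = 1, class = "logLik")
}

#' @export
fitted.psat_fit <- function(object, ...) object$track

#' Draw new posterior trajectories from a fit
#' @param object a `psat_fit`.
#' @param nsim number of trajectories.
#' @param seed RNG seed.
#' @param ... unused.
#' @return a `track_samples` object.
#' @export
simulate.psat_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ffobj <- structure(list(filtered = object$filtered), class = "hmm_filter")
  sample_tracks(ffobj, object$kernel, n = nsim,
                seed = seed %||% (object$seed + 1),
                grid = object$grid, dates = object$dates)
}

#' Plot the residency surface and mean route of a fit
#' @param x a `psat_fit`.
#' @param ... passed to [graphics::image()].
#' @export
plot.psat_fit <- function(x, ...) {
  rd <- residency_distribution(x)
  lat_u <- sort(unique(x$grid$lat))
  lon_u <- sort(unique(x$grid$lon))
  z <- matrix(NA_real_, length(lon_u), length(lat_u))
  li <- match(x$grid$lat, lat_u); lj <- match(x$grid$lon, lon_u)
  z[cbind(lj, li)] <- rd$values
  image(lon_u, lat_u, z, col = hcl.colors(64, "YlGnBu", rev = TRUE),
        xlab = "longitude", ylab = "latitude", ...)
  lines(x$track$mean_lon, x$track$mean_lat, lwd = 2)
  points(x$deployment$release_lon, x$deployment$release_lat, pch = 15)
  points(x$deployment$popup_lon, x$deployment$popup_lat, pch = 4, lwd = 2)
  invisible(x)
}
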