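# Synthetic deployments: a biased random-walk fish over the synthetic ocean,
# and the PSAT record it would archive.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is designed around:
#' surface-oriented fish (80 % of samples shallower than 10 m) with
#' occasional deeper dives, 30-min archival sampling, 31 % transmission
#' dropout (69 % mean data recovery), a programmed 90-day deployment with
#' premature release after 5 days at constant depth, and a directed
#' poleward feeding migration of ~40 km/day over an idealised subarctic
#' ocean (meridional SST gradient 0.4 degC per degree latitude, 3 degC
#' seasonal amplitude).
#'
#' @param ... overrides of any default listed below.
#' @return classed list of simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # environment grid
    lat_range = c(38, 78), lon_range = c(-30, 30), res_deg = 1,
    sst_ref_c = 12, sst_gradient_c_per_deg = 0.4,
    sst_seasonal_amp_c = 3, sst_noise_sd_c = 1.2,
    land_width_deg = 3, shelf_width_deg = 5, basin_depth_m = 3000,
    # movement
    speed_km_day = 40, speed_sd_km = 8, bias = 0.8,
    target_lat = 70, target_lon = 5,
    release_lat = 55, release_lon = 0,
    release_date = as.Date("2010-05-01"), deployment_days = 90,
    # tag behaviour and sensing
    sampling_interval_min = 30, surface_fraction = 0.8,
    dive_depth_meanlog = log(50), dive_depth_sdlog = 0.6,
    sst_obs_noise_sd_c = 0.5, twilight_noise_sd_min = 10,
    dropout = 0.31, constant_depth_window_days = 5,
    constant_depth_range_m = 3, popup_noise_sd_km = 5,
    force_constant_depth_from_day = NULL,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    psat_stop(paste("unknown sim_config field(s):",
                    paste(unknown, collapse = ", ")), "psat_config_error")
  cfg[names(over)] <- over
  validate_sim_config(structure(cfg, class = "sim_config"))
}

as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  do.call(sim_config, as.list(x))
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) psat_stop(msg, "psat_config_error")
  chk(cfg$res_deg > 0, "res_deg must be positive")
  chk(all(c(cfg$sst_noise_sd_c, cfg$sst_obs_noise_sd_c,
            cfg$twilight_noise_sd_min, cfg$speed_sd_km,
            cfg$popup_noise_sd_km) >= 0), "noise sds must be >= 0")
  chk(cfg$dropout >= 0 && cfg$dropout <= 1, "dropout must lie in [0, 1]")
  chk(cfg$bias >= 0 && cfg$bias <= 1, "bias must lie in [0, 1]")
  chk(cfg$sampling_interval_min >= 15 && cfg$sampling_interval_min <= 60,
      "sampling_interval_min must lie in [15, 60]")
  chk(cfg$surface_fraction >= 0 && cfg$surface_fraction <= 1,
      "surface_fraction must lie in [0, 1]")
  chk(cfg$constant_depth_window_days %in% c(4, 5),
      "constant_depth_window_days must be 4 or 5")
  cfg
}

#' Simulate a true daily migration track
#'
#' Daily biased random walk: with probability `bias` the day's heading is
#' the great-circle bearing to the target, otherwise uniform; step length is
#' Gaussian around `speed_km_day` (truncated at 0 and at mean + 4 sd). Steps
#' onto land or out of the domain are rejected and the heading redrawn.
#'
#' @param env an [env_grid()].
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param tag_id,population labels for the resulting deployment.
#' @return object of class `true_track`: a [tag_deployment()] plus a
#'   data.frame of daily true positions.
#' @export
simulate_track <- function(env, config, seed = config$seed,
                           tag_id = "sim-1", population = "sim") {
  config <- as_sim_config(config)
  lat <- config$release_lat; lon <- config$release_lon
  if (!env_in_domain(env, lat, lon) || env_is_land_at(env, lat, lon))
    stop_input("release location must be an ocean cell inside the domain")
  set.seed(seed %% .Machine$integer.max)
  n <- config$deployment_days
  dates <- config$release_date + 0:n
  lats <- numeric(n + 1); lons <- numeric(n + 1)
  lats[1] <- lat; lons[1] <- lon
  max_step <- config$speed_km_day + 4 * config$speed_sd_km
  for (d in seq_len(n)) {
    step <- min(max(0, rnorm(1, config$speed_km_day, config$speed_sd_km)),
                max_step)
    dist_t <- great_circle_distance(lats[d], lons[d],
                                    config$target_lat, config$target_lon)
    step <- min(step, dist_t)  # do not overshoot the target
    placed <- FALSE
    if (step == 0) {
      lats[d + 1] <- lats[d]; lons[d + 1] <- lons[d]; placed <- TRUE
    }
    tries <- 0
    while (!placed && tries < 500) {
      tries <- tries + 1
      heading <- if (runif(1) < config$bias)
        gc_bearing(lats[d], lons[d], config$target_lat, config$target_lon)
      else runif(1, 0, 360)
      p <- gc_destination(lats[d], lons[d], heading, step)
      if (env_in_domain(env, p["lat"], p["lon"]) &&
          !env_is_land_at(env, p["lat"], p["lon"])) {
        lats[d + 1] <- p["lat"]; lons[d + 1] <- p["lon"]; placed <- TRUE
      }
    }
    if (!placed)
      psat_stop("no feasible daily step: position appears landlocked",
                "psat_simulation_error")
  }
  dep <- tag_deployment(tag_id, population, config$release_date, lat, lon)
  structure(list(deployment = dep,
                 positions = data.frame(date = dates, lat = lats, lon = lons),
                 config = config),
            class = "true_track")
}

#' @export
print.true_track <- function(x, ...) {
  p <- x$positions
  cat(sprintf("<true_track> %s: %d days, release (%.2f, %.2f) -> end (%.2f, %.2f)\n",
              x$deployment$tag_id, nrow(p) - 1, p$lat[1], p$lon[1],
              p$lat[nrow(p)], p$lon[nrow(p)]))
  invisible(x)
}

#' Simulate the PSAT record of a true track
#'
#' Emulates the archived series: depth samples are surface-layer draws
#' (uniform on 0-10 m) with probability `surface_fraction` and log-normal
#' dives (10 m + lognormal, capped near the local bottom) otherwise;
#' temperature is the environment SST at the true position and month plus
#' Gaussian sensor noise; a twilight pair per day comes from the solar
#' geometry at the true position plus Gaussian timing noise (missing during
#' polar day/night); each sample is then independently lost with probability
#' `dropout`. The series ends at the programmed pop-up date, or earlier if
#' depth stays within `constant_depth_range_m` over the trailing
#' `constant_depth_window_days` (the premature-release rule). The pop-up
#' position is the true end position plus Gaussian Argos-scale noise.
#'
#' @param track a [simulate_track()] result.
#' @param env the [env_grid()] the track lives on.
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return a [tag_series()] whose deployment has pop-up fields set.
#' @export
simulate_tag_series <- function(track, env, config, seed = config$seed + 1) {
  config <- as_sim_config(config)
  pos <- track$positions
  if (!nrow(pos)) stop_input("track is empty")
  set.seed(seed %% .Machine$integer.max)
  dt_min <- config$sampling_interval_min
  n_days <- nrow(pos) - 1

  day0 <- as.POSIXct(paste(format(pos$date[1]), "00:00:00"), tz = "UTC")
  ts <- day0 + seq(dt_min * 60, n_days * 86400, by = dt_min * 60)
  # calendar-day offset: a sample on date release + d uses the day-d position
  day_idx <- pmin(n_days, floor(as.numeric(difftime(ts, day0, units = "days"))))

  lat_s <- pos$lat[day_idx + 1]; lon_s <- pos$lon[day_idx + 1]
  month_s <- as.integer(format(pos$date[day_idx + 1], "%m"))

  deep <- runif(length(ts)) > config$surface_fraction
  depth <- runif(length(ts), 0, 10)
  if (any(deep)) {
    bot <- env_bathy_at(env, lat_s[deep], lon_s[deep])
    depth[deep] <- pmin(10 + rlnorm(sum(deep), config$dive_depth_meanlog,
                                    config$dive_depth_sdlog),
                        pmax(bot - 5, 11))
  }
  if (!is.null(config$force_constant_depth_from_day))
    depth[day_idx >= config$force_constant_depth_from_day] <- 5

  temp <- env_sst_at(env, lat_s, lon_s, month_s) +
    rnorm(length(ts), 0, config$sst_obs_noise_sd_c)

  # premature release: depth range < threshold over the trailing window
  popup_day <- n_days
  W <- config$constant_depth_window_days
  for (d in W:n_days) {
    idx <- day_idx > d - W & day_idx <= d
    rng <- range(depth[idx])
    if (diff(rng) < config$constant_depth_range_m) { popup_day <- d; break }
  }

  keep_day <- day_idx <= popup_day
  ts <- ts[keep_day]; depth <- depth[keep_day]; temp <- temp[keep_day]
  day_idx <- day_idx[keep_day]
  n_scheduled <- length(ts)

  # twilights from the true position each day, with timing noise
  tw_dates <- pos$date[1 + seq_len(popup_day)]
  tw <- lapply(seq_len(popup_day), function(d) {
    t <- twilight_times(pos$lat[d + 1], pos$lon[d + 1], tw_dates[d])
    if (is.na(t$sunrise)) return(c(NA_real_, NA_real_))
    round(as.numeric(c(t$sunrise, t$sunset)) +
            rnorm(2, 0, config$twilight_noise_sd_min * 60))
  })
  tw <- do.call(rbind, tw)
  twilights <- data.frame(
    date = tw_dates,
    sunrise_utc = as.POSIXct(tw[, 1], origin = "1970-01-01", tz = "UTC"),
    sunset_utc = as.POSIXct(tw[, 2], origin = "1970-01-01", tz = "UTC"))

  kept <- runif(length(ts)) >= config$dropout
  samples <- data.frame(timestamp = ts[kept], depth_m = depth[kept],
                        temperature_c = temp[kept])

  end_lat <- pos$lat[popup_day + 1]; end_lon <- pos$lon[popup_day + 1]
  off <- gc_destination(end_lat, end_lon, runif(1, 0, 360),
                        abs(rnorm(1, 0, config$popup_noise_sd_km)))
  dep <- track$deployment
  dep$popup_date <- pos$date[popup_day + 1]
  dep$popup_lat <- unname(off["lat"]); dep$popup_lon <- unname(off["lon"])

  out <- tag_series(dep, samples, twilights)
  out$scheduled_samples <- n_scheduled
  out
}
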