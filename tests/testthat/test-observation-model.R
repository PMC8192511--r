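# Daily summaries, light geolocation and likelihood surfaces.

test_that("daily observations aggregate depth and shallow-water temperature", {
  dep <- tag_deployment("t1", "X", "2010-05-01", 55, 0)
  ts <- as.POSIXct("2010-05-01 06:00:00", tz = "UTC") + 0:2 * 3600
  s <- data.frame(timestamp = ts, depth_m = c(1, 3, 25),
                  temperature_c = c(10.0, 10.2, 8.0))
  obs <- daily_observations(tag_series(dep, s))
  expect_equal(nrow(obs), 1)
  expect_equal(obs$max_depth_m, 25)
  expect_equal(obs$sst_c, 10.1)   # 25 m sample excluded from the SST mean

  s2 <- data.frame(timestamp = ts, depth_m = c(25, 30, 40),
                   temperature_c = c(8, 7, 6))
  obs2 <- daily_observations(tag_series(dep, s2))
  expect_true(is.na(obs2$sst_c))
  expect_equal(obs2$max_depth_m, 40)

  # a fully dropped day is absent, an empty series gives an empty frame
  s3 <- rbind(s, data.frame(timestamp = ts + 2 * 86400, depth_m = 5,
                            temperature_c = 9))
  obs3 <- daily_observations(tag_series(dep, s3))
  expect_equal(nrow(obs3), 2)
  expect_false(as.Date("2010-05-02") %in% obs3$date)
  expect_equal(nrow(daily_observations(tag_series(dep, s[0, ]))), 0)
})

test_that("light positions recover longitude from local noon and latitude from day length", {
  eq <- as.Date("2010-03-22")  # equinox
  lp <- light_position(as.POSIXct(paste(eq, "06:00:00"), tz = "UTC"),
                       as.POSIXct(paste(eq, "18:00:00"), tz = "UTC"), eq)
  expect_equal(lp$lon, 0)
  expect_false(lp$lat_usable)   # 12-h day: inversion degenerate

  lp2 <- light_position(as.POSIXct(paste(eq, "05:00:00"), tz = "UTC"),
                        as.POSIXct(paste(eq, "17:00:00"), tz = "UTC"), eq)
  expect_equal(lp2$lon, 15)     # one hour early noon = 15 deg east

  # round trip through the forward geometry away from the equinox
  for (case in list(c(58, -5), c(45, 12), c(62, 20))) {
    d <- as.Date("2010-05-10")
    tw <- twilight_times(case[1], case[2], d)
    lp3 <- light_position(tw$sunrise, tw$sunset, d)
    expect_equal(lp3$lon, case[2], tolerance = 1e-6)
    expect_equal(lp3$lat, case[1], tolerance = 0.05)
    expect_true(lp3$lat_usable)
  }

  expect_error(light_position(as.POSIXct(paste(eq, "18:00:00"), tz = "UTC"),
                              as.POSIXct(paste(eq, "06:00:00"), tz = "UTC"),
                              eq),
               class = "psat_input_error")
})

test_that("daily likelihood is the product of the available components", {
  env <- tiny_env(2, 2, sst_base = 10, sst_slope = -1, bathy = 400)
  env$bathymetry[1, ] <- 600   # southern row deeper
  g <- build_grid(env, 1, "latlon")
  par <- obs_params()

  # depth-only: bathymetry indicator
  obs <- list(date = as.Date("2010-06-01"), max_depth_m = 500, sst_c = NA,
              light_lon = NA, light_lat = NA, lat_usable = FALSE)
  L <- daily_likelihood(obs, g, env, par)
  deep_ok <- g$bathy + par$bathy_tol_m >= 500
  expect_true(all(L$values[!deep_ok] == 0))
  expect_equal(length(unique(L$values[deep_ok])), 1)

  # sst-only on a noise-free field: argmax at exact matches
  obs2 <- list(date = as.Date("2010-06-01"), max_depth_m = NA, sst_c = 9,
               light_lon = NA, light_lat = NA, lat_usable = FALSE)
  L2 <- daily_likelihood(obs2, g, env, par)
  match_cells <- which(abs(psatHMM:::grid_sst(g, env, 6) - 9) < 1e-12)
  expect_setequal(which(L2$values == max(L2$values)), match_cells)

  # all three components: hand-multiplied product over the 4 cells
  obs3 <- list(date = as.Date("2010-06-01"), max_depth_m = 450, sst_c = 9.4,
               light_lon = 0.6, light_lat = 50.2, lat_usable = TRUE)
  L3 <- daily_likelihood(obs3, g, env, par)
  hand <- dnorm(psatHMM:::wrap_lon(g$lon - 0.6), 0, par$sigma_lon_deg) *
    dnorm(g$lat - 50.2, 0, par$sigma_lat_deg) *
    dnorm(9.4, psatHMM:::grid_sst(g, env, 6), par$sigma_sst_c) *
    as.numeric(g$bathy + par$bathy_tol_m >= 450)
  expect_equal(L3$values, hand, tolerance = 1e-12)

  # sigma_sst -> 0 concentrates on exact matches only
  par0 <- obs_params(sigma_sst_c = 1e-4)
  L4 <- daily_likelihood(obs2, g, env, par0)
  expect_setequal(which(L4$values > 0), match_cells)
})

test_that("anchor surfaces pin to ocean cells at the requested scale", {
  env <- tiny_env(5, 5, land = cbind(3, 3))
  g <- build_grid(env, 1, "latlon")

  a <- anchor_surface(g, 51.2, 1.9, 0)
  expect_equal(sum(a$values > 0), 1)
  near <- which.min(great_circle_distance(51.2, 1.9, g$lat, g$lon))
  expect_equal(which(a$values == 1), near)

  # Argos-scale anchor: >99% of mass in the containing + adjacent cells
  a2 <- anchor_surface(g, 51, 1, 10)
  v <- a2$values / sum(a2$values)
  nearby <- great_circle_distance(51, 1, g$lat, g$lon) < 1.5 * 111.2
  expect_gt(sum(v[nearby]), 0.99)

  # a land location snaps to the nearest ocean cell
  a3 <- anchor_surface(g, 52, 2, 0)   # (3,3) is land
  expect_equal(sum(a3$values > 0), 1)
  expect_false(g$lat[which(a3$values == 1)] == 52 &
                 g$lon[which(a3$values == 1)] == 2)

  expect_error(anchor_surface(g, 70, 40, 0), class = "psat_anchor_error")
})

test_that("adding observation components tightens localisation on simulated days", {
  cfg <- quick_cfg(deployment_days = 60, sst_obs_noise_sd_c = 0.3,
                   twilight_noise_sd_min = 3)
  env <- generate_environment(cfg)
  trk <- simulate_track(env, cfg, seed = 21)
  ser <- simulate_tag_series(trk, env, cfg, seed = 22)
  g <- build_grid(env, 1, "latlon")
  obs <- daily_observations(ser)
  par <- obs_params(sigma_sst_c = 0.3)

  err <- function(drop) {
    vapply(seq_len(nrow(obs)), function(r) {
      o <- as.list(obs[r, ])
      for (f in drop) o[[f]] <- NA
      L <- daily_likelihood(o, g, env, par)
      if (L$degenerate) return(NA_real_)
      i <- which.max(L$values)
      truth <- trk$positions[trk$positions$date == o$date, ]
      great_circle_distance(g$lat[i], g$lon[i], truth$lat, truth$lon)
    }, numeric(1))
  }
  e_depth <- err(c("sst_c", "light_lon", "light_lat"))
  e_sst <- err(c("light_lon", "light_lat"))
  e_all <- err(character())
  expect_gt(sum(!is.na(e_all)), 50)
  expect_lte(mean(e_sst, na.rm = TRUE), mean(e_depth, na.rm = TRUE))
  expect_lte(mean(e_all, na.rm = TRUE), mean(e_sst, na.rm = TRUE))

  # noise-free observations put the true cell in the argmax set
  cfg0 <- quick_cfg(deployment_days = 20, sst_obs_noise_sd_c = 0,
                    twilight_noise_sd_min = 0)
  trk0 <- simulate_track(env, cfg0, seed = 31)
  ser0 <- simulate_tag_series(trk0, env, cfg0, seed = 32)
  obs0 <- daily_observations(ser0)
  for (r in seq_len(nrow(obs0))) {
    L <- daily_likelihood(obs0[r, ], g, env, obs_params(sigma_sst_c = 0.2))
    truth <- trk0$positions[trk0$positions$date == obs0$date[r], ]
    true_cell <- which.min(great_circle_distance(truth$lat, truth$lon,
                                                 g$lat, g$lon))
    expect_gte(L$values[true_cell], max(L$values) * (1 - 1e-9))
  }
})
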