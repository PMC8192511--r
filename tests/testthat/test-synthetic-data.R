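# The generator must reproduce the statistical structure the analysis
# assumes: poleward SST gradient, seasonal cycle, surface-oriented depth
# use, dropout, solar twilights, premature-release rule.

test_that("synthetic SST decreases polewards and has the configured seasonal cycle", {
  cfg <- quick_cfg(sst_noise_sd_c = 0, sst_seasonal_amp_c = 0)
  env <- generate_environment(cfg)
  i40 <- which.min(abs(env$lat - 52)); i70 <- which.min(abs(env$lat - 64))
  for (m in 1:12)
    expect_true(all(env$sst[m, i40, ] > env$sst[m, i70, ]))

  cfg2 <- quick_cfg(sst_seasonal_amp_c = 4)
  env2 <- generate_environment(cfg2)
  # July minus January is the peak-to-trough of the cosine; the (static)
  # spatial noise cancels in the difference
  expect_equal(env2$sst[7, 3, 9] - env2$sst[1, 3, 9], 8, tolerance = 1e-12)

  expect_identical(generate_environment(cfg2)$sst, env2$sst)
  expect_error(generate_environment(quick_cfg(lat_range = c(50, 50.4))),
               class = "psat_config_error")
})

test_that("simulated tracks respect bias, speed and the land mask", {
  cfg <- quick_cfg(bias = 1, speed_sd_km = 0, deployment_days = 10)
  env <- generate_environment(cfg)
  trk <- simulate_track(env, cfg)
  d_target <- great_circle_distance(trk$positions$lat, trk$positions$lon,
                                    cfg$target_lat, cfg$target_lon)
  # deterministic geodesic pursuit: each day closes exactly one step
  expect_equal(diff(d_target), rep(-cfg$speed_km_day, 10), tolerance = 1e-6)

  cfg0 <- quick_cfg(speed_km_day = 0, speed_sd_km = 0, deployment_days = 5)
  trk0 <- simulate_track(env, cfg0)
  expect_true(all(trk0$positions$lat == trk0$positions$lat[1]))
  expect_true(all(trk0$positions$lon == trk0$positions$lon[1]))

  cfg8 <- quick_cfg(bias = 0.8, deployment_days = 30)
  trk8 <- simulate_track(env, cfg8, seed = 42)
  d <- great_circle_distance(trk8$positions$lat, trk8$positions$lon,
                             cfg8$target_lat, cfg8$target_lon)
  expect_lt(d[length(d)], d[1])

  # no position on land, steps bounded
  expect_false(any(psatHMM:::env_is_land_at(env, trk8$positions$lat,
                                            trk8$positions$lon)))
  steps <- great_circle_distance(trk8$positions$lat[-1],
                                 trk8$positions$lon[-1],
                                 trk8$positions$lat[-31],
                                 trk8$positions$lon[-31])
  expect_true(all(steps <= cfg8$speed_km_day + 4 * cfg8$speed_sd_km + 1e-9))

  cfg_land <- quick_cfg(release_lat = 55, release_lon = -11.5)
  expect_error(simulate_track(env, cfg_land), class = "psat_input_error")
})

test_that("tag series match configured dropout, surface fraction and SST", {
  cfg <- quick_cfg(dropout = 0, deployment_days = 110,
                   sampling_interval_min = 15, sst_obs_noise_sd_c = 0)
  env <- generate_environment(cfg)
  trk <- simulate_track(env, cfg, seed = 3)
  ser <- simulate_tag_series(trk, env, cfg, seed = 4)
  expect_equal(nrow(ser$samples) / ser$scheduled_samples, 1)

  # surface occupancy within 3 binomial sds of 0.8 at n >= 10,000
  n <- nrow(ser$samples)
  expect_gt(n, 10000)
  frac <- mean(ser$samples$depth_m < 10)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n))

  # noise-free SST equals the field at the true cell
  day_idx <- as.numeric(as.Date(ser$samples$timestamp, tz = "UTC") -
                          trk$positions$date[1])
  truth <- trk$positions[day_idx + 1, ]
  expect_equal(ser$samples$temperature_c,
               psatHMM:::env_sst_at(env, truth$lat, truth$lon,
                                    as.integer(format(truth$date, "%m"))),
               tolerance = 1e-12)

  # dropout 0.31 on >= 10,000 scheduled samples: ~69% recovery
  cfgd <- quick_cfg(dropout = 0.31, deployment_days = 110,
                    sampling_interval_min = 15)
  serd <- simulate_tag_series(trk, env, cfgd, seed = 5)
  frac_kept <- nrow(serd$samples) / serd$scheduled_samples
  expect_gt(serd$scheduled_samples, 10000)
  expect_gt(frac_kept, 0.67)
  expect_lt(frac_kept, 0.71)

  # determinism
  s1 <- simulate_tag_series(trk, env, cfgd, seed = 7)
  s2 <- simulate_tag_series(trk, env, cfgd, seed = 7)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$twilights, s2$twilights)
})

test_that("twilight geometry is self-consistent and noon maps to longitude", {
  # local noon at longitude 0 is 12:00 UTC when noise-free
  tw <- twilight_times(50, 0, as.Date("2010-05-01"))
  mid <- tw$sunrise + as.numeric(difftime(tw$sunset, tw$sunrise,
                                          units = "secs")) / 2
  expect_identical(format(mid, "%H:%M:%S"), "12:00:00")

  # polar day: no twilights
  twp <- twilight_times(75, 0, as.Date("2010-06-21"))
  expect_true(is.na(twp$sunrise))
})

test_that("constant-depth rule releases the tag after the programmed window", {
  cfg <- quick_cfg(deployment_days = 40, force_constant_depth_from_day = 21,
                   constant_depth_window_days = 5, dropout = 0)
  env <- generate_environment(cfg)
  trk <- simulate_track(env, cfg, seed = 11)
  ser <- simulate_tag_series(trk, env, cfg, seed = 12)
  expect_identical(ser$deployment$popup_date, cfg$release_date + 25)
  expect_lte(max(as.Date(ser$samples$timestamp, tz = "UTC")),
             cfg$release_date + 25)
})
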