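# Filtering, smoothing, sampling and diffusion estimation.

test_that("forward filter reproduces hand-computed small cases", {
  k <- make_kernel(matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE))
  ff <- forward_filter(make_lik(c(1, 0)), k, list(make_lik(c(1, 1))))
  expect_equal(ff$filtered[, 2], c(0.7, 0.3))

  # uniform everything on a doubly-balanced kernel stays uniform
  ffu <- forward_filter(make_lik(c(0.5, 0.5)), k,
                        replicate(4, make_lik(c(1, 1)), simplify = FALSE))
  expect_true(all(abs(ffu$filtered - 0.5) < 1e-12))

  # identity kernel with a point anchor is absorbing
  ki <- make_kernel(diag(3))
  ffi <- forward_filter(make_lik(c(0, 1, 0)), ki,
                        replicate(3, make_lik(c(1, 1, 1)), simplify = FALSE))
  expect_true(all(ffi$filtered[2, ] == 1))

  expect_error(forward_filter(make_lik(c(0, 0)), k, list()),
               class = "psat_init_error")
})

test_that("backward smoother matches hand cases and handles single days", {
  k <- make_kernel(matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE))
  ff <- forward_filter(make_lik(c(1, 0)), k, list(make_lik(c(1, 1))))
  sm <- backward_smooth(ff, k)
  expect_equal(sm[, 1], c(1, 0))          # day 0 anchor is retained
  expect_equal(sm[, 2], ff$filtered[, 2]) # final smoothed = final filtered

  ff1 <- forward_filter(make_lik(c(0.3, 0.7)), k, list())
  expect_equal(backward_smooth(ff1, k), ff1$filtered)
})

test_that("smoothed marginals equal exhaustive path enumeration", {
  set.seed(2024)
  for (i in 1:25) {
    inst <- random_hmm_instance()
    k <- make_kernel(inst$W)
    ff <- forward_filter(make_lik(inst$prior), k,
                         lapply(inst$liks, make_lik))
    sm <- backward_smooth(ff, k)
    oracle <- enum_marginals(inst$prior, inst$W, inst$liks)
    expect_equal(sm, oracle, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(colSums(sm), rep(1, inst$days), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("log-likelihood is invariant to state relabelling", {
  set.seed(5)
  inst <- random_hmm_instance(max_cells = 10, max_days = 4)
  k <- make_kernel(inst$W)
  ff <- forward_filter(make_lik(inst$prior), k, lapply(inst$liks, make_lik))
  perm <- sample(inst$K)
  kp <- make_kernel(inst$W[perm, perm])
  ffp <- forward_filter(make_lik(inst$prior[perm]), kp,
                        lapply(inst$liks, function(v) make_lik(v[perm])))
  expect_equal(ff$log_lik, ffp$log_lik, tolerance = 1e-12)
})

test_that("diffusion estimation recovers the generating scale and flags flat data", {
  # random-walk fish (bias 0) whose daily displacement matches D = 1000
  cfg <- quick_cfg(bias = 0, speed_km_day = 56, speed_sd_km = 23,
                   deployment_days = 60, sst_obs_noise_sd_c = 0.2,
                   twilight_noise_sd_min = 2, release_lon = 2)
  env <- generate_environment(cfg)
  trk <- simulate_track(env, cfg, seed = 61)
  ser <- simulate_tag_series(trk, env, cfg, seed = 62)
  g <- build_grid(env, 1, "latlon")
  obs <- daily_observations(ser)
  par <- obs_params(sigma_sst_c = 0.3, sigma_lon_deg = 0.6,
                    sigma_lat_deg = 1.0)
  dep <- ser$deployment
  dates <- seq(dep$release_date, dep$popup_date, by = "day")
  anchor0 <- anchor_surface(g, dep$release_lat, dep$release_lon, 0)
  liks <- lapply(seq_along(dates)[-1], function(t) {
    r <- which(obs$date == dates[t])
    if (length(r)) daily_likelihood(obs[r, ], g, env, par) else NULL
  })
  D_hat <- estimate_diffusion(anchor0, liks, g, bounds = c(100, 8000))
  expect_gte(as.numeric(D_hat), 500)
  expect_lte(as.numeric(D_hat), 2000)
  # optimality against the bounds
  ll_at <- function(D) forward_filter(anchor0, movement_kernel(g, D),
                                      liks)$log_lik
  expect_gte(attr(D_hat, "log_lik"), ll_at(100))
  expect_gte(attr(D_hat, "log_lik"), ll_at(8000))

  # anchors only: no movement information
  flat_liks <- replicate(5, NULL, simplify = FALSE)
  expect_warning(D_flat <- estimate_diffusion(anchor0, flat_liks, g,
                                              bounds = c(100, 1000)),
                 "flat")
  expect_equal(as.numeric(D_flat), 550)
})

test_that("FFBS sampling is coherent, reproducible and matches the posterior", {
  # degenerate posterior: all paths identical
  ki <- make_kernel(diag(3))
  ff <- forward_filter(make_lik(c(0, 1, 0)), ki,
                       replicate(3, make_lik(c(0, 1, 0)), simplify = FALSE))
  s <- sample_tracks(ff, ki, n = 50, seed = 1)
  expect_true(all(s$cells == 2))
  expect_error(sample_tracks(ff, ki, n = 0), class = "psat_input_error")

  set.seed(99)
  inst <- random_hmm_instance(max_cells = 9, max_days = 5)
  k <- make_kernel(inst$W)
  ff <- forward_filter(make_lik(inst$prior), k, lapply(inst$liks, make_lik))
  s1 <- sample_tracks(ff, k, n = 400, seed = 7)
  s2 <- sample_tracks(ff, k, n = 400, seed = 7)
  expect_identical(s1$cells, s2$cells)

  # empirical day marginals approach the smoothed marginals
  sm <- backward_smooth(ff, k)
  big <- sample_tracks(ff, k, n = 10000, seed = 8)
  for (t in seq_len(ncol(sm))) {
    emp <- tabulate(big$cells[, t], nbins = inst$K) / 10000
    expect_lt(0.5 * sum(abs(emp - sm[, t])), 0.05)
  }
})

test_that("mean tracks average on the sphere and handle the dateline", {
  grid <- list(lat = c(10, 10), lon = c(179, -179), n = 2)
  samples <- structure(list(cells = matrix(c(1, 2), 2, 3), n = 2,
                            grid = grid, dates = 0:2, seed = 1),
                       class = "track_samples")
  mt <- mean_track(samples)
  expect_equal(abs(mt$mean_lon), rep(180, 3), tolerance = 1e-9)
  expect_equal(mt$mean_lat, rep(10, 3), tolerance = 0.01)

  one <- structure(list(cells = matrix(2, 5, 4), n = 5, grid = grid,
                        dates = 0:3, seed = 1), class = "track_samples")
  mt1 <- mean_track(one)
  expect_equal(mt1$mean_lat, rep(10, 4))
  expect_equal(mt1$mean_lon, rep(-179, 4))
  expect_equal(mt1$angular_sd_deg, rep(0, 4))

  # MC mean approaches the exact smoothed posterior mean
  set.seed(17)
  inst <- random_hmm_instance(max_cells = 9, max_days = 5)
  k <- make_kernel(inst$W)
  ff <- forward_filter(make_lik(inst$prior), k, lapply(inst$liks, make_lik))
  sm <- backward_smooth(ff, k)
  g9 <- list(lat = 50 + rep(0:2, 3), lon = rep(0:2, each = 3), n = inst$K)
  g9$lat <- g9$lat[seq_len(inst$K)]; g9$lon <- g9$lon[seq_len(inst$K)]
  s <- sample_tracks(ff, k, n = 10000, seed = 4, grid = g9, dates = NULL)
  mt <- mean_track(s)
  for (t in seq_len(ncol(sm))) {
    exact <- psatHMM:::sphere_mean(g9$lat, g9$lon, w = sm[, t])
    expect_lt(great_circle_distance(exact["lat"], exact["lon"],
                                    mt$mean_lat[t], mt$mean_lon[t]), 5)
  }
})

test_that("track comparison measures great-circle separation", {
  a <- data.frame(date = as.Date("2010-05-01") + 0:4,
                  mean_lat = seq(55, 56, length.out = 5),
                  mean_lon = rep(0, 5))
  expect_equal(compare_tracks(a, a)$daily_km, rep(0, 5))
  b <- a; b$mean_lat <- b$mean_lat + 1
  cmp <- compare_tracks(a, b)
  expect_equal(cmp$daily_km, rep(111.19, 5), tolerance = 1e-3)
  expect_equal(cmp$mean_km, 111.19, tolerance = 1e-3)
  b2 <- b[-1, ]
  expect_error(compare_tracks(a, b2), class = "psat_alignment_error")
})
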