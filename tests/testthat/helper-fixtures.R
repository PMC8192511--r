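# Small, fully controlled fixtures built in code.

# hand-built environment grid: constant-depth ocean with optional land cells
# and an SST field that is a known linear function of latitude (+ offsets)
tiny_env <- function(nlat = 4, nlon = 4, lat0 = 50, lon0 = 0, res = 1,
                     land = NULL, sst_base = 10, sst_slope = -0.5,
                     bathy = 1000) {
  lat <- lat0 + (seq_len(nlat) - 1) * res
  lon <- lon0 + (seq_len(nlon) - 1) * res
  sst <- array(0, c(12, nlat, nlon))
  for (m in 1:12) sst[m, , ] <- matrix(sst_base + sst_slope * (lat - lat0),
                                       nlat, nlon)
  lm <- matrix(FALSE, nlat, nlon)
  if (!is.null(land)) lm[land] <- TRUE
  b <- matrix(bathy, nlat, nlon)
  b[lm] <- 0
  env_grid(lat, lon, sst, b, lm)
}

# a fast small-scale simulation setup
quick_cfg <- function(...) {
  sim_config(lat_range = c(50, 65), lon_range = c(-12, 15),
             deployment_days = 15, ...)
}

# likelihood surface straight from values (bypasses the observation model)
make_lik <- function(values, date = as.Date("2010-06-01")) {
  structure(list(date = date, values = values, components = "test",
                 degenerate = all(values <= 0)),
            class = "likelihood_surface")
}

# wrap an arbitrary row-stochastic matrix as a movement kernel
make_kernel <- function(W) {
  structure(list(W = methods::as(Matrix::Matrix(W, sparse = TRUE),
                                 "CsparseMatrix"),
                 D = NA_real_, radius_km = NA_real_, n = nrow(W)),
            class = "movement_kernel")
}

# minimal fit-shaped object for the residency functions
fake_fit <- function(smoothed, grid = NULL, tag_id = "f1") {
  K <- nrow(smoothed)
  if (is.null(grid))
    grid <- list(lat = rep(50, K), lon = seq_len(K), n = K)
  list(smoothed = smoothed, grid = grid,
       deployment = list(tag_id = tag_id))
}

point_rd <- function(K, at, grid = NULL) {
  v <- numeric(K); v[at] <- 1
  psatHMM:::new_residency(v, grid %||% list(lat = rep(0, K), lon = seq_len(K)),
                          "p", 1L, 20L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
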