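# Filtering, smoothing, diffusion estimation and track sampling.
# All recursions run in linear space with per-day renormalisation; the
# accumulated normalisers give the data log-likelihood.

#' Forward filter
#'
#' `filtered(t) = normalise(lik(t) * kernel-prediction of filtered(t-1))`,
#' starting from the day-0 anchor. Days whose likelihood is `NULL` (no data)
#' or degenerate (all zero, e.g. an impossible SST match) fall back to the
#' prediction alone and are recorded, not fatal.
#'
#' @param anchor0 `likelihood_surface` for day 0 (usually the release
#'   anchor); must be normalisable.
#' @param kernel a [movement_kernel()].
#' @param liks list of `likelihood_surface` (or `NULL`) for days 1..T.
#' @return object of class `hmm_filter`: `filtered` (K x (T+1) matrix),
#'   `log_lik`, and `degenerate_days` (1-based day indices that used the
#'   prediction only).
#' @export
forward_filter <- function(anchor0, kernel, liks) {
  a0 <- anchor0$values
  if (length(a0) != kernel$n)
    psat_stop("anchor surface does not match the kernel grid",
              "psat_shape_error")
  if (sum(a0) <= 0)
    psat_stop("day-0 anchor is all zero; cannot initialise the filter",
              "psat_init_error")
  T_ <- length(liks)
  f <- matrix(0, kernel$n, T_ + 1)
  f[, 1] <- a0 / sum(a0)
  log_lik <- 0
  degen <- integer()
  for (t in seq_len(T_)) {
    pred <- as.numeric(Matrix::crossprod(kernel$W, f[, t]))
    lik <- liks[[t]]
    if (is.null(lik) || lik$degenerate) {
      if (!is.null(lik)) degen <- c(degen, t)
      f[, t + 1] <- pred / sum(pred)
    } else {
      if (length(lik$values) != kernel$n)
        psat_stop("likelihood surface does not match the kernel grid",
                  "psat_shape_error")
      v <- pred * lik$values
      nrm <- sum(v)
      if (nrm <= 0 || !is.finite(nrm)) {
        degen <- c(degen, t)
        f[, t + 1] <- pred / sum(pred)
      } else {
        f[, t + 1] <- v / nrm
        log_lik <- log_lik + log(nrm)
      }
    }
  }
  structure(list(filtered = f, log_lik = log_lik, degenerate_days = degen,
                 n_days = T_),
            class = "hmm_filter")
}

#' Backward smoother
#'
#' Standard Rauch-style backward pass on the filtered surfaces:
#' `smoothed(T) = filtered(T)` and, descending,
#' `smoothed(t) = filtered(t) * W %*% (smoothed(t+1) / prediction(t+1))`.
#'
#' @param ff an [forward_filter()] result.
#' @param kernel the same [movement_kernel()].
#' @return K x (T+1) matrix of smoothed surfaces, each summing to 1.
#' @export
backward_smooth <- function(ff, kernel) {
  f <- ff$filtered
  if (nrow(f) != kernel$n)
    psat_stop("filter and kernel grids differ", "psat_shape_error")
  T1 <- ncol(f)
  s <- matrix(0, nrow(f), T1)
  s[, T1] <- f[, T1]
  if (T1 == 1) return(s)
  for (t in (T1 - 1):1) {
    pred <- as.numeric(Matrix::crossprod(kernel$W, f[, t]))
    ratio <- ifelse(pred > 0, s[, t + 1] / pred, 0)
    v <- f[, t] * as.numeric(kernel$W %*% ratio)
    s[, t] <- v / sum(v)
  }
  s
}

#' Maximum-likelihood diffusion coefficient
#'
#' Golden-section search of the forward-filter log-likelihood over `D`
#' within `bounds`, to 1 % relative tolerance. A flat likelihood (no
#' movement information, e.g. anchors only) triggers a warning and returns
#' the interval midpoint.
#'
#' @param anchor0,liks as in [forward_filter()].
#' @param grid the [build_grid()] state grid.
#' @param bounds positive finite `c(lower, upper)` in km^2/day.
#' @param rel_tol relative convergence tolerance on `D` (default 0.01).
#' @param truncation_sds kernel truncation, see [movement_kernel()].
#' @return the fitted `D` (km^2/day) with the achieved log-likelihood as
#'   attribute `"log_lik"`.
#' @export
estimate_diffusion <- function(anchor0, liks, grid, bounds = c(10, 5000),
                               rel_tol = 0.01, truncation_sds = 4) {
  if (any(!is.finite(bounds)) || any(bounds <= 0) || bounds[1] >= bounds[2])
    stop_input("bounds must be a positive finite increasing interval")
  ll <- function(D) forward_filter(anchor0,
                                   movement_kernel(grid, D, truncation_sds),
                                   liks)$log_lik
  gr <- (sqrt(5) - 1) / 2
  a <- bounds[1]; b <- bounds[2]
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- ll(c_); fd <- ll(d_)
  fa <- ll(a); fb <- ll(b)
  if (max(fa, fb, fc, fd) - min(fa, fb, fc, fd) < 1e-8) {
    warning("log-likelihood is flat in D over the bounds; returning midpoint")
    out <- mean(bounds)
    attr(out, "log_lik") <- ll(out)
    return(out)
  }
  while ((b - a) > rel_tol * (a + b) / 2) {
    if (fc >= fd) { b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- ll(c_)
    } else { a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- ll(d_)
    }
  }
  out <- (a + b) / 2
  attr(out, "log_lik") <- ll(out)
  out
}

#' Sample joint trajectories (forward-filter backward-sample)
#'
#' Draws exact joint-posterior trajectories: the final state from the last
#' filtered surface, then each earlier state from the filtered surface
#' reweighted by the kernel column of the following draw. Temporal
#' coherence is what distinguishes these from independent draws off the
#' smoothed marginals.
#'
#' @param ff an [forward_filter()] result.
#' @param kernel the same [movement_kernel()].
#' @param n number of trajectories (the route reconstruction default is
#'   1000).
#' @param seed RNG seed; identical seeds give identical sample sets.
#' @param grid optional [build_grid()] (enables coordinate lookup later).
#' @param dates optional vector of dates for the columns.
#' @return object of class `track_samples`: integer matrix `cells`
#'   (n x days) of state indices plus the grid/date references.
#' @export
sample_tracks <- function(ff, kernel, n = 1000, seed = 1,
                          grid = NULL, dates = NULL) {
  if (n <= 0) stop_input("number of sampled tracks must be positive")
  f <- ff$filtered
  T1 <- ncol(f)
  set.seed(seed %% .Machine$integer.max)
  cells <- matrix(0L, n, T1)
  cells[, T1] <- sample.int(nrow(f), n, replace = TRUE, prob = f[, T1])
  W <- kernel$W  # CsparseMatrix: columns are cheap to slice
  p <- W@p; ri <- W@i; xs <- W@x
  for (t in seq(T1 - 1, 1)) {
    ft <- f[, t]
    for (j in unique(cells[, t + 1])) {
      take <- which(cells[, t + 1] == j)
      nz <- if (p[j + 1] > p[j]) (p[j] + 1):p[j + 1] else integer()
      idx <- ri[nz] + 1L
      w <- ft[idx] * xs[nz]
      if (!length(w) || sum(w) <= 0) { idx <- seq_along(ft); w <- ft }
      cells[take, t] <- idx[sample.int(length(idx), length(take),
                                       replace = TRUE, prob = w)]
    }
  }
  structure(list(cells = cells, n = n, seed = seed, grid = grid,
                 dates = dates),
            class = "track_samples")
}

#' Mean route of a trajectory sample set
#'
#' Per-day mean of the sampled positions taken on the unit sphere
#' (dateline-safe), with per-day dispersion as the angular standard
#' deviation about the mean (degrees).
#'
#' @param samples a [sample_tracks()] result carrying a grid.
#' @param grid,dates overrides if not embedded in `samples`.
#' @return data.frame `date`, `mean_lat`, `mean_lon`, `sd_lat`, `sd_lon`,
#'   `angular_sd_deg`.
#' @export
mean_track <- function(samples, grid = samples$grid, dates = samples$dates) {
  if (is.null(grid)) stop_input("a state grid is required to map cells")
  T1 <- ncol(samples$cells)
  if (is.null(dates)) dates <- seq_len(T1) - 1
  rows <- lapply(seq_len(T1), function(t) {
    la <- grid$lat[samples$cells[, t]]
    lo <- grid$lon[samples$cells[, t]]
    m <- sphere_mean(la, lo)
    ang <- great_circle_distance(m["lat"], m["lon"], la, lo) /
      (pi * EARTH_RADIUS_KM / 180)
    data.frame(mean_lat = unname(m["lat"]), mean_lon = unname(m["lon"]),
               sd_lat = sd(la),
               sd_lon = rad2deg(sqrt(-2 * log(max(1e-12, sqrt(
                 mean(cos(deg2rad(lo)))^2 + mean(sin(deg2rad(lo)))^2))))),
               angular_sd_deg = sqrt(mean(ang^2)))
  })
  out <- cbind(data.frame(date = dates), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Compare two mean tracks
#'
#' @param a,b mean-track data.frames (same dates).
#' @return list with the per-day great-circle separations (km) and their
#'   mean and maximum.
#' @export
compare_tracks <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(as.character(a$date) == as.character(b$date)))
    psat_stop("tracks cover different dates", "psat_alignment_error")
  d <- great_circle_distance(a$mean_lat, a$mean_lon, b$mean_lat, b$mean_lon)
  list(daily_km = d, mean_km = mean(d), max_km = max(d))
}
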