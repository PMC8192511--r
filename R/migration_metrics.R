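# Migratory and behavioural summaries: distance-from-release profiles,
# weekly-distance regression, depth-use fractions, monthly thermal niche.

#' Weekly distance-from-release profile
#'
#' Weeks are consecutive 7-day blocks counted from the release date (days
#' 1-7 form week 1); each week's value is the mean over its days of the
#' straight-line (great-circle) distance between the day's route position
#' and the release location.
#'
#' @param track a mean-track data.frame (`date`, `mean_lat`, `mean_lon`),
#'   e.g. from [fitted.psat_fit()], whose first row is the release day.
#' @param release_lat,release_lon the release location, degrees.
#' @return data.frame `week`, `mean_km`, `n_days`; a final partial week is
#'   kept and flagged in the `partial` column.
#' @export
weekly_distance_profile <- function(track, release_lat, release_lon) {
  if (nrow(track) < 2) stop_input("track must cover at least one day")
  day <- seq_len(nrow(track)) - 1           # day 0 = release
  d <- great_circle_distance(release_lat, release_lon,
                             track$mean_lat, track$mean_lon)
  keep <- day >= 1
  week <- ceiling(day[keep] / 7)
  agg <- tapply(d[keep], week, mean)
  n <- tapply(d[keep], week, length)
  out <- data.frame(week = as.integer(names(agg)),
                    mean_km = as.numeric(agg),
                    n_days = as.integer(n))
  out$partial <- out$n_days < 7
  if (nrow(track) - 1 < 7)
    attr(out, "single_partial_week") <- TRUE
  out
}

#' Regression of weekly distance on week index
#'
#' Ordinary least squares of the weekly mean distance on the week number,
#' restricted to the first `max_week` weeks after release (default 11, the
#' transit phase to the feeding areas).
#'
#' @param profile a [weekly_distance_profile()] (or a group-mean version
#'   with `week` and `mean_km` columns).
#' @param max_week last week included in the fit.
#' @return list `slope` (km/week), `intercept` (km), `r_squared`.
#' @export
distance_regression <- function(profile, max_week = 11) {
  p <- profile[profile$week >= 1 & profile$week <= max_week, ]
  if (nrow(p) < 3)
    psat_stop("need at least 3 weekly points within max_week",
              "psat_insufficient_data_error")
  fit <- lm(mean_km ~ week, data = p)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Depth-use summary over a period
#'
#' Fraction of retained samples deeper than `threshold_m` within a period
#' of the deployment, plus the maximum recorded depth. The
#' `"post-migration"` preset keeps samples strictly more than 77 days
#' (11 weeks) after release.
#'
#' @param series a [tag_series()].
#' @param threshold_m depth threshold in m (default 10).
#' @param period `NULL` (whole record), `"post-migration"`, or
#'   `c(first_day, last_day)` in days after release (inclusive).
#' @return list `fraction_deeper` (proportion of samples deeper than the
#'   threshold), `max_depth_m`, `n_samples`, `empty` flag.
#' @export
depth_use <- function(series, threshold_m = 10, period = NULL) {
  if (threshold_m <= 0) stop_input("threshold must be positive")
  s <- series$samples
  day_after <- as.numeric(as.Date(s$timestamp, tz = "UTC") -
                            series$deployment$release_date)
  if (is.null(period)) {
    keep <- rep(TRUE, nrow(s))
  } else if (identical(period, "post-migration")) {
    keep <- day_after > 77
  } else {
    keep <- day_after >= period[1] & day_after <= period[2]
  }
  s <- s[keep, , drop = FALSE]
  if (!nrow(s))
    return(list(fraction_deeper = NA_real_, max_depth_m = NA_real_,
                n_samples = 0L, empty = TRUE))
  list(fraction_deeper = mean(s$depth_m > threshold_m),
       max_depth_m = max(s$depth_m),
       n_samples = nrow(s), empty = FALSE)
}

#' Monthly thermal niche by group
#'
#' Five-number temperature summary per (group, calendar month) over all
#' retained samples (no depth filter: this is the temperature where the
#' fish resided, not the SST proxy), with the number of fish and the number
#' of recordings contributing. Months without samples are omitted.
#'
#' @param series_by_group named list of lists of [tag_series()].
#' @return data.frame `group`, `month`, `n_fish`, `n_records`, `t_min`,
#'   `t_q1`, `t_median`, `t_q3`, `t_max`.
#' @export
monthly_thermal_niche <- function(series_by_group) {
  rows <- list()
  for (g in names(series_by_group)) {
    per_fish <- lapply(series_by_group[[g]], function(sr) {
      s <- sr$samples
      data.frame(fish = sr$deployment$tag_id,
                 month = as.integer(format(as.Date(s$timestamp, tz = "UTC"),
                                           "%m")),
                 temp = s$temperature_c)
    })
    all <- do.call(rbind, per_fish)
    for (m in sort(unique(all$month))) {
      x <- all[all$month == m, ]
      q <- quantile(x$temp, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      rows[[length(rows) + 1]] <-
        data.frame(group = g, month = m,
                   n_fish = length(unique(x$fish)), n_records = nrow(x),
                   t_min = q[1], t_q1 = q[2], t_median = q[3],
                   t_q3 = q[4], t_max = q[5])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
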