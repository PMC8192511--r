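# Mean-sun solar geometry shared by the simulator (emits twilights) and the
# observation model (inverts them). The sun crosses the -0.833 deg altitude
# at sunrise/sunset (refraction + solar radius). A mean sun is used: local
# solar noon is 12:00 UTC minus lon/15 h with no equation-of-time term, so
# twilight midpoints map to longitude exactly and the same geometry that
# generated a twilight pair can invert it without bias.

SUN_ALTITUDE_DEG <- -0.833

# approximate solar declination (degrees) for a day-of-year
solar_declination <- function(doy) {
  -23.44 * cos(2 * pi * (doy + 10) / 365.25)
}

# day-of-year values where the declination crosses zero
EQUINOX_DOY <- c(81, 264)

# day length in hours at latitude/declination; 0 = polar night, 24 = polar day
day_length_hours <- function(lat_deg, decl_deg) {
  phi <- deg2rad(lat_deg); dec <- deg2rad(decl_deg)
  cosH <- (sin(deg2rad(SUN_ALTITUDE_DEG)) - sin(phi) * sin(dec)) /
    (cos(phi) * cos(dec))
  ifelse(cosH >= 1, 0, ifelse(cosH <= -1, 24, 2 * rad2deg(acos(cosH)) / 15))
}

#' Sunrise and sunset times for a position and date
#'
#' Mean-sun twilight model: local solar noon at `12 - lon/15` hours UTC,
#' half-day length from the standard hour-angle relation at a sun altitude
#' of -0.833 degrees. Above the polar circles the pair is missing (`NA`).
#'
#' @param lat,lon position in decimal degrees.
#' @param date a `Date` (UTC calendar day).
#' @return list with POSIXct `sunrise`, `sunset` (NA during polar day/night)
#'   and the day length in hours.
#' @export
twilight_times <- function(lat, lon, date) {
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  L <- day_length_hours(lat, solar_declination(doy))
  if (L <= 0 || L >= 24)
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA),
                day_length_h = L))
  noon <- 12 - lon / 15
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  list(sunrise = midnight + (noon - L / 2) * 3600,
       sunset = midnight + (noon + L / 2) * 3600,
       day_length_h = L)
}

#' Light-based position from a twilight pair
#'
#' Longitude comes from the local-noon offset (15 degrees per hour between
#' 12:00 UTC and the sunrise/sunset midpoint). Latitude is recovered by
#' inverting the day-length/declination relation. Near the equinoxes the day
#' length is ~12 h at every latitude and the inversion is degenerate, so
#' `lat_usable` is `FALSE` within `equinox_window_days` of an equinox or when
#' the day length is within 10 minutes of 12 h; the longitude remains valid.
#'
#' @param sunrise,sunset POSIXct twilight times (UTC).
#' @param date the `Date` the pair belongs to.
#' @param equinox_window_days half-width of the latitude blackout around each
#'   equinox, days (default 10).
#' @return list with `lon`, `lat` (degrees, `NA` if unrecoverable) and
#'   logical `lat_usable`.
#' @export
light_position <- function(sunrise, sunset, date, equinox_window_days = 10) {
  if (is.na(sunrise) || is.na(sunset))
    return(list(lon = NA_real_, lat = NA_real_, lat_usable = FALSE))
  if (sunset <= sunrise)
    stop_input("sunset must follow sunrise")
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  mid_h <- as.numeric(difftime(sunrise, midnight, units = "hours")) +
    as.numeric(difftime(sunset, sunrise, units = "hours")) / 2
  lon <- wrap_lon(15 * (12 - mid_h))
  L <- as.numeric(difftime(sunset, sunrise, units = "hours"))

  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  dec <- solar_declination(doy)
  lat <- invert_day_length(L, dec)

  near_equinox <- any(abs(doy - EQUINOX_DOY) <= equinox_window_days)
  usable <- !is.na(lat) && !near_equinox && abs(L - 12) >= 10 / 60
  list(lon = lon, lat = lat, lat_usable = usable)
}

# solve sin(h0) = sin(phi) sin(dec) + cos(phi) cos(dec) cos(H0) for phi,
# H0 the half day length as an hour angle. Linear-in-(sin,cos) form gives a
# closed-form pair; the candidate reproducing the observed day length wins.
invert_day_length <- function(day_length_h, decl_deg) {
  H0 <- deg2rad(day_length_h / 2 * 15)
  dec <- deg2rad(decl_deg)
  A <- sin(dec)
  B <- cos(dec) * cos(H0)
  R <- sqrt(A^2 + B^2)
  s <- sin(deg2rad(SUN_ALTITUDE_DEG)) / R
  if (abs(s) > 1) return(NA_real_)
  alpha <- atan2(B, A)
  cand <- rad2deg(c(asin(s) - alpha, pi - asin(s) - alpha))
  cand <- wrap_lon(cand)                       # fold into (-180, 180)
  cand <- cand[abs(cand) <= 90]
  if (!length(cand)) return(NA_real_)
  err <- abs(day_length_hours(cand, decl_deg) - day_length_h)
  cand[which.min(err)]
}
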