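# Spherical-earth geodesy. All distances use the mean earth radius
# 6371.0 km; coordinates are decimal degrees, longitude in [-180, 180).

EARTH_RADIUS_KM <- 6371.0

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap longitudes into [-180, 180)
#' @param lon numeric vector of longitudes in degrees.
#' @return wrapped longitudes.
#' @keywords internal
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0 km, the "straight line"
#' migration distance used throughout the package (release-to-pop-up
#' distances, weekly distance profiles, movement kernel).
#'
#' @param lat1,lon1 coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 coordinates of the second point(s), decimal degrees.
#' @return distance(s) in km; vectorised with recycling.
#' @examples
#' great_circle_distance(0, 0, 1, 0)   # one degree of latitude, ~111.19 km
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop_input("latitudes must lie in [-90, 90]")
  if (any(!is.finite(c(lat1, lon1, lat2, lon2))))
    stop_input("coordinates must be finite")
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(wrap_lon(lon2 - lon1))
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# initial great-circle bearing from point 1 to point 2, degrees in [0, 360)
gc_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dlam <- deg2rad(wrap_lon(lon2 - lon1))
  th <- atan2(sin(dlam) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam))
  (rad2deg(th) + 360) %% 360
}

# destination point after travelling dist_km on initial bearing (degrees)
gc_destination <- function(lat, lon, bearing_deg, dist_km) {
  p1 <- deg2rad(lat); l1 <- deg2rad(lon)
  th <- deg2rad(bearing_deg)
  d <- dist_km / EARTH_RADIUS_KM
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1),
                   cos(d) - sin(p1) * sin(p2))
  c(lat = rad2deg(p2), lon = wrap_lon(rad2deg(l2)))
}

# mean position on the unit sphere (dateline-safe); optional weights
sphere_mean <- function(lat, lon, w = NULL) {
  p <- deg2rad(lat); l <- deg2rad(lon)
  if (is.null(w)) w <- rep(1, length(lat))
  w <- w / sum(w)
  x <- sum(w * cos(p) * cos(l))
  y <- sum(w * cos(p) * sin(l))
  z <- sum(w * sin(p))
  c(lat = rad2deg(atan2(z, sqrt(x^2 + y^2))),
    lon = wrap_lon(rad2deg(atan2(y, x))))
}
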