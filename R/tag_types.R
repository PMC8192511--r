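# Core tag containers: deployment metadata and the archived time series.

#' Tag deployment metadata
#'
#' @param tag_id character identifier.
#' @param population population / tagging-area label.
#' @param release_date `Date` (UTC calendar day) of release.
#' @param release_lat,release_lon release position, decimal degrees.
#' @param popup_date optional `Date` the tag surfaced.
#' @param popup_lat,popup_lon optional Argos pop-up position.
#' @param body_length_cm,body_mass_kg optional fish size at tagging.
#' @return an object of class `tag_deployment`.
#' @export
tag_deployment <- function(tag_id, population, release_date,
                           release_lat, release_lon,
                           popup_date = NULL, popup_lat = NULL,
                           popup_lon = NULL, body_length_cm = NULL,
                           body_mass_kg = NULL) {
  release_date <- as.Date(release_date)
  if (abs(release_lat) > 90) stop_validation("release_lat out of [-90, 90]")
  if (release_lon < -180 || release_lon >= 180)
    stop_validation("release_lon out of [-180, 180)")
  if (!is.null(popup_date)) {
    popup_date <- as.Date(popup_date)
    if (popup_date < release_date)
      stop_validation("popup_date precedes release_date")
  }
  for (v in c(body_length_cm, body_mass_kg))
    if (!is.null(v) && v <= 0) stop_validation("body size must be positive")
  structure(list(tag_id = as.character(tag_id),
                 population = as.character(population),
                 release_date = release_date,
                 release_lat = release_lat, release_lon = release_lon,
                 popup_date = popup_date,
                 popup_lat = popup_lat, popup_lon = popup_lon,
                 body_length_cm = body_length_cm,
                 body_mass_kg = body_mass_kg),
            class = "tag_deployment")
}

#' Archived tag time series
#'
#' Samples lie on a fixed programming interval (15-60 min); transmission
#' dropout leaves gaps, so successive timestamps must be strictly increasing
#' and separated by integer multiples of the base interval.
#'
#' @param deployment a [tag_deployment()].
#' @param samples data.frame with POSIXct `timestamp` (UTC), `depth_m` >= 0
#'   and `temperature_c`.
#' @param twilights optional data.frame with `date`, `sunrise_utc`,
#'   `sunset_utc` (POSIXct, may be NA above the polar circle).
#' @return an object of class `tag_series`.
#' @export
tag_series <- function(deployment, samples, twilights = NULL) {
  stopifnot(inherits(deployment, "tag_deployment"))
  need <- c("timestamp", "depth_m", "temperature_c")
  if (!all(need %in% names(samples)))
    stop_format(paste("samples missing column(s):",
                      paste(setdiff(need, names(samples)), collapse = ", ")))
  if (nrow(samples)) {
    bad <- which(samples$depth_m < 0)
    if (length(bad))
      stop_validation(paste0("negative depth on row(s) ",
                             paste(head(bad, 5), collapse = ", ")))
    dt <- diff(as.numeric(samples$timestamp)) / 60
    if (any(dt <= 0))
      stop_validation("timestamps must be strictly increasing")
    if (length(dt)) {
      base <- min(dt)
      if (base < 15 - 1e-6 || base > 60 + 1e-6)
        stop_validation("sampling interval must lie in [15, 60] minutes")
      if (any(abs(dt / base - round(dt / base)) > 1e-6))
        stop_validation("sample spacing must be a multiple of the base interval")
    }
  }
  if (!is.null(twilights)) {
    tw_need <- c("date", "sunrise_utc", "sunset_utc")
    if (!all(tw_need %in% names(twilights)))
      stop_format("twilights must have date, sunrise_utc, sunset_utc")
    twilights$date <- as.Date(twilights$date)
  }
  structure(list(deployment = deployment, samples = samples,
                 twilights = twilights),
            class = "tag_series")
}

#' @export
print.tag_series <- function(x, ...) {
  d <- x$deployment
  cat(sprintf("<tag_series> %s (%s): %d samples", d$tag_id, d$population,
              nrow(x$samples)))
  if (nrow(x$samples))
    cat(sprintf(", %s to %s", format(min(x$samples$timestamp)),
                format(max(x$samples$timestamp))))
  cat("\n")
  invisible(x)
}
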