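# Plain-text interchange. Tag series travel as a CSV of samples
# (timestamp,depth_m,temperature_c; ISO-8601 UTC timestamps, "." decimal,
# empty string = missing) with a JSON metadata companion and a twilight CSV.
# Gridded fields (environment, residency surfaces) travel as JSON with
# explicit axes, which round-trips at full double precision.

ts_fmt <- "%Y-%m-%dT%H:%M:%SZ"

companion_paths <- function(path) {
  base <- sub("\\.csv$", "", path)
  list(samples = path, meta = paste0(base, "_meta.json"),
       twilight = paste0(base, "_twilight.csv"))
}

#' Write a tag series to CSV + JSON companions
#'
#' @param series a [tag_series()].
#' @param path path of the sample CSV; `<base>_meta.json` and
#'   `<base>_twilight.csv` are written alongside.
#' @return `path`, invisibly.
#' @export
write_tag_series <- function(series, path) {
  p <- companion_paths(path)
  s <- series$samples
  out <- data.frame(timestamp = strftime(s$timestamp, ts_fmt, tz = "UTC"),
                    depth_m = s$depth_m, temperature_c = s$temperature_c)
  write.csv(out, p$samples, row.names = FALSE, quote = FALSE)
  dep <- series$deployment
  meta <- lapply(unclass(dep), function(v)
    if (inherits(v, "Date")) format(v) else v)
  jsonlite::write_json(meta, p$meta, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  tw <- series$twilights
  if (!is.null(tw)) {
    twout <- data.frame(
      date = format(tw$date),
      sunrise_utc = ifelse(is.na(tw$sunrise_utc), "",
                           strftime(tw$sunrise_utc, ts_fmt, tz = "UTC")),
      sunset_utc = ifelse(is.na(tw$sunset_utc), "",
                          strftime(tw$sunset_utc, ts_fmt, tz = "UTC")))
    write.csv(twout, p$twilight, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a tag series written by [write_tag_series()]
#'
#' Mandatory sample columns are `timestamp`, `depth_m`, `temperature_c`;
#' unparseable rows are rejected with their row numbers, and invariant
#' violations (negative depth, non-monotone timestamps) are errors, never
#' silently repaired.
#'
#' @param path path of the sample CSV.
#' @return a validated [tag_series()].
#' @export
read_tag_series <- function(path) {
  p <- companion_paths(path)
  if (!file.exists(p$samples)) stop_format(paste("no such file:", p$samples))
  raw <- read.csv(p$samples, colClasses = "character")
  need <- c("timestamp", "depth_m", "temperature_c")
  if (!all(need %in% names(raw)))
    stop_format(paste("missing mandatory column(s):",
                      paste(setdiff(need, names(raw)), collapse = ", ")))
  ts <- as.POSIXct(raw$timestamp, format = ts_fmt, tz = "UTC")
  depth <- suppressWarnings(as.numeric(raw$depth_m))
  temp <- suppressWarnings(as.numeric(raw$temperature_c))
  bad <- which(is.na(ts) | is.na(depth))
  if (length(bad))
    stop_format(paste0("unparseable field(s) on row(s) ",
                       paste(head(bad, 5), collapse = ", ")))
  samples <- data.frame(timestamp = ts, depth_m = depth,
                        temperature_c = temp)

  if (!file.exists(p$meta))
    stop_format(paste("missing metadata companion:", p$meta))
  meta <- jsonlite::read_json(p$meta, simplifyVector = TRUE)
  dep <- tag_deployment(meta$tag_id, meta$population, meta$release_date,
                        meta$release_lat, meta$release_lon,
                        popup_date = meta$popup_date,
                        popup_lat = meta$popup_lat,
                        popup_lon = meta$popup_lon,
                        body_length_cm = meta$body_length_cm,
                        body_mass_kg = meta$body_mass_kg)

  tw <- NULL
  if (file.exists(p$twilight)) {
    twraw <- read.csv(p$twilight, colClasses = "character")
    tw <- data.frame(
      date = as.Date(twraw$date),
      sunrise_utc = as.POSIXct(ifelse(twraw$sunrise_utc == "", NA,
                                      twraw$sunrise_utc),
                               format = ts_fmt, tz = "UTC"),
      sunset_utc = as.POSIXct(ifelse(twraw$sunset_utc == "", NA,
                                     twraw$sunset_utc),
                              format = ts_fmt, tz = "UTC"))
  }
  tag_series(dep, samples, tw)
}

#' Write an environment grid as JSON
#' @param env an [env_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  obj <- list(lat = env$lat, lon = env$lon, month = 1:12,
              sst = env$sst, bathymetry = env$bathymetry,
              land_mask = env$land_mask)
  jsonlite::write_json(obj, path, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read an environment grid written by [write_environment()]
#' @param path input path.
#' @return a validated [env_grid()].
#' @export
read_environment <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("lat", "lon", "sst", "bathymetry", "land_mask")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop_format(paste("missing variable(s):", paste(miss, collapse = ", ")))
  env_grid(obj$lat, obj$lon, array(obj$sst, dim(obj$sst)),
           matrix(obj$bathymetry, nrow(obj$bathymetry)),
           matrix(as.logical(obj$land_mask), nrow(obj$land_mask)))
}

#' Write a mean track to CSV
#' @param track a mean-track data.frame (see [mean_track()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  if (is.null(track) || !nrow(track))
    stop_input("track is empty; nothing to write")
  out <- data.frame(date = format(as.Date(track$date)),
                    mean_lat = track$mean_lat, mean_lon = track$mean_lon,
                    sd_lat = track$sd_lat, sd_lon = track$sd_lon)
  write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mean track written by [write_track()]
#' @param path input path.
#' @return data.frame `date`, `mean_lat`, `mean_lon`, `sd_lat`, `sd_lon`.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  raw <- read.csv(path)
  need <- c("date", "mean_lat", "mean_lon", "sd_lat", "sd_lon")
  if (!all(need %in% names(raw)))
    stop_format("track file lacks mandatory columns")
  raw$date <- as.Date(raw$date)
  raw
}

#' Write a residency distribution as JSON
#' @param rd a [residency_distribution()] (must be normalised).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residency <- function(rd, path) {
  if (any(rd$values < 0) || abs(sum(rd$values) - 1) > 1e-9)
    stop_validation("residency distribution must be normalised")
  obj <- list(lat = rd$grid$lat, lon = rd$grid$lon, rd = rd$values,
              source = rd$source, n_fish = rd$n_fish,
              fish_days = rd$fish_days)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a residency distribution written by [write_residency()]
#' @param path input path.
#' @return a `residency_distribution` (grid holds cell coordinates only).
#' @export
read_residency <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("lat", "lon", "rd") %in% names(obj)))
    stop_format("residency file lacks lat/lon/rd")
  if (any(obj$rd < 0) || abs(sum(obj$rd) - 1) > 1e-9)
    stop_validation("stored residency distribution is not normalised")
  new_residency(obj$rd, list(lat = obj$lat, lon = obj$lon),
                obj$source %||% "file", obj$n_fish %||% NA_integer_,
                obj$fish_days %||% NA_integer_)
}
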