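#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over
#' coordinates; arguments are recycled to a common length.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1)   # one degree of arc on the equator, ~111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  r <- 6371
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  # clamp against rounding just past 1 for antipodal points
  2 * r * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]", call. = FALSE)
  if (any(lon <= -180 | lon > 180))
    stop("longitude out of range (-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Construct a foraging trip object
#'
#' A trip is an ordered set of GPS fixes for one bird on one excursion from
#' the colony. Fixes must strictly increase in time.
#'
#' @param bird_id,trip_id Identifiers (coerced to character).
#' @param time Fix times: `POSIXct` or numeric seconds since epoch (UTC).
#' @param lat,lon Fix coordinates, decimal degrees.
#' @param colony Length-2 numeric `(lat, lon)` of the central place.
#' @return An object of class `ee_trip`: a list with elements `bird_id`,
#'   `trip_id`, `fixes` (data.frame `time`, `lat`, `lon`) and `colony`.
#' @export
ee_trip <- function(bird_id, trip_id, time, lat, lon, colony) {
  if (inherits(time, "POSIXct")) time <- as.numeric(time)
  if (length(time) < 2) stop("a trip needs at least 2 fixes", call. = FALSE)
  if (length(lat) != length(time) || length(lon) != length(time))
    stop("time, lat, lon must have equal length", call. = FALSE)
  check_coords(lat, lon)
  o <- order(time)
  time <- time[o]; lat <- lat[o]; lon <- lon[o]
  if (any(diff(time) == 0))
    stop(sprintf("duplicate timestamps in trip '%s'", trip_id[1]),
         call. = FALSE)
  structure(list(
    bird_id = as.character(bird_id[1]),
    trip_id = as.character(trip_id[1]),
    fixes = data.frame(time = time, lat = lat, lon = lon),
    colony = as.numeric(colony)
  ), class = "ee_trip")
}

#' @export
print.ee_trip <- function(x, ...) {
  cat(sprintf("<ee_trip> bird %s trip %s: %d fixes, %.2f days\n",
              x$bird_id, x$trip_id, nrow(x$fixes),
              diff(range(x$fixes$time)) / 86400))
  invisible(x)
}

parse_track_times <- function(ts) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  out <- rep(NA_real_, length(ts))
  for (f in fmts) {
    need <- is.na(out)
    if (!any(need)) break
    out[need] <- as.numeric(strptime(ts[need], f, tz = "UTC"))
  }
  out
}

#' Read GPS tracks and split them into foraging trips
#'
#' Reads a delimited track table (columns `bird_id`, `trip_id`, `timestamp`,
#' `lat`, `lon`; timestamps ISO-8601 UTC), removes fixes at the nest (within
#' `colony_radius_km` of the colony), groups the remainder by
#' `(bird_id, trip_id)` and sorts by time. Trips left with fewer than two
#' fixes are dropped with a warning.
#'
#' @param path Path to a comma-delimited track file with a header row.
#' @param colony Length-2 numeric `(lat, lon)` of the colony.
#' @param colony_radius_km Radius around the colony treated as "at the
#'   nest"; default 2 km.
#' @return Named list of [ee_trip] objects (names are `bird_id.trip_id`).
#' @export
read_tracks <- function(path, colony, colony_radius_km = 2) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(bird_id = "character",
                                        trip_id = "character"))
  need <- c("bird_id", "trip_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(raw)))
    stop("track file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tt <- suppressWarnings(parse_track_times(raw$timestamp))
  if (anyNA(tt)) {
    bad <- which(is.na(tt))[1]
    stop(sprintf("unparseable timestamp at row %d: '%s'",
                 bad, raw$timestamp[bad]), call. = FALSE)
  }
  badc <- which(!is.finite(raw$lat) | !is.finite(raw$lon) |
                  abs(raw$lat) > 90 | raw$lon <= -180 | raw$lon > 180)
  if (length(badc))
    stop(sprintf("invalid coordinates at row %d", badc[1]), call. = FALSE)
  at_nest <- haversine_km(raw$lat, raw$lon, colony[1], colony[2]) <=
    colony_radius_km
  kept <- raw[!at_nest, , drop = FALSE]
  kept$time <- tt[!at_nest]
  trips <- list()
  dropped <- character()
  for (key in unique(paste(kept$bird_id, kept$trip_id, sep = "."))) {
    g <- kept[paste(kept$bird_id, kept$trip_id, sep = ".") == key, ]
    if (nrow(g) < 2) {
      dropped <- c(dropped, key)
      next
    }
    trips[[key]] <- ee_trip(g$bird_id[1], g$trip_id[1],
                            g$time, g$lat, g$lon, colony)
  }
  n_all_nest <- setdiff(unique(paste(raw$bird_id, raw$trip_id, sep = ".")),
                        c(names(trips), dropped))
  if (length(dropped) || length(n_all_nest))
    warning(sprintf("%d trip(s) dropped (< 2 fixes away from the colony)",
                    length(dropped) + length(n_all_nest)), call. = FALSE)
  trips
}

#' Per-trip summary metrics
#'
#' Trip duration (days between first and last fix), total distance (sum of
#' great-circle step lengths, km) and maximum range (largest distance from
#' the colony, km).
#'
#' @param trip An [ee_trip].
#' @param colony `(lat, lon)`; defaults to the trip's own colony.
#' @return One-row data.frame: `duration_days`, `total_distance_km`,
#'   `max_range_km`, `n_fixes`.
#' @export
trip_metrics <- function(trip, colony = trip$colony) {
  f <- trip$fixes
  n <- nrow(f)
  steps <- haversine_km(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
  data.frame(
    duration_days = (f$time[n] - f$time[1]) / 86400,
    total_distance_km = sum(steps),
    max_range_km = max(haversine_km(f$lat, f$lon, colony[1], colony[2])),
    n_fixes = n
  )
}

step_speeds_kmh <- function(trip) {
  f <- trip$fixes
  n <- nrow(f)
  d <- haversine_km(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
  dt <- diff(f$time) / 3600
  if (any(dt <= 0)) stop("zero or negative time step", call. = FALSE)
  d / dt
}

#' Remove on-water drift periods by a speed filter
#'
#' Drops every fix whose arriving step (from the preceding fix) is slower
#' than `vmax_exclusive`; slow tortuous drift on the water would otherwise
#' masquerade as area-restricted search. The first fix of a trip is always
#' retained.
#'
#' By default speeds are judged once, on the original consecutive steps
#' (so a step bridging a removed drift run is not re-examined); with
#' `iterate = TRUE` the rule is re-applied until no slow step remains,
#' which makes the operation idempotent at the cost of eroding fixes
#' adjacent to long drifts.
#'
#' @param trip An [ee_trip] of raw fixes.
#' @param vmax_exclusive Exclusive speed threshold in km/h; default 10.
#' @param iterate Re-apply the rule to a fixed point; default `FALSE`.
#' @return The filtered [ee_trip].
#' @export
speed_filter <- function(trip, vmax_exclusive = 10, iterate = FALSE) {
  repeat {
    v <- step_speeds_kmh(trip)
    keep <- c(TRUE, v >= vmax_exclusive)
    if (sum(keep) == 1)
      warning("all steps slower than the threshold; only the first fix ",
              "kept", call. = FALSE)
    out <- trip
    out$fixes <- trip$fixes[keep, , drop = FALSE]
    rownames(out$fixes) <- NULL
    if (!iterate || all(keep) || nrow(out$fixes) < 2) return(out)
    trip <- out
  }
}

# local equirectangular chart about a reference latitude (km)
ll_to_local_km <- function(lat, lon, ref_lat, ref_lon) {
  kpd <- pi * 6371 / 180
  cbind(x = (lon - ref_lon) * kpd * cos(ref_lat * pi / 180),
        y = (lat - ref_lat) * kpd)
}

local_km_to_ll <- function(x, y, ref_lat, ref_lon) {
  kpd <- pi * 6371 / 180
  cbind(lat = ref_lat + y / kpd,
        lon = ref_lon + x / (kpd * cos(ref_lat * pi / 180)))
}

#' Rediscretize a trip to equidistant along-track steps
#'
#' First-passage-time analysis requires points spaced equally in along-track
#' distance. Points are placed every `step_km` of cumulative great-circle
#' distance by linear interpolation within the original segment, in a local
#' planar chart about the segment midpoint latitude; times are interpolated
#' linearly in distance.
#'
#' @param trip An [ee_trip] (normally speed-filtered first).
#' @param step_km Step length in km; default 1.
#' @return An object of class `ee_path`: data.frame with `lat`, `lon`,
#'   `time`, plus attribute `step_km`.
#' @export
rediscretize <- function(trip, step_km = 1) {
  f <- trip$fixes
  n <- nrow(f)
  seg <- haversine_km(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
  cum <- c(0, cumsum(seg))
  L <- cum[n]
  if (L < step_km) stop("trip too short", call. = FALSE)

  # relative epsilon so a path of length n * step_km (up to rounding)
  # yields n + 1 points with the endpoint included
  n_pts <- floor(L / step_km + 1e-7) + 1
  targets <- pmin((seq_len(n_pts) - 1) * step_km, L)
  # segment index for each target distance: cum[i] <= s < cum[i+1]
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  idx[idx >= n] <- n - 1
  frac <- (targets - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  midlat <- (f$lat[idx] + f$lat[idx + 1]) / 2
  p1 <- ll_to_local_km(f$lat[idx], f$lon[idx], midlat, f$lon[idx])
  p2 <- ll_to_local_km(f$lat[idx + 1], f$lon[idx + 1], midlat, f$lon[idx])
  xi <- p1[, 1] + frac * (p2[, 1] - p1[, 1])
  yi <- p1[, 2] + frac * (p2[, 2] - p1[, 2])
  ll <- local_km_to_ll(xi, yi, midlat, f$lon[idx])
  ti <- f$time[idx] + frac * (f$time[idx + 1] - f$time[idx])
  out <- data.frame(lat = ll[, 1], lon = ll[, 2], time = ti)
  out$lat[1] <- f$lat[1]; out$lon[1] <- f$lon[1]; out$time[1] <- f$time[1]
  structure(out, step_km = step_km, class = c("ee_path", "data.frame"))
}

#' @describeIn ee_trip Plot the track with the colony marked.
#' @param x An `ee_trip`.
#' @param ... Passed to [plot()].
#' @export
plot.ee_trip <- function(x, ...) {
  graphics::plot(x$fixes$lon, x$fixes$lat, type = "l",
                 xlab = "longitude", ylab = "latitude",
                 main = sprintf("bird %s trip %s", x$bird_id, x$trip_id),
                 ...)
  graphics::points(x$colony[2], x$colony[1], pch = 17, col = 2, cex = 1.3)
  invisible(x)
}
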