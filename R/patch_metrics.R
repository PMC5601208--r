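#' Map area-restricted-search segments back to real time
#'
#' Each ARS segment of the path becomes a zone with entry and exit times
#' taken from the interpolated times of its first and one-past-last path
#' point (last point of the path for the final segment).
#'
#' @param trip The source [ee_trip] (used for its identifiers).
#' @param path The `ee_path` the segmentation was computed on.
#' @param labeling An `ee_ars_labeling` from [classify_ars()].
#' @param seg The matching `ee_segmentation`.
#' @return data.frame with one row per ARS zone: `trip_id`, `entry_time`,
#'   `exit_time` (seconds since epoch, UTC), `duration_h`.
#' @export
zones_from_segments <- function(trip, path, labeling, seg) {
  n <- nrow(path)
  ars <- which(labeling$is_ars)
  if (!length(ars))
    return(data.frame(trip_id = character(), entry_time = numeric(),
                      exit_time = numeric(), duration_h = numeric()))
  entry <- path$time[seg$segments$start[ars]]
  exit <- path$time[pmin(seg$segments$end[ars], n)]
  data.frame(trip_id = trip$trip_id, entry_time = entry, exit_time = exit,
             duration_h = (exit - entry) / 3600)
}

#' Count landings inside a zone
#'
#' A landing is a maximal run of consecutive slow raw steps
#' (speed < `vmax` km/h) — a multi-fix sit on the water is one event, not
#' one per fix. A run belongs to the zone whose time interval contains the
#' run's midpoint, so runs straddling a boundary are assigned
#' unambiguously. Counting uses the unfiltered trip: the slow fixes removed
#' before first-passage-time analysis are exactly the landings.
#'
#' @param trip_raw The raw (unfiltered) [ee_trip].
#' @param zone One-row data.frame with `entry_time` and `exit_time`
#'   (seconds since epoch), as produced by [zones_from_segments()].
#' @param vmax Exclusive slow-speed threshold, km/h; default 10.
#' @return Integer count of landings.
#' @export
count_landings <- function(trip_raw, zone, vmax = 10) {
  f <- trip_raw$fixes
  if (zone$entry_time < f$time[1] - 1e-6 ||
      zone$exit_time > f$time[nrow(f)] + 1e-6)
    stop("zone lies outside the trip's time span", call. = FALSE)
  slow <- step_speeds_kmh(trip_raw) < vmax
  if (!any(slow)) return(0L)
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (f$time[starts] + f$time[ends + 1L]) / 2   # step i spans fixes i, i+1
  sum(r$values & mid >= zone$entry_time & mid <= zone$exit_time)
}

# deterministic per-trip RNG stream: a small hash of (global seed, trip id)
# so adding or removing trips never reshuffles the others' draws
trip_seed <- function(global_seed, trip_id) {
  h <- as.numeric(global_seed) %% 2147483647
  for (code in utf8ToInt(as.character(trip_id)))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Assemble the per-trip exploration-exploitation traits
#'
#' Combines the zone table, the area-restricted-search scale and the trip
#' metrics into the four trait values: `n_patches` (number of ARS zones),
#' `size_of_patch_km` (the ARS scale), and `time_in_patch_h` /
#' `foraging_effort` taken from one zone selected uniformly at random
#' (trips differ in zone count, so a single randomly chosen zone keeps one
#' measure per trip). Selection uses a dedicated RNG stream seeded from
#' `(seed, trip_id)`.
#'
#' @param trip The raw [ee_trip].
#' @param zones Zone table from [zones_from_segments()], with a
#'   `n_landings` column already attached (see [count_landings()]).
#' @param ars_scale_km The trip's ARS scale in km.
#' @param seed Global integer seed for the zone selection.
#' @param year Optional year label for downstream models.
#' @return One-row data.frame: identifiers, `year`, `time_in_patch_h`,
#'   `foraging_effort`, `size_of_patch_km`, `n_patches`, plus the
#'   [trip_metrics()] columns. Trait fields are `NA` when the trip has no
#'   ARS zone.
#' @export
assemble_traits <- function(trip, zones, ars_scale_km, seed,
                            year = NA_integer_) {
  tm <- trip_metrics(trip)
  n_patches <- nrow(zones)
  if (n_patches == 0) {
    tip <- NA_real_; eff <- NA_real_
  } else {
    pick <- if (n_patches == 1) 1L else {
      rng <- local_rng(trip_seed(seed, trip$trip_id))
      rng(n_patches)
    }
    tip <- zones$duration_h[pick]
    eff <- zones$n_landings[pick]
  }
  cbind(data.frame(bird_id = trip$bird_id, trip_id = trip$trip_id,
                   year = year, time_in_patch_h = tip,
                   foraging_effort = eff,
                   size_of_patch_km = ars_scale_km,
                   n_patches = n_patches),
        tm)
}

# draw one index in 1..n from an isolated RNG state
local_rng <- function(seed) {
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    runif(20)   # warm up the stream: nearby seeds decorrelate
    sample.int(n, 1L)
  }
}
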