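test_that("haversine matches closed-form arcs and is a metric", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 1), pi * 6371 / 180, tolerance = 1e-4)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-5)
  set.seed(4)
  lat <- runif(30, -80, 80); lon <- runif(30, -179, 180)
  i <- sample(30, 20, TRUE); j <- sample(30, 20, TRUE)
  k <- sample(30, 20, TRUE)
  d_ij <- haversine_km(lat[i], lon[i], lat[j], lon[j])
  expect_equal(d_ij, haversine_km(lat[j], lon[j], lat[i], lon[i]))
  expect_true(all(d_ij >= 0))
  expect_true(all(d_ij <= haversine_km(lat[i], lon[i], lat[k], lon[k]) +
                    haversine_km(lat[k], lon[k], lat[j], lon[j]) + 1e-9))
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, -180, 0, 0), "longitude")
})

test_that("haversine agrees with an independent geodesy library", {
  skip_if_not_installed("geosphere")
  set.seed(11)
  p1 <- cbind(runif(50, -179, 180), runif(50, -85, 85))
  p2 <- cbind(runif(50, -179, 180), runif(50, -85, 85))
  ref <- geosphere::distHaversine(p1, p2, r = 6371)
  expect_equal(haversine_km(p1[, 2], p1[, 1], p2[, 2], p2[, 1]), ref,
               tolerance = 1e-9)
})

test_that("read_tracks removes nest fixes, groups trips, validates input", {
  tr <- fixture_trip("straight_line")
  # first fixes sit at the colony; push the track file through read_tracks
  f <- tempfile(fileext = ".csv")
  fx <- make_fixture("straight_line", colony = COLONY)
  write.csv(fx$tracks, f, row.names = FALSE)
  trips <- read_tracks(f, COLONY, colony_radius_km = 2)
  expect_length(trips, 1)
  # colony-adjacent fixes are gone, the rest are intact and time-sorted
  expect_lt(nrow(trips[[1]]$fixes), nrow(tr$fixes))
  expect_true(all(diff(trips[[1]]$fixes$time) > 0))
  expect_true(all(haversine_km(trips[[1]]$fixes$lat, trips[[1]]$fixes$lon,
                               COLONY[1], COLONY[2]) > 2))

  # a trip entirely at the nest yields an empty set with a warning
  fx0 <- make_fixture("null_colony", colony = COLONY)
  f0 <- tempfile(fileext = ".csv")
  write.csv(fx0$tracks, f0, row.names = FALSE)
  expect_warning(trips0 <- read_tracks(f0, COLONY, 2), "dropped")
  expect_length(trips0, 0)

  # unparseable row errors with its row number
  bad <- fx$tracks
  bad$timestamp[3] <- "not-a-time"
  fb <- tempfile(fileext = ".csv")
  write.csv(bad, fb, row.names = FALSE)
  expect_error(read_tracks(fb, COLONY, 2), "row 3")

  # duplicate timestamp within a trip errors naming the trip
  dup <- fx$tracks
  dup$timestamp[10] <- dup$timestamp[9]
  fd <- tempfile(fileext = ".csv")
  write.csv(dup, fd, row.names = FALSE)
  expect_error(read_tracks(fd, COLONY, 2), "straight_line_1")
})

test_that("synthetic track files round-trip through read_tracks", {
  sim <- simulate_tracks(small_sim(21, n_birds = 2, trips_per_bird = 1))
  f <- tempfile(fileext = ".csv")
  write.csv(sim$tracks, f, row.names = FALSE)
  trips <- read_tracks(f, COLONY, 2)
  for (tr in trips) {
    src <- sim$tracks[sim$tracks$trip_id == tr$trip_id, ]
    src_t <- forageEE:::parse_track_times(src$timestamp)
    at_sea <- haversine_km(src$lat, src$lon, COLONY[1], COLONY[2]) > 2
    expect_equal(tr$fixes$time, src_t[at_sea])
    expect_equal(tr$fixes$lat, src$lat[at_sea])
    expect_equal(tr$fixes$lon, src$lon[at_sea])
  }
})

test_that("trip metrics match definitions and a brute-force oracle", {
  t0 <- as.numeric(as.POSIXct("2013-01-01", tz = "UTC"))
  # two fixes 1 h and ~30 km apart, colony at the first fix
  ll <- forageEE:::local_km_to_ll(c(0, 30), c(0, 0), COLONY[1], COLONY[2])
  tr <- ee_trip("b", "t", c(t0, t0 + 3600), ll[, 1], ll[, 2],
                colony = c(ll[1, 1], ll[1, 2]))
  m <- trip_metrics(tr, colony = c(ll[1, 1], ll[1, 2]))
  expect_equal(m$duration_days, 1 / 24)
  expect_equal(m$total_distance_km, 30, tolerance = 1e-4)
  expect_equal(m$max_range_km, 30, tolerance = 1e-4)
  expect_true(m$max_range_km <= m$total_distance_km + 1e-9)

  # permuting then re-sorting fixes leaves metrics unchanged
  sim <- simulate_tracks(small_sim(31, n_birds = 1, trips_per_bird = 1))
  tr2 <- tracks_to_trip(sim$tracks)
  perm <- sample(nrow(tr2$fixes))
  tr2p <- ee_trip(tr2$bird_id, tr2$trip_id, tr2$fixes$time[perm],
                  tr2$fixes$lat[perm], tr2$fixes$lon[perm], COLONY)
  expect_equal(trip_metrics(tr2p), trip_metrics(tr2))

  # total distance equals an independent pairwise sum
  f <- tr2$fixes
  tot <- 0
  for (i in 2:nrow(f))
    tot <- tot + haversine_km(f$lat[i - 1], f$lon[i - 1], f$lat[i],
                              f$lon[i])
  expect_equal(trip_metrics(tr2)$total_distance_km, tot, tolerance = 1e-12)
})

test_that("speed filter applies the arrival-step rule", {
  t0 <- as.numeric(as.POSIXct("2013-01-01", tz = "UTC"))
  mk_trip <- function(step_km) {
    ll <- forageEE:::local_km_to_ll(cumsum(c(0, step_km)),
                                    rep(0, length(step_km) + 1),
                                    COLONY[1], COLONY[2])
    ee_trip("b", "t", t0 + 3600 * (0:length(step_km)), ll[, 1], ll[, 2],
            COLONY)
  }
  fast <- mk_trip(rep(50, 8))          # all 50 km/h: unchanged
  expect_equal(nrow(speed_filter(fast)$fixes), 9)
  slow <- mk_trip(rep(5, 8))           # all 5 km/h: only the first fix
  expect_warning(fs <- speed_filter(slow), "first fix")
  expect_equal(nrow(fs$fixes), 1)

  # mixed speeds: retained set equals the literal per-step rule
  set.seed(8)
  steps <- sample(c(3, 5, 20, 50), 40, TRUE)
  tr <- mk_trip(steps)
  got <- speed_filter(tr, 10)
  v <- numeric(40)
  for (i in 1:40) v[i] <- haversine_km(tr$fixes$lat[i], tr$fixes$lon[i],
                                       tr$fixes$lat[i + 1],
                                       tr$fixes$lon[i + 1]) /
    ((tr$fixes$time[i + 1] - tr$fixes$time[i]) / 3600)
  expect_equal(got$fixes$time, tr$fixes$time[c(TRUE, v >= 10)])

  # the fixed-point variant is idempotent on realistic tracks
  sim <- simulate_tracks(small_sim(41, n_birds = 2, trips_per_bird = 2))
  f <- tempfile(fileext = ".csv")
  write.csv(sim$tracks, f, row.names = FALSE)
  for (tr in read_tracks(f, COLONY, 2)) {
    f1 <- speed_filter(tr, iterate = TRUE)
    f2 <- speed_filter(f1, iterate = TRUE)
    expect_identical(f1$fixes, f2$fixes)
  }
})

test_that("rediscretization yields equidistant points with linear times", {
  t0 <- as.numeric(as.POSIXct("2013-01-01", tz = "UTC"))
  # due north so the equirectangular chart is geodesic-exact
  ll <- forageEE:::local_km_to_ll(c(0, 0), c(0, 10), COLONY[1], COLONY[2])
  tr <- ee_trip("b", "t", c(t0, t0 + 3600), ll[, 1], ll[, 2], COLONY)
  p <- rediscretize(tr, 1)
  expect_equal(nrow(p), 11)
  d <- haversine_km(p$lat[-11], p$lon[-11], p$lat[-1], p$lon[-1])
  expect_equal(d, rep(1, 10), tolerance = 1e-5)
  expect_equal(diff(p$time), rep(360, 10), tolerance = 1e-4)

  # point count is floor(L / step) + 1 on a drift-filtered synthetic trip;
  # chords never exceed the along-track step
  sim <- simulate_tracks(small_sim(51, n_birds = 1, trips_per_bird = 1))
  tr2 <- speed_filter(tracks_to_trip(sim$tracks))
  L <- trip_metrics(tr2)$total_distance_km
  p2 <- rediscretize(tr2, 1)
  expect_equal(nrow(p2), floor(L / 1) + 1)
  d2 <- haversine_km(p2$lat[-nrow(p2)], p2$lon[-nrow(p2)],
                     p2$lat[-1], p2$lon[-1])
  expect_true(all(d2 <= 1 + 1e-3))
  expect_equal(median(d2), 1, tolerance = 1e-3)
  expect_true(all(diff(p2$time) > 0))

  # on a smooth transit-only trip the spacing is uniform and total
  # distance is preserved within 1%
  sim0 <- simulate_tracks(small_sim(52, n_birds = 1, trips_per_bird = 1,
                                    mean_patches_per_trip = 0,
                                    landing_rate_transit = 0))
  tr0 <- speed_filter(tracks_to_trip(sim0$tracks))
  L0 <- trip_metrics(tr0)$total_distance_km
  p0 <- rediscretize(tr0, 1)
  d0 <- haversine_km(p0$lat[-nrow(p0)], p0$lon[-nrow(p0)],
                     p0$lat[-1], p0$lon[-1])
  # uniform spacing except for windows spanning a heading change (vertex
  # windows deviate by about turn_sd^2 / 8) or the turnaround
  expect_gt(mean(abs(d0 - 1) < 5e-3), 0.98)
  expect_equal(sum(d0), L0, tolerance = 0.01)

  # re-rediscretizing an equidistant path with the same step reproduces it
  tr3 <- ee_trip("b", "t", p$time, p$lat, p$lon, COLONY)
  p3 <- rediscretize(tr3, 1)
  expect_equal(p3$lat, p$lat, tolerance = 1e-6)
  expect_equal(p3$lon, p$lon, tolerance = 1e-6)

  expect_error(rediscretize(ee_trip("b", "t", c(t0, t0 + 60),
                                    c(-46, -46.001), c(51, 51), COLONY),
                            5), "too short")
})
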