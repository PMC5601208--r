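# shared test helpers: fixture -> trip, random path builders, and the
# independent brute-force oracles the implementation is checked against

COLONY <- c(-46, 51)

fixture_trip <- function(name) {
  fx <- make_fixture(name, colony = COLONY)
  tracks_to_trip(fx$tracks)
}

tracks_to_trip <- function(tracks, colony = COLONY) {
  ee_trip(tracks$bird_id[1], tracks$trip_id[1],
          forageEE:::parse_track_times(tracks$timestamp),
          tracks$lat, tracks$lon, colony)
}

# a compact simulation config for unit tests: same movement modes as the
# defaults, smaller geography so trips stay short
small_sim <- function(seed, n_birds = 6, trips_per_bird = 2, ...) {
  args <- list(n_birds = n_birds, trips_per_bird = trips_per_bird,
               patch_dist_min_km = 50, patch_dist_max_km = 120,
               mean_patches_per_trip = 2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# random jagged path as an ee_path: cumulative planar steps about the
# colony, equal nominal spacing not required by fpt_at_point's contract
random_path <- function(n, seed, step_mean = 1) {
  set.seed(seed)
  h <- cumsum(stats::rnorm(n, 0, 0.6))
  d <- stats::rexp(n - 1, 1 / step_mean)
  x <- c(0, cumsum(d * cos(h[-1]))) + stats::runif(1, -5, 5)
  y <- c(0, cumsum(d * sin(h[-1]))) + stats::runif(1, -5, 5)
  ll <- forageEE:::local_km_to_ll(x, y, COLONY[1], COLONY[2])
  tt <- as.numeric(as.POSIXct("2013-02-01", tz = "UTC")) +
    cumsum(c(0, stats::runif(n - 1, 120, 600)))
  structure(data.frame(lat = ll[, 1], lon = ll[, 2], time = tt),
            step_km = NA_real_, class = c("ee_path", "data.frame"))
}

# brute-force first passage time: walk away from point i one step at a
# time in each direction, test the circle crossing directly, interpolate
# the crossing instant within the straddling step
fpt_oracle <- function(path, i, r) {
  n <- nrow(path)
  cross_time <- function(dir) {
    j <- i
    repeat {
      j2 <- j + dir
      if (j2 < 1 || j2 > n) return(NA_real_)
      d1 <- haversine_km(path$lat[i], path$lon[i], path$lat[j], path$lon[j])
      d2 <- haversine_km(path$lat[i], path$lon[i], path$lat[j2],
                         path$lon[j2])
      if (d1 <= r && d2 > r) {
        f <- (r - d1) / (d2 - d1)
        return(path$time[j] + f * (path$time[j2] - path$time[j]))
      }
      j <- j2
    }
  }
  fwd <- cross_time(+1)
  bwd <- cross_time(-1)
  if (is.na(fwd) || is.na(bwd)) return(NA_real_)
  (fwd - bwd) / 3600
}

# exhaustive optimal-contrast search over all partitions of 1..n into k
# segments of length >= lmin (independent of the DP implementation)
contrast_oracle <- function(y, k, lmin) {
  n <- length(y)
  seg_cost <- function(a, b) {
    yy <- y[a:b]
    v <- max(mean(yy^2) - mean(yy)^2, 1e-8 * stats::var(y))
    length(yy) * log(v)
  }
  best <- Inf
  recurse <- function(start, left, acc) {
    if (left == 1) {
      if (n - start + 1 >= lmin) {
        tot <- acc + seg_cost(start, n)
        if (tot < best) best <<- tot
      }
      return(invisible())
    }
    for (end in (start + lmin - 1):(n - (left - 1) * lmin)) {
      recurse(end + 1, left - 1, acc + seg_cost(start, end))
    }
  }
  recurse(1, k, 0)
  best
}

# closed-form method-of-moments variance components for a balanced
# one-way layout (a groups x m replicates)
anova_oneway_vc <- function(y, g) {
  m <- unique(table(g))
  stopifnot(length(m) == 1)
  a <- length(unique(g))
  gm <- tapply(y, g, mean)
  msb <- m * sum((gm - mean(y))^2) / (a - 1)
  msw <- sum((y - gm[as.character(g)])^2) / (a * (m - 1))
  c(v_between = (msb - msw) / m, v_within = msw)
}
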