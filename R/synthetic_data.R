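#' Configuration for the synthetic track generator
#'
#' Defaults emulate central-place foraging of a large procellariiform at a
#' Southern Ocean colony: fixes every 15 min, trips leaving and returning
#' to a colony at 46S 51E, fast directed transit between patches, slow
#' tortuous search inside circular patches, and on-water landings as
#' sub-10 km/h drift runs. Per-bird and per-year random effects act on log
#' patch residence time, and a per-bird boldness covariate scales patch
#' radius multiplicatively.
#'
#' @param n_birds,trips_per_bird,n_years Population design.
#' @param fix_interval_min GPS fix cadence, minutes.
#' @param colony `(lat, lon)` of the colony.
#' @param transit_speed_kmh,transit_turn_sd Transit mode: speed (km/h) and
#'   wrapped-normal turn SD (radians).
#' @param patch_speed_kmh,patch_turn_sd Search mode inside patches.
#' @param patch_radius_km Baseline patch radius, km.
#' @param patch_dist_min_km,patch_dist_max_km Distance range from the
#'   previous location to the next patch centre.
#' @param mean_patches_per_trip Poisson mean of the true patch count.
#' @param residence_base_h Baseline patch residence, hours (log scale
#'   location).
#' @param v_bird,v_year,v_resid Variance components on log residence.
#' @param boldness_sd SD of latent per-bird boldness.
#' @param beta_boldness_on_patch_radius Slope of log patch radius on
#'   boldness.
#' @param landing_rate_in_patch,landing_rate_transit Landing event rates,
#'   events/hour.
#' @param landing_duration_min,landing_speed_kmh Landing run length and
#'   drift speed.
#' @param jitter_km SD of isotropic observation noise on fix positions.
#' @param seed Integer seed.
#' @return List of class `ee_sim_config`.
#' @export
sim_config <- function(n_birds = 30, trips_per_bird = 2, n_years = 3,
                       fix_interval_min = 15, colony = c(-46, 51),
                       transit_speed_kmh = 45, transit_turn_sd = 0.15,
                       patch_speed_kmh = 20, patch_turn_sd = 1.2,
                       patch_radius_km = 30,
                       patch_dist_min_km = 80, patch_dist_max_km = 250,
                       mean_patches_per_trip = 3.15,
                       residence_base_h = 8,
                       v_bird = 0.4, v_year = 0.05, v_resid = 0.6,
                       boldness_sd = 1,
                       beta_boldness_on_patch_radius = -0.13,
                       landing_rate_in_patch = 1.5,
                       landing_rate_transit = 0.1,
                       landing_duration_min = 30,
                       landing_speed_kmh = 2,
                       jitter_km = 0.03, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$fix_interval_min >= 1, cfg$transit_speed_kmh > 0,
            cfg$patch_speed_kmh > 0, cfg$patch_radius_km > 0,
            cfg$mean_patches_per_trip >= 0, cfg$residence_base_h > 0,
            cfg$v_bird >= 0, cfg$v_year >= 0, cfg$v_resid >= 0,
            cfg$landing_speed_kmh > 0, cfg$n_birds >= 1,
            cfg$patch_dist_max_km <= 3000)
  structure(cfg, class = "ee_sim_config")
}

.unit <- function(theta) c(cos(theta), sin(theta))

# one synthetic trip in local planar km about the colony (origin).
# Returns fixes (t, x, y, phase) and per-patch ground truth.
.sim_trip <- function(cfg, t0, radius_b, log_res_mu) {
  dt_h <- cfg$fix_interval_min / 60
  dt_s <- cfg$fix_interval_min * 60
  n_p <- stats::rpois(1, cfg$mean_patches_per_trip)
  tt <- t0; pos <- c(0, 0)
  T <- numeric(0); X <- numeric(0); Y <- numeric(0); PH <- character(0)
  add <- function(phase) {
    T[length(T) + 1L] <<- tt; X[length(X) + 1L] <<- pos[1]
    Y[length(Y) + 1L] <<- pos[2]; PH[length(PH) + 1L] <<- phase
  }
  add("colony")
  land_left <- 0L
  just_landed <- FALSE   # one-fix refractory keeps landing runs separable
  n_land_fix <- max(1L, as.integer(round(cfg$landing_duration_min /
                                           cfg$fix_interval_min)))
  step_to <- function(target, phase, rate) {
    # biased correlated walk toward `target`, with Poisson landing runs
    repeat {
      d <- sqrt(sum((target - pos)^2))
      if (phase == "transit_home" && d <= cfg$transit_speed_kmh * dt_h)
        break
      if (phase == "transit" && d <= radius_b) break
      tt <<- tt + dt_s
      if (land_left > 0L ||
          (!just_landed && stats::runif(1) < rate * dt_h)) {
        if (land_left == 0L) land_left <<- n_land_fix
        pos <<- pos + cfg$landing_speed_kmh * dt_h *
          .unit(stats::runif(1, 0, 2 * pi))
        land_left <<- land_left - 1L
        if (land_left == 0L) just_landed <<- TRUE
        add("landing")
      } else {
        just_landed <<- FALSE
        h <- atan2(target[2] - pos[2], target[1] - pos[1]) +
          stats::rnorm(1, 0, cfg$transit_turn_sd)
        pos <<- pos + cfg$transit_speed_kmh * dt_h * .unit(h)
        add("transit")
      }
      if (length(T) > 2e5) stop("runaway trip simulation", call. = FALSE)
    }
  }
  patches <- NULL
  if (n_p == 0) {
    # exploration-only trip: out to a waypoint and straight back
    wp <- stats::runif(1, cfg$patch_dist_min_km, cfg$patch_dist_max_km) *
      .unit(stats::runif(1, 0, 2 * pi))
    step_to(wp, "transit", cfg$landing_rate_transit)
  }
  for (p in seq_len(n_p)) {
    centre <- pos + stats::runif(1, cfg$patch_dist_min_km,
                                 cfg$patch_dist_max_km) *
      .unit(stats::runif(1, 0, 2 * pi))
    if (sqrt(sum(centre^2)) > 3000)
      centre <- 0.5 * centre  # keep geometry feasible
    step_to(centre, "transit", cfg$landing_rate_transit)
    res_h <- exp(stats::rnorm(1, log_res_mu, sqrt(cfg$v_resid)))
    n_fix <- max(4L, as.integer(round(res_h / dt_h)))
    entry <- tt + dt_s
    h <- stats::runif(1, 0, 2 * pi)
    n_landings <- 0L
    for (i in seq_len(n_fix)) {
      tt <- tt + dt_s
      if (land_left > 0L ||
          (!just_landed &&
             stats::runif(1) < cfg$landing_rate_in_patch * dt_h)) {
        if (land_left == 0L) {
          land_left <- n_land_fix
          n_landings <- n_landings + 1L
        }
        pos <- pos + cfg$landing_speed_kmh * dt_h *
          .unit(stats::runif(1, 0, 2 * pi))
        land_left <- land_left - 1L
        if (land_left == 0L) just_landed <- TRUE
        add("landing")
      } else {
        just_landed <- FALSE
        # full-length steps only: at the boundary the heading is redrawn
        # until the step stays inside, so every search step moves at
        # exactly patch_speed and stays identifiable against drift
        step_len <- cfg$patch_speed_kmh * dt_h
        h <- h + stats::rnorm(1, 0, cfg$patch_turn_sd)
        prop <- pos + step_len * .unit(h)
        tries <- 0L
        while (sqrt(sum((prop - centre)^2)) > radius_b && tries < 30L) {
          h <- h + stats::rnorm(1, 0, 2 * cfg$patch_turn_sd)
          prop <- pos + step_len * .unit(h)
          tries <- tries + 1L
        }
        if (sqrt(sum((prop - centre)^2)) > radius_b) {
          h <- atan2(centre[2] - pos[2], centre[1] - pos[1])
          prop <- pos + step_len * .unit(h)
        }
        pos <- prop
        add("patch")
      }
    }
    patches <- rbind(patches, data.frame(
      patch = p, centre_x = centre[1], centre_y = centre[2],
      radius_km = radius_b, entry_time = entry, exit_time = tt,
      residence_h = res_h, n_landings = n_landings))
  }
  land_left <- 0L
  step_to(c(0, 0), "transit_home", cfg$landing_rate_transit)
  tt <- tt + dt_s; pos <- c(0, 0)
  add("colony")
  list(fixes = data.frame(time = T, x = X, y = Y, phase = PH),
       patches = patches, n_patches = n_p)
}

#' Simulate a tracked population with full ground truth
#'
#' Generates GPS-like tracks, boldness tests and breeding outcomes under
#' the configuration in [sim_config()], recording everything the pipeline
#' is later asked to recover: per-fix behavioural phase, patch geometry
#' and visit intervals, landing counts, latent boldness, and the variance
#' components on log patch residence.
#'
#' @param cfg An `ee_sim_config`.
#' @param dir Optional directory; when given, writes `tracks.csv`,
#'   `boldness.csv`, `breeding.csv` and a `ground_truth.yaml` sidecar.
#' @return List with `tracks` (data.frame `bird_id`, `trip_id`,
#'   `timestamp`, `lat`, `lon`), `boldness_tests`, `breeding` and `truth`
#'   (list: `birds`, `trips`, `patches`, `phases`).
#' @export
simulate_tracks <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  years <- 2010 + seq_len(cfg$n_years) - 1
  u_year <- stats::setNames(stats::rnorm(cfg$n_years, 0, sqrt(cfg$v_year)),
                            years)
  birds <- data.frame(
    bird_id = sprintf("B%03d", seq_len(cfg$n_birds)),
    boldness = stats::rnorm(cfg$n_birds, 0, cfg$boldness_sd),
    u_bird = stats::rnorm(cfg$n_birds, 0, sqrt(cfg$v_bird)))
  birds$patch_radius_km <- cfg$patch_radius_km *
    exp(cfg$beta_boldness_on_patch_radius * birds$boldness)
  tracks <- vector("list", cfg$n_birds * cfg$trips_per_bird)
  phases <- vector("list", length(tracks))
  trip_rows <- vector("list", length(tracks))
  patch_rows <- vector("list", length(tracks))
  k <- 0L
  for (b in seq_len(cfg$n_birds)) {
    trip_years <- sample(years, cfg$trips_per_bird, replace = TRUE)
    for (tr in seq_len(cfg$trips_per_bird)) {
      k <- k + 1L
      yr <- trip_years[tr]
      t0 <- as.numeric(as.POSIXct(sprintf("%d-01-10 00:00:00", yr),
                                  tz = "UTC")) + (tr - 1) * 45 * 86400
      sim <- .sim_trip(cfg, t0, birds$patch_radius_km[b],
                       log(cfg$residence_base_h) + birds$u_bird[b] +
                         u_year[as.character(yr)])
      trip_id <- sprintf("%s_T%02d", birds$bird_id[b], tr)
      f <- sim$fixes
      jx <- stats::rnorm(nrow(f), 0, cfg$jitter_km)
      jy <- stats::rnorm(nrow(f), 0, cfg$jitter_km)
      ll <- local_km_to_ll(f$x + jx, f$y + jy, cfg$colony[1], cfg$colony[2])
      tracks[[k]] <- data.frame(
        bird_id = birds$bird_id[b], trip_id = trip_id,
        timestamp = format(as.POSIXct(f$time, origin = "1970-01-01",
                                      tz = "UTC"), "%Y-%m-%dT%H:%M:%S"),
        lat = ll[, 1], lon = ll[, 2])
      phases[[k]] <- data.frame(bird_id = birds$bird_id[b],
                                trip_id = trip_id, time = f$time,
                                phase = f$phase)
      trip_rows[[k]] <- data.frame(bird_id = birds$bird_id[b],
                                   trip_id = trip_id, year = yr,
                                   n_patches_true = sim$n_patches)
      if (!is.null(sim$patches))
        patch_rows[[k]] <- cbind(trip_id = trip_id, sim$patches)
    }
  }
  truth <- list(birds = birds,
                trips = do.call(rbind, trip_rows),
                patches = do.call(rbind, patch_rows),
                phases = do.call(rbind, phases),
                u_year = u_year)
  boldness_tests <- .sim_boldness(cfg, birds)
  breeding <- .sim_breeding(cfg, birds, truth$trips)
  out <- list(tracks = do.call(rbind, tracks),
              boldness_tests = boldness_tests, breeding = breeding,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$tracks, file.path(dir, "tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(boldness_tests, file.path(dir, "boldness.csv"),
                     row.names = FALSE)
    utils::write.csv(breeding, file.path(dir, "breeding.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(
      birds = birds, trips = truth$trips, patches = truth$patches,
      u_year = as.list(u_year)), file.path(dir, "ground_truth.yaml"))
  }
  out
}

# ordinal 0-4 approach-test scores: latent boldness + observer offset +
# observation-number drift, rounded and clamped
.sim_boldness <- function(cfg, birds) {
  observers <- sprintf("O%d", 1:4)
  obs_off <- stats::rnorm(length(observers), 0, 0.3)
  rows <- list()
  for (b in seq_len(nrow(birds))) {
    n_tests <- sample(3:6, 1)
    obs <- sample(seq_along(observers), n_tests, replace = TRUE)
    latent <- 2 + birds$boldness[b] + obs_off[obs] -
      0.05 * seq_len(n_tests) + stats::rnorm(n_tests, 0, 0.4)
    rows[[b]] <- data.frame(bird_id = birds$bird_id[b],
                            observer = observers[obs],
                            obs_number = seq_len(n_tests),
                            score = pmin(4, pmax(0, round(latent))))
  }
  do.call(rbind, rows)
}

.sim_breeding <- function(cfg, birds, trips) {
  by <- unique(trips[, c("bird_id", "year")])
  by$success <- stats::rbinom(nrow(by), 1, 0.6)
  by
}

#' Deterministic analytic test fixtures
#'
#' Small hand-constructed tracks whose first-passage-time and segmentation
#' answers are known in closed form: `straight_line` (constant-speed due
#' east transit), `single_patch` and `two_patch` (fast transits joined to
#' dense slow search in 30 km circles), `null_colony` (all fixes at the
#' nest).
#'
#' @param name One of `"straight_line"`, `"single_patch"`, `"two_patch"`,
#'   `"null_colony"`.
#' @param colony `(lat, lon)`; default `c(-46, 51)`.
#' @return List with `tracks` (track-file data.frame) and `expected`
#'   (named list of analytically known values).
#' @export
make_fixture <- function(name = c("straight_line", "single_patch",
                                  "two_patch", "null_colony"),
                         colony = c(-46, 51)) {
  name <- match.arg(name)
  t0 <- as.numeric(as.POSIXct("2013-01-10 00:00:00", tz = "UTC"))
  dt <- 15 * 60
  mk <- function(x, y, bird = "FX1", trip = paste0(name, "_1")) {
    ll <- local_km_to_ll(x, y, colony[1], colony[2])
    data.frame(bird_id = bird, trip_id = trip,
               timestamp = format(as.POSIXct(t0 + dt * (seq_along(x) - 1),
                                             origin = "1970-01-01",
                                             tz = "UTC"),
                                  "%Y-%m-%dT%H:%M:%S"),
               lat = ll[, 1], lon = ll[, 2])
  }
  # deterministic dense slow search in a circle: spiral-like rosette,
  # step length fixed so per-step speed stays above the drift filter
  patch_pts <- function(centre, r = 30, n = 48, step = 4) {
    x <- centre[1]; y <- centre[2]; h <- 0.3
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      h <- h + 2.4
      px <- x + step * cos(h); py <- y + step * sin(h)
      dc <- sqrt((px - centre[1])^2 + (py - centre[2])^2)
      if (dc > r) {
        px <- centre[1] + (2 * r - dc) / dc * (px - centre[1])
        py <- centre[2] + (2 * r - dc) / dc * (py - centre[2])
      }
      x <- px; y <- py; xs[i] <- x; ys[i] <- y
    }
    cbind(xs, ys)
  }
  transit_x <- function(from, to, step = 12.5)
    seq(from, to, by = if (to >= from) step else -step)
  if (name == "straight_line") {
    x <- transit_x(0, 737.5)           # 50 km/h at 15-min fixes
    return(list(tracks = mk(x, rep(0, length(x))),
                expected = list(speed_kmh = 50, fpt_h_at_r = function(r)
                  2 * r / 50)))
  }
  if (name == "null_colony") {
    n <- 10
    return(list(tracks = mk(0.2 * cos(1:n), 0.2 * sin(1:n)),
                expected = list(n_trips = 0)))
  }
  out1 <- transit_x(0, 150)
  p1 <- patch_pts(c(180, 0))
  if (name == "single_patch") {
    back <- transit_x(p1[nrow(p1), 1], 0)
    x <- c(out1, p1[, 1], back)
    y <- c(rep(0, length(out1)), p1[, 2], rep(p1[nrow(p1), 2],
                                              length(back)))
    return(list(tracks = mk(x, y),
                expected = list(n_ars_zones = 1, patch_radius_km = 30)))
  }
  # two_patch: second dense circle 160 km north of the first
  p2 <- patch_pts(c(180, 160))
  bridge_y <- seq(p1[nrow(p1), 2], 160, by = 12.5)
  back <- transit_x(p2[nrow(p2), 1], 0)
  x <- c(out1, p1[, 1], rep(p1[nrow(p1), 1], length(bridge_y)), p2[, 1],
         back)
  y <- c(rep(0, length(out1)), p1[, 2], bridge_y, p2[, 2],
         rep(p2[nrow(p2), 2], length(back)))
  list(tracks = mk(x, y),
       expected = list(n_ars_zones = 2, patch_radius_km = 30))
}
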