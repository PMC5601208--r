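#' Default pipeline configuration
#'
#' All tunable parameters of the trajectory-to-statistics pipeline with
#' their reference defaults: colony location and exclusion radius, the
#' on-water speed filter, the rediscretization step, the first-passage-time
#' radius grid, the segmentation tuning (`seg_kmax`, `seg_lmin`,
#' `seg_threshold_S`), and the bootstrap size for repeatability.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    colony_lat = -46, colony_lon = 51, colony_radius_km = 2,
    speed_filter_kmh = 10, step_km = 1,
    fpt_radii_min_km = 2, fpt_radii_max_km = 400, fpt_n_radii = 50,
    fpt_min_defined = 5,
    seg_kmax = 30, seg_lmin = 5, seg_threshold_S = 0.75,
    n_boot = 1000, global_seed = 1,
    tracks_file = NULL, boldness_file = NULL, breeding_file = NULL,
    metadata_file = NULL, out_dir = "ee_output")
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config key(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Load a pipeline configuration file
#'
#' Reads a YAML key-value file and merges it over [default_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  do.call(default_config, yaml::read_yaml(path))
}

# per-trip trait extraction; any stage failure is rethrown naming the
# stage and the offending trip
.trip_stage <- function(stage, trip_id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for trip '%s': %s", stage, trip_id,
                 conditionMessage(e)), call. = FALSE))
}

#' Extract exploration-exploitation traits from trips
#'
#' Runs the trajectory stages on each trip: speed filter, rediscretization,
#' first-passage-time profile, area-restricted-search scale, penalized
#' segmentation of the FPT series at that scale, ARS classification, zone
#' construction, landing counts and trait assembly. Trips whose FPT
#' profile has no defined variance (too short to cross the smallest
#' radius) yield missing trait fields with a warning.
#'
#' @param trips List of [ee_trip] objects, e.g. from [read_tracks()].
#' @param config Configuration list from [default_config()].
#' @return List with `traits` (data.frame, one row per trip), `profiles`
#'   (named list of `ee_fpt_profile`), `segments` (data.frame of per-trip
#'   segment tables: `trip_id`, `segment_index`, `start_idx`, `end_idx`,
#'   `mean_fpt_h`, `is_ars`).
#' @export
extract_traits <- function(trips, config = default_config()) {
  radii <- fpt_default_radii(config$fpt_radii_min_km,
                             config$fpt_radii_max_km, config$fpt_n_radii)
  traits <- vector("list", length(trips))
  profiles <- vector("list", length(trips))
  segtabs <- vector("list", length(trips))
  for (i in seq_along(trips)) {
    trip <- trips[[i]]
    id <- trip$trip_id
    year <- as.integer(format(as.POSIXct(trip$fixes$time[1],
                                         origin = "1970-01-01",
                                         tz = "UTC"), "%Y"))
    filt <- .trip_stage("speed_filter", id,
                        speed_filter(trip, config$speed_filter_kmh))
    path <- .trip_stage("rediscretize", id,
                        rediscretize(filt, config$step_km))
    prof <- .trip_stage("fpt_profile", id, suppressWarnings(
      fpt_profile(path, radii, config$fpt_min_defined)))
    profiles[[i]] <- prof
    if (!is.finite(prof$ars_scale_km)) {
      warning("trip '", id, "': no defined FPT variance; traits missing",
              call. = FALSE)
      traits[[i]] <- assemble_traits(trip, zones_from_segments(
        trip, path, structure(list(is_ars = logical(0)),
                              class = "ee_ars_labeling"),
        NULL), NA_real_, config$global_seed, year)
      next
    }
    series_raw <- prof$fpt[, match(prof$ars_scale_km, prof$radii)]
    series <- .trip_stage("segmentation", id, interpolate_na(series_raw))$x
    seg <- .trip_stage("segmentation", id,
                       lavielle_segment(series, config$seg_kmax,
                                        config$seg_lmin,
                                        config$seg_threshold_S))
    lab <- classify_ars(seg, series_raw)
    zones <- .trip_stage("zones", id,
                         zones_from_segments(trip, path, lab, seg))
    if (nrow(zones))
      zones$n_landings <- vapply(seq_len(nrow(zones)), function(z)
        .trip_stage("landings", id,
                    count_landings(trip, zones[z, ],
                                   config$speed_filter_kmh)),
        numeric(1))
    traits[[i]] <- assemble_traits(trip, zones, prof$ars_scale_km,
                                   config$global_seed, year)
    segtabs[[i]] <- data.frame(
      trip_id = id, segment_index = seq_len(seg$k),
      start_idx = seg$segments$start, end_idx = seg$segments$end,
      mean_fpt_h = lab$segment_mean_fpt, is_ars = lab$is_ars)
  }
  list(traits = do.call(rbind, traits), profiles = profiles,
       segments = do.call(rbind, segtabs))
}

# canonical trait names used by the statistics stage
.trait_cols <- c(time_in_patch = "time_in_patch_h",
                 foraging_effort = "foraging_effort",
                 size_of_patch = "size_of_patch_km",
                 n_patches = "n_patches")

#' Trait statistics: correlations, strategy score, repeatability, drivers
#'
#' The statistics stage of the pipeline. Builds the trait matrix (one
#' randomly selected trait set per trip), computes pairwise Pearson
#' correlations, the PCA strategy score (PC1, log(x+2) transformed),
#' per-bird boldness estimates, repeatability of the strategy score and
#' every trait, boldness driver tests, trip-metric associations and
#' binary fitness models where the corresponding inputs are supplied.
#' Correlations and the PCA use the raw traits; the mixed models see the
#' traits on the log scale (`log` for durations and scales, `log(x + 1)`
#' for counts), standardized, so estimates are reported on the logged
#' scale.
#'
#' @param traits Trait table from [extract_traits()].
#' @param boldness_tests Optional approach-test table (`bird_id`,
#'   `observer`, `obs_number`, `score`).
#' @param breeding Optional breeding table (`bird_id`, `year`, `success`).
#' @param metadata Optional bird metadata (`bird_id`, `age`, `sex`) which
#'   switches the driver tests to the full boldness + age + sex + age:sex
#'   model.
#' @param config Configuration list.
#' @return List with components `correlations`, `pca`, `scores`,
#'   `boldness`, `repeatability`, `drivers`, `trip_metric_models`,
#'   `fitness` (entries `NULL` when their inputs are absent).
#' @export
ee_analysis <- function(traits, boldness_tests = NULL, breeding = NULL,
                        metadata = NULL, config = default_config()) {
  tm <- traits[, .trait_cols]
  colnames(tm) <- names(.trait_cols)
  corr <- pearson_matrix(tm)
  pca <- pca_ee(tm)
  scores <- data.frame(traits[pca$rows, c("bird_id", "trip_id", "year")],
                       pc1 = pca$scores, pc1_log = pca$transformed_scores)
  dat <- cbind(traits, pc1 = NA_real_, pc1_log = NA_real_)
  dat$pc1[pca$rows] <- pca$scores
  dat$pc1_log[pca$rows] <- pca$transformed_scores
  # responses enter the mixed models on the log scale: durations and
  # scales are log-normal-like, counts get log(x + 1)
  dat$time_in_patch <- log(dat$time_in_patch_h)
  dat$size_of_patch <- log(dat$size_of_patch_km)
  dat$foraging_effort <- log1p(dat$foraging_effort)
  dat$n_patches <- log1p(dat$n_patches)
  responses <- c("pc1_log", names(.trait_cols))
  dat <- standardize_traits(dat, c(responses, "duration_days",
                                   "total_distance_km", "max_range_km"))
  bold <- NULL
  if (!is.null(boldness_tests)) {
    bold <- boldness_scores(boldness_tests)
    dat$boldness <- bold$estimate[match(dat$bird_id, bold$bird_id)]
  }
  if (!is.null(metadata)) {
    dat$age <- metadata$age[match(dat$bird_id, metadata$bird_id)]
    dat$sex <- factor(metadata$sex[match(dat$bird_id, metadata$bird_id)])
  }
  rep_list <- lapply(responses, function(rv) {
    if (all(is.na(dat[[rv]]))) return(NULL)
    r <- repeatability(dat, rv, n_boot = config$n_boot,
                       seed = config$global_seed)
    data.frame(response = rv, r = r$r, ci_low = r$ci_low,
               ci_high = r$ci_high, p = r$p,
               v_bird = r$vc$v_bird, v_year = r$vc$v_year,
               v_resid = r$vc$v_resid)
  })
  rep_tab <- do.call(rbind, rep_list)
  drivers <- NULL
  if (!is.null(bold)) {
    use_meta <- !is.null(metadata)
    drv <- if (use_meta) c("boldness", "age", "sex") else "boldness"
    intn <- if (use_meta) "age:sex" else NULL
    drivers <- do.call(rbind, lapply(responses, function(rv) {
      if (all(is.na(dat[[rv]]))) return(NULL)
      d <- driver_test(dat, rv, drivers = drv, interaction = intn)
      cbind(response = rv, as.data.frame(d))
    }))
  }
  tmm <- do.call(rbind, lapply(
    c("duration_days", "total_distance_km", "max_range_km"),
    function(mcol) {
      d <- trip_metric_association(dat, mcol, response = "pc1_log")
      cbind(response = "pc1_log", as.data.frame(d))
    }))
  fitness <- NULL
  if (!is.null(breeding)) {
    dat$success <- breeding$success[match(paste(dat$bird_id, dat$year),
                                          paste(breeding$bird_id,
                                                breeding$year))]
    fitness <- do.call(rbind, lapply(responses, function(rv) {
      if (all(is.na(dat[[rv]]))) return(NULL)
      fm <- tryCatch(fitness_model(dat, rv), error = function(e) {
        warning("fitness model for '", rv, "' failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(fm)) return(NULL)
      cbind(response = "success", as.data.frame(fm))
    }))
  }
  list(correlations = corr,
       pca = data.frame(trait = rownames(pca$loadings), pca$loadings,
                        row.names = NULL),
       variance_explained = pca$variance_explained,
       scores = scores, boldness = bold, repeatability = rep_tab,
       drivers = drivers, trip_metric_models = tmm, fitness = fitness,
       data = dat)
}

#' Run the full pipeline from a configuration
#'
#' Reads the track (and optional boldness / breeding / metadata) files
#' named in the configuration, extracts per-trip traits and runs the
#' statistics stage, writing every intermediate and final table to the
#' output directory along with a run log.
#'
#' @param config Configuration list (see [default_config()] /
#'   [load_config()]).
#' @return Invisibly, the list of results (traits plus the [ee_analysis()]
#'   components).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.null(config$tracks_file))
    stop("config$tracks_file is required", call. = FALSE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out, "run_log.txt")
  logln <- function(...) cat(sprintf(...), "\n", sep = "",
                             file = log_file, append = TRUE)
  cat("", file = log_file)
  logln("forageEE %s | seed %d | %s",
        as.character(utils::packageVersion("forageEE")),
        config$global_seed, format(Sys.time(), tz = "UTC"))
  trips <- read_tracks(config$tracks_file,
                       c(config$colony_lat, config$colony_lon),
                       config$colony_radius_km)
  logln("read %d trip(s) from %s", length(trips), config$tracks_file)
  tr <- extract_traits(trips, config)
  utils::write.csv(tr$traits, file.path(out, "trip_traits.csv"),
                   row.names = FALSE)
  if (!is.null(tr$segments))
    utils::write.csv(tr$segments, file.path(out, "segments.csv"),
                     row.names = FALSE)
  prof_tab <- do.call(rbind, lapply(seq_along(tr$profiles), function(i)
    data.frame(trip_id = trips[[i]]$trip_id,
               radius_km = tr$profiles[[i]]$radii,
               var_log_fpt = tr$profiles[[i]]$var_log_fpt)))
  utils::write.csv(prof_tab, file.path(out, "fpt_variance_profiles.csv"),
                   row.names = FALSE)
  read_opt <- function(f) if (!is.null(f)) utils::read.csv(
    f, stringsAsFactors = FALSE, colClasses = c(bird_id = "character"))
  res <- ee_analysis(tr$traits,
                     boldness_tests = read_opt(config$boldness_file),
                     breeding = read_opt(config$breeding_file),
                     metadata = read_opt(config$metadata_file),
                     config = config)
  utils::write.csv(res$scores, file.path(out, "ee_scores.csv"),
                   row.names = FALSE)
  ve_row <- data.frame(trait = "variance_explained",
                       t(res$variance_explained))
  names(ve_row) <- names(res$pca)
  pca_rep <- rbind(res$pca, ve_row)
  utils::write.csv(pca_rep, file.path(out, "pca_report.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$correlations$r),
                   file.path(out, "correlations.csv"))
  if (!is.null(res$boldness))
    utils::write.csv(res$boldness, file.path(out, "boldness.csv"),
                     row.names = FALSE)
  if (!is.null(res$repeatability))
    utils::write.csv(res$repeatability, file.path(out, "repeatability.csv"),
                     row.names = FALSE)
  if (!is.null(res$drivers))
    utils::write.csv(res$drivers, file.path(out, "drivers.csv"),
                     row.names = FALSE)
  utils::write.csv(res$trip_metric_models,
                   file.path(out, "trip_metric_models.csv"),
                   row.names = FALSE)
  if (!is.null(res$fitness))
    utils::write.csv(res$fitness, file.path(out, "fitness.csv"),
                     row.names = FALSE)
  logln("wrote %d trait row(s); %d with defined patches",
        nrow(tr$traits), sum(!is.na(tr$traits$time_in_patch_h)))
  invisible(c(list(traits = tr$traits, segments = tr$segments), res))
}

#' Command-line entry point
#'
#' Thin argv-style interface over the pipeline:
#' `simulate` (synthetic data generation), `traits`
#' (tracks to trip traits), `stats` (traits to statistics) or `all`.
#' Flags: `--config FILE`, `--seed N`, `--out DIR`.
#'
#' @param args Character vector, e.g. `commandArgs(trailing = TRUE)`.
#' @return Integer exit status, invisibly (0 on success).
#' @export
ee_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: forage_ee <simulate|traits|stats|all>",
    "[--config FILE] [--seed N] [--out DIR]")
  fail <- function(msg) {
    message(msg, "\n", usage)
    return(invisible(1L))
  }
  if (!length(args) ||
      !args[1] %in% c("simulate", "traits", "stats", "all"))
    return(fail("missing or unknown subcommand"))
  cmd <- args[1]
  opts <- list(config = NULL, seed = NULL, out = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i + 1 > length(args))
      return(fail(paste("bad flag:", args[i])))
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- tryCatch(
    if (is.null(opts$config)) default_config() else load_config(opts$config),
    error = function(e) e)
  if (inherits(cfg, "error")) return(fail(conditionMessage(cfg)))
  if (!is.null(opts$seed)) cfg$global_seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  status <- tryCatch({
    if (cmd == "simulate" || (cmd == "all" && is.null(cfg$tracks_file))) {
      sim <- simulate_tracks(sim_config(seed = cfg$global_seed),
                             dir = cfg$out_dir)
      cfg$tracks_file <- file.path(cfg$out_dir, "tracks.csv")
      cfg$boldness_file <- file.path(cfg$out_dir, "boldness.csv")
      cfg$breeding_file <- file.path(cfg$out_dir, "breeding.csv")
    }
    if (cmd %in% c("traits", "stats", "all")) run_pipeline(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
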