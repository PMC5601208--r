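#' Default first-passage-time radius grid
#'
#' Fifty logarithmically spaced radii spanning 2-400 km, the range over
#' which area-restricted search is sought; log spacing resolves the small
#' scales where it typically occurs.
#'
#' @param min_km,max_km Grid range in km.
#' @param n Number of radii.
#' @return Strictly increasing numeric vector of radii (km).
#' @export
fpt_default_radii <- function(min_km = 2, max_km = 400, n = 50) {
  exp(seq(log(min_km), log(max_km), length.out = n))
}

# distances (km) from path point i to every path point
.path_dist_to <- function(path, i) {
  haversine_km(path$lat[i], path$lon[i], path$lat, path$lon)
}

# first crossing time of the circle of radius r about point i, searching
# forward (dir = +1) or backward (dir = -1); NA when the path never exits
.first_crossing <- function(d, time, i, r, dir) {
  n <- length(d)
  js <- if (dir > 0) seq_len(n - i) + i else rev(seq_len(i - 1))
  if (!length(js)) return(NA_real_)
  dd <- d[js]
  out <- which(dd > r)
  if (!length(out)) return(NA_real_)
  k <- js[out[1]]                       # first point outside
  prev <- k - dir                        # last point inside (d <= r)
  f <- (r - d[prev]) / (d[k] - d[prev])
  time[prev] + f * (time[k] - time[prev])
}

#' First passage time at one path point
#'
#' Time taken to cross a circle of radius `r` centred on path point `i`:
#' elapsed time between the backward and forward first crossings, with
#' crossing instants linearly interpolated within the straddling step.
#' Undefined (`NA`) when the path never leaves the circle on either side.
#'
#' @param path An `ee_path` from [rediscretize()].
#' @param i Point index.
#' @param r Circle radius, km (> 0).
#' @return First passage time in hours, or `NA`.
#' @export
fpt_at_point <- function(path, i, r) {
  if (r <= 0) stop("radius must be positive", call. = FALSE)
  d <- .path_dist_to(path, i)
  fwd <- .first_crossing(d, path$time, i, r, +1)
  bwd <- .first_crossing(d, path$time, i, r, -1)
  if (is.na(fwd) || is.na(bwd)) return(NA_real_)
  (fwd - bwd) / 3600
}

#' First-passage-time profile of a path
#'
#' Computes first passage time at every path point for every radius, the
#' per-radius variance of log first passage time (natural log, over defined
#' entries only), and the area-restricted-search scale (radius of peak
#' variance). Radii with fewer than `min_defined` defined entries get an
#' undefined variance, which keeps end-of-track effects from dominating.
#'
#' @param path An `ee_path`.
#' @param radii Strictly increasing radii in km; default
#'   [fpt_default_radii()].
#' @param min_defined Minimum defined first-passage times per radius for
#'   the variance to be reported; default 5.
#' @return Object of class `ee_fpt_profile`: list with `radii`, `fpt`
#'   (points x radii matrix, hours, `NA` where undefined), `var_log_fpt`,
#'   and `ars_scale_km` (`NA` when no variance is defined).
#' @export
fpt_profile <- function(path, radii = fpt_default_radii(), min_defined = 5) {
  if (!length(radii)) stop("empty radius grid", call. = FALSE)
  if (any(diff(radii) <= 0))
    stop("radii must be strictly increasing", call. = FALSE)
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  n <- nrow(path)
  tt <- path$time
  m <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n)) {
    d <- .path_dist_to(path, i)
    # forward/backward running maxima are non-decreasing, so the first
    # exit index for each radius is a single findInterval lookup
    t_f <- rep(NA_real_, length(radii))
    t_b <- t_f
    if (i < n) {
      cf <- cummax(d[(i + 1):n])
      jf <- findInterval(radii, cf) + 1L        # first index with cum > r
      ok <- jf <= length(cf)
      k <- i + jf[ok]
      f <- (radii[ok] - d[k - 1L]) / (d[k] - d[k - 1L])
      t_f[ok] <- tt[k - 1L] + f * (tt[k] - tt[k - 1L])
    }
    if (i > 1) {
      cb <- cummax(d[(i - 1):1])
      jb <- findInterval(radii, cb) + 1L
      ok <- jb <= length(cb)
      k <- i - jb[ok]
      f <- (radii[ok] - d[k + 1L]) / (d[k] - d[k + 1L])
      t_b[ok] <- tt[k + 1L] + f * (tt[k] - tt[k + 1L])
    }
    m[i, ] <- (t_f - t_b) / 3600
  }
  ndef <- colSums(!is.na(m))
  v <- rep(NA_real_, length(radii))
  enough <- ndef >= min_defined
  v[enough] <- apply(m[, enough, drop = FALSE], 2,
                     function(col) stats::var(log(col[!is.na(col)])))
  if (!any(enough))
    warning("no radius has enough defined first-passage times",
            call. = FALSE)
  prof <- structure(list(radii = radii, fpt = m, var_log_fpt = v,
                         n_defined = ndef),
                    class = "ee_fpt_profile")
  prof$ars_scale_km <- if (any(is.finite(v))) ars_scale(prof) else NA_real_
  prof
}

#' Area-restricted-search scale of a profile
#'
#' The radius at which the variance of log first passage time peaks,
#' interpreted as the characteristic size of foraging patches. Ties break
#' toward the smaller radius.
#'
#' @param profile An `ee_fpt_profile`.
#' @return Scale in km.
#' @export
ars_scale <- function(profile) {
  v <- profile$var_log_fpt
  if (!any(is.finite(v))) stop("no ARS scale: no defined variance",
                               call. = FALSE)
  profile$radii[which.max(v)]
}

#' @export
print.ee_fpt_profile <- function(x, ...) {
  cat(sprintf(
    "<ee_fpt_profile> %d points x %d radii [%.3g, %.3g] km; ARS scale %s km\n",
    nrow(x$fpt), length(x$radii), min(x$radii), max(x$radii),
    format(x$ars_scale_km, digits = 3)))
  invisible(x)
}

#' @describeIn fpt_profile Plot the variance-of-log-FPT curve against
#'   radius (log axis), marking the ARS scale.
#' @param x An `ee_fpt_profile`.
#' @param ... Passed to [plot()].
#' @export
plot.ee_fpt_profile <- function(x, ...) {
  graphics::plot(x$radii, x$var_log_fpt, type = "b", log = "x",
                 xlab = "radius (km)", ylab = "var(log FPT)", ...)
  if (is.finite(x$ars_scale_km)) {
    graphics::abline(v = x$ars_scale_km, lty = 2)
    graphics::mtext(sprintf("ARS scale %.1f km", x$ars_scale_km),
                    side = 3, line = 0, adj = 1, cex = 0.8)
  }
  invisible(x)
}
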