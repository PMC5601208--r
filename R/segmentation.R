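#' Penalized change-point segmentation of a first-passage-time series
#'
#' Splits a numeric series into segments homogeneous in mean and variance
#' using the Lavielle penalized-contrast approach: for each candidate
#' number of segments `k` the optimal partition minimizes the Gaussian
#' contrast \eqn{\sum_s n_s \log \hat\sigma^2_s} by dynamic programming
#' (within-segment maximum-likelihood variances, floored at
#' `1e-8 * var(series)`), and `k` is then chosen as the largest value whose
#' normalized contrast decrease exceeds the threshold `S`.
#'
#' The selection rule rescales the contrast curve \eqn{J(k)} to
#' \eqn{\tilde J(k)} decreasing from `kmax` to 1, and computes the second
#' difference \eqn{D(k) = \tilde J(k-1) - 2\tilde J(k) + \tilde J(k+1)}
#' (with \eqn{D(1) = \infty}); the chosen `k` is the largest with
#' \eqn{D(k) > S}.
#'
#' @param series Numeric vector, all finite; length at least `2 * lmin`.
#' @param kmax Maximum number of segments; default 30.
#' @param lmin Minimum segment length in points; default 5 (5 km of path at
#'   the default 1 km step).
#' @param S Selection threshold on the normalized contrast decrease;
#'   default 0.75.
#' @return Object of class `ee_segmentation`: list with `k`, `segments`
#'   (data.frame `start`, `end` — half-open `[start, end)` point indices —
#'   plus per-segment `mean` and `var`), `breakpoints` (interior segment
#'   starts), and `contrasts` (optimal contrast for each candidate `k`).
#' @export
lavielle_segment <- function(series, kmax = 30, lmin = 5, S = 0.75) {
  if (any(!is.finite(series))) stop("series has non-finite values",
                                    call. = FALSE)
  n <- length(series)
  if (n < 2 * lmin) stop("series too short for segmentation", call. = FALSE)
  if (kmax < 1) stop("kmax must be >= 1", call. = FALSE)
  kmax_eff <- max(1L, min(as.integer(kmax), n %/% as.integer(lmin)))
  v_tot <- stats::var(series)
  if (v_tot <= .Machine$double.eps * (1 + mean(series^2))) {
    # constant series: one segment, nothing to split
    return(structure(list(
      k = 1L,
      segments = data.frame(start = 1L, end = n + 1L,
                            mean = mean(series), var = 0),
      breakpoints = integer(0),
      contrasts = NA_real_), class = "ee_segmentation"))
  }
  eps <- 1e-8 * v_tot
  dp <- lavielle_dp(as.numeric(series), kmax_eff, as.integer(lmin), eps)
  J <- dp$contrasts
  k <- choose_k_lavielle(J, S)
  starts <- dp$starts[[k]]
  ends <- c(starts[-1], n + 1L)
  seg_stat <- vapply(seq_along(starts), function(s) {
    y <- series[starts[s]:(ends[s] - 1L)]
    c(mean(y), stats::var(y) * (length(y) - 1) / length(y))
  }, numeric(2))
  structure(list(
    k = k,
    segments = data.frame(start = starts, end = ends,
                          mean = seg_stat[1, ], var = seg_stat[2, ]),
    breakpoints = starts[-1],
    contrasts = J
  ), class = "ee_segmentation")
}

# largest k whose normalized second-difference contrast decrease exceeds S
choose_k_lavielle <- function(J, S) {
  ok <- which(is.finite(J))
  if (length(ok) < 2) return(1L)
  kmax <- max(ok)
  span <- J[1] - J[kmax]
  if (!is.finite(span) || span <= .Machine$double.eps * abs(J[1]) ||
      span <= 0)
    return(1L)
  Jt <- (J[seq_len(kmax)] - J[kmax]) / span * (kmax - 1) + 1
  D <- rep(NA_real_, kmax)
  D[1] <- Inf
  if (kmax >= 3)
    for (k in 2:(kmax - 1)) D[k] <- Jt[k - 1] - 2 * Jt[k] + Jt[k + 1]
  cand <- which(is.finite(D) & D > S | D == Inf)
  as.integer(max(cand))
}

#' @export
print.ee_segmentation <- function(x, ...) {
  cat(sprintf("<ee_segmentation> %d segment(s), breakpoints: %s\n", x$k,
              if (length(x$breakpoints))
                paste(x$breakpoints, collapse = ", ") else "none"))
  invisible(x)
}

#' Classify segments as area-restricted search
#'
#' A segment is an area-restricted-search (ARS) zone when its mean first
#' passage time is strictly greater than the mean over the whole trip;
#' segments at or below the trip mean are non-ARS (exploration / transit).
#' Means are taken over defined (non-`NA`) entries.
#'
#' @param seg An `ee_segmentation` of the series.
#' @param series The first-passage-time series (hours) that was segmented;
#'   may contain `NA` for undefined entries.
#' @return Object of class `ee_ars_labeling`: list with `is_ars` (logical
#'   per segment) and `trip_mean_fpt` (hours).
#' @export
classify_ars <- function(seg, series) {
  if (seg$segments$end[nrow(seg$segments)] - 1L != length(series))
    stop("segmentation does not partition the series", call. = FALSE)
  trip_mean <- mean(series, na.rm = TRUE)
  seg_means <- vapply(seq_len(nrow(seg$segments)), function(s) {
    y <- series[seg$segments$start[s]:(seg$segments$end[s] - 1L)]
    mean(y, na.rm = TRUE)
  }, numeric(1))
  structure(list(is_ars = seg_means > trip_mean,
                 segment_mean_fpt = seg_means,
                 trip_mean_fpt = trip_mean),
            class = "ee_ars_labeling")
}

# fill undefined entries by linear interpolation (ends carried); the DP
# needs a complete series and gaps are short end effects
interpolate_na <- function(x) {
  if (!anyNA(x)) return(list(x = x, filled = logical(length(x))))
  filled <- is.na(x)
  if (all(filled)) stop("series entirely undefined", call. = FALSE)
  idx <- seq_along(x)
  x[filled] <- stats::approx(idx[!filled], x[!filled], xout = idx[filled],
                             rule = 2)$y
  list(x = x, filled = filled)
}
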