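#' Standardize trait columns to mean 0, SD 1
#'
#' All explanatory and response variables entering the statistical models
#' are standardized so coefficients are comparable across traits.
#' Standardization is over non-missing entries, per column.
#'
#' @param df data.frame.
#' @param cols Character vector of column names to standardize.
#' @return `df` with the named columns replaced by their z-scores.
#' @export
standardize_traits <- function(df, cols) {
  for (cl in cols) {
    x <- df[[cl]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning("column '", cl, "' is constant; left unstandardized",
              call. = FALSE)
      next
    }
    df[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  df
}

#' Pairwise Pearson correlations among traits
#'
#' Pairwise-complete Pearson correlation matrix with two-sided p-values
#' from the t transform, as used to test whether the foraging traits form
#' a correlated trade-off.
#'
#' @param m Numeric matrix or data.frame (rows = trips, columns = traits).
#' @return List with `r` (correlations, unit diagonal), `p` (p-values,
#'   `NA` diagonal) and `n` (pairwise complete counts). Constant columns
#'   give `NA` entries with a warning.
#' @export
pearson_matrix <- function(m) {
  m <- as.matrix(m)
  p <- ncol(m)
  r <- diag(1, p); pv <- matrix(NA_real_, p, p); nn <- matrix(NA_real_, p, p)
  dimnames(r) <- dimnames(pv) <- dimnames(nn) <-
    list(colnames(m), colnames(m))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    ok <- stats::complete.cases(m[, c(i, j)])
    nn[i, j] <- nn[j, i] <- sum(ok)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for columns ",
                          i, ",", j, call. = FALSE)
    if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
      warning("constant column: correlation undefined", call. = FALSE)
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  list(r = r, p = pv, n = nn)
}

#' Principal-component exploration-exploitation strategy score
#'
#' PCA of the standardized trait matrix (equivalently, eigendecomposition
#' of its correlation matrix). PC1 summarizes the trade-off in a single
#' score; its sign is fixed so the `time_in_patch` loading is positive,
#' making larger scores mean exploitation and smaller scores exploration.
#'
#' @param m Numeric matrix or data.frame with the four trait columns;
#'   rows with any missing value are dropped (complete-case).
#' @param time_in_patch_col Column (name or index) anchoring the sign
#'   convention; default `"time_in_patch"` if present, else column 1.
#' @return Object of class `ee_score`: list with `loadings` (columns =
#'   PCs, unit norm), `variance_explained` (fractions summing to 1),
#'   `scores` (PC1 per retained row), `transformed_scores`
#'   (`log(score + 2)` via [transform_pc1()]), and `rows` (indices of the
#'   complete rows used).
#' @export
pca_ee <- function(m, time_in_patch_col = NULL) {
  m <- as.matrix(m)
  if (is.null(time_in_patch_col))
    time_in_patch_col <- if ("time_in_patch" %in% colnames(m))
      "time_in_patch" else 1L
  keep <- stats::complete.cases(m)
  if (sum(keep) < 5) stop("need at least 5 complete rows for PCA",
                          call. = FALSE)
  x <- m[keep, , drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  scores <- pc$x
  anchor <- load[time_in_patch_col, 1]
  if (is.finite(anchor) && anchor < 0) {
    load[, 1] <- -load[, 1]
    scores[, 1] <- -scores[, 1]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = load, variance_explained = ve,
                 scores = scores[, 1],
                 transformed_scores = transform_pc1(scores[, 1]),
                 rows = which(keep)),
            class = "ee_score")
}

#' @export
print.ee_score <- function(x, ...) {
  cat("<ee_score> PC1 loadings:\n")
  print(round(x$loadings[, 1], 3))
  cat(sprintf("PC1 variance explained: %.2f\n", x$variance_explained[1]))
  invisible(x)
}

#' Log transform of the strategy score
#'
#' `log(score + 2)`, the variance-stabilizing transform applied to the PC1
#' strategy score before modelling. Scores at or below `-2 + eps_clip` are
#' clipped to the floor with a warning rather than producing `-Inf`.
#'
#' @param score Numeric vector of PC1 scores.
#' @param eps_clip Clipping floor for `score + 2`; default `1e-6`.
#' @return `log(score + 2)` (natural log).
#' @export
transform_pc1 <- function(score, eps_clip = 1e-6) {
  shifted <- score + 2
  if (any(shifted < eps_clip, na.rm = TRUE))
    warning(sum(shifted < eps_clip, na.rm = TRUE),
            " score(s) at or below -2 clipped before log transform",
            call. = FALSE)
  log(pmax(shifted, eps_clip))
}

#' Per-bird boldness scores from approach tests
#'
#' Each test scores the bird's response to a neutral human approacher on an
#' ordinal 0-4 scale (no response ... stands up); the per-test score is the
#' maximum behaviour recorded. Because observer identity and observation
#' number affect scores, a linear model with additive observer,
#' observation-number and bird terms is fitted and the per-bird
#' coefficients are extracted and mean-centred over birds.
#'
#' @param tests data.frame with columns `bird_id`, `observer`,
#'   `obs_number` and `score` (0-4, already the per-test maximum).
#' @param method `"fixed"` (default): bird as fixed coefficients;
#'   `"random"`: bird as a random intercept (lme4), centred conditional
#'   modes.
#' @return data.frame `bird_id`, `estimate` (mean-centred), `n_tests`.
#' @export
boldness_scores <- function(tests, method = c("fixed", "random")) {
  method <- match.arg(method)
  need <- c("bird_id", "observer", "obs_number", "score")
  if (!all(need %in% names(tests)))
    stop("tests must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  all_birds <- unique(as.character(tests$bird_id))
  tests <- tests[!is.na(tests$score), , drop = FALSE]
  if (!nrow(tests)) stop("no non-missing test scores", call. = FALSE)
  if (any(tests$score < 0 | tests$score > 4))
    stop("scores must lie in 0..4", call. = FALSE)
  lost <- setdiff(all_birds, unique(as.character(tests$bird_id)))
  if (length(lost))
    warning(length(lost), " bird(s) with all-missing tests excluded",
            call. = FALSE)
  tests$bird_id <- factor(tests$bird_id)
  tests$observer <- factor(tests$observer)
  multi_obs <- nlevels(tests$observer) > 1
  if (method == "fixed") {
    fml <- if (multi_obs) score ~ 0 + bird_id + observer + obs_number
    else score ~ 0 + bird_id + obs_number
    fit <- stats::lm(fml, data = tests)
    cf <- stats::coef(fit)
    est <- cf[paste0("bird_id", levels(tests$bird_id))]
    names(est) <- levels(tests$bird_id)
  } else {
    fml <- if (multi_obs) score ~ observer + obs_number + (1 | bird_id)
    else score ~ obs_number + (1 | bird_id)
    fit <- lme4::lmer(fml, data = tests)
    re <- lme4::ranef(fit)$bird_id
    est <- stats::setNames(re[, 1], rownames(re))
  }
  est <- est - mean(est)
  data.frame(bird_id = names(est), estimate = unname(est),
             n_tests = as.integer(table(tests$bird_id)[names(est)]))
}
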