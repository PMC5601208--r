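.lmer_ctrl <- function() lme4::lmerControl(
  check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))

.glmer_ctrl <- function() lme4::glmerControl(
  check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))

# formula assembly: response ~ fixed terms + (1|bird) [+ (1|year)]
# grouping factors with a single level are dropped with a message
.lmm_formula <- function(response, fixed, data, bird, year) {
  re <- character()
  for (g in c(bird, year)) {
    if (!g %in% names(data)) next
    if (length(unique(data[[g]][!is.na(data[[g]])])) >= 2)
      re <- c(re, sprintf("(1 | %s)", g))
    else message("grouping factor '", g, "' has a single level; dropped")
  }
  if (!length(re)) stop("no usable random-effect grouping factor",
                        call. = FALSE)
  rhs <- paste(c(if (length(fixed)) fixed else "1", re), collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

.check_rank <- function(fml, data) {
  X <- stats::model.matrix(lme4::nobars(fml), data)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    dropped <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
}

.vc_from_fit <- function(fit, bird, year) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  list(v_bird = getv(bird), v_year = getv(year),
       v_resid = getv("Residual"))
}

#' Fit a random-intercept mixed model
#'
#' Linear mixed model of a (standardized) response with random intercepts
#' for bird identity and year, fitted by restricted maximum likelihood.
#' This is the variance-decomposition engine behind repeatability and all
#' driver tests.
#'
#' @param data data.frame with the response, fixed-effect columns and the
#'   grouping columns.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (e.g.
#'   `c("boldness", "age", "sex", "age:sex")`); empty for intercept-only.
#' @param bird,year Grouping column names; default `"bird_id"`, `"year"`.
#' @param reml Fit by REML (default) or full maximum likelihood.
#' @return Object of class `ee_vc`: list with `v_bird`, `v_year`,
#'   `v_resid`, `fixed_effects` (data.frame `term`, `estimate`, `se`) and
#'   the underlying `fit` (`merMod`), or a degenerate all-zero result with
#'   a warning when the response is constant.
#' @export
fit_lmm <- function(data, response, fixed = character(),
                    bird = "bird_id", year = "year", reml = TRUE) {
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found",
                       call. = FALSE)
  data <- data[!is.na(y), , drop = FALSE]
  y <- data[[response]]
  if (stats::var(y) == 0) {
    warning("response is constant; all variance components zero",
            call. = FALSE)
    return(structure(list(v_bird = 0, v_year = 0, v_resid = 0,
                          fixed_effects = data.frame(
                            term = "(Intercept)", estimate = y[1], se = 0),
                          fit = NULL, degenerate = TRUE),
                     class = "ee_vc"))
  }
  if (year %in% names(data)) data[[year]] <- factor(data[[year]])
  fml <- .lmm_formula(response, fixed, data, bird, year)
  .check_rank(fml, data)
  fit <- lme4::lmer(fml, data = data, REML = reml,
                    control = .lmer_ctrl())
  vc <- .vc_from_fit(fit, bird, year)
  cf <- summary(fit)$coefficients
  structure(c(vc, list(
    fixed_effects = data.frame(term = rownames(cf),
                               estimate = cf[, "Estimate"],
                               se = cf[, "Std. Error"],
                               row.names = NULL),
    fit = fit, degenerate = FALSE)), class = "ee_vc")
}

#' @export
print.ee_vc <- function(x, ...) {
  cat(sprintf("<ee_vc> v_bird = %.4g, v_year = %.4g, v_resid = %.4g\n",
              x$v_bird, x$v_year, x$v_resid))
  invisible(x)
}

.r_from_vc <- function(v, include_year) {
  den <- v$v_bird + v$v_resid + if (include_year) v$v_year else 0
  if (den <= 0) return(0)
  v$v_bird / den
}

#' Repeatability of a trait with bootstrap CI and likelihood-ratio p
#'
#' Repeatability is the fraction of phenotypic variance attributable to
#' among-individual differences,
#' `R = v_bird / (v_bird + v_year + v_resid)` (the year component can be
#' excluded from the denominator via `include_year`). The confidence
#' interval comes from a parametric bootstrap — responses simulated from
#' the fitted model, the model refitted, `R` recomputed, percentile
#' interval taken — and the p-value from a likelihood-ratio test of
#' `v_bird = 0` against the boundary null (50:50 mixture of a point mass
#' at zero and chi-square with 1 df).
#'
#' @inheritParams fit_lmm
#' @param n_boot Bootstrap iterations; default 1000 (values below 100
#'   trigger a warning).
#' @param seed Integer seed for the bootstrap simulations.
#' @param include_year Include the year variance in the denominator
#'   (default `TRUE`).
#' @param level Confidence level; default 0.95.
#' @return Object of class `ee_repeatability`: list with `r`, `ci_low`,
#'   `ci_high`, `p`, `lrt`, `n_boot_ok`, `n_boot_failed` and the variance
#'   components `vc`.
#' @export
repeatability <- function(data, response, fixed = character(),
                          n_boot = 1000, seed = 1,
                          bird = "bird_id", year = "year",
                          include_year = TRUE, level = 0.95) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals",
                            call. = FALSE)
  vc <- fit_lmm(data, response, fixed, bird = bird, year = year,
                reml = TRUE)
  if (isTRUE(vc$degenerate))
    return(structure(list(r = 0, ci_low = 0, ci_high = 0, p = 1, lrt = 0,
                          n_boot_ok = 0, n_boot_failed = 0, vc = vc),
                     class = "ee_repeatability"))
  r <- .r_from_vc(vc, include_year)
  fit <- vc$fit
  # LRT of the bird variance against the boundary-corrected null
  data2 <- data[!is.na(data[[response]]), , drop = FALSE]
  if (year %in% names(data2)) data2[[year]] <- factor(data2[[year]])
  rhs_fixed <- paste(if (length(fixed)) fixed else "1", collapse = " + ")
  has_year <- year %in% names(data2) &&
    length(unique(data2[[year]])) >= 2
  red <- if (has_year)
    lme4::lmer(stats::as.formula(
      paste(response, "~", rhs_fixed, "+ (1 |", year, ")")),
      data = data2, REML = TRUE,
      control = .lmer_ctrl())
  else stats::lm(stats::as.formula(paste(response, "~", rhs_fixed)),
                 data = data2)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                       as.numeric(stats::logLik(red))))
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  # parametric bootstrap
  sims <- stats::simulate(fit, nsim = n_boot, seed = seed)
  rs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    rs[b] <- tryCatch({
      fb <- suppressMessages(suppressWarnings(
        lme4::refit(fit, newresp = sims[[b]])))
      .r_from_vc(.vc_from_fit(fb, bird, year), include_year)
    }, error = function(e) NA_real_)
  }
  ok <- rs[!is.na(rs)]
  qa <- (1 - level) / 2
  ci <- if (length(ok)) stats::quantile(ok, c(qa, 1 - qa), names = FALSE)
  else c(NA_real_, NA_real_)
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], p = p, lrt = lrt,
                 n_boot_ok = length(ok),
                 n_boot_failed = n_boot - length(ok), vc = vc),
            class = "ee_repeatability")
}

#' @export
print.ee_repeatability <- function(x, ...) {
  cat(sprintf("<ee_repeatability> R = %.3f (%.3f, %.3f); LRT p = %.3g\n",
              x$r, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

.lrt_pair <- function(full, reduced) {
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(reduced))))
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  list(chisq = stat, df = df,
       p = stats::pchisq(stat, df = max(df, 1), lower.tail = FALSE))
}

.fit_ml <- function(data, response, fixed, bird, year) {
  fml <- .lmm_formula(response, fixed, data, bird, year)
  .check_rank(fml, data)
  lme4::lmer(fml, data = data, REML = FALSE,
             control = .lmer_ctrl())
}

.coef_rows <- function(fit, term) {
  cf <- tryCatch(suppressWarnings(summary(fit)$coefficients),
                 error = function(e) NULL)
  if (is.null(cf)) {  # degenerate fit (e.g. zero residual variance)
    fe <- lme4::fixef(fit)
    hit <- grepl(term, names(fe), fixed = TRUE)
    if (!any(hit)) return(data.frame(estimate = NA_real_, se = NA_real_))
    return(data.frame(estimate = unname(fe[hit][1]), se = NA_real_))
  }
  hit <- grepl(term, rownames(cf), fixed = TRUE)
  if (!any(hit)) return(data.frame(estimate = NA_real_, se = NA_real_))
  data.frame(estimate = cf[hit, "Estimate"][1], se = cf[hit, "Std. Error"][1])
}

#' Test intrinsic drivers of a foraging trait
#'
#' Fits the trait against boldness, age, sex and the age-by-sex
#' interaction with bird and year random intercepts, by full maximum
#' likelihood. Each term's significance is a likelihood-ratio (ANOVA)
#' comparison between models with and without that term; a non-significant
#' interaction (p >= `alpha_drop`) is dropped and the main effects are
#' then reported from the reduced model.
#'
#' @inheritParams fit_lmm
#' @param drivers Main-effect terms; default
#'   `c("boldness", "age", "sex")`.
#' @param interaction Interaction term, or `NULL` for none; default
#'   `"age:sex"`.
#' @param alpha_drop Significance level below which the interaction is
#'   retained; default 0.05.
#' @return Object of class `ee_driver_fit`: data.frame with one row per
#'   term (`term`, `chisq`, `df`, `p`, `estimate`, `se`) and attributes
#'   `interaction_dropped` and `response`.
#' @export
driver_test <- function(data, response,
                        drivers = c("boldness", "age", "sex"),
                        interaction = "age:sex", alpha_drop = 0.05,
                        bird = "bird_id", year = "year") {
  data <- data[stats::complete.cases(
    data[, c(response, drivers), drop = FALSE]), , drop = FALSE]
  if (year %in% names(data)) data[[year]] <- factor(data[[year]])
  rows <- list()
  int_dropped <- FALSE
  if (!is.null(interaction)) {
    full <- .fit_ml(data, response, c(drivers, interaction), bird, year)
    no_int <- .fit_ml(data, response, drivers, bird, year)
    t_int <- .lrt_pair(full, no_int)
    est <- .coef_rows(full, gsub("\\s", "", interaction))
    rows[[interaction]] <- data.frame(term = interaction,
                                      chisq = t_int$chisq, df = t_int$df,
                                      p = t_int$p, est)
    int_dropped <- t_int$p >= alpha_drop
    base <- if (int_dropped) no_int else full
    base_terms <- if (int_dropped) drivers else c(drivers, interaction)
  } else {
    base <- .fit_ml(data, response, drivers, bird, year)
    base_terms <- drivers
  }
  for (d in drivers) {
    red <- .fit_ml(data, response, setdiff(base_terms, d), bird, year)
    tt <- .lrt_pair(base, red)
    rows[[d]] <- data.frame(term = d, chisq = tt$chisq, df = tt$df,
                            p = tt$p, .coef_rows(base, d))
  }
  out <- do.call(rbind, c(rows[drivers],
                          if (!is.null(interaction)) rows[interaction]))
  rownames(out) <- NULL
  structure(out, interaction_dropped = int_dropped, response = response,
            class = c("ee_driver_fit", "data.frame"))
}

#' Association between the strategy score and a trip metric
#'
#' Regresses the (log-transformed, standardized) strategy score on a
#' single trip metric — duration, total distance or maximum range, fitted
#' one at a time because the metrics covary strongly — with bird and year
#' random intercepts, testing the slope by likelihood ratio.
#'
#' @inheritParams fit_lmm
#' @param metric Predictor column name.
#' @param response Response column; default `"pc1_log"`.
#' @return `ee_driver_fit` with a single row for the metric.
#' @export
trip_metric_association <- function(data, metric, response = "pc1_log",
                                    bird = "bird_id", year = "year") {
  driver_test(data, response, drivers = metric, interaction = NULL,
              bird = bird, year = year)
}

#' Binary fitness model for a foraging trait
#'
#' Logistic mixed model of breeding success (0/1) on one trait at a time
#' (the traits covary), with bird and year random intercepts; the trait
#' effect is tested by likelihood ratio.
#'
#' @inheritParams fit_lmm
#' @param trait Trait column name (standardized upstream).
#' @param success Binary response column; default `"success"`.
#' @return `ee_driver_fit` with one row for the trait.
#' @export
fitness_model <- function(data, trait, success = "success",
                          bird = "bird_id", year = "year") {
  data <- data[stats::complete.cases(
    data[, c(success, trait), drop = FALSE]), , drop = FALSE]
  y <- data[[success]]
  if (!all(y %in% c(0, 1))) stop("success must be 0/1", call. = FALSE)
  if (length(unique(y)) == 1) {
    warning("success is constant; trait effect degenerate", call. = FALSE)
    out <- data.frame(term = trait, chisq = 0, df = 1, p = 1,
                      estimate = 0, se = NA_real_)
    return(structure(out, interaction_dropped = FALSE, response = success,
                     class = c("ee_driver_fit", "data.frame")))
  }
  if (year %in% names(data)) data[[year]] <- factor(data[[year]])
  fml_full <- .lmm_formula(success, trait, data, bird, year)
  fml_red <- .lmm_formula(success, character(), data, bird, year)
  ctrl <- .glmer_ctrl()
  full <- lme4::glmer(fml_full, data = data, family = stats::binomial,
                      control = ctrl)
  est <- .coef_rows(full, trait)
  if (is.finite(est$estimate) && abs(est$estimate) > 15)
    stop("complete separation suspected: |coefficient| > 15 on the ",
         "log-odds scale", call. = FALSE)
  red <- lme4::glmer(fml_red, data = data, family = stats::binomial,
                     control = ctrl)
  tt <- .lrt_pair(full, red)
  out <- data.frame(term = trait, chisq = tt$chisq, df = tt$df, p = tt$p,
                    est)
  structure(out, interaction_dropped = FALSE, response = success,
            class = c("ee_driver_fit", "data.frame"))
}
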