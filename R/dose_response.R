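# Dose-response analysis: correlate per-pouch mosquito mortality with
# simulated AI concentration, fit a linear mortality~concentration model
# (the study's functional model), and invert it to the concentration that
# achieves a target mortality (e.g. C100, the 100%-mortality level).

#' Assemble a dose-mortality observation table
#'
#' One row per pouch: simulated concentration at the pouch position and the
#' observed deaths out of `n` caged mosquitoes.
#'
#' @param site_id character pouch identifiers
#' @param concentration_ppm simulated time-averaged concentration, ppm (>= 0)
#' @param deaths dead mosquitoes per pouch (0 <= deaths <= n)
#' @param n mosquitoes per pouch (> 0)
#' @param level_label height level per pouch (optional)
#' @param period_h exposure period, h (24 or 48; optional)
#' @return data.frame of class `sr_dose_obs` with a `mortality` column
#'   (= deaths / n)
#' @export
dose_observations <- function(site_id, concentration_ppm, deaths, n,
                              level_label = NA_character_,
                              period_h = NA_real_) {
  if (any(concentration_ppm < 0)) stop("invalid observations: negative concentration")
  if (any(n <= 0)) stop("invalid observations: n must be > 0")
  if (any(deaths < 0 | deaths > n)) stop("invalid observations: deaths outside [0, n]")
  df <- data.frame(site_id = as.character(site_id),
                   concentration_ppm = as.numeric(concentration_ppm),
                   deaths = as.integer(deaths), n = as.integer(n),
                   mortality = as.numeric(deaths) / as.numeric(n),
                   level_label = level_label, period_h = period_h,
                   stringsAsFactors = FALSE)
  class(df) <- c("sr_dose_obs", "data.frame")
  df
}

#' Abbott correction for control mortality
#'
#' The standard bioassay adjustment of treatment mortality for mortality in
#' an independent control: `(observed - control) / (1 - control)`, clipped
#' to [0, 1]. The identity when control mortality is zero.
#'
#' @param observed_mortality observed mortality fraction(s)
#' @param control_mortality control mortality fraction (< 1)
#' @return corrected mortality fraction(s) in [0, 1]
#' @export
abbott_correction <- function(observed_mortality, control_mortality) {
  if (any(control_mortality >= 1)) stop("degenerate control")
  corrected <- (observed_mortality - control_mortality) /
    (1 - control_mortality)
  if (any(corrected < 0)) {
    warning("observed mortality below control; corrected value clipped to 0")
  }
  pmin(pmax(corrected, 0), 1)
}

#' Fit the linear dose-response model
#'
#' Ordinary least squares of mortality fraction on concentration (ppm),
#' unweighted and per pouch, matching the study's functional model. The
#' bounded-response caveat of a linear fit is deliberate: see the methods
#' vignette; [fit_logistic()] is available for sensitivity analysis.
#'
#' @param obs an `sr_dose_obs` table (>= 3 rows, concentrations not all
#'   identical)
#' @param stratum label recorded on the fit (bookkeeping only)
#' @return object of class `sr_dose_fit`: slope (fraction/ppm), intercept
#'   (fraction), r_squared, n_obs, stratum, period
#' @export
fit_linear <- function(obs, stratum = "all") {
  if (nrow(obs) < 3) stop("insufficient data: need at least 3 observations")
  x <- obs$concentration_ppm; y <- obs$mortality
  if (diff(range(x)) == 0) stop("no dose variation: all concentrations equal")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  period <- if (all(!is.na(obs$period_h)) && length(unique(obs$period_h)) == 1)
    obs$period_h[1] else NA_real_
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, n_obs = nrow(obs), stratum = stratum,
                 period_h = period, c_target = NA_real_,
                 target_mortality = NA_real_,
                 max_observed_ppm = max(x), model = "linear"),
            class = "sr_dose_fit")
}

#' Logistic dose-response fit (sensitivity analysis only)
#'
#' Binomial GLM of deaths/n on concentration with a logit link. Provided as
#' a non-default alternative to [fit_linear()]; never used for headline
#' thresholds, whose definition (finite concentration at 100% mortality)
#' requires the linear model.
#'
#' @inheritParams fit_linear
#' @return an `sr_dose_fit` with `model = "logistic"` (slope and intercept
#'   on the logit scale)
#' @export
fit_logistic <- function(obs, stratum = "all") {
  if (nrow(obs) < 3) stop("insufficient data: need at least 3 observations")
  x <- obs$concentration_ppm
  if (diff(range(x)) == 0) stop("no dose variation: all concentrations equal")
  fit <- stats::glm(cbind(obs$deaths, obs$n - obs$deaths) ~ x,
                    family = stats::binomial())
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = NA_real_, n_obs = nrow(obs), stratum = stratum,
                 period_h = NA_real_, c_target = NA_real_,
                 target_mortality = NA_real_,
                 max_observed_ppm = max(x), model = "logistic"),
            class = "sr_dose_fit")
}

#' Invert a fit to the concentration achieving a target mortality
#'
#' For the linear model: `c = (target - intercept) / slope`. For the
#' logistic model: `c = (logit(target) - intercept) / slope` (target < 1).
#' A warning is issued when the result extrapolates beyond the largest
#' observed concentration, as the study's own 100%-mortality thresholds do.
#'
#' @param fit an `sr_dose_fit` with slope > 0
#' @param target target mortality fraction in (0, 1]
#' @return the fit with `c_target` (ppm) and `target_mortality` filled in
#' @export
concentration_for_mortality <- function(fit, target = 1.0) {
  if (target <= 0 || target > 1) stop("target mortality must lie in (0, 1]")
  if (!is.finite(fit$slope) || fit$slope <= 0) stop("non-positive dose effect")
  if (fit$model == "logistic") {
    if (target == 1) stop("logistic model reaches 100% only asymptotically")
    c_target <- (stats::qlogis(target) - fit$intercept) / fit$slope
  } else {
    c_target <- (target - fit$intercept) / fit$slope
  }
  if (c_target < 0) {
    warning("baseline mortality already exceeds target; c_target set to 0")
    c_target <- 0
  }
  if (is.finite(fit$max_observed_ppm) && c_target > fit$max_observed_ppm) {
    warning(sprintf(
      "c_target %.4g ppm extrapolates beyond the largest observed concentration %.4g ppm",
      c_target, fit$max_observed_ppm))
  }
  fit$c_target <- c_target
  fit$target_mortality <- target
  fit
}

#' Stratified dose-response fits
#'
#' One [fit_linear()] per stratum of `by` columns (typically `level_label`
#' and/or `period_h`). Strata that fail the fit preconditions (too few
#' pouches, no dose variation) are reported as skipped, not fatal.
#'
#' @param obs an `sr_dose_obs` table
#' @param by character vector of stratification columns
#' @param target optional target mortality; when given, each fit is
#'   inverted with [concentration_for_mortality()]
#' @return list with elements `fits` (named list of `sr_dose_fit`) and
#'   `skipped` (named character vector of reasons)
#' @export
stratified_fits <- function(obs, by = "level_label", target = NULL) {
  key <- interaction(obs[, by, drop = FALSE], drop = TRUE, sep = "/")
  groups <- split(seq_len(nrow(obs)), key)
  fits <- list(); skipped <- character(0)
  for (g in names(groups)) {
    sub <- obs[groups[[g]], , drop = FALSE]
    res <- tryCatch({
      f <- fit_linear(sub, stratum = g)
      if (!is.null(target)) f <- concentration_for_mortality(f, target)
      f
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "sr_dose_fit")) fits[[g]] <- res
    else skipped[g] <- res
  }
  if (!length(fits)) stop("no fittable strata")
  list(fits = fits, skipped = skipped)
}

#' Predicted mortality under a fit
#'
#' @param fit an `sr_dose_fit`
#' @param concentration_ppm concentration(s), ppm
#' @return predicted mortality fraction(s) (not clipped)
#' @export
predict_mortality <- function(fit, concentration_ppm) {
  eta <- fit$intercept + fit$slope * concentration_ppm
  if (fit$model == "logistic") stats::plogis(eta) else eta
}

#' Read / write dose observation CSV
#'
#' Columns: `site_id, concentration_ppm, deaths, n` and optionally
#' `level_label, period_h`.
#'
#' @param path CSV path
#' @return an `sr_dose_obs`
#' @export
read_dose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "concentration_ppm", "deaths", "n")
  if (!all(need %in% names(df))) {
    stop("malformed dose CSV: need columns ", paste(need, collapse = ", "))
  }
  dose_observations(df$site_id, df$concentration_ppm, df$deaths, df$n,
                    level_label = if ("level_label" %in% names(df))
                      df$level_label else NA_character_,
                    period_h = if ("period_h" %in% names(df))
                      df$period_h else NA_real_)
}

#' @rdname read_dose_csv
#' @param obs an `sr_dose_obs`
#' @export
write_dose_csv <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' Fits as a one-row-per-fit data frame
#'
#' @param fits an `sr_dose_fit` or list of them
#' @return data.frame with stratum, slope, intercept, r2, n_obs, c_target
#' @export
fits_to_table <- function(fits) {
  if (inherits(fits, "sr_dose_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(stratum = f$stratum, model = f$model, slope = f$slope,
               intercept = f$intercept, r2 = f$r_squared, n_obs = f$n_obs,
               period_h = f$period_h, target_mortality = f$target_mortality,
               c_target_ppm = f$c_target, stringsAsFactors = FALSE)
  }))
}

#' @exportS3Method base::print
print.sr_dose_fit <- function(x, ...) {
  cat(sprintf("<sr_dose_fit %s> stratum %s: mortality = %.4g + %.4g * c_ppm (r2 = %.3f, n = %d)\n",
              x$model, x$stratum, x$intercept, x$slope, x$r_squared, x$n_obs))
  if (!is.na(x$c_target)) {
    cat(sprintf("  c(target mortality %.0f%%) = %.4g ppm\n",
                100 * x$target_mortality, x$c_target))
  }
  invisible(x)
}
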