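# Evaporation kinetics of binary AI/solvent formulations and conversion of
# measured mass loss into device-level release-rate schedules.
#
# The liquid is described by three component masses (AI, solvent, water).
# With A the open surface area (cm^2) and x_i the instantaneous mass
# fraction of component i in the liquid, the kinetic model is
#
#   dm_s/dt  = -k_solvent * A * x_s
#   dm_ai/dt = -k_ai * (1 + alpha * x_s) * A * x_ai
#   dm_w/dt  = +k_water_uptake * A          (until a configurable ceiling)
#
# i.e. each component evaporates in proportion to its surface availability,
# and the volatile solvent carries AI with it (alpha >= 0 is the solvent
# enhancement). This is the minimal model that reproduces the two observed
# behaviours: AI loss accelerates with solvent fraction, and all
# formulations converge to the pure-AI rate once the solvent is gone.

#' Evaporation kinetics parameters
#'
#' @param k_ai pure-AI areal evaporation flux, g h^-1 cm^-2 (>= 0)
#' @param k_solvent pure-solvent areal flux, g h^-1 cm^-2 (>= 0)
#' @param alpha dimensionless solvent-enhancement coefficient (>= 0)
#' @param k_water_uptake hygroscopic water uptake flux, g h^-1 cm^-2 (>= 0)
#' @param surface_area_cm2 open liquid surface area, cm^2 (> 0)
#' @param water_ceiling_g water uptake stops at this mass, g
#' @return object of class `sr_evap_params`
#' @export
evap_params <- function(k_ai, k_solvent, alpha = 0, k_water_uptake = 0,
                        surface_area_cm2, water_ceiling_g = Inf) {
  if (k_ai < 0 || k_solvent < 0 || alpha < 0 || k_water_uptake < 0) {
    stop("invalid kinetics: rate constants must be >= 0")
  }
  if (surface_area_cm2 <= 0) stop("invalid kinetics: surface area must be > 0")
  structure(list(k_ai = k_ai, k_solvent = k_solvent, alpha = alpha,
                 k_water_uptake = k_water_uptake,
                 surface_area_cm2 = surface_area_cm2,
                 water_ceiling_g = water_ceiling_g),
            class = "sr_evap_params")
}

#' Evaporation mass time series
#'
#' @param times_h strictly increasing times, h, starting at 0
#' @param ai_mass_g,solvent_mass_g,water_mass_g component masses, g, one per
#'   time point (>= 0)
#' @return object of class `sr_evap_series`
#' @export
evaporation_series <- function(times_h, ai_mass_g, solvent_mass_g,
                               water_mass_g = rep(0, length(times_h))) {
  times_h <- as.numeric(times_h)
  if (length(times_h) < 1 || times_h[1] != 0 || any(diff(times_h) <= 0)) {
    stop("invalid series: times must increase strictly from 0")
  }
  n <- length(times_h)
  if (length(ai_mass_g) != n || length(solvent_mass_g) != n ||
      length(water_mass_g) != n) {
    stop("invalid series: mass vectors must match times")
  }
  if (any(c(ai_mass_g, solvent_mass_g, water_mass_g) < 0)) {
    stop("invalid series: masses must be >= 0")
  }
  structure(list(times_h = times_h, ai_mass_g = as.numeric(ai_mass_g),
                 solvent_mass_g = as.numeric(solvent_mass_g),
                 water_mass_g = as.numeric(water_mass_g)),
            class = "sr_evap_series")
}

evap_derivs <- function(m, params) {
  m <- pmax(m, 0)
  total <- sum(m)
  if (total <= 0) return(c(0, 0, 0))
  x <- m / total
  A <- params$surface_area_cm2
  d_ai <- -params$k_ai * (1 + params$alpha * x[2]) * A * x[1]
  d_s <- -params$k_solvent * A * x[2]
  d_w <- if (m[3] < params$water_ceiling_g) params$k_water_uptake * A else 0
  # no evaporation from an exhausted component
  if (m[1] <= 0) d_ai <- 0
  if (m[2] <= 0) d_s <- 0
  c(d_ai, d_s, d_w)
}

#' Simulate formulation evaporation
#'
#' Integrates the binary-formulation kinetic ODEs (see the package overview
#' in the methods vignette) with a fixed-step classical 4th-order
#' Runge-Kutta scheme, internal step <= `max_step_h`, and reports the
#' component masses on the requested time grid. Component masses are
#' clamped at zero on depletion.
#'
#' @param form a [formulation()] giving initial masses
#' @param params an [evap_params()]
#' @param times_h output time grid, h, strictly increasing from 0
#' @param max_step_h internal integrator step bound, h
#' @return an [evaporation_series()]
#' @export
simulate_evaporation <- function(form, params, times_h, max_step_h = 0.01) {
  if (!inherits(params, "sr_evap_params")) stop("invalid kinetics")
  times_h <- as.numeric(times_h)
  if (length(times_h) < 1 || times_h[1] != 0 || any(diff(times_h) <= 0)) {
    stop("invalid series: times must increase strictly from 0")
  }
  m <- c(form$initial_ai_mass_g, form$initial_solvent_mass_g,
         form$initial_water_mass_g)
  out <- matrix(NA_real_, nrow = length(times_h), ncol = 3)
  out[1, ] <- m
  for (i in seq_along(times_h)[-1]) {
    span <- times_h[i] - times_h[i - 1]
    nstep <- max(1L, ceiling(span / max_step_h))
    h <- span / nstep
    for (s in seq_len(nstep)) {
      k1 <- evap_derivs(m, params)
      k2 <- evap_derivs(m + h / 2 * k1, params)
      k3 <- evap_derivs(m + h / 2 * k2, params)
      k4 <- evap_derivs(m + h * k3, params)
      m <- pmax(m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    }
    out[i, ] <- m
  }
  evaporation_series(times_h, out[, 1], out[, 2], out[, 3])
}

#' Piecewise-linear release rate curve
#'
#' @param times_h knot times, h
#' @param rate_mg_s emission rate at each knot, mg/s (>= 0); linear between
#'   knots
#' @return object of class `sr_rate_curve`
#' @export
rate_curve <- function(times_h, rate_mg_s) {
  times_h <- as.numeric(times_h); rate_mg_s <- as.numeric(rate_mg_s)
  if (length(times_h) != length(rate_mg_s)) {
    stop("invalid rate curve: lengths differ")
  }
  if (any(diff(times_h) <= 0)) stop("invalid rate curve: times not increasing")
  if (any(rate_mg_s < 0)) stop("invalid rate curve: negative rate")
  structure(list(times_h = times_h, rate_mg_s = rate_mg_s),
            class = "sr_rate_curve")
}

#' Estimate the AI release-rate curve from a mass time series
#'
#' Differentiates the AI mass numerically: central finite differences at
#' interior knots, one-sided differences at the endpoints, converted from
#' g/h to mg/s. Negative estimates (possible under measurement noise) are
#' floored at zero with a warning; noise must not become a negative source.
#'
#' @param series an [evaporation_series()] with at least 2 points
#' @return an `sr_rate_curve` on the same knots
#' @export
estimate_rate_curve <- function(series) {
  t <- series$times_h; m <- series$ai_mass_g
  n <- length(t)
  if (n < 2) stop("insufficient series: need at least 2 time points")
  loss <- numeric(n)  # -dm/dt in g/h
  loss[1] <- -(m[2] - m[1]) / (t[2] - t[1])
  loss[n] <- -(m[n] - m[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    loss[i] <- -(m[i + 1] - m[i - 1]) / (t[i + 1] - t[i - 1])
  }
  if (any(loss < 0)) {
    warning(sprintf("%d negative rate estimate(s) floored at 0",
                    sum(loss < 0)))
    loss <- pmax(loss, 0)
  }
  rate_curve(t, g_per_h_to_mg_per_s(loss))
}

#' Scale a rate curve from the characterization vessel to the device
#'
#' Release through a porous membrane is proportional to open surface area,
#' so rates measured in an open tube are scaled by the ratio of the device
#' open area to the source-vessel open area.
#'
#' @param curve an `sr_rate_curve`
#' @param source_area_cm2 open area of the measurement vessel, cm^2 (> 0)
#' @param device_area_cm2 open (pore) area of the device, cm^2 (> 0)
#' @return scaled `sr_rate_curve`
#' @export
scale_rate_to_device <- function(curve, source_area_cm2, device_area_cm2) {
  if (source_area_cm2 <= 0 || device_area_cm2 <= 0) stop("invalid area")
  rate_curve(curve$times_h,
             curve$rate_mg_s * device_area_cm2 / source_area_cm2)
}

#' Total open pore area of a device membrane
#'
#' @param n_pores number of outlet pores
#' @param pore_diameter_um pore diameter, micrometers
#' @return open area, cm^2
#' @examples
#' device_pore_area(1000, 200)  # ~0.314 cm^2
#' @export
device_pore_area <- function(n_pores, pore_diameter_um) {
  if (n_pores <= 0 || pore_diameter_um <= 0) stop("invalid area")
  r_cm <- pore_diameter_um * 1e-4 / 2
  n_pores * pi * r_cm^2
}

#' Build a piecewise-constant release schedule from a rate curve
#'
#' Resamples the piecewise-linear curve to one constant rate per knot
#' interval (the trapezoid-consistent interval mean, so total released mass
#' is preserved), then multiplies the rates inside the exothermic boost
#' window `[0, boost_duration_h]` by `boost_factor`. A breakpoint is
#' inserted at the boost end if it falls inside an interval.
#'
#' @param curve an `sr_rate_curve`
#' @param boost_factor exothermic-activation multiplier (>= 1)
#' @param boost_duration_h boost window length, h (>= 0)
#' @return an [release_schedule()]
#' @export
build_release_schedule <- function(curve, boost_factor = 1,
                                   boost_duration_h = 0) {
  if (boost_factor < 1) stop("invalid boost")
  if (boost_duration_h < 0) stop("invalid boost")
  t <- curve$times_h; r <- curve$rate_mg_s
  if (t[1] != 0) { t <- c(0, t); r <- c(r[1], r) }
  if (boost_duration_h > 0 && boost_duration_h < max(t) &&
      !(boost_duration_h %in% t)) {
    rb <- stats::approx(t, r, xout = boost_duration_h)$y
    idx <- order(c(t, boost_duration_h))
    r <- c(r, rb)[idx]
    t <- sort(c(t, boost_duration_h))
  }
  n <- length(t)
  if (n == 1) {
    bp <- 0; rates <- r
  } else {
    bp <- t[-n]
    rates <- (r[-n] + r[-1]) / 2  # interval mean of the linear curve
    # hold the final knot rate beyond the last measurement
    bp <- c(bp, t[n]); rates <- c(rates, r[n])
  }
  mid <- bp + c(diff(bp) / 2, 0)
  boosted <- mid < boost_duration_h
  rates[boosted] <- rates[boosted] * boost_factor
  release_schedule(bp, rates, boost_factor, boost_duration_h)
}

#' Read / write evaporation series CSV
#'
#' Columns: `time_h, ai_mass_g, solvent_mass_g, water_mass_g`.
#'
#' @param path CSV path
#' @return an [evaporation_series()]
#' @export
read_evaporation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "ai_mass_g", "solvent_mass_g", "water_mass_g")
  if (!all(need %in% names(df))) {
    stop("malformed evaporation CSV: need columns ", paste(need, collapse = ", "))
  }
  evaporation_series(df$time_h, df$ai_mass_g, df$solvent_mass_g, df$water_mass_g)
}

#' @rdname read_evaporation_csv
#' @param series an [evaporation_series()]
#' @export
write_evaporation_csv <- function(series, path) {
  utils::write.csv(data.frame(time_h = series$times_h,
                              ai_mass_g = series$ai_mass_g,
                              solvent_mass_g = series$solvent_mass_g,
                              water_mass_g = series$water_mass_g),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a rate curve CSV (`time_h, rate_mg_s`)
#'
#' @param curve an `sr_rate_curve`
#' @param path CSV path
#' @export
write_rate_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_h = curve$times_h,
                              rate_mg_s = curve$rate_mg_s),
                   path, row.names = FALSE)
  invisible(path)
}
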