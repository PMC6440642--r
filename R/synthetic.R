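# Synthetic-data generators: everything the pipeline consumes can be
# produced here, seeded and reproducible — evaporation series with
# gravimetric noise, scene presets matching the semi-field tent and the
# outdoor ring layouts, and binomial pouch mortality from a known linear
# dose-response. The presets' geometric defaults are documented in the
# methods vignette; the trial-reported quantities (tent dimensions, fan
# speed, wind speed, device rates, pouch counts) are wired in directly.

#' Synthetic mortality generator configuration
#'
#' @param seed integer RNG seed
#' @param noise_sd_mass gravimetric noise SD for evaporation series, g
#' @param true_slope generating dose-response slope, fraction/ppm
#' @param true_intercept generating baseline mortality, fraction
#' @param n_per_pouch mosquitoes per pouch (study default 20)
#' @param control_mortality mortality in control pouches, fraction
#' @return object of class `sr_generator_config`
#' @export
generator_config <- function(seed = 1L, noise_sd_mass = 0.02,
                             true_slope = 4.0, true_intercept = 0.1,
                             n_per_pouch = 20L, control_mortality = 0.05) {
  if (noise_sd_mass < 0) stop("invalid generator config: noise_sd_mass")
  if (n_per_pouch <= 0) stop("invalid generator config: n_per_pouch")
  if (control_mortality < 0 || control_mortality > 1) {
    stop("invalid generator config: control_mortality")
  }
  structure(list(seed = as.integer(seed), noise_sd_mass = noise_sd_mass,
                 true_slope = true_slope, true_intercept = true_intercept,
                 n_per_pouch = as.integer(n_per_pouch),
                 control_mortality = control_mortality),
            class = "sr_generator_config")
}

#' Generate a noisy evaporation series
#'
#' Forward-simulates the kinetic model and adds independent Gaussian
#' gravimetric noise to each reading (clipped at zero mass). The default
#' sampling grid matches the characterization protocol: readings at 0, 12,
#' 24, 48 and 96 h.
#'
#' @param form a [formulation()]
#' @param params an [evap_params()]
#' @param times_h sampling times, h
#' @param noise_sd_mass per-reading mass noise SD, g
#' @param seed integer RNG seed
#' @return an [evaporation_series()]
#' @export
generate_evaporation_series <- function(form, params,
                                        times_h = c(0, 12, 24, 48, 96),
                                        noise_sd_mass = 0.02, seed = 1L) {
  clean <- simulate_evaporation(form, params, times_h)
  if (noise_sd_mass == 0) return(clean)
  set.seed(seed)
  n <- length(times_h)
  noisy <- function(x) pmax(x + stats::rnorm(n, 0, noise_sd_mass), 0)
  evaporation_series(times_h, noisy(clean$ai_mass_g),
                     noisy(clean$solvent_mass_g), noisy(clean$water_mass_g))
}

# device emission rates (mg/s) by formulation and trial window, as reported
TENT_RATES <- list(`24` = c(pct30 = 0.224, pct100 = 0.042),
                   `48` = c(pct30 = 0.116, pct100 = 0.024))

#' Semi-field tent scene preset
#'
#' A 7 x 5 x 3 m tent standing on the ground inside a 9 x 7 x 4 m exterior
#' domain, with door openings on both short walls, two fans blowing inward
#' at 1 m/s at the entrances, ambient wind of 5 km/h along the tent axis,
#' six center devices (three 30%-formulation, three 100%-formulation) at
#' the window-averaged rates of the chosen trial period, and 27 pouches of
#' 20 mosquitoes (a 3 x 3 plan grid at quarter points, at heights 0.5, 1.5
#' and 2.5 m).
#'
#' @param period_h trial period: 24 or 48 h (selects the device rates)
#' @param fan_face_m fan face side length, m
#' @param door_width_m,door_height_m door opening dimensions, m
#' @param n_per_pouch mosquitoes per pouch
#' @return a validated `sr_scene`
#' @export
make_tent_scene <- function(period_h = 24, fan_face_m = 0.5,
                            door_width_m = 1.0, door_height_m = 2.0,
                            n_per_pouch = 20L) {
  if (!period_h %in% c(24, 48)) stop("period_h must be 24 or 48")
  rates <- TENT_RATES[[as.character(period_h)]]
  tent_min <- c(1, 1, 0); tent_max <- c(8, 6, 3)
  ymid <- (tent_min[2] + tent_max[2]) / 2
  doors <- list(
    opening("x-", c(ymid, door_height_m / 2), door_width_m, door_height_m),
    opening("x+", c(ymid, door_height_m / 2), door_width_m, door_height_m)
  )
  enc <- enclosure(tent_min, tent_max, wall_thickness_cells = 1L,
                   openings = doors)
  fans <- list(
    fan(c(tent_min[1] + 0.5, ymid, 1.0), c(1, 0, 0), fan_face_m, fan_face_m, 1.0),
    fan(c(tent_max[1] - 0.5, ymid, 1.0), c(-1, 0, 0), fan_face_m, fan_face_m, 1.0)
  )
  xc <- (tent_min[1] + tent_max[1]) / 2
  devices <- c(
    lapply(1:3, function(i) {
      device_source(c(xc - 0.6 + 0.3 * i, ymid - 0.2, 0.25),
                    release_schedule(0, rates["pct30"]),
                    sprintf("CRD-30pct-%d", i))
    }),
    lapply(1:3, function(i) {
      device_source(c(xc - 0.6 + 0.3 * i, ymid + 0.2, 0.25),
                    release_schedule(0, rates["pct100"]),
                    sprintf("CRD-100pct-%d", i))
    })
  )
  fx <- tent_min[1] + (tent_max[1] - tent_min[1]) * c(0.25, 0.5, 0.75)
  fy <- tent_min[2] + (tent_max[2] - tent_min[2]) * c(0.25, 0.5, 0.75)
  levels <- c(low = 0.5, mid = 1.5, high = 2.5)
  pouches <- list()
  for (i in 1:3) for (j in 1:3) for (l in names(levels)) {
    pouches[[length(pouches) + 1L]] <- pouch_site(
      sprintf("p%d%d-%s", i, j, l), c(fx[i], fy[j], levels[[l]]),
      level_label = l, n_mosquitoes = n_per_pouch)
  }
  scene(domain_box_m = c(9, 7, 4), enclosure = enc,
        ambient_wind_mps = c(5 / 3.6, 0, 0), fans = fans,
        devices = devices, pouches = pouches, duration_h = period_h)
}

#' Outdoor ring scene preset
#'
#' An open domain with six center devices 0.5 m above the ground and 30
#' pouches on two sets of concentric rings (radii 0.5, 1.25 and 2.5 m; 5
#' pouches per ring) at heights 1.0 and 1.5 m, plus 5 control pouches 25 m
#' away (flagged `control`; outside the simulated domain). The trial's
#' ambient wind was not recorded, so the caller must supply a wind vector.
#'
#' @param wind_mps ambient wind vector, m/s (required)
#' @param period_h trial period, h (device rates use the 24 h values for
#'   a 24 h trial, 48 h values otherwise)
#' @param domain_box_m domain extents, m
#' @param n_per_pouch mosquitoes per pouch
#' @return a validated `sr_scene`
#' @export
make_outdoor_scene <- function(wind_mps, period_h = 24,
                               domain_box_m = c(8, 8, 4),
                               n_per_pouch = 20L) {
  if (missing(wind_mps)) stop("outdoor preset requires a wind vector")
  rates <- TENT_RATES[[if (period_h <= 24) "24" else "48"]]
  ctr <- c(domain_box_m[1] / 2, domain_box_m[2] / 2)
  devices <- c(
    lapply(1:3, function(i) {
      device_source(c(ctr[1] - 0.4 + 0.2 * i, ctr[2] - 0.1, 0.5),
                    release_schedule(0, rates["pct30"]),
                    sprintf("CRD-30pct-%d", i))
    }),
    lapply(1:3, function(i) {
      device_source(c(ctr[1] - 0.4 + 0.2 * i, ctr[2] + 0.1, 0.5),
                    release_schedule(0, rates["pct100"]),
                    sprintf("CRD-100pct-%d", i))
    })
  )
  radii <- c(0.5, 1.25, 2.5)
  heights <- c(`1.0m` = 1.0, `1.5m` = 1.5)
  pouches <- list()
  for (h in seq_along(heights)) {
    for (r in seq_along(radii)) {
      for (a in 0:4) {
        # offset the second set so the two heights interleave in azimuth
        theta <- 2 * pi * a / 5 + (h - 1) * pi / 5
        pos <- c(ctr + radii[r] * c(cos(theta), sin(theta)), heights[[h]])
        pouches[[length(pouches) + 1L]] <- pouch_site(
          sprintf("ring%g-h%g-%d", radii[r], heights[[h]], a + 1),
          pos, level_label = names(heights)[h],
          ring_label = sprintf("r%g", radii[r]), n_mosquitoes = n_per_pouch)
      }
    }
  }
  ctrl_dirs <- rbind(c(0, -1), c(0, -1), c(-1, 0), c(1, 0), c(0, 1))
  for (i in seq_len(nrow(ctrl_dirs))) {
    pouches[[length(pouches) + 1L]] <- pouch_site(
      sprintf("control-%d", i), c(ctr + 25 * ctrl_dirs[i, ], 0.5),
      level_label = "control", ring_label = "control",
      n_mosquitoes = n_per_pouch, control = TRUE)
  }
  scene(domain_box_m = domain_box_m, enclosure = NULL,
        ambient_wind_mps = wind_mps, devices = devices, pouches = pouches,
        duration_h = period_h)
}

#' Generate binomial pouch mortality from a known dose-response
#'
#' Each pouch's death probability is the clipped linear response
#' `p = clip(true_intercept + true_slope * c, 0, 1)`; deaths are drawn
#' binomially with `n_per_pouch` trials. Seeded and reproducible.
#'
#' @param concentration_ppm simulated concentration per pouch, ppm (>= 0)
#' @param config an [generator_config()]
#' @param site_id optional pouch ids (default p1, p2, ...)
#' @param level_label,period_h optional metadata per pouch
#' @return an `sr_dose_obs` table
#' @export
generate_pouch_mortality <- function(concentration_ppm, config,
                                     site_id = NULL,
                                     level_label = NA_character_,
                                     period_h = NA_real_) {
  if (any(concentration_ppm < 0)) stop("concentrations must be >= 0")
  m <- length(concentration_ppm)
  if (is.null(site_id)) site_id <- sprintf("p%d", seq_len(m))
  p <- pmin(pmax(config$true_intercept +
                   config$true_slope * concentration_ppm, 0), 1)
  set.seed(config$seed)
  deaths <- stats::rbinom(m, config$n_per_pouch, p)
  dose_observations(site_id, concentration_ppm, deaths,
                    rep(config$n_per_pouch, m),
                    level_label = level_label, period_h = period_h)
}
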