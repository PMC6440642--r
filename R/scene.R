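# Scene description: the geometric and physical configuration of a
# protection-efficacy scenario. Coordinates are in meters, right-handed,
# z up, with the origin at the minimum corner of the domain box; a position
# belongs to the half-open cell [x, x + dx) on each axis when discretized.

#' Active-ingredient formulation
#'
#' A binary formulation of a volatile active ingredient (AI) in a solvent,
#' plus water taken up by hygroscopicity.
#'
#' @param ai_name name of the active ingredient (e.g. "metofluthrin")
#' @param ai_volume_fraction AI volume fraction of the formulation, in [0,1]
#' @param solvent_name solvent name (e.g. "IPA")
#' @param initial_ai_mass_g,initial_solvent_mass_g,initial_water_mass_g
#'   initial component masses, g (all >= 0)
#' @return object of class `sr_formulation`
#' @export
formulation <- function(ai_name = "metofluthrin", ai_volume_fraction,
                        solvent_name = "IPA", initial_ai_mass_g,
                        initial_solvent_mass_g, initial_water_mass_g = 0) {
  if (!is.numeric(ai_volume_fraction) || ai_volume_fraction < 0 ||
      ai_volume_fraction > 1) {
    stop("invalid formulation: ai_volume_fraction must lie in [0, 1]")
  }
  masses <- c(initial_ai_mass_g, initial_solvent_mass_g, initial_water_mass_g)
  if (any(!is.finite(masses)) || any(masses < 0)) {
    stop("invalid formulation: masses must be finite and >= 0")
  }
  structure(list(
    ai_name = as.character(ai_name),
    ai_volume_fraction = as.numeric(ai_volume_fraction),
    solvent_name = as.character(solvent_name),
    initial_ai_mass_g = as.numeric(initial_ai_mass_g),
    initial_solvent_mass_g = as.numeric(initial_solvent_mass_g),
    initial_water_mass_g = as.numeric(initial_water_mass_g)
  ), class = "sr_formulation")
}

#' Fan (prescribed-velocity patch)
#'
#' A fan is modelled as a rectangular patch of prescribed face-normal
#' velocity ("speed jump") inside the flow domain. The normal must be
#' aligned with a coordinate axis, which is how the discrete velocity
#' composition imposes it on cell faces.
#'
#' @param center_m fan face center, m (x, y, z)
#' @param normal unit vector of flow direction; must be +-x, +-y or +-z
#' @param face_width_m,face_height_m fan face dimensions, m (> 0); width is
#'   measured along the first in-plane axis in (x, y, z) order, height along
#'   the second
#' @param speed_mps face-normal air speed, m/s (>= 0)
#' @return object of class `sr_fan`
#' @export
fan <- function(center_m, normal, face_width_m, face_height_m, speed_mps) {
  center_m <- as.numeric(center_m)
  normal <- as.numeric(normal)
  if (length(center_m) != 3 || length(normal) != 3) {
    stop("invalid fan: center and normal must have 3 components")
  }
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-8) stop("invalid fan: |normal| != 1")
  if (sum(abs(normal) > 1e-12) != 1) {
    stop("invalid fan: normal must be axis-aligned")
  }
  if (face_width_m <= 0 || face_height_m <= 0) {
    stop("invalid fan: face dimensions must be > 0")
  }
  if (speed_mps < 0) stop("invalid fan: speed must be >= 0")
  structure(list(
    center_m = center_m, normal = normal,
    face_width_m = as.numeric(face_width_m),
    face_height_m = as.numeric(face_height_m),
    speed_mps = as.numeric(speed_mps)
  ), class = "sr_fan")
}

#' Wall opening (door) on an enclosure face
#'
#' @param face wall face carrying the opening: one of "x-", "x+", "y-",
#'   "y+", "z-", "z+" (minus = low-coordinate wall)
#' @param center_m 2-vector: opening center in the two in-plane axes, in
#'   (x, y, z) order with the face axis removed
#' @param width_m,height_m opening dimensions along the first / second
#'   in-plane axis, m
#' @return object of class `sr_opening`
#' @export
opening <- function(face, center_m, width_m, height_m) {
  if (!face %in% c("x-", "x+", "y-", "y+", "z-", "z+")) {
    stop("invalid opening: unknown face")
  }
  center_m <- as.numeric(center_m)
  if (length(center_m) != 2) stop("invalid opening: center must be 2-vector")
  if (width_m <= 0 || height_m <= 0) stop("invalid opening: dimensions <= 0")
  structure(list(face = face, center_m = center_m,
                 width_m = as.numeric(width_m),
                 height_m = as.numeric(height_m)),
            class = "sr_opening")
}

#' Enclosure (tent) inside the flow domain
#'
#' An axis-aligned box of solid walls with optional rectangular openings
#' (doors). Wall thickness is expressed in grid cells so the discrete wall
#' is always watertight at the chosen resolution.
#'
#' @param box_min_m,box_max_m enclosure extents, m
#' @param wall_thickness_cells wall thickness in grid cells (>= 1)
#' @param openings list of [opening()] objects
#' @return object of class `sr_enclosure`
#' @export
enclosure <- function(box_min_m, box_max_m, wall_thickness_cells = 1L,
                      openings = list()) {
  box_min_m <- as.numeric(box_min_m); box_max_m <- as.numeric(box_max_m)
  if (length(box_min_m) != 3 || length(box_max_m) != 3 ||
      any(box_max_m <= box_min_m)) {
    stop("invalid enclosure: box extents degenerate")
  }
  if (wall_thickness_cells < 1) stop("invalid enclosure: wall thickness < 1")
  for (op in openings) {
    if (!inherits(op, "sr_opening")) stop("invalid enclosure: bad opening")
    ax <- opening_axes(op$face)
    lo <- op$center_m - c(op$width_m, op$height_m) / 2
    hi <- op$center_m + c(op$width_m, op$height_m) / 2
    tol <- 1e-9
    if (any(lo < box_min_m[ax$inplane] - tol) ||
        any(hi > box_max_m[ax$inplane] + tol)) {
      stop("invalid enclosure: opening outside wall face")
    }
  }
  structure(list(box_min_m = box_min_m, box_max_m = box_max_m,
                 wall_thickness_cells = as.integer(wall_thickness_cells),
                 openings = openings),
            class = "sr_enclosure")
}

# face string -> list(axis, side, inplane axes indices)
opening_axes <- function(face) {
  axis <- match(substr(face, 1, 1), c("x", "y", "z"))
  list(axis = axis, side = if (substr(face, 2, 2) == "-") -1L else 1L,
       inplane = setdiff(1:3, axis))
}

#' Piecewise-constant device release schedule
#'
#' `rates_mg_s[i]` applies on the interval
#' `[breakpoints_h[i], breakpoints_h[i+1])`; the last rate holds from the
#' last breakpoint onward. An exothermic activation boost multiplies the
#' rate during the first `boost_duration_h` hours (the stored rates already
#' include the boost; the factor and duration are kept for provenance).
#'
#' @param breakpoints_h strictly increasing times, h, starting at 0
#' @param rates_mg_s emission rate per interval, mg/s (>= 0); same length
#'   as `breakpoints_h`
#' @param boost_factor multiplicative boost already applied over
#'   `[0, boost_duration_h]` (>= 1)
#' @param boost_duration_h boost duration, h (>= 0)
#' @return object of class `sr_schedule`
#' @export
release_schedule <- function(breakpoints_h, rates_mg_s, boost_factor = 1,
                             boost_duration_h = 0) {
  breakpoints_h <- as.numeric(breakpoints_h)
  rates_mg_s <- as.numeric(rates_mg_s)
  if (length(breakpoints_h) < 1 || breakpoints_h[1] != 0 ||
      any(diff(breakpoints_h) <= 0)) {
    stop("invalid schedule: breakpoints must increase strictly from 0")
  }
  if (length(rates_mg_s) != length(breakpoints_h) || any(rates_mg_s < 0)) {
    stop("invalid schedule: one non-negative rate per interval required")
  }
  if (boost_factor < 1) stop("invalid boost")
  if (boost_duration_h < 0) stop("invalid boost")
  structure(list(breakpoints_h = breakpoints_h, rates_mg_s = rates_mg_s,
                 boost_factor = as.numeric(boost_factor),
                 boost_duration_h = as.numeric(boost_duration_h)),
            class = "sr_schedule")
}

#' Evaluate a release schedule
#'
#' @param schedule an [release_schedule()] object
#' @param t_h time(s), h
#' @return emission rate(s), mg/s
#' @export
schedule_rate_at <- function(schedule, t_h) {
  idx <- findInterval(t_h, schedule$breakpoints_h, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  schedule$rates_mg_s[idx]
}

#' Total mass released by a schedule over a window
#'
#' @param schedule an [release_schedule()] object
#' @param duration_h window length, h (window starts at 0)
#' @return released mass, mg
#' @export
schedule_released_mass <- function(schedule, duration_h) {
  bp <- c(schedule$breakpoints_h, Inf)
  total <- 0
  for (i in seq_along(schedule$rates_mg_s)) {
    lo <- bp[i]; hi <- min(bp[i + 1], duration_h)
    if (hi > lo) total <- total + schedule$rates_mg_s[i] * (hi - lo) * 3600
  }
  total
}

#' Point source device
#'
#' @param position_m device position, m; must lie strictly inside the
#'   domain box and in a fluid (non-wall) cell once discretized
#' @param schedule an [release_schedule()]
#' @param label device label, e.g. "CRD-30pct-1"
#' @return object of class `sr_device`
#' @export
device_source <- function(position_m, schedule, label = "device") {
  position_m <- as.numeric(position_m)
  if (length(position_m) != 3) stop("invalid device: position must be 3-vector")
  if (!inherits(schedule, "sr_schedule")) stop("invalid device: schedule")
  structure(list(position_m = position_m, schedule = schedule,
                 label = as.character(label)),
            class = "sr_device")
}

#' Mosquito pouch site
#'
#' A fine-mesh cage of mosquitoes at a fixed position: the spatial mortality
#' sensor of the study. Control pouches sit far from the devices and may lie
#' outside the simulated domain; they are flagged with `control = TRUE` and
#' exempt from the inside-domain check.
#'
#' @param id site identifier
#' @param position_m pouch position, m
#' @param level_label height level label (e.g. "low", "mid", "high")
#' @param ring_label ring label for outdoor layouts ("" if none)
#' @param n_mosquitoes mosquitoes per pouch (> 0; study default 20)
#' @param control logical; TRUE for control pouches
#' @return object of class `sr_pouch`
#' @export
pouch_site <- function(id, position_m, level_label = "", ring_label = "",
                       n_mosquitoes = 20L, control = FALSE) {
  position_m <- as.numeric(position_m)
  if (length(position_m) != 3) stop("invalid pouch: position must be 3-vector")
  if (n_mosquitoes <= 0) stop("invalid pouch: n_mosquitoes must be > 0")
  structure(list(id = as.character(id), position_m = position_m,
                 level_label = as.character(level_label),
                 ring_label = as.character(ring_label),
                 n_mosquitoes = as.integer(n_mosquitoes),
                 control = isTRUE(control)),
            class = "sr_pouch")
}

#' Assemble and validate a scene
#'
#' @param domain_box_m domain extents (Lx, Ly, Lz), m; the domain spans
#'   `[0, L]` on each axis
#' @param enclosure an [enclosure()] or NULL for an open domain
#' @param ambient_wind_mps ambient wind vector, m/s
#' @param fans list of [fan()] objects
#' @param devices list of [device_source()] objects
#' @param pouches list of [pouch_site()] objects
#' @param duration_h trial duration, h (> 0)
#' @param air_temperature_K,air_pressure_Pa air state for ppm conversion
#' @return validated object of class `sr_scene`
#' @export
scene <- function(domain_box_m, enclosure = NULL,
                  ambient_wind_mps = c(0, 0, 0),
                  fans = list(), devices = list(), pouches = list(),
                  duration_h, air_temperature_K = DEFAULT_AIR_TEMPERATURE_K,
                  air_pressure_Pa = DEFAULT_AIR_PRESSURE_PA) {
  sc <- structure(list(
    domain_box_m = as.numeric(domain_box_m),
    enclosure = enclosure,
    ambient_wind_mps = as.numeric(ambient_wind_mps),
    fans = fans, devices = devices, pouches = pouches,
    duration_h = as.numeric(duration_h),
    air_temperature_K = as.numeric(air_temperature_K),
    air_pressure_Pa = as.numeric(air_pressure_Pa)
  ), class = "sr_scene")
  validate_scene(sc)
  sc
}

inside_box <- function(p, box, strict = TRUE, tol = 1e-9) {
  if (strict) all(p > 0 + tol) && all(p < box - tol)
  else all(p >= -tol) && all(p <= box + tol)
}

#' Validate scene invariants
#'
#' Checks every geometric and physical invariant of a scene; stops with an
#' `invalid scene: <field>` message naming the first offending field.
#'
#' @param sc an `sr_scene`
#' @return the scene, invisibly, if valid
#' @export
validate_scene <- function(sc) {
  box <- sc$domain_box_m
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("invalid scene: domain_box_m")
  }
  if (length(sc$ambient_wind_mps) != 3 || any(!is.finite(sc$ambient_wind_mps))) {
    stop("invalid scene: ambient_wind_mps")
  }
  if (!is.finite(sc$duration_h) || sc$duration_h <= 0) {
    stop("invalid scene: duration_h")
  }
  if (sc$air_temperature_K <= 0) stop("invalid scene: air_temperature_K")
  if (sc$air_pressure_Pa <= 0) stop("invalid scene: air_pressure_Pa")
  if (!is.null(sc$enclosure)) {
    if (!inherits(sc$enclosure, "sr_enclosure")) stop("invalid scene: enclosure")
    if (any(sc$enclosure$box_min_m < 0) || any(sc$enclosure$box_max_m > box)) {
      stop("invalid scene: enclosure")
    }
  }
  for (i in seq_along(sc$fans)) {
    f <- sc$fans[[i]]
    if (!inherits(f, "sr_fan") || !inside_box(f$center_m, box)) {
      stop(sprintf("invalid scene: fans[%d].center", i))
    }
  }
  for (i in seq_along(sc$devices)) {
    d <- sc$devices[[i]]
    if (!inherits(d, "sr_device")) stop(sprintf("invalid scene: devices[%d]", i))
    if (!inside_box(d$position_m, box)) {
      stop(sprintf("invalid scene: devices[%d].position", i))
    }
  }
  ids <- character(0)
  for (i in seq_along(sc$pouches)) {
    p <- sc$pouches[[i]]
    if (!inherits(p, "sr_pouch")) stop(sprintf("invalid scene: pouches[%d]", i))
    if (!p$control && !inside_box(p$position_m, box)) {
      stop(sprintf("invalid scene: pouches[%d].position", i))
    }
    ids <- c(ids, p$id)
  }
  if (anyDuplicated(ids)) stop("invalid scene: pouches (duplicate ids)")
  invisible(sc)
}

#' @exportS3Method base::print
print.sr_scene <- function(x, ...) {
  cat(sprintf("<sr_scene> domain %.3g x %.3g x %.3g m, duration %g h\n",
              x$domain_box_m[1], x$domain_box_m[2], x$domain_box_m[3],
              x$duration_h))
  if (!is.null(x$enclosure)) {
    d <- x$enclosure$box_max_m - x$enclosure$box_min_m
    cat(sprintf("  enclosure %.3g x %.3g x %.3g m, %d opening(s)\n",
                d[1], d[2], d[3], length(x$enclosure$openings)))
  }
  cat(sprintf("  wind (%.3g, %.3g, %.3g) m/s; %d fan(s), %d device(s), %d pouch(es)\n",
              x$ambient_wind_mps[1], x$ambient_wind_mps[2],
              x$ambient_wind_mps[3],
              length(x$fans), length(x$devices), length(x$pouches)))
  invisible(x)
}
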