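# Scene configuration I/O. The on-disk format is YAML with units encoded in
# the key names (_m, _mps, _h, _K, _Pa, _mg_s). Unknown keys are rejected so
# typos never silently change a scenario. Numbers are written with full
# precision, which makes read(write(scene)) an exact identity.

SCENE_KEYS <- c("domain_box_m", "enclosure", "ambient_wind_mps", "fans",
                "devices", "pouches", "duration_h", "air_temperature_K",
                "air_pressure_Pa")
ENCLOSURE_KEYS <- c("box_min_m", "box_max_m", "wall_thickness_cells", "openings")
OPENING_KEYS <- c("face", "center_m", "width_m", "height_m")
FAN_KEYS <- c("center_m", "normal", "face_width_m", "face_height_m", "speed_mps")
DEVICE_KEYS <- c("position_m", "schedule", "label")
SCHEDULE_KEYS <- c("breakpoints_h", "rates_mg_s", "boost_factor",
                   "boost_duration_h")
POUCH_KEYS <- c("id", "position_m", "level_label", "ring_label",
                "n_mosquitoes", "control")

check_keys <- function(x, allowed, where, optional = character(0)) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("malformed config: unknown key(s) in %s: %s",
                 where, paste(extra, collapse = ", ")))
  }
  missing <- setdiff(setdiff(allowed, optional), names(x))
  if (length(missing)) {
    stop(sprintf("malformed config: missing key(s) in %s: %s",
                 where, paste(missing, collapse = ", ")))
  }
}

#' Read a scene configuration file
#'
#' Parses and fully validates a YAML scene description (see
#' [write_scene()] for the schema); every scene invariant is checked and
#' unknown keys are rejected.
#'
#' @param path path to a scene YAML file
#' @return validated `sr_scene`
#' @examples
#' sc <- read_scene(system.file("extdata", "example_scene.yaml",
#'                              package = "srvolume"))
#' sc
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop("malformed config: file not found")
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed config: ", conditionMessage(e)))
  if (!is.list(raw)) stop("malformed config: top level must be a mapping")
  check_keys(raw, SCENE_KEYS, "scene", optional = "enclosure")
  enc <- NULL
  if (!is.null(raw$enclosure)) {
    e <- raw$enclosure
    check_keys(e, ENCLOSURE_KEYS, "enclosure")
    ops <- lapply(seq_along(e$openings), function(i) {
      o <- e$openings[[i]]
      check_keys(o, OPENING_KEYS, sprintf("openings[%d]", i))
      opening(o$face, o$center_m, o$width_m, o$height_m)
    })
    enc <- enclosure(e$box_min_m, e$box_max_m, e$wall_thickness_cells, ops)
  }
  fans <- lapply(seq_along(raw$fans), function(i) {
    f <- raw$fans[[i]]
    check_keys(f, FAN_KEYS, sprintf("fans[%d]", i))
    fan(f$center_m, f$normal, f$face_width_m, f$face_height_m, f$speed_mps)
  })
  devices <- lapply(seq_along(raw$devices), function(i) {
    d <- raw$devices[[i]]
    check_keys(d, DEVICE_KEYS, sprintf("devices[%d]", i))
    check_keys(d$schedule, SCHEDULE_KEYS, sprintf("devices[%d].schedule", i))
    sch <- release_schedule(d$schedule$breakpoints_h, d$schedule$rates_mg_s,
                            d$schedule$boost_factor,
                            d$schedule$boost_duration_h)
    device_source(d$position_m, sch, d$label)
  })
  pouches <- lapply(seq_along(raw$pouches), function(i) {
    p <- raw$pouches[[i]]
    check_keys(p, POUCH_KEYS, sprintf("pouches[%d]", i))
    pouch_site(p$id, p$position_m, p$level_label, p$ring_label,
               p$n_mosquitoes, p$control)
  })
  scene(domain_box_m = raw$domain_box_m, enclosure = enc,
        ambient_wind_mps = raw$ambient_wind_mps,
        fans = fans, devices = devices, pouches = pouches,
        duration_h = raw$duration_h,
        air_temperature_K = raw$air_temperature_K,
        air_pressure_Pa = raw$air_pressure_Pa)
}

scene_to_list <- function(sc) {
  enc <- NULL
  if (!is.null(sc$enclosure)) {
    enc <- list(
      box_min_m = sc$enclosure$box_min_m,
      box_max_m = sc$enclosure$box_max_m,
      wall_thickness_cells = sc$enclosure$wall_thickness_cells,
      openings = lapply(sc$enclosure$openings, function(o) {
        list(face = o$face, center_m = o$center_m,
             width_m = o$width_m, height_m = o$height_m)
      })
    )
  }
  list(
    domain_box_m = sc$domain_box_m,
    enclosure = enc,
    ambient_wind_mps = sc$ambient_wind_mps,
    fans = lapply(sc$fans, function(f) {
      list(center_m = f$center_m, normal = f$normal,
           face_width_m = f$face_width_m, face_height_m = f$face_height_m,
           speed_mps = f$speed_mps)
    }),
    devices = lapply(sc$devices, function(d) {
      list(position_m = d$position_m,
           schedule = list(breakpoints_h = d$schedule$breakpoints_h,
                           rates_mg_s = d$schedule$rates_mg_s,
                           boost_factor = d$schedule$boost_factor,
                           boost_duration_h = d$schedule$boost_duration_h),
           label = d$label)
    }),
    pouches = lapply(sc$pouches, function(p) {
      list(id = p$id, position_m = p$position_m,
           level_label = p$level_label, ring_label = p$ring_label,
           n_mosquitoes = p$n_mosquitoes, control = p$control)
    }),
    duration_h = sc$duration_h,
    air_temperature_K = sc$air_temperature_K,
    air_pressure_Pa = sc$air_pressure_Pa
  )
}

#' Write a scene configuration file
#'
#' Serializes a validated scene to YAML. Round-trips exactly:
#' `read_scene(write_scene(sc, path))` reproduces `sc`.
#'
#' @param sc a validated `sr_scene`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scene <- function(sc, path) {
  validate_scene(sc)
  txt <- yaml::as.yaml(scene_to_list(sc), precision = 22L)
  writeLines(txt, path)
  invisible(path)
}
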