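# End-to-end orchestration: scene -> velocity -> transport -> pouch
# concentrations -> mortality (measured or synthetic) -> dose-response fit
# -> threshold inversion -> protection bubble -> report. Every stage is a
# plain exported function; run_pipeline() wires them together, writes the
# artifacts and returns a reproducible run manifest.

pipeline_defaults <- function() {
  list(
    scene = list(preset = "tent24"),
    transport = list(dx = 0.25, eddy_diffusivity = 0.05, dt_s = 1,
                     scheme = "implicit_upwind", window_s = 1800,
                     avg_start_s = 900),
    observations = list(source = "synthetic", true_slope = 4.0,
                        true_intercept = 0.1, n_per_pouch = 20,
                        control_mortality = 0.05),
    dose = list(target = 1.0, abbott = FALSE, by = NULL),
    bubble = list(connectivity = "all"),
    seed = 1L
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the full protection-efficacy pipeline
#'
#' Stages, in order: load or synthesize the scene; discretize and compose
#' the divergence-free flow; solve transient transport over a quasi-steady
#' exposure window; sample pouch concentrations; obtain pouch mortality
#' (from a CSV or the synthetic binomial generator); fit the linear
#' dose-response; invert it at the target mortality; compute the protection
#' bubble. Any stage failure aborts with a stage-tagged error. All
#' randomness derives from `config$seed`.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Sections (all optional, with documented defaults):
#'   `scene` (`preset` = "tent24"/"tent48"/"outdoor" + `wind_mps`, or
#'   `file`), `transport` (`dx`, `eddy_diffusivity`, `dt_s`, `scheme`,
#'   `window_s`, `avg_start_s`), `observations` (`source` = "synthetic"
#'   with generator parameters, or "file" + `file`), `dose` (`target`,
#'   `abbott`, `control_mortality`, `by`), `bubble` (`connectivity`),
#'   `seed`.
#' @param out_dir output directory (created if missing)
#' @return run manifest (list): config hash, seed, package version, stage
#'   timings (s), output paths, warnings, and the headline numbers
#'   (`c_target_ppm`, `voxel_volume_m3`, `mesh_volume_m3`)
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("srvolume_run_")) {
  config_hash <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config)) stop("config error: file not found")
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.na(config_hash)) {
    config_hash <- unname(tools::md5sum(
      textConnection_md5(yaml::as.yaml(cfg, precision = 22L))))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c(); outputs <- character(0)
  warns <- character(0)
  note <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[stage] <<- proc.time()[["elapsed"]] - t0
    res
  }

  sc <- note("scene", {
    s <- cfg$scene
    if (!is.null(s$file)) read_scene(s$file)
    else switch(s$preset,
      tent24 = make_tent_scene(24),
      tent48 = make_tent_scene(48),
      outdoor = make_outdoor_scene(s$wind_mps),
      stop("unknown scene preset"))
  })
  scene_path <- file.path(out_dir, "scene.yaml")
  write_scene(sc, scene_path); outputs <- c(outputs, scene_path)

  field <- note("transport", {
    tr <- cfg$transport
    grid <- build_grid(sc, tr$dx)
    vel <- compose_velocity_field(sc, grid)
    params <- transport_params(eddy_diffusivity = tr$eddy_diffusivity,
                               dt_s = tr$dt_s, scheme = tr$scheme)
    solve_transport(grid, vel, params, sc$devices,
                    duration_h = tr$window_s / 3600,
                    avg_window_s = c(tr$avg_start_s, tr$window_s),
                    conversion = list(temperature_K = sc$air_temperature_K,
                                      pressure_Pa = sc$air_pressure_Pa,
                                      molar_mass = MW_METOFLUTHRIN))
  })
  field_path <- file.path(out_dir, "field_time_average.vtk")
  write_field_vtk(field, field_path); outputs <- c(outputs, field_path)

  conc <- note("sample", pouch_concentration_table(field, sc))
  conc_path <- file.path(out_dir, "pouch_concentrations.csv")
  utils::write.csv(conc, conc_path, row.names = FALSE)
  outputs <- c(outputs, conc_path)

  obs <- note("observations", {
    o <- cfg$observations
    if (identical(o$source, "file")) {
      read_dose_csv(o$file)
    } else {
      gen <- generator_config(seed = cfg$seed,
                              true_slope = o$true_slope,
                              true_intercept = o$true_intercept,
                              n_per_pouch = o$n_per_pouch,
                              control_mortality = o$control_mortality)
      generate_pouch_mortality(conc$c_ppmv, gen, site_id = conc$site_id,
                               level_label = conc$level_label,
                               period_h = sc$duration_h)
    }
  })

  fit <- note("dose", {
    d <- cfg$dose
    if (isTRUE(d$abbott)) {
      ctrl <- if (!is.null(d$control_mortality)) d$control_mortality
              else cfg$observations$control_mortality
      obs$mortality <- abbott_correction(obs$mortality, ctrl)
    }
    f <- fit_linear(obs)
    concentration_for_mortality(f, d$target)
  })
  fit_path <- file.path(out_dir, "fit.csv")
  utils::write.csv(fits_to_table(fit), fit_path, row.names = FALSE)
  outputs <- c(outputs, fit_path)

  bub <- note("bubble", bubble_report(field, fit, sc, cfg$bubble$connectivity))
  bubble_path <- file.path(out_dir, "bubble.json")
  write_bubble_json(bub, bubble_path); outputs <- c(outputs, bubble_path)
  if (!is.null(bub$mesh)) {
    stl_path <- file.path(out_dir, "bubble.stl")
    write_stl_ascii(bub$mesh, stl_path); outputs <- c(outputs, stl_path)
  }

  manifest <- list(
    config_hash = config_hash,
    seed = cfg$seed,
    tool_version = as.character(utils::packageVersion("srvolume")),
    stage_timings_s = as.list(timings),
    outputs = outputs,
    warnings = warns,
    c_target_ppm = fit$c_target,
    r_squared = fit$r_squared,
    voxel_volume_m3 = bub$voxel_volume_m3,
    mesh_volume_m3 = bub$mesh_volume_m3
  )
  missing <- outputs[!file.exists(outputs)]
  if (length(missing)) stop("[manifest] declared outputs missing: ",
                            paste(missing, collapse = ", "))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$manifest_path <- manifest_path
  invisible(manifest)
}

# md5 of an in-memory string via a temp file (tools::md5sum wants a path)
textConnection_md5 <- function(txt) {
  tf <- tempfile()
  writeLines(txt, tf)
  tf
}
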