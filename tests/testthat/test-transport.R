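# Grid construction, velocity composition and the finite-volume solver.

test_that("grids discretize open boxes and reject bad resolutions", {
  sc <- scene(domain_box_m = c(2, 1, 1), duration_h = 1)
  g <- build_grid(sc, 0.5)
  expect_equal(g$shape, c(4L, 2L, 2L))
  expect_false(any(g$solid))
  expect_error(build_grid(sc, -1), "dx")
  expect_error(build_grid(sc, 0.8), "divide|cells")
})

test_that("the tent walls are solid, doors are carved, interior is hollow", {
  sc <- make_tent_scene(24)
  g <- build_grid(sc, 0.25)
  expect_equal(g$shape, c(36L, 28L, 16L))
  # the tent footprint is 7 x 5 x 3 m = 28 x 20 x 12 cells at dx 0.25
  ix <- (round(1 / 0.25) + 1):round(8 / 0.25)
  expect_equal(length(ix), 28)
  # a wall cell away from the doors
  expect_true(g$solid[ix[1], 10, 11])
  # tent interior is fluid
  expect_false(any(g$solid[ix[3:26], 6:23, 2:11]))
  # door cells on the x- wall near mid-height are carved
  jmid <- round(3.5 / 0.25)
  expect_false(g$solid[ix[1], jmid, 4])
  # exterior volume exists around the tent
  expect_false(any(g$solid[1:3, , ]))

  # a coarse grid cannot resolve the 1 m door
  expect_error(build_grid(sc, 1.75), "too coarse|divide")
})

test_that("an enclosure flush with the domain boundary is rejected", {
  enc <- enclosure(c(0, 0, 0), c(2, 2, 2))
  sc <- scene(domain_box_m = c(2, 4, 4), enclosure = enc, duration_h = 1)
  expect_error(build_grid(sc, 0.5), "exterior volume required")
})

test_that("uniform wind in an open empty domain passes projection untouched", {
  sc <- scene(domain_box_m = c(4, 2, 2), duration_h = 1,
              ambient_wind_mps = c(5 / 3.6, 0, 0))
  g <- build_grid(sc, 0.25, ground = FALSE)
  v <- compose_velocity_field(sc, g)
  expect_equal(max(abs(v$U - 5 / 3.6)), 0, tolerance = 1e-12)
  expect_equal(max(abs(v$V)), 0, tolerance = 1e-12)
  expect_lt(v$max_div, 1e-10)
})

test_that("a sealed box with no wind and no fans has zero flow", {
  sc <- scene(domain_box_m = c(2, 2, 2), duration_h = 1)
  g <- build_grid(sc, 0.5)
  v <- compose_velocity_field(sc, g, boundary = "closed")
  expect_equal(max(abs(v$U), abs(v$V), abs(v$W)), 0)
})

test_that("a ducted fan's flux is carried through downstream cross-sections", {
  # fan mounted in the doorway of an enclosure: continuity forces every
  # interior cross-section to carry the prescribed fan flux
  enc <- enclosure(c(1, 1, 0), c(5, 3, 2),
                   openings = list(
                     opening("x-", c(2, 1), 1.0, 1.0),
                     opening("x+", c(2, 1), 1.0, 1.0)))
  sc <- scene(domain_box_m = c(6, 4, 3), enclosure = enc, duration_h = 1,
              fans = list(fan(c(1.25, 2, 1), c(1, 0, 0), 1.0, 1.0, 1.0)))
  g <- build_grid(sc, 0.25)
  v <- compose_velocity_field(sc, g)
  dx <- g$dx
  p <- round(1.25 / dx) + 1
  fan_flux <- sum(v$U[p, , ] * (v$U[p, , ] != 0) *
                    (abs(v$U[p, , ] - 1) < 1e-9)) * dx^2
  expect_gt(fan_flux, 0)
  # interior cross-sections of the enclosure (walls contribute zero)
  jin <- (round(1 / dx) + 2):(round(3 / dx) - 1)
  kin <- 1:(round(2 / dx) - 1)
  for (xplane in round(c(2, 3, 4) / dx) + 1) {
    flux <- sum(v$U[xplane, jin, kin]) * dx^2
    expect_lt(abs(flux - fan_flux), 0.01 * fan_flux)
  }
})

test_that("a closed box conserves injected mass exactly in the source cell", {
  sc <- minimal_scene(rate = 1, box = c(2, 1, 1))
  g <- build_grid(sc, 0.25)
  v <- compose_velocity_field(sc, g, boundary = "closed")
  # zero velocity, zero-ish diffusivity: all mass stays in the source cell
  p <- transport_params(eddy_diffusivity = 1e-12, dt_s = 1,
                        scheme = "explicit_upwind", boundary = "closed")
  f <- solve_transport(g, v, p, sc$devices, duration_h = 100 / 3600)
  total <- sum(f$snapshots[[1]]$values) * g$dx^3
  expect_equal(total, 100, tolerance = 1e-9)
  idx <- f$source_cells[1, ]
  expect_equal(f$snapshots[[1]]$values[idx[1], idx[2], idx[3]] * g$dx^3,
               100, tolerance = 1e-6)
})

test_that("strong diffusion mixes a closed box to the conservation mean", {
  sc <- scene(domain_box_m = c(2.5, 2, 2), duration_h = 1,
              devices = list(device_source(c(1.25, 1, 1),
                                           release_schedule(0, 1), "d")))
  g <- build_grid(sc, 0.25)
  v <- compose_velocity_field(sc, g, boundary = "closed")
  p <- transport_params(eddy_diffusivity = 0.5, dt_s = 1, boundary = "closed")
  f <- solve_transport(g, v, p, sc$devices, duration_h = 1000 / 3600,
                       avg_window_s = c(999, 1000))
  final <- f$snapshots[[length(f$snapshots)]]$values
  expect_lt(f$mass_balance_rel_error, 1e-9)
  expect_equal(mean(final), 1000 / 10, tolerance = 1e-9)  # 1000 mg in 10 m^3
  expect_lt(stats::sd(final) / mean(final), 0.01)
})

test_that("implicit and explicit schemes agree on the well-mixed box", {
  sc <- scene(domain_box_m = c(2, 1, 1), duration_h = 1,
              devices = list(device_source(c(1, 0.5, 0.5),
                                           release_schedule(0, 0.5), "d")))
  g <- build_grid(sc, 0.25)
  v <- compose_velocity_field(sc, g, boundary = "closed")
  pim <- transport_params(eddy_diffusivity = 0.3, dt_s = 0.5,
                          boundary = "closed")
  pex <- transport_params(eddy_diffusivity = 0.3, dt_s = 0.015,
                          scheme = "explicit_upwind", boundary = "closed")
  fim <- solve_transport(g, v, pim, sc$devices, duration_h = 200 / 3600)
  fex <- solve_transport(g, v, pex, sc$devices, duration_h = 200 / 3600)
  a <- fim$snapshots[[length(fim$snapshots)]]$values
  b <- fex$snapshots[[length(fex$snapshots)]]$values
  expect_lt(max(abs(a - b)) / max(b), 0.02)
})

test_that("explicit steps exceeding the stability limit are refused", {
  sc <- minimal_scene()
  g <- build_grid(sc, 0.25)
  v <- compose_velocity_field(sc, g, boundary = "closed")
  p <- transport_params(eddy_diffusivity = 0.5, dt_s = 5,
                        scheme = "explicit_upwind", boundary = "closed")
  expect_error(solve_transport(g, v, p, sc$devices, duration_h = 0.1),
               "unstable step size")
})

test_that("sources inside walls are refused", {
  enc <- enclosure(c(1, 1, 0), c(3, 3, 2))
  sc <- scene(domain_box_m = c(4, 4, 3), enclosure = enc, duration_h = 1,
              devices = list(device_source(c(1.1, 2, 1.5),
                                           release_schedule(0, 1), "d")))
  g <- build_grid(sc, 0.25)
  v <- compose_velocity_field(sc, g)
  p <- transport_params(eddy_diffusivity = 0.05, dt_s = 1)
  expect_error(solve_transport(g, v, p, sc$devices, duration_h = 0.01),
               "source inside wall")
})

test_that("upwind concentrations stay non-negative under wind and diffusion", {
  sc <- scene(domain_box_m = c(4, 2, 2), duration_h = 1,
              ambient_wind_mps = c(1, 0.3, 0),
              devices = list(device_source(c(1, 1, 1),
                                           release_schedule(0, 1), "d")))
  g <- build_grid(sc, 0.25, ground = FALSE)
  v <- compose_velocity_field(sc, g)
  p <- transport_params(eddy_diffusivity = 0.05, dt_s = 0.05,
                        scheme = "explicit_upwind")
  f <- solve_transport(g, v, p, sc$devices, duration_h = 60 / 3600)
  expect_true(all(f$snapshots[[1]]$values >= 0))
  expect_lt(f$mass_balance_rel_error, 1e-9)
  expect_gt(f$outflow_mass_mg, 0)
})

test_that("a pure-diffusion point release approaches the Gaussian kernel", {
  D <- 0.002
  src <- c(1.55, 1.55, 1.55)
  sc <- scene(domain_box_m = c(3, 3, 3), duration_h = 1,
              devices = list(device_source(src,
                                           release_schedule(c(0, 0.5 / 3600),
                                                            c(720, 0)), "d")))
  g <- build_grid(sc, 0.1, ground = FALSE)
  v <- compose_velocity_field(sc, g)
  p <- transport_params(eddy_diffusivity = D, dt_s = 0.25,
                        scheme = "explicit_upwind")
  t_end <- 50
  f <- solve_transport(g, v, p, sc$devices, duration_h = t_end / 3600)
  M <- f$injected_mass_mg  # 720 mg/s for 0.5 s
  pts <- expand.grid(x = src[1] + c(-0.5, -0.4, 0.4, 0.5),
                     y = src[2], z = src[3])
  num <- sample_at_points(f, as.matrix(pts), stat = length(f$snapshots))
  r <- abs(pts$x - src[1])  # >= 3 cells from the source
  ana <- M / (4 * pi * D * t_end)^1.5 * exp(-r^2 / (4 * D * t_end))
  expect_lt(max(abs(num - ana) / ana), 0.10)
})

test_that("trilinear sampling is exact for uniform and linear fields", {
  f <- synthetic_field(function(x, y, z) 7, box = c(2, 2, 2), dx = 0.25)
  pts <- matrix(runif(15, 0.3, 1.7), ncol = 3)
  expect_equal(sample_at_points(f, pts), rep(7, 5), tolerance = 1e-12)

  flin <- synthetic_field(function(x, y, z) 2 + 3 * x, box = c(2, 2, 2),
                          dx = 0.25)
  pts <- cbind(runif(5, 0.3, 1.7), 1, 1)
  expect_equal(sample_at_points(flin, pts), 2 + 3 * pts[, 1],
               tolerance = 1e-12)

  # cell-center sampling equals the nearest-cell value on a random field
  set.seed(9)
  frand <- synthetic_field(function(x, y, z) 0, box = c(2, 2, 2), dx = 0.25)
  frand$time_average <- array(runif(prod(frand$grid$shape)),
                              dim = frand$grid$shape)
  idx <- cbind(sample(1:8, 5, TRUE), sample(1:8, 5, TRUE), sample(1:8, 5, TRUE))
  centers <- (idx - 0.5) * 0.25
  expect_equal(sample_at_points(frand, centers),
               frand$time_average[idx], tolerance = 1e-12)

  expect_error(sample_at_points(f, matrix(c(5, 5, 5), 1)), "outside domain")
})

test_that("ppm conversion follows the ideal-gas relation and round-trips", {
  expect_equal(mass_conc_to_ppmv(0), 0)
  expect_equal(mass_conc_to_ppmv(1, 360.45, 298.15, 101325),
               8.314462618 * 298.15 / 101325 * 1e3 / 360.45,
               tolerance = 1e-12)
  expect_equal(mass_conc_to_ppmv(1), 0.0679, tolerance = 1e-3)
  expect_equal(ppmv_to_mass_conc(mass_conc_to_ppmv(1)), 1, tolerance = 1e-12)
  expect_error(mass_conc_to_ppmv(1, -1), "positive")
})
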