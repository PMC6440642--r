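# Evaporation kinetics, rate estimation and schedule construction.

pure_ai_form <- function(m0 = 1) formulation(
  ai_volume_fraction = 1, initial_ai_mass_g = m0,
  initial_solvent_mass_g = 0, initial_water_mass_g = 0)

test_that("pure AI evaporates linearly at k_ai * A until exhaustion", {
  par <- evap_params(k_ai = 0.01, k_solvent = 0, surface_area_cm2 = 1)
  ser <- simulate_evaporation(pure_ai_form(1), par, times_h = 0:10)
  expect_equal(ser$ai_mass_g, pmax(1 - 0.01 * (0:10), 0), tolerance = 1e-10)
  expect_equal(ser$solvent_mass_g, rep(0, 11))
})

test_that("with inert solvent (k_solvent = 0, alpha = 0) the components decouple", {
  par <- evap_params(k_ai = 0.02, k_solvent = 0, alpha = 0,
                     surface_area_cm2 = 2)
  form <- formulation(ai_volume_fraction = 0.5, initial_ai_mass_g = 1,
                      initial_solvent_mass_g = 1)
  ser <- simulate_evaporation(form, par, times_h = seq(0, 5, 0.5))
  expect_equal(ser$solvent_mass_g, rep(1, 11), tolerance = 1e-12)
  # AI loss rate is k_ai * A * x_ai with x_ai < 1, so slower than pure AI
  pure <- simulate_evaporation(pure_ai_form(1), par, times_h = seq(0, 5, 0.5))
  expect_true(all(ser$ai_mass_g[-1] > pure$ai_mass_g[-1]))
})

test_that("two-component kinetics match an independent stiff integrator", {
  skip_if_not_installed("deSolve")
  par <- evap_params(k_ai = 0.005, k_solvent = 0.08, alpha = 5,
                     k_water_uptake = 1e-4, surface_area_cm2 = 5.7,
                     water_ceiling_g = 0.5)
  form <- formulation(ai_volume_fraction = 0.3, initial_ai_mass_g = 1.2,
                      initial_solvent_mass_g = 2.2,
                      initial_water_mass_g = 0.01)
  times <- seq(0, 24, 2)
  mine <- simulate_evaporation(form, par, times)
  rhs <- function(t, y, p) list(srvolume:::evap_derivs(y, par))
  ref <- deSolve::ode(c(1.2, 2.2, 0.01), times, rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  m_ref <- unname(ref[, 2:4])
  m_mine <- cbind(mine$ai_mass_g, mine$solvent_mass_g, mine$water_mass_g)
  expect_lt(max(abs(m_mine - m_ref) / pmax(m_ref, 1e-9)), 1e-6)
})

test_that("mass is conserved: initial - final = integral of emission", {
  par <- evap_params(k_ai = 0.01, k_solvent = 0.05, alpha = 3,
                     surface_area_cm2 = 4)
  form <- formulation(ai_volume_fraction = 0.3, initial_ai_mass_g = 1,
                      initial_solvent_mass_g = 1.5)
  times <- seq(0, 48, 0.25)
  ser <- simulate_evaporation(form, par, times)
  curve <- estimate_rate_curve(ser)
  # trapezoid integral of the estimated mg/s curve, back to grams
  rate_g_h <- curve$rate_mg_s * 3.6
  integral <- sum(diff(times) * (head(rate_g_h, -1) + tail(rate_g_h, -1)) / 2)
  expect_equal(integral, ser$ai_mass_g[1] - ser$ai_mass_g[length(times)],
               tolerance = 1e-3)
})

test_that("formulation AI rates converge to the pure-AI rate as solvent depletes", {
  par <- evap_params(k_ai = 0.002, k_solvent = 0.15, alpha = 5,
                     surface_area_cm2 = 5.7)
  times <- seq(0, 96, 1)
  fracs <- c(0.2, 0.35, 0.5)
  total0 <- 12  # grams of formulation in the tube
  finals <- vapply(fracs, function(fr) {
    form <- formulation(ai_volume_fraction = fr,
                        initial_ai_mass_g = total0 * fr * 1.1,
                        initial_solvent_mass_g = total0 * (1 - fr) * 0.786)
    ser <- simulate_evaporation(form, par, times)
    nlast <- length(times)
    expect_gt(ser$ai_mass_g[nlast], 0)  # AI not exhausted at 96 h
    x_s_final <- ser$solvent_mass_g[nlast] /
      (ser$ai_mass_g[nlast] + ser$solvent_mass_g[nlast])
    expect_lt(x_s_final, 0.02)  # solvent depleted by 96 h
    curve <- estimate_rate_curve(ser)
    curve$rate_mg_s[nlast]
  }, numeric(1))
  pure_rate <- par$k_ai * par$surface_area_cm2 * 1000 / 3600
  # all final rates within 10% of the pure-AI areal rate
  expect_true(all(abs(finals - pure_rate) / pure_rate < 0.1))
})

test_that("more solvent never slows instantaneous AI emission at equal AI mass", {
  par <- evap_params(k_ai = 0.01, k_solvent = 0.02, alpha = 4,
                     surface_area_cm2 = 3)
  ai <- 1
  rates <- vapply(c(0, 0.5, 1, 2, 4), function(ms) {
    -srvolume:::evap_derivs(c(ai, ms, 0), par)[1] * ai  # per unit x_ai
  }, numeric(1))
  # normalized AI flux k_ai*(1+alpha*x_s)*A is non-decreasing in solvent
  xs <- c(0, 0.5, 1, 2, 4) / (ai + c(0, 0.5, 1, 2, 4))
  flux <- par$k_ai * (1 + par$alpha * xs) * par$surface_area_cm2
  expect_true(all(diff(flux) >= 0))
  expect_true(all(diff(vapply(c(0, 0.5, 1, 2, 4), function(ms) {
    d <- srvolume:::evap_derivs(c(ai, ms, 0), par)
    -d[1] / (ai / (ai + ms))  # flux per unit mass fraction
  }, numeric(1))) >= -1e-12))
})

test_that("finite differences recover linear decay and floor noise at zero", {
  ser <- evaporation_series(c(0, 12, 24), c(1.0, 0.5, 0.0), rep(0, 3))
  curve <- estimate_rate_curve(ser)
  expect_equal(curve$rate_mg_s, rep(0.5 / 12 * 1000 / 3600, 3),
               tolerance = 1e-12)

  flat <- evaporation_series(c(0, 12, 24), rep(1, 3), rep(0, 3))
  expect_equal(estimate_rate_curve(flat)$rate_mg_s, rep(0, 3))

  rising <- evaporation_series(c(0, 12, 24), c(1.0, 1.1, 1.0), rep(0, 3))
  expect_warning(cr <- estimate_rate_curve(rising), "floored")
  expect_true(all(cr$rate_mg_s >= 0))

  expect_error(estimate_rate_curve(evaporation_series(0, 1, 0)),
               "insufficient series")
})

test_that("rate-curve estimation refines toward generator truth on denser grids", {
  par <- evap_params(k_ai = 0.01, k_solvent = 0.05, alpha = 3,
                     surface_area_cm2 = 4)
  form <- formulation(ai_volume_fraction = 0.3, initial_ai_mass_g = 2,
                      initial_solvent_mass_g = 1.5)
  true_rate_at <- function(ser, i) {
    m <- c(ser$ai_mass_g[i], ser$solvent_mass_g[i], ser$water_mass_g[i])
    -srvolume:::evap_derivs(m, par)[1] * 1000 / 3600
  }
  errs <- vapply(c(2, 1, 0.5), function(step) {
    times <- seq(0, 12, step)
    ser <- simulate_evaporation(form, par, times)
    curve <- estimate_rate_curve(ser)
    interior <- 2:(length(times) - 1)
    truth <- vapply(interior, function(i) true_rate_at(ser, i), numeric(1))
    max(abs(curve$rate_mg_s[interior] - truth) / truth)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # truncation error shrinks with the grid
  expect_lt(errs[3], 1e-3)
})

test_that("noisy generated series recover the noiseless rates approximately", {
  par <- evap_params(k_ai = 0.005, k_solvent = 0.08, alpha = 5,
                     surface_area_cm2 = 5.7)
  form <- formulation(ai_volume_fraction = 0.3, initial_ai_mass_g = 1.2,
                      initial_solvent_mass_g = 2.2)
  times <- seq(0, 96, 4)
  clean <- simulate_evaporation(form, par, times)
  clean_rates <- estimate_rate_curve(clean)$rate_mg_s
  noisy <- generate_evaporation_series(form, par, times,
                                       noise_sd_mass = 0.005, seed = 7)
  noisy_rates <- suppressWarnings(estimate_rate_curve(noisy)$rate_mg_s)
  # noise sd 5 mg over 4 h spacing -> rate sd ~ sqrt(2)*0.005/8 g/h
  tol <- 6 * sqrt(2) * 0.005 / 8 * 1000 / 3600
  expect_lt(max(abs(noisy_rates - clean_rates)), tol)
})

test_that("area scaling multiplies rates by the device/source ratio", {
  curve <- rate_curve(c(0, 12), c(2, 1))
  expect_equal(scale_rate_to_device(curve, 10, 10)$rate_mg_s, c(2, 1))
  expect_equal(scale_rate_to_device(curve, 10, 5)$rate_mg_s, c(1, 0.5))
  expect_error(scale_rate_to_device(curve, 0, 5), "invalid area")
  # 1000 pores of 200 um diameter
  expect_equal(device_pore_area(1000, 200), 1000 * pi * 0.01^2)
  expect_equal(device_pore_area(1000, 200), 0.3142, tolerance = 1e-3)
})

test_that("release schedules preserve boosted mass integrals", {
  flat <- rate_curve(c(0, 24), c(0.1, 0.1))
  sch0 <- build_release_schedule(flat, boost_factor = 1)
  expect_equal(schedule_rate_at(sch0, c(0, 10, 23.9)), rep(0.1, 3))

  sch <- build_release_schedule(flat, boost_factor = 2, boost_duration_h = 8)
  expect_equal(schedule_released_mass(sch, 24),
               0.2 * 8 * 3600 + 0.1 * 16 * 3600)
  expect_error(build_release_schedule(flat, boost_factor = 0.5),
               "invalid boost")

  # piecewise-linear curve: schedule preserves the trapezoid integral
  tri <- rate_curve(c(0, 6, 24), c(0.3, 0.1, 0.1))
  sch2 <- build_release_schedule(tri)
  expect_equal(schedule_released_mass(sch2, 24),
               ((0.3 + 0.1) / 2 * 6 + 0.1 * 18) * 3600)
})

test_that("evaporation CSV I/O round-trips", {
  ser <- evaporation_series(c(0, 12, 24, 48, 96),
                            c(2, 1.5, 1.2, 0.9, 0.5),
                            c(3, 1, 0.3, 0.05, 0),
                            c(0, 0.02, 0.04, 0.05, 0.05))
  path <- tempfile(fileext = ".csv")
  write_evaporation_csv(ser, path)
  expect_equal(read_evaporation_csv(path), ser)
})
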