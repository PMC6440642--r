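# Fixtures shared across tests; everything is built in code.

# a conversion triple for which ppm == mg/m^3 (molar mass chosen so the
# ideal-gas factor is exactly 1); lets geometric tests state thresholds
# directly in field units
identity_conversion <- function() {
  list(temperature_K = 298.15, pressure_Pa = 101325,
       molar_mass = 8.314462618 * 298.15 / 101325 * 1e3)
}

# wrap an analytic function c(x, y, z) into an sr_conc_field on an open box
synthetic_field <- function(fun, box = c(4, 4, 4), dx = 0.1,
                            source_cells = NULL) {
  sc <- scene(domain_box_m = box, duration_h = 1)
  grid <- build_grid(sc, dx, ground = FALSE)
  n <- grid$shape
  ctr <- lapply(1:3, function(a) (seq_len(n[a]) - 0.5) * dx)
  vals <- array(0, dim = n)
  for (k in seq_len(n[3])) {
    xy <- outer(ctr[[1]], ctr[[2]],
                function(x, y) fun(x, y, ctr[[3]][k]) + 0 * x)
    vals[, , k] <- xy
  }
  structure(list(grid = grid,
                 snapshots = list(list(time_s = 0, values = vals)),
                 time_average = vals, avg_window_s = c(0, 1),
                 outflow_mass_mg = 0, injected_mass_mg = sum(vals) * dx^3,
                 mass_balance_rel_error = 0,
                 source_cells = source_cells,
                 conversion = identity_conversion()),
            class = "sr_conc_field")
}

# minimal open-box scene with one device
minimal_scene <- function(rate = 1, box = c(2, 1, 1)) {
  scene(domain_box_m = box, duration_h = 1,
        devices = list(device_source(box / 2, release_schedule(0, rate), "d")))
}

# a random valid scene for round-trip property tests
random_scene <- function() {
  box <- runif(3, 4, 10)
  enc <- NULL
  if (runif(1) < 0.5) {
    lo <- runif(3, 0.5, 1.5); hi <- box - runif(3, 0.5, 1.5)
    lo[3] <- 0  # enclosures stand on the ground
    ops <- list()
    if (runif(1) < 0.7) {
      ops <- list(opening("x-", c(mean(c(lo[2], hi[2])), 0.75), 0.8, 1.5))
    }
    enc <- enclosure(lo, hi, sample(1:2, 1), ops)
  }
  nfan <- sample(0:2, 1)
  fans <- lapply(seq_len(nfan), function(i) {
    ax <- sample(1:3, 1)
    nrm <- c(0, 0, 0); nrm[ax] <- sample(c(-1, 1), 1)
    fan(runif(3, 1, 3), nrm, runif(1, 0.2, 0.8), runif(1, 0.2, 0.8),
        runif(1, 0, 2))
  })
  ndev <- sample(1:3, 1)
  devices <- lapply(seq_len(ndev), function(i) {
    nb <- sample(1:3, 1)
    bp <- c(0, sort(runif(nb - 1, 1, 20)))
    device_source(runif(3, 0.5, 3), release_schedule(bp, runif(nb, 0, 0.5),
                                                     1 + runif(1), runif(1, 0, 8)),
                  sprintf("dev%d", i))
  })
  npou <- sample(0:4, 1)
  pouches <- lapply(seq_len(npou), function(i) {
    pouch_site(sprintf("p%d", i), runif(3, 0.5, 3),
               level_label = sample(c("low", "mid", "high"), 1),
               n_mosquitoes = sample(10:25, 1),
               control = runif(1) < 0.1)
  })
  scene(domain_box_m = box, enclosure = enc,
        ambient_wind_mps = runif(3, -1, 1), fans = fans, devices = devices,
        pouches = pouches, duration_h = runif(1, 1, 48),
        air_temperature_K = runif(1, 280, 310),
        air_pressure_Pa = runif(1, 9e4, 1.1e5))
}
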