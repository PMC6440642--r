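# Dose-response regression, threshold inversion and stratified analysis.

make_obs <- function(conc, mortality, n = 20, ...) {
  deaths <- round(mortality * n)
  dose_observations(sprintf("p%d", seq_along(conc)), conc, deaths, n, ...)
}

test_that("Abbott correction handles the standard cases", {
  expect_equal(abbott_correction(0.6, 0.2), 0.5)
  expect_equal(abbott_correction(0.37, 0), 0.37)        # identity at zero control
  expect_warning(res <- abbott_correction(0.1, 0.2), "clipped")
  expect_equal(res, 0)
  expect_error(abbott_correction(0.5, 1), "degenerate control")
  # monotone in observed mortality
  obs <- seq(0, 1, 0.05)
  expect_true(all(diff(suppressWarnings(
    abbott_correction(obs, 0.15))) >= 0))
})

test_that("collinear points give the exact line", {
  obs <- make_obs(c(0, 1, 2), c(0.1, 0.5, 0.9), n = 10)
  fit <- fit_linear(obs)
  expect_equal(fit$slope, 0.4, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("OLS equals the brute-force normal-equations oracle", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(3:40, 1)
    x <- runif(m, 0, 0.5)
    if (diff(range(x)) == 0) next
    deaths <- sample(0:20, m, replace = TRUE)
    obs <- dose_observations(sprintf("p%d", 1:m), x, deaths, 20)
    fit <- fit_linear(obs)
    # normal equations assembled by hand
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% obs$mortality)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
    expect_equal(fit$slope, beta[2], tolerance = 1e-12)
    ssr <- sum((obs$mortality - X %*% beta)^2)
    sst <- sum((obs$mortality - mean(obs$mortality))^2)
    if (sst > 0) expect_equal(fit$r_squared, 1 - ssr / sst, tolerance = 1e-10)
  }
})

test_that("degenerate regressions are rejected", {
  expect_error(fit_linear(make_obs(c(1, 2), c(0.1, 0.2))), "insufficient data")
  expect_error(fit_linear(make_obs(c(1, 1, 1), c(0.1, 0.2, 0.3))),
               "no dose variation")
})

test_that("threshold inversion is exact and self-consistent", {
  fit <- fit_linear(make_obs(c(0, 1, 2), c(0.1, 0.5, 0.9)))
  inv <- suppressWarnings(concentration_for_mortality(fit, 1.0))
  expect_equal(inv$c_target, 2.25, tolerance = 1e-12)
  expect_equal(predict_mortality(inv, inv$c_target), 1.0, tolerance = 1e-12)
  # extrapolation beyond observed range is flagged
  expect_warning(concentration_for_mortality(fit, 1.0), "extrapolates")

  # saturated baseline clips to zero with warning
  sat <- fit_linear(make_obs(c(0, 1, 2), c(0.95, 0.97, 1.0)))
  expect_warning(inv0 <- concentration_for_mortality(sat, 0.9), "exceeds target")
  expect_equal(inv0$c_target, 0)

  neg <- fit_linear(make_obs(c(0, 1, 2), c(0.9, 0.5, 0.1)))
  expect_error(concentration_for_mortality(neg, 1.0),
               "non-positive dose effect")
  expect_error(concentration_for_mortality(fit, 0), "target mortality")
})

test_that("simulated binomial data recover the generating parameters", {
  true_slope <- 4; true_int <- 0.1
  conc <- rep(seq(0.02, 0.2, length.out = 9), each = 3)  # 27 pouches
  nseeds <- 50
  slopes <- numeric(nseeds); c100 <- numeric(nseeds)
  for (s in seq_len(nseeds)) {
    gen <- generator_config(seed = s, true_slope = true_slope,
                            true_intercept = true_int)
    obs <- generate_pouch_mortality(conc, gen)
    fit <- fit_linear(obs)
    slopes[s] <- fit$slope
    c100[s] <- suppressWarnings(
      concentration_for_mortality(fit, 1.0)$c_target)
  }
  se <- stats::sd(slopes) / sqrt(nseeds)
  expect_lt(abs(mean(slopes) - true_slope), 2 * se + 1e-9)
  true_c100 <- (1 - true_int) / true_slope
  expect_lt(abs(mean(c100) - true_c100) / true_c100, 0.1)
})

test_that("stratified fits are per-stratum and tolerate degenerate strata", {
  obs1 <- make_obs(c(0, 0.1, 0.2, 0.3), c(0.1, 0.3, 0.5, 0.7),
                   level_label = "low")
  obs2 <- obs1; obs2$level_label <- "high"
  both <- rbind(obs1, obs2)
  class(both) <- class(obs1)
  res <- stratified_fits(both, by = "level_label")
  expect_length(res$fits, 2)
  expect_equal(res$fits[["low"]]$slope, res$fits[["high"]]$slope)

  # one stratum without dose variation is skipped, not fatal
  obs3 <- make_obs(rep(0.2, 4), c(0.4, 0.5, 0.45, 0.55), level_label = "mid")
  withmid <- rbind(both, obs3)
  class(withmid) <- class(obs1)
  res2 <- stratified_fits(withmid, by = "level_label")
  expect_length(res2$fits, 2)
  expect_match(res2$skipped[["mid"]], "no dose variation")

  expect_error(stratified_fits(obs3, by = "level_label"), "no fittable strata")
})

test_that("a steeper low-level response yields a lower stratified C100", {
  conc <- rep(seq(0.05, 0.25, length.out = 9), 2)
  lvl <- rep(c("low", "high"), each = 9)
  hits <- 0
  nrep <- 100
  for (s in seq_len(nrep)) {
    p_low <- pmin(0.1 + 6 * conc[1:9], 1)
    p_high <- pmin(0.1 + 3 * conc[10:18], 1)
    set.seed(1000 + s)
    deaths <- rbinom(18, 20, c(p_low, p_high))
    obs <- dose_observations(sprintf("p%d", 1:18), conc, deaths, 20,
                             level_label = lvl)
    res <- suppressWarnings(
      stratified_fits(obs, by = "level_label", target = 1.0))
    c_low <- res$fits[["low"]]$c_target
    c_high <- res$fits[["high"]]$c_target
    if (!is.null(c_low) && !is.null(c_high) && c_low < c_high) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("logistic alternative fits and inverts sanely", {
  set.seed(3)
  conc <- seq(0.01, 0.4, length.out = 30)
  p <- plogis(-2 + 15 * conc)
  obs <- dose_observations(sprintf("p%d", 1:30), conc,
                           rbinom(30, 50, p), 50)
  fit <- fit_logistic(obs)
  expect_equal(fit$slope, 15, tolerance = 0.35)
  inv <- suppressWarnings(concentration_for_mortality(fit, 0.9))
  expect_equal(predict_mortality(inv, inv$c_target), 0.9, tolerance = 1e-9)
  expect_error(concentration_for_mortality(fit, 1.0), "asymptotically")
})

test_that("dose CSV I/O round-trips the observation table", {
  obs <- make_obs(c(0.05, 0.1, 0.2), c(0.2, 0.45, 0.8),
                  level_label = c("low", "mid", "high"), period_h = 24)
  path <- tempfile(fileext = ".csv")
  write_dose_csv(obs, path)
  back <- read_dose_csv(path)
  expect_equal(back$mortality, obs$mortality)
  expect_equal(back$concentration_ppm, obs$concentration_ppm)
  expect_equal(back$level_label, obs$level_label)
})
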