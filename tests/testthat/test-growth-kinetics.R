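# Trajectory preprocessing and Theil-Sen rate/lag/yield extraction.

test_that("pathlength correction and blank arithmetic match their definitions", {
  expect_equal(pathlength_correct(0.28, 0.56), 0.5)
  expect_equal(pathlength_correct(c(1, 2, 3), 1), c(1, 2, 3))
  expect_error(pathlength_correct(1, 0), "> 0")

  expect_equal(estimate_blank_absorbance(c(0.110, 0.112, 0.2), 0.01), 0.101)
  expect_equal(estimate_blank_absorbance(c(0.110, 0.112), 0), 0.111)
  expect_error(estimate_blank_absorbance(0.1, 0.01), "at least 2")
})

test_that("global fluorescence blank averages over non-marker wells", {
  readings <- tibble::tibble(
    time_h = rep(0:2, 2),
    well = rep(c("A1", "B1"), each = 3),
    channel = "YFP",
    value = c(500, 600, 700, 50, 50, 50)
  )
  meta <- tibble::tibble(well = c("A1", "B1"),
                         marker = c("YFP", "CFP"))
  expect_equal(estimate_blank_fluorescence(readings, meta, "YFP"), 50)
  meta2 <- tibble::tibble(well = c("A1", "B1"), marker = c("YFP", "YFP"))
  expect_error(estimate_blank_fluorescence(readings, meta2, "YFP"),
               "No wells")
})

test_that("blank and pathlength recovery from the generator round-trips", {
  ro <- noiseless_readout(od_blank = 0.09, od_per_bu = 0.56)
  s <- strain_params("S", 0.47, initial_abundance = 1e-2, yield_cap = 0.5,
                     marker = "none")
  sim <- simulate_growth_curve(s, ro, seq(0, 24, by = 1 / 6))
  bu <- pathlength_correct(sim$value[sim$channel == "A600"], 0.56)
  blank <- estimate_blank_absorbance(bu, 1e-2)
  # the estimator averages the first two samples, during which the culture
  # already grows a little: intrinsic bias a0 * (exp(mu * dt) - 1) / 2
  bias <- 1e-2 * (exp(0.47 / 6) - 1) / 2
  expect_equal(blank, 0.09 / 0.56 + bias, tolerance = 1e-9)
  lat <- latent_abundances(sim)
  expect_lt(max(abs((bu - blank) - lat$abundance)), 5e-4)
})

test_that("smoothing matches direct windowed means and truncates the horizon", {
  const <- tibble::tibble(time_h = seq(0, 10, by = 0.5), abundance = 2)
  expect_equal(smooth_and_truncate(const, 7, 24)$abundance,
               rep(2, nrow(const)))

  lin <- tibble::tibble(time_h = 0:20, abundance = 3 + 0.5 * (0:20))
  sm <- smooth_and_truncate(lin, 7, horizon = Inf)
  expect_equal(sm$abundance, direct_rolling_mean(lin$abundance, 7))
  expect_equal(sm$abundance[4:18], lin$abundance[4:18])  # interior unchanged
  expect_equal(sm$abundance[1], mean(lin$abundance[1:4]))  # shrunken edge

  long <- tibble::tibble(time_h = seq(0, 60, by = 1 / 6),
                         abundance = runif(361))
  expect_lte(max(smooth_and_truncate(long, 7, horizon = 24)$time_h), 24)
  expect_error(smooth_and_truncate(long[0, ], 7, 24), "Empty")
  expect_error(smooth_and_truncate(long, 6, 24), "odd")
})

test_that("Theil-Sen equals the brute-force pairwise-slope median", {
  # exact exponential: every pairwise slope is the rate
  t <- seq(0, 12, by = 0.25)
  a <- 0.01 * exp(0.47 * t)
  ts <- theil_sen_loglinear(t, a)
  expect_equal(ts$slope, 0.47, tolerance = 1e-12)

  # toy series with an outlier, vs explicit enumeration
  t5 <- c(0, 1, 2, 3, 4)
  a5 <- c(0.01, 0.016, 0.5, 0.04, 0.065)
  bf <- brute_force_theil_sen(t5, log(a5))
  ts5 <- theil_sen_loglinear(t5, a5)
  expect_equal(ts5$slope, bf$slope)
  expect_equal(ts5$intercept, bf$intercept)

  # log-linearity: scaling shifts the intercept, not the slope
  sc <- theil_sen_loglinear(t5, 7 * a5)
  expect_equal(sc$slope, ts5$slope)
  expect_equal(sc$intercept, ts5$intercept + log(7))

  # tied times are excluded from the pair set
  tied <- theil_sen_loglinear(c(0, 0, 1, 2), c(0.01, 0.02, 0.02, 0.04))
  expect_true(is.finite(tied$slope))

  # non-positive abundances are dropped with a warning
  expect_warning(theil_sen_loglinear(0:4, c(0.01, -1, 0.02, 0.04, 0.08)),
                 "non-positive")
})

test_that("Theil-Sen resists up to 29 percent arbitrary outliers", {
  t <- seq(0, 14, by = 1)  # 15 points
  a <- 0.01 * exp(0.35 * t)
  set.seed(11)
  for (rep in 1:5) {
    contaminated <- a
    idx <- sample(15, 4)  # 26.7 % of points
    contaminated[idx] <- 10^runif(4, -6, 2)
    fit <- suppressWarnings(theil_sen_loglinear(t, contaminated))
    expect_equal(fit$slope, 0.35, tolerance = 1e-6)
  }
})

test_that("rolling rates track the local slope with shrinking edge windows", {
  t <- seq(0, 24, by = 1 / 6)
  a <- 0.01 * exp(0.47 * t)
  rr <- rolling_rate(t, a, window = 19, min_window = 10)
  # the shrunken edge window still holds 10 points, so every position has
  # an estimate; all equal the true rate on an exact exponential
  expect_true(all(!is.na(rr)))
  expect_true(all(abs(rr - 0.47) < 1e-9))

  # lag then exponential: near zero in the lag, near the rate in log phase,
  # matching windowed brute-force estimates pointwise
  lagexp <- ifelse(t < 8, 0.01, 0.01 * exp(0.4 * (t - 8)))
  rr2 <- rolling_rate(t, lagexp, 19, 10)
  mid_lag <- which(t > 2 & t < 6)
  expect_true(all(abs(rr2[mid_lag]) < 1e-9))
  mid_log <- which(t > 12 & t < 20)
  expect_true(all(abs(rr2[mid_log] - 0.4) < 1e-9))
  i <- which.min(abs(t - 8))  # transition point: compare to brute force
  idx <- (i - 9):(i + 9)
  expect_equal(rr2[i], brute_force_theil_sen(t[idx], log(lagexp[idx]))$slope)

  expect_error(rolling_rate(1:9, exp(1:9), 19, 10), "shorter")
})

test_that("fit windows match their analytic definitions", {
  t <- seq(0, 24, by = 1 / 6)
  a <- 0.01 * exp(0.3 * t)
  # fixed: strictly inside (1.5e-2, 6e-2); crossing times solved analytically
  mask <- select_fit_window(a, "fixed")
  lo_t <- log(1.5) / 0.3
  hi_t <- log(6) / 0.3
  expect_equal(which(mask), which(t > lo_t & t < hi_t))

  low <- rep(0.01, length(t))
  expect_equal(sum(select_fit_window(low, "fixed")), 0)
  rr_low <- rolling_rate(t, low, 19, 10)
  expect_equal(sum(select_fit_window(low, "dynamic", rr_low)), 0)

  # dynamic: from the first point above 1.5e-2 through the last point whose
  # rolling rate exceeds 0.1/h, found by brute-force scan
  sat <- pmin(0.01 * exp(0.4 * t), 0.2)
  rr <- rolling_rate(t, sat, 19, 10)
  dyn <- select_fit_window(sat, "dynamic", rr)
  first <- which(sat > 1.5e-2)[1]
  last <- max(which(!is.na(rr) & rr > 0.1))
  expect_equal(which(dyn), first:last)
  expect_error(select_fit_window(sat, "dynamic"), "rolling_rates")
})

test_that("rates, lags and yields recover generator truth without noise", {
  plate <- study_coculture_plate()
  fits <- run_growth_pipeline(plate$readings, plate$metadata)$fits
  sal <- fits[fits$strain %in% "Sal" & fits$well == "A1", ]
  dep <- fits[fits$strain %in% "Dep" & fits$well == "A1", ]
  expect_equal(sal$rate, 0.47, tolerance = 1e-6)
  expect_equal(dep$rate, 0.40, tolerance = 1e-6)
  # lag recovered within one sampling interval (10 min)
  expect_lt(abs(sal$lag_h - 0), 1 / 6)
  expect_lt(abs(dep$lag_h - 4), 1 / 6)
  # yields exactly at the caps
  expect_equal(sal$yield_24h, 0.55, tolerance = 1e-9)
  expect_equal(dep$yield_24h, 0.055, tolerance = 1e-9)
  expect_equal(sal$yield_24h / dep$yield_24h, 10, tolerance = 1e-9)
})

test_that("nongrowing and sparse trajectories yield rate 0 and lag -Inf", {
  flat <- tibble::tibble(time_h = seq(0, 24, by = 1 / 6), abundance = 5e-3)
  fit <- fit_growth(flat, known_initial_abundance = 5e-3)
  expect_equal(fit$rate, 0)
  expect_equal(fit$lag_h, -Inf)

  # six in-window points: below the seven-point minimum even though a slope
  # would be estimable
  t6 <- seq(0, 2.5, by = 0.5)
  a6 <- 2e-2 * exp(0.3 * t6)  # all six points inside the fixed band
  fit6 <- fit_growth(tibble::tibble(time_h = t6, abundance = a6),
                     known_initial_abundance = 1e-2,
                     config = growth_config(window_mode = "fixed",
                                            rolling_min = 2),
                     mode = "fixed")
  expect_equal(fit6$rate, 0)
  expect_equal(fit6$lag_h, -Inf)
})

test_that("lag interpolation passes through the known inoculum", {
  # no-lag exponential from a0: the fitted line crosses ln(a0) at t = 0
  expect_equal(lag_time(0.47, log(1e-2), 1e-2), 0)
  expect_equal(lag_time(0, NA, 1e-2), -Inf)
  expect_error(lag_time(0.4, -4, 0), "> 0")
})

test_that("yield is the smoothed abundance nearest the evaluation time", {
  t <- seq(0, 30, by = 0.5)
  still_growing <- tibble::tibble(time_h = t,
                                  abundance = 0.01 * exp(0.1 * t))
  expect_equal(growth_yield(still_growing, 24), 0.01 * exp(0.1 * 24))
  short <- tibble::tibble(time_h = seq(0, 20, 0.5), abundance = 1)
  expect_error(growth_yield(short, 24), "cover")
})

test_that("scaling all raw reads leaves rate and lag unchanged after recalibration", {
  plate <- study_coculture_plate()
  fits1 <- run_growth_pipeline(plate$readings, plate$metadata)$fits
  scaled <- plate$readings
  scaled$value[scaled$channel != "A600"] <-
    scaled$value[scaled$channel != "A600"] * 3.7
  fits2 <- run_growth_pipeline(scaled, plate$metadata)$fits
  expect_equal(fits1$rate, fits2$rate, tolerance = 1e-9)
  expect_equal(fits1$lag_h, fits2$lag_h, tolerance = 1e-6)
})

test_that("parameter recovery across a rate/lag grid under default noise", {
  set.seed(101)
  grid <- expand.grid(mu = c(0.1, 0.3, 0.5, 0.7), lag = c(0, 4, 8))
  errs <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    s <- strain_params("S", grid$mu[i], lag = grid$lag[i],
                       initial_abundance = 1e-2, yield_cap = 0.55,
                       marker = "none")
    sim <- simulate_growth_curve(s, readout_params(),
                                 t_grid = seq(0, 24, by = 1 / 6))
    bu <- pathlength_correct(sim$value[sim$channel == "A600"], 0.56)
    blank <- estimate_blank_absorbance(bu, 1e-2)
    fit <- fit_growth(tibble::tibble(time_h = seq(0, 24, by = 1 / 6),
                                     abundance = bu - blank),
                      known_initial_abundance = 1e-2,
                      config = growth_config())
    tibble::tibble(rate_err = abs(fit$rate - grid$mu[i]),
                   lag_err = abs(fit$lag_h - grid$lag[i]))
  })
  expect_lte(median(errs$rate_err), 0.01)
  expect_lte(median(errs$lag_err), 0.5)
})
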