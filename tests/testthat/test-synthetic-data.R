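# Generator contracts: latent growth model, readout model, event tables,
# serial transfers.

test_that("latent abundance follows the lag/exponential/cap update rule", {
  s <- strain_params("S", growth_rate = 0.47, lag = 0,
                     initial_abundance = 1e-2, yield_cap = 10,
                     marker = "none")
  sim <- simulate_growth_curve(s, noiseless_readout(),
                               t_grid = seq(0, 24, by = 1))
  lat <- latent_abundances(sim)
  expect_equal(lat$abundance[lat$time_h == 10], 1e-2 * exp(4.7))

  # lag holds the inoculum constant, then growth restarts from it
  s2 <- strain_params("S", 0.5, lag = 5, initial_abundance = 1e-2,
                      yield_cap = 10, marker = "none")
  lat2 <- latent_abundances(
    simulate_growth_curve(s2, noiseless_readout(), t_grid = 0:24))
  expect_true(all(lat2$abundance[lat2$time_h <= 5] == 1e-2))
  expect_equal(lat2$abundance[lat2$time_h == 9], 1e-2 * exp(0.5 * 4))
})

test_that("yield caps impose the final latent abundance ratio", {
  s1 <- strain_params("A", 0.47, initial_abundance = 5e-3, yield_cap = 0.55,
                      marker = "CFP")
  s2 <- strain_params("B", 0.40, initial_abundance = 5e-3, yield_cap = 0.055,
                      marker = "YFP")
  lat <- latent_abundances(
    simulate_growth_curve(list(s1, s2), noiseless_readout(),
                          t_grid = seq(0, 24, by = 1 / 6)))
  finals <- tapply(lat$abundance, lat$strain,
                   function(a) a[length(a)])
  expect_equal(unname(finals["A"] / finals["B"]), 10)
})

test_that("noise-free fluorescence is exactly proportional to the marked strain", {
  s1 <- strain_params("A", 0.47, initial_abundance = 5e-3, yield_cap = 0.55,
                      marker = "CFP")
  s2 <- strain_params("B", 0.40, initial_abundance = 5e-3, yield_cap = 0.055,
                      marker = "YFP")
  ro <- noiseless_readout(channel_gain = c(CFP = 1200, YFP = 800))
  sim <- simulate_growth_curve(list(s1, s2), ro, seq(0, 24, by = 0.5))
  lat <- latent_abundances(sim)
  cfp <- sim$value[sim$channel == "CFP"]
  expect_equal(cfp, 1200 * lat$abundance[lat$strain == "A"])
  yfp <- sim$value[sim$channel == "YFP"]
  expect_equal(yfp, 800 * lat$abundance[lat$strain == "B"])
})

test_that("latent abundances are non-decreasing and capped", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- strain_params("S", runif(1, 0.1, 0.7), lag = runif(1, 0, 8),
                       initial_abundance = 1e-2, yield_cap = runif(1, 0.1, 1),
                       marker = "none")
    lat <- latent_abundances(
      simulate_growth_curve(s, readout_params(), seq(0, 24, by = 1 / 6),
                            seed = seed))
    expect_true(all(lat$abundance > 0))
    expect_true(all(diff(lat$abundance) >= 0))
    expect_true(all(lat$abundance <= s$yield_cap + 1e-12))
  }
})

test_that("generator is reproducible under a fixed seed and rejects bad input", {
  s <- strain_params("S", 0.4, marker = "CFP")
  a <- simulate_growth_curve(s, readout_params(), seed = 42)
  b <- simulate_growth_curve(s, readout_params(), seed = 42)
  expect_identical(a, b)

  s2 <- strain_params("T", 0.3, marker = "CFP")
  expect_error(simulate_growth_curve(list(s, s2), readout_params()),
               "distinct markers")
  expect_error(simulate_growth_curve(s, readout_params(), t_grid = numeric()),
               "empty")
  expect_error(simulate_growth_curve(s, readout_params(),
                                     t_grid = c(0, 1, 1)),
               "strictly increasing")
})

test_that("dose-response panel rates follow the 4PL equation", {
  base <- strain_params("Dep", 0.4, initial_abundance = 1e-2,
                        yield_cap = 0.5, marker = "none")
  p <- list(ybottom = 0, ytop = 0.40, n = 2, ec50 = 1.5e-11)
  doses <- 10^seq(-13, -9, length.out = 10)
  panel <- simulate_dose_response_panel(base, doses, p, noiseless_readout(),
                                        t_grid = seq(0, 24, by = 1))
  # oracle: direct numeric evaluation of the printed equation
  direct <- p$ybottom + doses^p$n * (p$ytop - p$ybottom) /
    (doses^p$n + p$ec50^p$n)
  expect_equal(panel$truth$growth_rate, direct, tolerance = 1e-12)
  # limits and midpoint
  expect_equal(four_pl(p$ec50, 0, 0.40, 2, p$ec50), 0.20)
  expect_equal(four_pl(0, 0, 0.40, 2, p$ec50), 0)
  expect_error(simulate_dose_response_panel(base, c(-1e-12, 1e-11), p),
               ">= 0")
})

test_that("event tables place point-mass clusters in the expected gates", {
  cl <- event_cluster(1000, fitc_log_mean = 4, fitc_log_sd = 1e-9,
                      amcyan_log_mean = 2, amcyan_log_sd = 1e-9)
  ev <- gate_events(simulate_event_table(cl, seed = 1),
                    scheme = gate_scheme("standard"))
  expect_true(all(ev$gate == "YPCN"))

  two <- list(marker_cluster("YFP", 5e4), marker_cluster("CFP", 5e4))
  ev2 <- gate_events(simulate_event_table(two, seed = 2),
                     scheme = gate_scheme("standard"))
  counts <- table(ev2$gate)
  r <- unname(counts["YNCP"] / counts["YPCN"])
  expect_lt(abs(r - 1), 0.05)  # symmetric clusters, sampling error only

  frac <- c(99000, 1000)
  ev3 <- gate_events(simulate_event_table(
    list(marker_cluster("CFP", frac[1]), marker_cluster("YFP", frac[2])),
    seed = 3), scheme = gate_scheme("standard"))
  counts3 <- table(ev3$gate)
  ratio <- unname(counts3["YNCP"] / counts3["YPCN"])
  # binomial expectation: 99 within ~3 sd of the denominator count
  expect_lt(abs(ratio - 99), 12)
})

test_that("serial transfers obey symmetry and the log-linear closed form", {
  mk <- function(mu, marker) {
    strain_params(marker, mu, lag = 0, initial_abundance = 3e-3,
                  yield_cap = 0.6, marker = marker)
  }
  eq <- simulate_serial_transfers(mk(0.4, "CFP"), mk(0.4, "YFP"),
                                  n_transfers = 6, dilution = 100,
                                  shared_yield_cap = 0.6)
  expect_equal(eq$ratio, rep(1, 7))

  # unbounded log phase: cap never reached within the cycle
  s1 <- mk(0.15, "CFP"); s2 <- mk(0.12, "YFP")
  tr <- simulate_serial_transfers(s1, s2, 8, 100, shared_yield_cap = 10)
  expect_equal(tr$t_grow[-1], rep(24, 8))
  expect_equal(diff(log10(tr$ratio)),
               rep((0.15 - 0.12) * 24 / log(10), 8), tolerance = 1e-9)

  # marker swap inverts the ratio exactly
  fwd <- simulate_serial_transfers(mk(0.68, "CFP"), mk(0.47, "YFP"),
                                   8, 100, 0.6)
  rev <- simulate_serial_transfers(mk(0.47, "YFP"), mk(0.68, "CFP"),
                                   8, 100, 0.6)
  expect_equal(fwd$ratio, 1 / rev$ratio, tolerance = 1e-12)

  expect_error(simulate_serial_transfers(mk(0.68, "CFP"), mk(0.47, "YFP"),
                                         2, 100, shared_yield_cap = 1e-3),
               "cap")
})

test_that("capped serial transfers match an independent fine-grid iteration", {
  s1 <- strain_params("Sal", 0.68, 0, 3e-3, 0.6, marker = "CFP")
  s2 <- strain_params("Dep", 0.47, 0, 3e-3, 0.6, marker = "YFP")
  tr <- simulate_serial_transfers(s1, s2, 5, 100, shared_yield_cap = 0.6)

  # oracle: scan a fine time grid for the cap crossing, using only the
  # analytic exponential update
  a <- c(3e-3, 3e-3)
  mu <- c(0.68, 0.47)
  tg <- seq(1e-5, 24, by = 1e-5)
  oracle <- numeric(5)
  for (k in 1:5) {
    a0 <- a / 100
    tot <- a0[1] * exp(mu[1] * tg) + a0[2] * exp(mu[2] * tg)
    hit <- which(tot >= 0.6)[1]
    t <- if (is.na(hit)) 24 else tg[hit]
    a <- a0 * exp(mu * t)
    oracle[k] <- a[1] / a[2]
  }
  expect_equal(tr$ratio[-1], oracle, tolerance = 1e-4)
})
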