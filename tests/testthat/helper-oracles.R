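# Independent oracles used across the suite.  Each is a deliberately naive
# implementation (explicit loops, brute-force enumeration, grid search) kept
# separate from the package's own code paths.

# median of all pairwise slopes, enumerated with explicit loops
brute_force_theil_sen <- function(times, y) {
  slopes <- c()
  n <- length(times)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[j] != times[i]) {
        slopes <- c(slopes, (y[j] - y[i]) / (times[j] - times[i]))
      }
    }
  }
  slope <- median(slopes)
  list(slope = slope, intercept = median(y) - slope * median(times))
}

# direct windowed means, one position at a time
direct_rolling_mean <- function(x, window) {
  half <- (window - 1) / 2
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    idx <- max(1, i - half):min(length(x), i + half)
    out[i] <- mean(x[idx])
  }
  out
}

# profile grid search for the 4PL: for each (log10 ec50, n) on a grid,
# ybottom/ytop have a closed-form least-squares solution since the model is
# linear in them given the saturation fraction
grid_search_4pl <- function(doses, responses,
                            log_ec50_grid, n_grid) {
  best <- list(rss = Inf)
  for (le in log_ec50_grid) {
    for (nn in n_grid) {
      frac <- ifelse(doses == 0, 0,
                     1 / (1 + exp(nn * (le * log(10) - log(doses)))))
      fit <- lm(responses ~ frac)
      rss <- sum(residuals(fit)^2)
      if (rss < best$rss) {
        best <- list(rss = rss, log_ec50 = le, n = nn,
                     ybottom = unname(coef(fit)[1]),
                     ytop = unname(coef(fit)[1] + coef(fit)[2]))
      }
    }
  }
  best
}

# textbook OLS slope, computed from the closed-form covariance formula
closed_form_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# standard noiseless two-strain study plate: salvager (CFP, 0.47/h, no lag,
# yield 0.55) and dependent (YFP, 0.40/h, 4 h lag, yield 0.055), inoculated
# 1:1 at 1e-2 b.u. total, sampled every 10 min for 24 h
study_coculture_plate <- function(readout = noiseless_readout(), seed = 1,
                                  n_reps = 1) {
  sal <- strain_params("Sal", 0.47, lag = 0, initial_abundance = 5e-3,
                       yield_cap = 0.55, marker = "CFP")
  dep <- strain_params("Dep", 0.40, lag = 4, initial_abundance = 5e-3,
                       yield_cap = 0.055, marker = "YFP")
  simulate_coculture_plate(list(sal, dep), readout, n_reps = n_reps,
                           seed = seed)
}
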