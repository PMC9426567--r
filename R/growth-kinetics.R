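# Extraction of growth rate, lag time and yield from abundance trajectories.
#
# The processing chain mirrors standard plate-reader practice for
# fluorescently deconvolved cocultures: pathlength correction into
# bacterial units (b.u.; 1 b.u. = blank-corrected OD600 of 1), blank
# subtraction (well-specific for absorbance, global for fluorescence),
# centered rolling-mean smoothing, and robust Theil-Sen log-linear rate
# estimation inside a fixed abundance band or a dynamically selected
# exponential-phase window.

#' Default analysis configuration
#'
#' Collects every tunable constant of the growth-kinetics pipeline with its
#' default value.
#'
#' @param fit_range Calibration fit interval in raw OD (default `c(0, 0.3)`).
#' @param pathlength_factor Raw absorbance per 1 cm-equivalent OD600
#'   (default 0.56, instrument/plate specific).
#' @param known_initial_abundance Inoculum abundance per well in b.u.
#'   (default 1e-2: OD-adjusted preculture diluted 1:10).
#' @param smooth_window Rolling-mean window in points (odd; default 7,
#'   minimum width 1 at the edges).
#' @param rolling_window,rolling_min Window and minimum width (points) for
#'   rolling growth-rate estimates (defaults 19 and 10).
#' @param window_mode `"dynamic"` or `"fixed"` fit-window selection.
#' @param lower_bound,upper_bound Abundance band for window selection
#'   (defaults 1.5e-2 and 6e-2 b.u.).
#' @param rate_threshold Rolling-rate cutoff for the dynamic window
#'   (default 0.1 1/h).
#' @param min_points Minimum points in the fit window for a nonzero rate
#'   (default 7).
#' @param horizon Truncation horizon in hours (24 or 60; default 24).
#' @param alpha Global significance level (default 0.05).
#' @param dilution Serial-transfer dilution factor (default 100).
#' @param total_events Cytometry events collected per mixed-culture sample
#'   (default 1e5).
#'
#' @return A named list of class `growth_config`.
#' @export
growth_config <- function(fit_range = c(0, 0.3),
                          pathlength_factor = 0.56,
                          known_initial_abundance = 1e-2,
                          smooth_window = 7,
                          rolling_window = 19,
                          rolling_min = 10,
                          window_mode = c("dynamic", "fixed"),
                          lower_bound = 1.5e-2,
                          upper_bound = 6e-2,
                          rate_threshold = 0.1,
                          min_points = 7,
                          horizon = 24,
                          alpha = 0.05,
                          dilution = 100,
                          total_events = 1e5) {
  window_mode <- match.arg(window_mode)
  stopifnot(pathlength_factor > 0, known_initial_abundance > 0,
            smooth_window >= 1, rolling_min >= 2, horizon > 0,
            dilution > 1, total_events >= 1)
  structure(as.list(environment()), class = "growth_config")
}

#' Pathlength-correct raw absorbance equivalents into bacterial units
#'
#' @param values Raw absorbance(-equivalent) readings.
#' @param correction_factor Raw absorbance per 1 cm-equivalent OD600 (> 0).
#' @return Abundances in b.u.
#' @export
pathlength_correct <- function(values, correction_factor = 0.56) {
  if (!is.numeric(correction_factor) || correction_factor <= 0) {
    abort("`correction_factor` must be > 0.")
  }
  values / correction_factor
}

#' Well-specific blank from the first two time points
#'
#' The absorbance blank of a well is the mean of its first two readings
#' minus the known inoculum abundance (both in b.u.).
#'
#' @param values Readings ordered by time (b.u.).
#' @param known_initial_abundance Inoculum abundance (>= 0, b.u.).
#' @return Scalar blank value.
#' @export
estimate_blank_absorbance <- function(values, known_initial_abundance) {
  if (length(values) < 2L) abort("Need at least 2 time points for a blank.")
  if (known_initial_abundance < 0) abort("`known_initial_abundance` must be >= 0.")
  mean(values[1:2]) - known_initial_abundance
}

#' Global fluorescence blank from non-marker wells
#'
#' The blank of a fluorescence channel is the grand mean of that channel
#' over all wells whose cultures do not carry the corresponding marker,
#' across all time points.
#'
#' @param readings Long plate tibble (`time_h`, `well`, `channel`, `value`).
#' @param metadata Well metadata (`well`, `marker`).
#' @param channel Fluorescence channel (`"CFP"` or `"YFP"`).
#' @return Scalar blank value (same units as `value`).
#' @export
estimate_blank_fluorescence <- function(readings, metadata, channel) {
  marker_wells <- metadata %>%
    filter(.data$marker == channel) %>%
    pull(.data$well)
  eligible <- setdiff(unique(metadata$well), marker_wells)
  if (length(eligible) == 0L) {
    abort(paste0("No wells without the ", channel, " marker available."))
  }
  vals <- readings %>%
    filter(.data$channel == !!channel, .data$well %in% eligible) %>%
    pull(.data$value)
  mean(vals)
}

# centered rolling mean with shrinking edge windows (minimum width
# min_periods), pandas-style
centered_rolling_mean <- function(x, window, min_periods = 1L) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out[(hi - lo + 1L) < min_periods] <- NA_real_
  out
}

#' Smooth and truncate an abundance trajectory
#'
#' Applies a centered, equal-weight rolling mean (window shrinking
#' symmetrically at the series edges down to one point) and then drops all
#' points later than the horizon.
#'
#' @param data Tibble with columns `time_h` and `abundance`.
#' @param window Odd window width in points (default 7).
#' @param horizon Truncation time in hours (default 24).
#' @return Tibble of the same shape, smoothed and truncated.
#' @export
smooth_and_truncate <- function(data, window = 7, horizon = 24) {
  if (nrow(data) == 0L) abort("Empty trajectory.")
  if (window %% 2 == 0) abort("`window` must be odd.")
  data %>%
    arrange(.data$time_h) %>%
    mutate(abundance = centered_rolling_mean(.data$abundance, window, 1L)) %>%
    filter(.data$time_h <= horizon)
}

#' Theil-Sen estimator on log-transformed abundances
#'
#' The slope is the median over all pairwise slopes
#' `(ln a_j - ln a_i) / (t_j - t_i)` for `i < j`; the intercept follows the
#' convention `median(ln a) - slope * median(t)`.  Pairs with identical
#' times are excluded; non-positive abundances are dropped with a warning.
#'
#' @param times Time points (h).
#' @param abundance Abundances (b.u.).
#' @param point_mask Optional logical/integer mask restricting the fit.
#' @return One-row tibble: `slope` (1/h), `intercept` (ln b.u. at t = 0),
#'   `n_points`.  `NA` slope if fewer than 2 usable points remain.
#' @export
theil_sen_loglinear <- function(times, abundance, point_mask = NULL) {
  if (!is.null(point_mask)) {
    times <- times[point_mask]
    abundance <- abundance[point_mask]
  }
  ok <- is.finite(times) & is.finite(abundance)
  if (any(abundance[ok] <= 0)) {
    warn("Dropping non-positive abundances before log transform.")
    ok <- ok & abundance > 0
  }
  t <- times[ok]
  y <- log(abundance[ok])
  if (length(t) < 2L) {
    return(tibble(slope = NA_real_, intercept = NA_real_,
                  n_points = length(t)))
  }
  ij <- combn(length(t), 2L)
  dt <- t[ij[2L, ]] - t[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  use <- dt != 0
  if (!any(use)) {
    return(tibble(slope = NA_real_, intercept = NA_real_,
                  n_points = length(t)))
  }
  slope <- median(dy[use] / dt[use])
  tibble(slope = slope,
         intercept = median(y) - slope * median(t),
         n_points = length(t))
}

#' Centered rolling-window growth-rate estimates
#'
#' Applies [theil_sen_loglinear()] in a centered rolling window (width
#' `window` points, shrinking at the edges but never below `min_window`;
#' positions whose window cannot reach `min_window` points get `NA`).
#'
#' @param times,abundance Trajectory vectors.
#' @param window Window width in points (default 19).
#' @param min_window Minimum window width (default 10).
#' @return Numeric vector of per-point rate estimates (1/h), same length as
#'   the input.
#' @export
rolling_rate <- function(times, abundance, window = 19, min_window = 10) {
  n <- length(times)
  if (n < min_window) {
    abort("Series shorter than the minimum rolling window.")
  }
  half <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    if (hi - lo + 1L < min_window) next
    idx <- lo:hi
    pos <- idx[is.finite(abundance[idx]) & abundance[idx] > 0]
    if (length(pos) < 2L) next
    fit <- suppressWarnings(theil_sen_loglinear(times[pos], abundance[pos]))
    out[i] <- fit$slope
  }
  out
}

#' Select the fit window for rate estimation
#'
#' In `"fixed"` mode the window is every point whose abundance lies strictly
#' between `lower_bound` and `upper_bound`.  In `"dynamic"` mode it is the
#' contiguous run from the first point above `lower_bound` through the
#' latest point whose rolling-window rate estimate exceeds
#' `rate_threshold`.
#'
#' @param abundance Smoothed abundances (b.u.).
#' @param mode `"fixed"` or `"dynamic"`.
#' @param rolling_rates Per-point rolling rates (required for dynamic mode).
#' @param lower_bound,upper_bound,rate_threshold See [growth_config()].
#' @return Logical mask over the trajectory (possibly all `FALSE`).
#' @export
select_fit_window <- function(abundance, mode = c("dynamic", "fixed"),
                              rolling_rates = NULL,
                              lower_bound = 1.5e-2, upper_bound = 6e-2,
                              rate_threshold = 0.1) {
  mode <- match.arg(mode)
  n <- length(abundance)
  mask <- rep(FALSE, n)
  if (mode == "fixed") {
    mask <- abundance > lower_bound & abundance < upper_bound
    mask[is.na(mask)] <- FALSE
    return(mask)
  }
  if (is.null(rolling_rates)) {
    abort("Dynamic window selection requires `rolling_rates`.")
  }
  above <- which(abundance > lower_bound)
  fast <- which(!is.na(rolling_rates) & rolling_rates > rate_threshold)
  if (length(above) == 0L || length(fast) == 0L) return(mask)
  first <- above[1L]
  last <- max(fast)
  if (last < first) return(mask)
  mask[first:last] <- TRUE
  mask
}

#' Lag time by back-extrapolation to the known inoculum
#'
#' The lag is the time at which the fitted exponential crosses the known
#' initial abundance: `(ln(a0) - intercept) / rate`.  Nongrowing
#' populations (rate 0) get lag `-Inf`.
#'
#' @param rate,intercept Theil-Sen fit (1/h; ln b.u.).
#' @param known_initial_abundance Inoculum abundance in b.u. (> 0).
#' @return Lag time in hours.
#' @export
lag_time <- function(rate, intercept, known_initial_abundance) {
  if (known_initial_abundance <= 0) {
    abort("`known_initial_abundance` must be > 0.")
  }
  if (is.na(rate) || rate == 0) return(-Inf)
  (log(known_initial_abundance) - intercept) / rate
}

#' Growth yield at a fixed time
#'
#' The smoothed abundance at the time point closest to `at` hours.
#'
#' @param data Smoothed trajectory tibble (`time_h`, `abundance`).
#' @param at Evaluation time in hours (default 24).
#' @return Yield in b.u.
#' @export
growth_yield <- function(data, at = 24) {
  if (nrow(data) == 0L) abort("Empty trajectory.")
  if (max(data$time_h) < at) {
    abort("Trajectory does not cover the yield evaluation time.")
  }
  data$abundance[which.min(abs(data$time_h - at))]
}

#' Fit growth parameters of one abundance trajectory
#'
#' Smooths and truncates the blank-corrected trajectory, selects the fit
#' window (fixed band or dynamic exponential-phase window), runs the
#' Theil-Sen estimator on log abundances, and derives lag time and 24-h
#' yield.  The rate is set to zero (and the lag to `-Inf`) when fewer than
#' `min_points` points fall into the window.
#'
#' @param data Tibble with columns `time_h` and `abundance` (blank-corrected
#'   b.u.).
#' @param known_initial_abundance Inoculum abundance of this trajectory's
#'   population in b.u.
#' @param config A [growth_config()].
#' @param mode Optional override of `config$window_mode`.
#'
#' @return One-row tibble: `rate` (1/h), `intercept` (ln b.u.), `lag_h`,
#'   `yield_24h` (b.u., `NA` if the trajectory ends before 24 h),
#'   `window_mode`, `n_points_used`.
#' @export
fit_growth <- function(data, known_initial_abundance = NULL,
                       config = growth_config(), mode = NULL) {
  mode <- mode %||% config$window_mode
  if (is.null(known_initial_abundance)) {
    known_initial_abundance <- config$known_initial_abundance
  }
  smoothed <- smooth_and_truncate(data, window = config$smooth_window,
                                  horizon = config$horizon)
  rates <- NULL
  if (mode == "dynamic" && nrow(smoothed) >= config$rolling_min) {
    rates <- rolling_rate(smoothed$time_h, smoothed$abundance,
                          window = config$rolling_window,
                          min_window = config$rolling_min)
  }
  mask <- if (mode == "dynamic" && is.null(rates)) {
    rep(FALSE, nrow(smoothed))
  } else {
    select_fit_window(smoothed$abundance, mode = mode,
                      rolling_rates = rates,
                      lower_bound = config$lower_bound,
                      upper_bound = config$upper_bound,
                      rate_threshold = config$rate_threshold)
  }
  yield <- if (max(smoothed$time_h) >= 24) growth_yield(smoothed, 24) else NA_real_

  if (sum(mask) < config$min_points) {
    return(tibble(rate = 0, intercept = NA_real_, lag_h = -Inf,
                  yield_24h = yield, window_mode = mode,
                  n_points_used = sum(mask)))
  }
  fit <- theil_sen_loglinear(smoothed$time_h, smoothed$abundance, mask)
  rate <- if (is.na(fit$slope) || fit$slope < 0) 0 else fit$slope
  tibble(rate = rate,
         intercept = fit$intercept,
         lag_h = lag_time(rate, fit$intercept, known_initial_abundance),
         yield_24h = yield,
         window_mode = mode,
         n_points_used = fit$n_points)
}

#' Deconvolve and fit every trajectory on a plate
#'
#' End-to-end growth analysis of a multichannel plate: calibrates the
#' fluorescence channels from single-marker control wells, converts
#' fluorescence to absorbance equivalents, pathlength-corrects all readings
#' into b.u., subtracts well-specific absorbance blanks and global
#' fluorescence blanks, and fits growth parameters per well and channel.
#' For mixed wells the fluorescence channels give the per-strain
#' trajectories; the absorbance channel gives the total.
#'
#' @param readings Long plate tibble (`time_h`, `well`, `channel`, `value`).
#' @param metadata Well metadata (`well`, `strain`, `marker`,
#'   `initial_abundance`, `role`); one row per well and strain.
#' @param config A [growth_config()].
#' @param calibration Optional precomputed calibration model; computed from
#'   the control wells when `NULL` and fluorescence channels are needed.
#'
#' @return Tibble with one row per fitted trajectory: `well`, `channel`,
#'   `strain` (NA for the absorbance total), the [fit_growth()] columns, and
#'   a `calibration`/`blanks` attribute pair for provenance.
#' @export
analyze_growth_plate <- function(readings, metadata,
                                 config = growth_config(),
                                 calibration = NULL) {
  channels <- unique(readings$channel)
  fluor <- intersect(c("CFP", "YFP"), channels)
  used_markers <- intersect(fluor, unique(metadata$marker))

  if (length(used_markers) > 0L && is.null(calibration)) {
    calibration <- calibrate_plate(readings, metadata,
                                   fit_range = config$fit_range)
  }

  # fluorescence -> absorbance equivalents
  conv <- readings
  for (ch in used_markers) {
    idx <- conv$channel == ch
    conv$value[idx] <- convert_fluorescence(conv$value[idx], calibration, ch)
  }
  # absorbance equivalents -> b.u.
  conv$value <- pathlength_correct(conv$value, config$pathlength_factor)

  # blanks: global per fluorescence channel, well-specific for absorbance
  fluor_blanks <- setNames(
    vapply(used_markers, function(ch) {
      estimate_blank_fluorescence(conv, metadata, ch)
    }, numeric(1)),
    used_markers
  )

  well_meta <- metadata %>%
    group_by(.data$well) %>%
    summarise(total_inoculum = sum(.data$initial_abundance),
              .groups = "drop")

  fits <- list()
  blanks <- list()
  for (w in unique(metadata$well)) {
    strains_here <- metadata %>% filter(.data$well == w)
    markers_here <- intersect(strains_here$marker, used_markers)
    for (ch in c("A600", markers_here)) {
      traj <- conv %>%
        filter(.data$well == w, .data$channel == ch) %>%
        arrange(.data$time_h)
      if (nrow(traj) == 0L) next
      if (ch == "A600") {
        blank <- estimate_blank_absorbance(traj$value,
                                           config$known_initial_abundance)
        a0 <- well_meta$total_inoculum[well_meta$well == w]
        strain <- NA_character_
      } else {
        blank <- fluor_blanks[[ch]]
        row <- strains_here %>% filter(.data$marker == ch)
        a0 <- row$initial_abundance[1L]
        strain <- row$strain[1L]
      }
      fit <- fit_growth(tibble(time_h = traj$time_h,
                               abundance = traj$value - blank),
                        known_initial_abundance = a0, config = config)
      fits[[length(fits) + 1L]] <- mutate(fit, well = w, channel = ch,
                                          strain = strain, .before = 1L)
      blanks[[length(blanks) + 1L]] <- tibble(well = w, channel = ch,
                                              blank = blank)
    }
  }
  out <- bind_rows(fits) %>%
    select("well", "channel", "strain", dplyr::everything())
  attr(out, "calibration") <- calibration
  attr(out, "blanks") <- bind_rows(blanks)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
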