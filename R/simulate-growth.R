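# Synthetic plate-reader data with known ground truth.
#
# The latent model is the minimal one consistent with the parameters the
# downstream pipeline extracts: a constant inoculum during the lag, pure
# exponential growth afterwards, and a hard stop at the yield cap.

#' Parameters of one bacterial subpopulation
#'
#' Bundles the latent growth parameters of a single strain.  Abundances are
#' expressed in bacterial units (b.u.), where 1 b.u. corresponds to a
#' blank-corrected, pathlength-corrected OD600 of 1.
#'
#' @param name Strain label (character scalar).
#' @param growth_rate Exponential growth rate in 1/h (>= 0).
#' @param lag Lag time in hours (>= 0); the strain sits at its inoculum
#'   abundance until `lag` and grows exponentially afterwards.
#' @param initial_abundance Inoculum abundance in b.u. (> 0).
#' @param yield_cap Maximal abundance in b.u.; growth stops when reached.
#' @param marker Fluorescent marker carried by the strain: `"CFP"`, `"YFP"`
#'   or `"none"`.
#'
#' @return An object of class `strain_params`.
#' @export
#' @examples
#' salvager <- strain_params("Sal", growth_rate = 0.47, lag = 0,
#'                           initial_abundance = 5e-3, yield_cap = 0.55,
#'                           marker = "CFP")
strain_params <- function(name, growth_rate, lag = 0,
                          initial_abundance = 5e-3, yield_cap = 0.55,
                          marker = c("none", "CFP", "YFP")) {
  marker <- match.arg(marker)
  if (!is.character(name) || length(name) != 1L) {
    abort("`name` must be a single character label.")
  }
  if (growth_rate < 0) abort("`growth_rate` must be >= 0.")
  if (lag < 0) abort("`lag` must be >= 0.")
  if (initial_abundance <= 0 || initial_abundance > yield_cap) {
    abort("`initial_abundance` must satisfy 0 < initial_abundance <= yield_cap.")
  }
  structure(
    list(name = name, growth_rate = growth_rate, lag = lag,
         initial_abundance = initial_abundance, yield_cap = yield_cap,
         marker = marker),
    class = "strain_params"
  )
}

#' Plate-reader readout model
#'
#' Describes how latent abundances map onto raw instrument readings.  The
#' absorbance channel reads `od_per_bu * total_abundance + od_blank`; each
#' fluorescence channel reads `gain * marked_abundance + background +
#' crosstalk * (other channel's marker signal)`.  Noise is multiplicative
#' Gaussian on the latent signal plus additive Gaussian read noise per
#' channel.  The paper-derived pipeline removes all of these nuisance terms;
#' their magnitudes here are artifact choices (the underlying study reports
#' only that read noise varied by channel).
#'
#' @param od_per_bu Raw absorbance units per b.u. (the effective optical
#'   pathlength of a filled 96-well; default 0.56).
#' @param od_blank Raw absorbance of medium + plate (default 0.09).
#' @param channel_gain Named numeric, fluorescence a.u. per b.u. for `CFP`
#'   and `YFP`.
#' @param channel_background Named numeric, background fluorescence a.u.
#' @param crosstalk Named numeric: fraction of the *other* channel's marker
#'   signal bleeding into this channel (a.u. per a.u.).  A scalar is
#'   recycled to both channels.
#' @param noise_sd_multiplicative Fractional (relative) noise on the latent
#'   signal; default 0.02 (2 %).
#' @param noise_sd_additive Named numeric of additive read-noise standard
#'   deviations per channel (`A600`, `CFP`, `YFP`), in channel units.  A
#'   scalar is recycled.
#' @param yfp_saturation_od Optional raw-OD level above which the YFP
#'   response flattens (emulating detector saturation at high density);
#'   `NULL` (default) disables the effect.
#'
#' @return An object of class `readout_params`.
#' @export
readout_params <- function(od_per_bu = 0.56,
                           od_blank = 0.09,
                           channel_gain = c(CFP = 1200, YFP = 800),
                           channel_background = c(CFP = 50, YFP = 40),
                           crosstalk = c(CFP = 0.002, YFP = 0.002),
                           noise_sd_multiplicative = 0.02,
                           noise_sd_additive = c(A600 = 0.002, CFP = 4, YFP = 4),
                           yfp_saturation_od = NULL) {
  expand <- function(x, channels) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, length(channels)), channels)
    if (!all(channels %in% names(x))) {
      abort(paste0("Expected named entries for: ", paste(channels, collapse = ", ")))
    }
    x[channels]
  }
  channel_gain <- expand(channel_gain, c("CFP", "YFP"))
  channel_background <- expand(channel_background, c("CFP", "YFP"))
  crosstalk <- expand(crosstalk, c("CFP", "YFP"))
  noise_sd_additive <- expand(noise_sd_additive, c("A600", "CFP", "YFP"))
  if (od_per_bu <= 0) abort("`od_per_bu` must be > 0.")
  if (any(channel_gain <= 0)) abort("Channel gains must be > 0.")
  if (any(crosstalk < 0)) abort("Crosstalk must be >= 0.")
  if (noise_sd_multiplicative < 0 || any(noise_sd_additive < 0)) {
    abort("Noise standard deviations must be >= 0.")
  }
  structure(
    list(od_per_bu = od_per_bu, od_blank = od_blank,
         channel_gain = channel_gain, channel_background = channel_background,
         crosstalk = crosstalk,
         noise_sd_multiplicative = noise_sd_multiplicative,
         noise_sd_additive = noise_sd_additive,
         yfp_saturation_od = yfp_saturation_od),
    class = "readout_params"
  )
}

#' Noise-free readout model
#'
#' Convenience constructor for a readout with all noise terms, crosstalk and
#' backgrounds set to zero, used for exact parameter-recovery checks.
#'
#' @param ... Passed on to [readout_params()] to override the zeroed
#'   defaults (e.g. `od_blank`).
#' @return A `readout_params` object.
#' @export
noiseless_readout <- function(...) {
  defaults <- list(
    channel_background = c(CFP = 0, YFP = 0),
    crosstalk = c(CFP = 0, YFP = 0),
    noise_sd_multiplicative = 0,
    noise_sd_additive = c(A600 = 0, CFP = 0, YFP = 0)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(readout_params, args)
}

# latent abundance of one strain on a time grid: lag -> exponential -> cap
latent_abundance <- function(strain, t_grid) {
  a <- ifelse(t_grid < strain$lag,
              strain$initial_abundance,
              strain$initial_abundance *
                exp(strain$growth_rate * (t_grid - strain$lag)))
  pmin(a, strain$yield_cap)
}

#' Simulate one plate-reader well
#'
#' Generates raw multichannel readings (absorbance at 600 nm plus CFP- and
#' YFP-like fluorescence) for one well containing one or more marked
#' subpopulations, on a shared time grid.  Latent per-strain abundances are
#' attached as the `"latent"` attribute for ground-truth checks (see
#' [latent_abundances()]).
#'
#' @param strains A `strain_params` object or list of them.  Two strains may
#'   share a well only if they carry distinct fluorescent markers.
#' @param readout A [readout_params()] object.
#' @param t_grid Strictly increasing vector of sampling times in hours
#'   (default: every 10 min for 24 h).
#' @param well Well label stored in the output.
#' @param seed Optional integer seed for the noise draws.
#'
#' @return A tibble with columns `time_h`, `well`, `channel`
#'   (`A600`/`CFP`/`YFP`) and `value` (raw instrument units).
#' @export
#' @examples
#' sal <- strain_params("Sal", 0.47, marker = "CFP")
#' sim <- simulate_growth_curve(sal, noiseless_readout(), seed = 1)
#' latent_abundances(sim)
simulate_growth_curve <- function(strains, readout = readout_params(),
                                  t_grid = seq(0, 24, by = 1 / 6),
                                  well = "A1", seed = NULL) {
  if (inherits(strains, "strain_params")) strains <- list(strains)
  if (length(t_grid) == 0L) abort("`t_grid` must not be empty.")
  if (any(diff(t_grid) <= 0)) abort("`t_grid` must be strictly increasing.")
  markers <- vapply(strains, function(s) s$marker, character(1))
  if (length(strains) > 1L && anyDuplicated(markers)) {
    abort("Strains sharing a well must carry distinct markers.")
  }
  if (!is.null(seed)) set.seed(seed)

  A <- vapply(strains, latent_abundance, numeric(length(t_grid)),
              t_grid = t_grid)
  A <- matrix(A, nrow = length(t_grid))
  total <- rowSums(A)

  marked <- function(marker) {
    idx <- which(markers == marker)
    if (length(idx)) A[, idx] else rep(0, length(t_grid))
  }
  a_cfp <- marked("CFP")
  a_yfp <- marked("YFP")

  sig_cfp <- readout$channel_gain[["CFP"]] * a_cfp
  sig_yfp <- readout$channel_gain[["YFP"]] * a_yfp
  if (!is.null(readout$yfp_saturation_od)) {
    raw_od_clean <- readout$od_per_bu * total + readout$od_blank
    flatten <- pmin(1, readout$yfp_saturation_od /
                         pmax(raw_od_clean, .Machine$double.eps))
    sig_yfp <- sig_yfp * flatten
  }

  noisy <- function(signal, channel) {
    mult <- readout$noise_sd_multiplicative
    addl <- readout$noise_sd_additive[[channel]]
    out <- signal
    if (mult > 0) out <- out * (1 + rnorm(length(out), sd = mult))
    if (addl > 0) out <- out + rnorm(length(out), sd = addl)
    out
  }

  vals_a600 <- noisy(readout$od_per_bu * total, "A600") + readout$od_blank
  vals_cfp <- noisy(sig_cfp, "CFP") + readout$channel_background[["CFP"]] +
    readout$crosstalk[["CFP"]] * sig_yfp
  vals_yfp <- noisy(sig_yfp, "YFP") + readout$channel_background[["YFP"]] +
    readout$crosstalk[["YFP"]] * sig_cfp

  readings <- tibble(
    time_h = rep(t_grid, 3L),
    well = well,
    channel = rep(c("A600", "CFP", "YFP"), each = length(t_grid)),
    value = c(vals_a600, vals_cfp, vals_yfp)
  )
  latent <- tibble(
    time_h = rep(t_grid, length(strains)),
    well = well,
    strain = rep(vapply(strains, `[[`, character(1), "name"),
                 each = length(t_grid)),
    abundance = as.vector(A)
  )
  attr(readings, "latent") <- latent
  readings
}

#' Latent ground-truth abundances of a simulated object
#'
#' @param x A tibble produced by [simulate_growth_curve()] or
#'   [simulate_coculture_plate()].
#' @return A tibble with columns `time_h`, `well`, `strain`, `abundance`.
#' @export
latent_abundances <- function(x) {
  latent <- attr(x, "latent")
  if (is.null(latent)) abort("`x` carries no latent ground truth.")
  latent
}

#' Simulate a plate with coculture and single-marker control wells
#'
#' Builds the minimal plate layout the deconvolution pipeline needs: one or
#' more replicate wells of the mixed culture, plus monoculture wells of each
#' marked strain (inoculated at the summed coculture inoculum) that serve
#' both as calibration controls and as non-marker wells for global
#' fluorescence-blank estimation.
#'
#' @param strains List of `strain_params` (distinct markers) for the mixed
#'   culture.
#' @param readout A [readout_params()] object.
#' @param t_grid Sampling times in hours.
#' @param n_reps Number of replicate coculture wells.
#' @param n_controls Number of replicate monoculture wells per marked strain.
#' @param seed Optional integer seed.
#'
#' @return A list with elements `readings` (long tibble), `metadata`
#'   (one row per well x strain: `well`, `strain`, `marker`,
#'   `initial_abundance`, `role`), and `truth` (latent abundances).
#' @export
simulate_coculture_plate <- function(strains, readout = readout_params(),
                                     t_grid = seq(0, 24, by = 1 / 6),
                                     n_reps = 1, n_controls = 1,
                                     seed = NULL) {
  if (inherits(strains, "strain_params")) strains <- list(strains)
  if (!is.null(seed)) set.seed(seed)
  total_inoc <- sum(vapply(strains, `[[`, numeric(1), "initial_abundance"))

  readings <- list()
  metadata <- list()
  truth <- list()
  add_well <- function(well, well_strains, role) {
    sim <- simulate_growth_curve(well_strains, readout, t_grid, well = well,
                                 seed = NULL)
    readings[[length(readings) + 1L]] <<- sim
    truth[[length(truth) + 1L]] <<- latent_abundances(sim)
    metadata[[length(metadata) + 1L]] <<- tibble(
      well = well,
      strain = vapply(well_strains, `[[`, character(1), "name"),
      marker = vapply(well_strains, `[[`, character(1), "marker"),
      initial_abundance = vapply(well_strains, `[[`, numeric(1),
                                 "initial_abundance"),
      role = role
    )
  }

  for (r in seq_len(n_reps)) {
    add_well(paste0("A", r), strains, "coculture")
  }
  marked <- Filter(function(s) s$marker != "none", strains)
  for (i in seq_along(marked)) {
    s <- marked[[i]]
    mono <- strain_params(s$name, s$growth_rate, s$lag,
                          initial_abundance = total_inoc,
                          yield_cap = s$yield_cap, marker = s$marker)
    for (r in seq_len(n_controls)) {
      add_well(paste0(LETTERS[i + 1L], r), list(mono), "control")
    }
  }

  out <- list(readings = bind_rows(readings),
              metadata = bind_rows(metadata),
              truth = bind_rows(truth),
              params = list(strains = lapply(strains, unclass),
                            readout = unclass(readout),
                            seed = seed))
  attr(out$readings, "latent") <- out$truth
  out
}

#' Simulate a dose-response panel of growth curves
#'
#' For each effector concentration, the simulated strain grows at the rate
#' given by the four-parameter logistic dose-response model evaluated at
#' that concentration (see [four_pl()]); one monoculture well is generated
#' per dose.
#'
#' @param base A `strain_params` object providing lag, inoculum and yield
#'   cap; its `growth_rate` is overridden per dose.
#' @param doses Non-negative effector concentrations (M).
#' @param fourpl Named list or vector with elements `ybottom`, `ytop`, `n`,
#'   `ec50` (the dose-response parameters; response units 1/h).
#' @param readout A [readout_params()] object.
#' @param t_grid Sampling times in hours.
#' @param seed Optional integer seed.
#'
#' @return A list with `readings` (long tibble with extra column `dose_M`),
#'   `truth` (tibble `dose_M`, `growth_rate`), `metadata`.
#' @export
simulate_dose_response_panel <- function(base, doses, fourpl,
                                         readout = readout_params(),
                                         t_grid = seq(0, 24, by = 1 / 6),
                                         seed = NULL) {
  if (any(doses < 0)) abort("Doses must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  fourpl <- as.list(fourpl)
  mu <- four_pl(doses, ybottom = fourpl$ybottom, ytop = fourpl$ytop,
                n = fourpl$n, ec50 = fourpl$ec50)

  sims <- vector("list", length(doses))
  meta <- vector("list", length(doses))
  for (i in seq_along(doses)) {
    well <- paste0("D", i)
    s <- strain_params(base$name, growth_rate = max(mu[i], 0), lag = base$lag,
                       initial_abundance = base$initial_abundance,
                       yield_cap = base$yield_cap, marker = base$marker)
    sims[[i]] <- simulate_growth_curve(list(s), readout, t_grid,
                                       well = well, seed = NULL) %>%
      mutate(dose_M = doses[i])
    meta[[i]] <- tibble(well = well, strain = base$name, marker = base$marker,
                        initial_abundance = base$initial_abundance,
                        role = "dose", dose_M = doses[i])
  }
  list(readings = bind_rows(sims),
       truth = tibble(dose_M = doses, growth_rate = mu),
       metadata = bind_rows(meta))
}
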