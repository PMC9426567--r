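# Fluorescence-to-absorbance calibration from single-marker control wells.
#
# Conversion factors are estimated per channel (and per any additional
# grouping key such as day or medium) as slopes of linear fits of raw
# fluorescence against raw absorbance, restricted to the low-OD range where
# the relation is linear, then averaged over replicate control wells.
# The stored factor is oriented as absorbance-equivalent per fluorescence
# a.u., so that multiplying raw fluorescence by the factor yields raw
# absorbance equivalents.

#' Fit a single fluorescence-to-absorbance conversion factor
#'
#' Regresses raw fluorescence on raw absorbance (with intercept, since
#' background fluorescence is nonzero), restricted to readings whose raw
#' absorbance lies strictly inside `fit_range`, and returns the conversion
#' factor oriented as absorbance per fluorescence a.u.
#'
#' Two orientations are available: `"reciprocal"` (default) takes the
#' reciprocal of the fluorescence-versus-absorbance slope; `"inverse_regression"`
#' fits absorbance on fluorescence directly.  For noiseless proportional
#' data both agree exactly.
#'
#' @param raw_fluor,raw_od Numeric vectors of paired raw readings.
#' @param fit_range Length-2 numeric: raw-OD interval used for the fit
#'   (default `c(0, 0.3)`; the wider interval `c(0, 0.6)` is also commonly
#'   used and supported).
#' @param method Factor orientation, see Details.
#'
#' @return A one-row tibble: `factor` (absorbance per a.u.; `NA` and
#'   `valid = FALSE` if the fitted slope is non-positive), `slope_fluor_per_od`,
#'   `intercept`, `n_points`, `valid`.
#' @export
#' @examples
#' od <- seq(0.02, 0.28, length.out = 10)
#' fit_conversion_factor(200 * od, od)  # factor = 1/200
fit_conversion_factor <- function(raw_fluor, raw_od, fit_range = c(0, 0.3),
                                  method = c("reciprocal",
                                             "inverse_regression")) {
  method <- match.arg(method)
  if (length(raw_fluor) != length(raw_od)) {
    abort("`raw_fluor` and `raw_od` must have equal length.")
  }
  keep <- is.finite(raw_fluor) & is.finite(raw_od) &
    raw_od > fit_range[1] & raw_od < fit_range[2]
  if (sum(keep) < 2L) {
    abort("Calibration failure: fewer than 2 readings inside the fit range.")
  }
  f <- raw_fluor[keep]
  od <- raw_od[keep]
  fwd <- lm(f ~ od)
  slope_fluor_per_od <- unname(coef(fwd)[2])
  factor <- switch(method,
    reciprocal = 1 / slope_fluor_per_od,
    inverse_regression = unname(coef(lm(od ~ f))[2])
  )
  valid <- is.finite(factor) && factor > 0 && slope_fluor_per_od > 0
  if (!valid) {
    warn("Non-positive calibration slope; factor flagged invalid.")
    factor <- NA_real_
  }
  tibble(factor = factor,
         slope_fluor_per_od = slope_fluor_per_od,
         intercept = unname(coef(fwd)[1]),
         n_points = sum(keep),
         valid = valid)
}

#' Average per-replicate conversion factors into a calibration model
#'
#' Takes a table of per-replicate factors (as returned by
#' [fit_conversion_factor()], optionally with key columns such as `channel`,
#' `day` or `medium`) and averages the valid factors within each key group.
#'
#' @param per_replicate_factors Tibble with at least columns `factor` and
#'   `valid`; any other non-diagnostic columns are treated as grouping keys.
#' @param keys Character vector of key column names; defaults to every
#'   column other than the per-fit diagnostics.
#'
#' @return A calibration model: tibble with the key columns, `factor`
#'   (arithmetic mean over valid replicates) and `n_replicates`.
#' @export
average_factors <- function(per_replicate_factors, keys = NULL) {
  stopifnot(is.data.frame(per_replicate_factors))
  diag_cols <- c("factor", "slope_fluor_per_od", "intercept", "n_points",
                 "valid", "well")
  if (is.null(keys)) {
    keys <- setdiff(names(per_replicate_factors), diag_cols)
  }
  df <- as_tibble(per_replicate_factors)
  if (!"valid" %in% names(df)) df$valid <- is.finite(df$factor)
  if (any(!df$valid)) {
    warn("Invalid conversion factors excluded from replicate averaging.")
  }
  grouped <- df %>%
    filter(.data$valid) %>%
    group_by(dplyr::across(dplyr::all_of(keys)))
  out <- grouped %>%
    summarise(factor = mean(.data$factor), n_replicates = n(),
              .groups = "drop")
  # every key combination present on input must survive with >= 1 valid fit
  all_keys <- distinct(df[, keys, drop = FALSE])
  if (nrow(out) < nrow(all_keys)) {
    abort("Missing calibration: a key group has no valid conversion factor.")
  }
  if (nrow(out) == 0L) abort("Missing calibration: no valid factors.")
  out
}

#' Convert raw fluorescence into raw-absorbance equivalents
#'
#' Multiplies raw fluorescence readings by the calibration factor stored for
#' the requested key.
#'
#' @param raw_fluor Numeric vector of raw fluorescence readings (a.u.).
#' @param model Calibration model from [average_factors()].
#' @param channel Channel key to look up (e.g. `"CFP"`); additional keys can
#'   be supplied via `...` as `name = value` pairs matching the model's key
#'   columns.
#' @param ... Further key filters.
#'
#' @return Numeric vector of raw-absorbance-equivalent readings.
#' @export
convert_fluorescence <- function(raw_fluor, model, channel, ...) {
  keys <- c(list(channel = channel), list(...))
  hit <- model
  for (k in names(keys)) {
    if (!k %in% names(hit)) abort(paste0("Calibration model has no key `", k, "`."))
    hit <- hit[hit[[k]] == keys[[k]], , drop = FALSE]
  }
  if (nrow(hit) != 1L) {
    abort(paste0("Missing calibration for key: ",
                 paste(names(keys), unlist(keys), sep = "=", collapse = ", ")))
  }
  raw_fluor * hit$factor[[1L]]
}

#' Calibrate a plate from its single-marker control wells
#'
#' Runs [fit_conversion_factor()] on every control well's (fluorescence,
#' absorbance) reading pairs — one fit per well and channel, using the
#' channel matching the well's marker — and averages replicates with
#' [average_factors()].
#'
#' @param readings Long plate tibble (`time_h`, `well`, `channel`, `value`).
#' @param metadata Well metadata with columns `well`, `marker`, `role`;
#'   wells with `role == "control"` and a fluorescent marker are used.
#' @param fit_range Raw-OD fit interval, see [fit_conversion_factor()].
#' @param method Factor orientation, see [fit_conversion_factor()].
#'
#' @return Calibration model tibble keyed by `channel`.
#' @export
calibrate_plate <- function(readings, metadata, fit_range = c(0, 0.3),
                            method = c("reciprocal", "inverse_regression")) {
  method <- match.arg(method)
  controls <- metadata %>%
    filter(.data$role == "control", .data$marker %in% c("CFP", "YFP"))
  if (nrow(controls) == 0L) {
    abort("No single-marker control wells available for calibration.")
  }
  wide <- readings %>%
    filter(.data$well %in% controls$well) %>%
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  fits <- purrr::map_dfr(seq_len(nrow(controls)), function(i) {
    w <- controls$well[i]
    ch <- controls$marker[i]
    d <- wide %>% filter(.data$well == w)
    fit_conversion_factor(d[[ch]], d[["A600"]], fit_range = fit_range,
                          method = method) %>%
      mutate(channel = ch, well = w)
  })
  model <- average_factors(fits, keys = "channel")
  attr(model, "fit_range") <- fit_range
  model
}
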