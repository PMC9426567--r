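# Readers/writers for the plain-text formats the pipeline consumes, and the
# end-to-end pipeline wrapper.

#' Read a plate time-series table
#'
#' Canonical input is a long CSV with columns `time_h`, `well`, `channel`,
#' `value`.  Wide plate-reader exports (one `time_h` column plus one column
#' per well named `<channel>_<well>`, e.g. `A600_A1`) are pivoted into the
#' same shape.  The time grid is validated per well and channel.
#'
#' @param path CSV file path.
#' @param layout `"long"` (default) or `"wide"`.
#' @return Long plate tibble sorted by well, channel, time.
#' @export
read_plate_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                            check.names = FALSE))
  if (layout == "wide") {
    if (!"time_h" %in% names(raw)) abort("Wide table needs a `time_h` column.")
    raw <- raw %>%
      tidyr::pivot_longer(-"time_h", names_to = c("channel", "well"),
                          names_sep = "_", values_to = "value")
  }
  required <- c("time_h", "well", "channel", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  validate_plate_table(raw[required])
}

validate_plate_table <- function(data) {
  dup <- data %>%
    dplyr::count(.data$well, .data$channel, .data$time_h) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("Duplicate (well, channel, time) readings, e.g. well ",
                 dup$well[1], " channel ", dup$channel[1], " at t = ",
                 dup$time_h[1], " h."))
  }
  out <- data %>% arrange(.data$well, .data$channel, .data$time_h)
  bad <- out %>%
    group_by(.data$well, .data$channel) %>%
    summarise(ok = all(diff(.data$time_h) > 0), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0L) {
    abort("Non-monotone time grid after sorting (tied time points).")
  }
  out
}

#' Write a plate time-series table
#'
#' @param data Long plate tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(data, path) {
  write.csv(data[c("time_h", "well", "channel", "value")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write a simulated plate with its ground-truth sidecar
#'
#' Persists a [simulate_coculture_plate()] result as the same long plate
#' CSV the readers consume, plus the well metadata, the latent ground-truth
#' abundances, and a JSON sidecar holding every generator parameter.
#'
#' @param sim List from [simulate_coculture_plate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plate_table(sim$readings, file.path(dir, "plate.csv"))
  write.csv(sim$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(sim$params, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cytometry event table
#'
#' Plain CSV with columns `sample_id`, `transfer`, `is_blank`, `FITC`,
#' `AmCyan` (one row per event).
#'
#' @param path CSV file path.
#' @return Event tibble.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  required <- c("sample_id", "transfer", "is_blank", "FITC", "AmCyan")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  raw$is_blank <- as.logical(raw$is_blank)
  if (any(!is.finite(raw$FITC)) || any(!is.finite(raw$AmCyan))) {
    abort("Event intensities must be finite.")
  }
  raw
}

#' Run the full growth-deconvolution pipeline
#'
#' Convenience wrapper binding calibration, conversion, blank subtraction,
#' smoothing and per-trajectory growth fitting, with a provenance manifest
#' recording every parameter used.  Deterministic given identical inputs
#' and configuration.
#'
#' @param readings Long plate tibble (or path to a long CSV).
#' @param metadata Well metadata tibble, see [analyze_growth_plate()].
#' @param config A [growth_config()].
#' @param out_dir Optional directory; when given, the fit table
#'   (`growth_fits.csv`), calibration (`calibration.csv`) and manifest
#'   (`manifest.json`) are written there.
#'
#' @return List with elements `fits`, `calibration`, `blanks`, `manifest`.
#' @export
run_growth_pipeline <- function(readings, metadata, config = growth_config(),
                                out_dir = NULL) {
  if (is.character(readings)) readings <- read_plate_table(readings)
  readings <- validate_plate_table(readings)
  fits <- analyze_growth_plate(readings, metadata, config = config)
  calibration <- attr(fits, "calibration")
  blanks <- attr(fits, "blanks")
  manifest <- list(
    config = config[setdiff(names(config), "window_mode")],
    window_mode = config$window_mode,
    n_wells = length(unique(metadata$well)),
    n_trajectories = nrow(fits),
    channels = sort(unique(readings$channel))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(fits, file.path(out_dir, "growth_fits.csv"), row.names = FALSE)
    if (!is.null(calibration)) {
      write.csv(calibration, file.path(out_dir, "calibration.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(fits = fits, calibration = calibration, blanks = blanks,
       manifest = manifest)
}
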