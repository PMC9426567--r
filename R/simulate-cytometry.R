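# Synthetic flow-cytometry event tables and serial-transfer trajectories
# with known ground truth.

#' Bivariate log-normal event cluster
#'
#' Describes one subpopulation's (FITC, AmCyan) intensity cluster on the
#' log10 scale.
#'
#' @param n_events Number of events to draw (>= 0).
#' @param fitc_log_mean,fitc_log_sd FITC log10-mean and log10-sd (sd > 0).
#' @param amcyan_log_mean,amcyan_log_sd AmCyan log10-mean and log10-sd.
#' @param label Ground-truth cluster label.
#' @return An object of class `event_cluster`.
#' @export
event_cluster <- function(n_events, fitc_log_mean, fitc_log_sd,
                          amcyan_log_mean, amcyan_log_sd, label = "cluster") {
  if (n_events < 0) abort("`n_events` must be >= 0.")
  if (fitc_log_sd <= 0 || amcyan_log_sd <= 0) abort("Cluster sds must be > 0.")
  structure(list(n_events = as.integer(n_events),
                 fitc_log_mean = fitc_log_mean, fitc_log_sd = fitc_log_sd,
                 amcyan_log_mean = amcyan_log_mean,
                 amcyan_log_sd = amcyan_log_sd, label = label),
            class = "event_cluster")
}

#' Default intensity clusters for marked strains and debris
#'
#' Cluster centers chosen to sit well inside the corresponding gates:
#' YFP-marked cells high in FITC and low in AmCyan, CFP-marked cells the
#' converse, and blank/debris events low in both channels.
#'
#' @param marker `"YFP"`, `"CFP"` or `"blank"`.
#' @param n_events Number of events.
#' @return An `event_cluster`.
#' @export
marker_cluster <- function(marker = c("YFP", "CFP", "blank"), n_events) {
  marker <- match.arg(marker)
  switch(marker,
    YFP = event_cluster(n_events, fitc_log_mean = 4.0, fitc_log_sd = 0.2,
                        amcyan_log_mean = 2.0, amcyan_log_sd = 0.3,
                        label = "YFP"),
    CFP = event_cluster(n_events, fitc_log_mean = 2.0, fitc_log_sd = 0.3,
                        amcyan_log_mean = 4.0, amcyan_log_sd = 0.2,
                        label = "CFP"),
    blank = event_cluster(n_events, fitc_log_mean = 1.5, fitc_log_sd = 0.3,
                          amcyan_log_mean = 1.5, amcyan_log_sd = 0.3,
                          label = "blank")
  )
}

#' Simulate a two-channel cytometry event table
#'
#' Draws per-cluster events from independent log10-normal intensity
#' distributions and appends blank/debris contamination events; the
#' ground-truth cluster label is retained per event.
#'
#' @param clusters An `event_cluster` or list of them.
#' @param blank_rate Number of contaminating debris events appended
#'   (default 0).
#' @param seed Optional integer seed.
#' @return Tibble with columns `FITC`, `AmCyan`, `cluster`.
#' @export
simulate_event_table <- function(clusters, blank_rate = 0, seed = NULL) {
  if (inherits(clusters, "event_cluster")) clusters <- list(clusters)
  total <- sum(vapply(clusters, `[[`, integer(1), "n_events")) + blank_rate
  if (total <= 0) abort("Total number of events must be > 0.")
  if (!is.null(seed)) set.seed(seed)
  if (blank_rate > 0) {
    clusters <- c(clusters, list(marker_cluster("blank", blank_rate)))
  }
  draws <- purrr::map_dfr(clusters, function(cl) {
    if (cl$n_events == 0L) {
      return(tibble(FITC = numeric(), AmCyan = numeric(),
                    cluster = character()))
    }
    tibble(
      FITC = 10^rnorm(cl$n_events, cl$fitc_log_mean, cl$fitc_log_sd),
      AmCyan = 10^rnorm(cl$n_events, cl$amcyan_log_mean, cl$amcyan_log_sd),
      cluster = cl$label
    )
  })
  draws
}

#' Simulate a serial-transfer (proliferation-dilution) trajectory
#'
#' Two strains are repeatedly grown in a shared batch and diluted.  Within
#' each cycle both strains grow exponentially from their post-dilution
#' abundances (after their lags) until the summed abundance reaches the
#' shared yield cap — growth of both strains stops simultaneously, carbon
#' being the shared limiting resource — or the cycle ends; then both are
#' diluted by the dilution factor.  The update is deterministic.
#'
#' @param strain1,strain2 `strain_params` objects (markers used for ratio
#'   orientation: the ratio is strain1:strain2).
#' @param n_transfers Number of dilution cycles.
#' @param dilution Dilution factor per transfer (> 1; default 100).
#' @param shared_yield_cap Summed abundance at which growth stops (b.u.).
#' @param cycle_h Cycle length in hours (default 24).
#' @return Tibble with one row per transfer (0 = inoculation state at the
#'   end of cycle 0): `transfer`, `abundance1`, `abundance2` (pre-dilution,
#'   b.u.), `ratio` (strain1/strain2), `t_grow` (hours of growth in the
#'   cycle until the cap or cycle end).
#' @export
simulate_serial_transfers <- function(strain1, strain2, n_transfers,
                                      dilution = 100, shared_yield_cap,
                                      cycle_h = 24) {
  if (dilution <= 1) abort("`dilution` must be > 1.")
  a <- c(strain1$initial_abundance, strain2$initial_abundance)
  if (sum(a) >= shared_yield_cap) {
    abort("Shared yield cap must exceed the total inoculum.")
  }
  mu <- c(strain1$growth_rate, strain2$growth_rate)
  lag <- c(strain1$lag, strain2$lag)

  total_at <- function(t, a0) {
    sum(a0 * exp(mu * pmax(0, t - lag)))
  }

  rows <- vector("list", n_transfers + 1L)
  rows[[1L]] <- tibble(transfer = 0, abundance1 = a[1], abundance2 = a[2],
                       ratio = a[1] / a[2], t_grow = 0)
  for (k in seq_len(n_transfers)) {
    a0 <- a / dilution
    if (sum(a0) >= shared_yield_cap) {
      abort("Shared yield cap smaller than the post-dilution inoculum.")
    }
    t_star <- if (total_at(cycle_h, a0) < shared_yield_cap) {
      cycle_h
    } else {
      uniroot(function(t) total_at(t, a0) - shared_yield_cap,
              lower = 0, upper = cycle_h, tol = 1e-12)$root
    }
    a <- a0 * exp(mu * pmax(0, t_star - lag))
    rows[[k + 1L]] <- tibble(transfer = k, abundance1 = a[1],
                             abundance2 = a[2], ratio = a[1] / a[2],
                             t_grow = t_star)
  }
  bind_rows(rows)
}

#' Turn a serial-transfer trajectory into cytometry samples
#'
#' For each transfer, draws `events_per_sample` events split binomially
#' between the two strains' intensity clusters according to the latent
#' composition, plus one blank sample of debris events per transfer —
#' yielding the raw event table the cytometry pipeline consumes.
#'
#' @param trajectory Output of [simulate_serial_transfers()].
#' @param marker1,marker2 Markers carried by strain 1 and strain 2
#'   (`"CFP"`/`"YFP"`).
#' @param events_per_sample Events per mixed-culture sample (default 1e5).
#' @param blank_events Debris events per blank sample (default 20).
#' @param sample_id Culture identifier stored in the output.
#' @param seed Optional integer seed.
#' @return Event tibble with columns `sample_id`, `transfer`, `is_blank`,
#'   `FITC`, `AmCyan`.
#' @export
simulate_transfer_events <- function(trajectory, marker1 = "CFP",
                                     marker2 = "YFP",
                                     events_per_sample = 1e5,
                                     blank_events = 20,
                                     sample_id = "culture1", seed = NULL) {
  stopifnot(marker1 %in% c("CFP", "YFP"), marker2 %in% c("CFP", "YFP"),
            marker1 != marker2)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(trajectory))
  for (i in seq_len(nrow(trajectory))) {
    frac1 <- trajectory$abundance1[i] /
      (trajectory$abundance1[i] + trajectory$abundance2[i])
    n1 <- rbinom(1L, events_per_sample, frac1)
    ev <- simulate_event_table(
      list(marker_cluster(marker1, n1),
           marker_cluster(marker2, events_per_sample - n1))
    ) %>%
      mutate(sample_id = sample_id, transfer = trajectory$transfer[i],
             is_blank = FALSE)
    bl <- simulate_event_table(marker_cluster("blank", blank_events)) %>%
      mutate(sample_id = paste0("blank_t", trajectory$transfer[i]),
             transfer = trajectory$transfer[i], is_blank = TRUE)
    out[[i]] <- bind_rows(ev, bl)
  }
  bind_rows(out) %>%
    select("sample_id", "transfer", "is_blank", "FITC", "AmCyan",
           dplyr::everything())
}
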