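# Two-color flow-cytometry gating, population ratios, detection limits and
# competition statistics for serial-transfer experiments.

#' Gate scheme thresholds
#'
#' Threshold gating of (FITC, AmCyan) intensities into the four classes
#' YPCN (YFP-positive-CFP-negative), YNCP, YNCN, and the residual class
#' YPCP.  The `"transfer_zero"` variant raises the AmCyan split to
#' 5e3 a.u. for the CFP gates, reflecting the different fluorescence of
#' exponential-phase, methionine-precultured cells at the first
#' measurement.
#'
#' @param variant `"standard"` or `"transfer_zero"`.
#' @return A named list of thresholds with class `gate_scheme`.
#' @export
gate_scheme <- function(variant = c("standard", "transfer_zero")) {
  variant <- match.arg(variant)
  th <- list(
    fitc_pos = 1e3,    # YFP-positive: FITC above this
    fitc_neg = 7e2,    # YFP-negative (for the CFP-positive gate): FITC below
    amcyan_pos = if (variant == "standard") 2e3 else 5e3,  # CFP-positive split
    amcyan_neg_ypcn = 4e3,  # CFP-negative bound in the YPCN gate
    amcyan_neg_yncn = if (variant == "standard") 2e3 else 5e3,
    variant = variant
  )
  structure(th, class = "gate_scheme")
}

#' Classify events into the four gate classes
#'
#' Vectorized gate assignment with strict inequalities; events matching no
#' explicit gate (including boundary equalities) fall into the residual
#' class YPCP.
#'
#' @param fitc,amcyan Event intensities (a.u., finite).
#' @param scheme A [gate_scheme()] or variant name.
#' @return Character vector of class labels
#'   (`"YPCN"`, `"YNCP"`, `"YNCN"`, `"YPCP"`).
#' @export
#' @examples
#' gate_event(2000, 1000)  # "YPCN"
gate_event <- function(fitc, amcyan, scheme = gate_scheme("standard")) {
  if (is.character(scheme)) scheme <- gate_scheme(scheme)
  if (any(!is.finite(fitc)) || any(!is.finite(amcyan))) {
    abort("Event intensities must be finite.")
  }
  out <- rep("YPCP", length(fitc))
  out[fitc > scheme$fitc_pos & amcyan < scheme$amcyan_neg_ypcn] <- "YPCN"
  out[fitc < scheme$fitc_neg & amcyan > scheme$amcyan_pos] <- "YNCP"
  out[fitc < scheme$fitc_pos & amcyan < scheme$amcyan_neg_yncn] <- "YNCN"
  out
}

#' Gate an event table
#'
#' Adds a `gate` column to a per-event table.  When the table carries a
#' `transfer` column, transfer 0 is gated with the `"transfer_zero"`
#' variant and all later transfers with the standard scheme (the default
#' behaviour of the study design); pass an explicit `scheme` to override.
#'
#' @param events Tibble with columns `FITC` and `AmCyan` (and optionally
#'   `transfer`).
#' @param scheme Optional [gate_scheme()] applied to every event.
#' @return The input tibble with an added `gate` column.
#' @export
gate_events <- function(events, scheme = NULL) {
  stopifnot(all(c("FITC", "AmCyan") %in% names(events)))
  if (!is.null(scheme)) {
    return(mutate(events, gate = gate_event(.data$FITC, .data$AmCyan, scheme)))
  }
  if ("transfer" %in% names(events)) {
    std <- gate_scheme("standard")
    t0 <- gate_scheme("transfer_zero")
    events %>%
      mutate(gate = ifelse(.data$transfer == 0,
                           gate_event(.data$FITC, .data$AmCyan, t0),
                           gate_event(.data$FITC, .data$AmCyan, std)))
  } else {
    mutate(events, gate = gate_event(.data$FITC, .data$AmCyan,
                                     gate_scheme("standard")))
  }
}

#' Count gate classes in a gated event table
#'
#' @param events Gated event tibble (with a `gate` column); grouping columns
#'   such as `sample_id`/`transfer`/`is_blank` are preserved.
#' @return Tibble with one row per group and columns `YPCN`, `YNCP`, `YNCN`,
#'   `YPCP`, `total`.
#' @export
count_gate_classes <- function(events) {
  stopifnot("gate" %in% names(events))
  keys <- intersect(c("sample_id", "transfer", "is_blank"), names(events))
  counts <- events %>%
    group_by(dplyr::across(dplyr::all_of(c(keys, "gate")))) %>%
    summarise(n = n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "gate", values_from = "n",
                       values_fill = 0L)
  for (cl in c("YPCN", "YNCP", "YNCN", "YPCP")) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  counts %>% mutate(total = .data$YPCN + .data$YNCP + .data$YNCN + .data$YPCP)
}

#' Salvager:dependent population ratio from gate counts
#'
#' The ratio of single-positive event counts, oriented by the marker map:
#' the numerator counts the salvager's marker class (YNCP when the salvager
#' carries CFP), the denominator the dependent's.  A zero denominator gives
#' `Inf` with an upper-censoring flag, a zero numerator gives 0 with a
#' lower-censoring flag.
#'
#' @param yncp,ypcn Event counts of the two single-positive classes.
#' @param marker_map Named character vector mapping roles to markers,
#'   default `c(salvager = "CFP", dependent = "YFP")`.
#' @return One-row tibble: `ratio`, `n_numerator`, `n_denominator`,
#'   `censored` (`"none"`, `"lower"`, `"upper"`).
#' @export
population_ratio <- function(yncp, ypcn,
                             marker_map = c(salvager = "CFP",
                                            dependent = "YFP")) {
  stopifnot(all(c("salvager", "dependent") %in% names(marker_map)))
  if (marker_map[["salvager"]] == marker_map[["dependent"]]) {
    abort("Salvager and dependent must carry distinct markers.")
  }
  class_count <- c(CFP = yncp, YFP = ypcn)  # CFP-positive events are YNCP
  num <- class_count[[marker_map[["salvager"]]]]
  den <- class_count[[marker_map[["dependent"]]]]
  censored <- "none"
  if (den == 0) {
    ratio <- Inf
    censored <- "upper"
  } else {
    ratio <- num / den
    if (num == 0) censored <- "lower"
  }
  tibble(ratio = ratio, n_numerator = num, n_denominator = den,
         censored = censored)
}

#' Transfer-specific detection limits of the population ratio
#'
#' From the gate counts of a blank sample: the lower limit is
#' `max(blank_YNCP, 1) / total_events`, the upper limit
#' `total_events / max(blank_YPCN, 1)` (the "or 1" rule applies when the
#' blank produced no such events).
#'
#' @param blank_yncp,blank_ypcn Blank-sample counts of the two
#'   single-positive classes.
#' @param total_events Events collected per mixed-culture sample
#'   (default 1e5).
#' @return One-row tibble: `lower_limit`, `upper_limit`.
#' @export
#' @examples
#' detection_limits(0, 0)  # 1e-5, 1e5
detection_limits <- function(blank_yncp, blank_ypcn, total_events = 1e5) {
  stopifnot(total_events >= 1)
  tibble(lower_limit = max(blank_yncp, 1) / total_events,
         upper_limit = total_events / max(blank_ypcn, 1))
}

#' Per-transfer population-ratio trajectory with detection limits
#'
#' Full cytometry path: gates the raw events (transfer-zero scheme at
#' transfer 0), counts classes per sample, computes the Sal:Dep ratio for
#' each culture sample and transfer-specific detection limits from the
#' blank samples, and flags ratios at or beyond the limits as censored.
#'
#' @param events Event tibble with columns `sample_id`, `transfer`,
#'   `is_blank`, `FITC`, `AmCyan`.
#' @param marker_map See [population_ratio()].
#' @param total_events Events per mixed-culture sample (default 1e5).
#' @return Tibble with one row per culture sample and transfer: `sample_id`,
#'   `transfer`, `ratio`, `n_numerator`, `n_denominator`, `lower_limit`,
#'   `upper_limit`, `censored`.
#' @export
ratio_trajectory <- function(events,
                             marker_map = c(salvager = "CFP",
                                            dependent = "YFP"),
                             total_events = 1e5) {
  stopifnot(all(c("sample_id", "transfer", "is_blank", "FITC", "AmCyan") %in%
                  names(events)))
  counts <- events %>% gate_events() %>% count_gate_classes()

  limits <- counts %>%
    filter(.data$is_blank) %>%
    group_by(.data$transfer) %>%
    summarise(blank_yncp = sum(.data$YNCP), blank_ypcn = sum(.data$YPCN),
              .groups = "drop")
  limits <- dplyr::bind_cols(
    limits["transfer"],
    purrr::map2_dfr(limits$blank_yncp, limits$blank_ypcn,
                    detection_limits, total_events = total_events)
  )

  cultures <- counts %>% filter(!.data$is_blank)
  ratios <- purrr::map_dfr(seq_len(nrow(cultures)), function(i) {
    population_ratio(cultures$YNCP[i], cultures$YPCN[i], marker_map)
  })
  out <- dplyr::bind_cols(
    cultures %>% select("sample_id", "transfer"),
    ratios
  ) %>%
    left_join(limits, by = "transfer")
  out %>%
    mutate(censored = dplyr::case_when(
      .data$censored != "none" ~ .data$censored,
      !is.na(.data$lower_limit) & .data$ratio <= .data$lower_limit ~ "lower",
      !is.na(.data$upper_limit) & .data$ratio >= .data$upper_limit ~ "upper",
      TRUE ~ "none"
    ))
}

#' Slope of log10 population ratio over transfers
#'
#' Ordinary least-squares slope of `log10(ratio)` against transfer index,
#' from `from_transfer` onwards; censored points (at or beyond the
#' detection limits) are excluded with a warning.
#'
#' @param trajectory One culture's rows of a [ratio_trajectory()] result
#'   (columns `transfer`, `ratio`, optionally `censored`).
#' @param from_transfer First transfer included (default 1).
#' @return One-row tibble: `slope` (per transfer), `se`, `intercept`, `n`.
#' @export
ratio_slope <- function(trajectory, from_transfer = 1) {
  df <- trajectory %>% filter(.data$transfer >= from_transfer)
  if ("censored" %in% names(df)) {
    n_cens <- sum(df$censored != "none")
    if (n_cens > 0) {
      warn(paste0(n_cens, " censored transfer(s) excluded from slope fit."))
      df <- df %>% filter(.data$censored == "none")
    }
  }
  df <- df %>% filter(is.finite(.data$ratio), .data$ratio > 0)
  if (nrow(df) < 3L) abort("Need >= 3 uncensored transfers for a slope.")
  fit <- lm(log10(ratio) ~ transfer, data = df)
  s <- summary(fit)$coefficients
  tibble(slope = s["transfer", "Estimate"],
         se = s["transfer", "Std. Error"],
         intercept = s["(Intercept)", "Estimate"],
         n = nrow(df))
}

#' Two-tailed t-test for a difference in ratio slopes
#'
#' `t = (slope1 - slope2) / sqrt(se1^2 + se2^2)` with
#' `df = n1 + n2 - 4` degrees of freedom.
#'
#' @param slope1,se1,n1 First slope estimate, its SE and number of points.
#' @param slope2,se2,n2 Second slope estimate, its SE and number of points.
#' @return One-row tibble: `estimate`, `statistic`, `df`, `p_value`.
#' @export
compare_slopes <- function(slope1, se1, n1, slope2, se2, n2) {
  pooled <- sqrt(se1^2 + se2^2)
  df <- n1 + n2 - 4
  if (pooled == 0) {
    if (slope1 == slope2) {
      return(tibble(estimate = 0, statistic = 0, df = df, p_value = 1))
    }
    warn("Zero pooled standard error with unequal slopes; p set to 0.")
    return(tibble(estimate = slope1 - slope2, statistic = Inf, df = df,
                  p_value = 0))
  }
  stat <- (slope1 - slope2) / pooled
  tibble(estimate = slope1 - slope2, statistic = stat, df = df,
         p_value = 2 * pt(-abs(stat), df = df))
}

#' All pairwise slope comparisons within or between groups
#'
#' Runs [compare_slopes()] for every pair of rows of a slope table (e.g.
#' the 66 pairs arising from 12 trajectories) and applies the
#' Holm-Bonferroni correction at level `alpha`.
#'
#' @param slopes Tibble with columns `slope`, `se`, `n` and an identifier
#'   column `id`.
#' @param alpha Global significance level (default 0.05).
#' @return Tibble with one row per pair: the two ids, `estimate`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`, `reject`.
#' @export
pairwise_slope_tests <- function(slopes, alpha = 0.05) {
  stopifnot(all(c("id", "slope", "se", "n") %in% names(slopes)))
  m <- nrow(slopes)
  if (m < 2L) abort("Need at least 2 slopes to compare.")
  ij <- combn(m, 2L)
  res <- purrr::map_dfr(seq_len(ncol(ij)), function(k) {
    i <- ij[1L, k]
    j <- ij[2L, k]
    dplyr::bind_cols(
      tibble(id1 = slopes$id[i], id2 = slopes$id[j]),
      compare_slopes(slopes$slope[i], slopes$se[i], slopes$n[i],
                     slopes$slope[j], slopes$se[j], slopes$n[j])
    )
  })
  hb <- holm_bonferroni(res$p_value, alpha = alpha)
  dplyr::bind_cols(res, hb[c("p_adjusted", "reject")])
}

#' Holm-Bonferroni step-down multiple-testing correction
#'
#' Rejects the ordered p-values `p_(k)` while `p_(k) <= alpha / (m - k + 1)`,
#' stopping at the first failure, and maps the decisions back to the input
#' order (computed via `stats::p.adjust(method = "holm")`, which implements
#' exactly this procedure).
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param alpha Global significance level (default 0.05).
#' @return Tibble: `p_value`, `p_adjusted`, `reject`.
#' @export
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.02))$reject  # all TRUE at alpha 0.05
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) < 1L) abort("Need at least one p-value.")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  adj <- stats::p.adjust(pvalues, method = "holm")
  tibble(p_value = pvalues, p_adjusted = adj, reject = adj <= alpha)
}
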