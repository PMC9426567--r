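# ggplot2 views of the main result types.

#' Plot raw or processed growth curves
#'
#' @param data Long plate tibble (`time_h`, `well`, `channel`, `value`) or a
#'   trajectory tibble with an `abundance` column.
#' @param log_y Log-scale the y axis (default TRUE).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(data, log_y = TRUE) {
  ycol <- if ("abundance" %in% names(data)) "abundance" else "value"
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$time_h, y = .data[[ycol]],
                                    colour = .data$channel,
                                    group = interaction(.data$well,
                                                        .data$channel))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)",
                  y = if (ycol == "abundance") "Abundance (b.u.)" else
                    "Raw reading") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn fit_4pl Plot the fitted dose-response curve over the data.
#' @param object A `fourpl_fit`.
#' @param ... Unused.
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  stopifnot(object$converged)
  df <- object$data
  pos <- df$dose[df$dose > 0]
  grid <- 10^seq(log10(min(pos)) - 0.5, log10(max(pos)) + 0.5,
                 length.out = 200)
  curve <- tibble(dose = grid,
                  response = four_pl(grid, object$params[["ybottom"]],
                                     object$params[["ytop"]],
                                     object$params[["n"]],
                                     object$params[["ec50"]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$params[["ec50"]],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (M)", y = "Response",
                  title = sprintf("EC50 = %.3g M", object$params[["ec50"]])) +
    ggplot2::theme_minimal()
}

#' Plot a population-ratio trajectory with its detection limits
#'
#' @param trajectory A [ratio_trajectory()] result.
#' @return A ggplot object (log10 ratio vs transfer; shaded region marks
#'   the transfer-specific detection limits).
#' @export
plot_ratio_trajectory <- function(trajectory) {
  ggplot2::ggplot(trajectory, ggplot2::aes(x = .data$transfer)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = log10(.data$lower_limit),
                                      ymax = log10(.data$upper_limit)),
                         fill = "grey90") +
    ggplot2::geom_line(ggplot2::aes(y = log10(.data$ratio),
                                    group = .data$sample_id)) +
    ggplot2::geom_point(ggplot2::aes(y = log10(.data$ratio),
                                     shape = .data$censored)) +
    ggplot2::labs(x = "Transfer", y = "log10 (Sal:Dep ratio)") +
    ggplot2::theme_minimal()
}
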