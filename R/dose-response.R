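# Four-parameter logistic dose-response fitting and EC50 inference.

#' Four-parameter logistic dose-response model
#'
#' Evaluates
#' \deqn{y = y_{bottom} + \frac{x^n (y_{top} - y_{bottom})}{x^n + EC_{50}^n}}
#' with effector concentration `x` (M) and response `y` (e.g. growth rate in
#' 1/h).  At `x = 0` the continuity value `ybottom` is returned.
#'
#' @param x Non-negative concentrations (M).
#' @param ybottom Response as `x -> 0`.
#' @param ytop Response as `x -> Inf`.
#' @param n Hill coefficient (non-zero).
#' @param ec50 Half-maximal effective concentration (> 0).
#' @return Numeric vector of responses.
#' @export
#' @examples
#' four_pl(1.5e-11, 0, 0.40, 2, 1.5e-11)  # midpoint: 0.20
four_pl <- function(x, ybottom, ytop, n, ec50) {
  if (any(x < 0)) abort("Concentrations must be >= 0.")
  if (ec50 <= 0) abort("`ec50` must be > 0.")
  if (n == 0) abort("Hill coefficient must be non-zero.")
  out <- numeric(length(x))
  zero <- x == 0
  out[zero] <- ybottom
  xs <- x[!zero]
  # evaluate on the log scale for numerical stability at extreme doses
  frac <- 1 / (1 + exp(n * (log(ec50) - log(xs))))
  out[!zero] <- ybottom + frac * (ytop - ybottom)
  out
}

fourpl_model <- function(x, ybottom, ytop, n, log10_ec50) {
  four_pl(x, ybottom, ytop, n, 10^log10_ec50)
}

#' Fit the four-parameter dose-response model
#'
#' Least-squares fit of [four_pl()] to (dose, response) data by
#' Levenberg-Marquardt, parameterized internally on `log10(EC50)` for
#' conditioning.  Initialization is deterministic: `ybottom`/`ytop` from the
#' extreme responses, `n = 1`, and EC50 at the dose nearest the half-range
#' crossing.  By default responses are averaged per dose before fitting
#' (replicate means); set `aggregate = "pooled"` to fit all points.
#'
#' @param data Tibble with the dose and response columns.
#' @param dose,response Column names (unquoted) holding concentrations (M)
#'   and responses.
#' @param aggregate `"means"` (default) or `"pooled"`.
#' @param start Optional named list overriding the automatic start values
#'   (`ybottom`, `ytop`, `n`, `ec50`).
#'
#' @return An object of class `fourpl_fit`: list with `params` (named
#'   estimates including `ec50`), `se` (delta-method standard errors),
#'   `n_points`, `converged`, `data` (points used), and the underlying
#'   `nls` object.  Use [tidy()]/[glance()] to extract tables.
#' @export
fit_4pl <- function(data, dose = dose_M, response = response,
                    aggregate = c("means", "pooled"), start = NULL) {
  aggregate <- match.arg(aggregate)
  df <- tibble(dose = dplyr::pull(data, {{ dose }}),
               response = dplyr::pull(data, {{ response }}))
  df <- df %>% filter(is.finite(.data$dose), is.finite(.data$response))
  if (aggregate == "means") {
    df <- df %>%
      group_by(.data$dose) %>%
      summarise(response = mean(.data$response), .groups = "drop")
  }
  if (nrow(df) < 4L) abort("Need at least 4 points for a determinate 4PL fit.")
  if (sum(df$dose > 0) < 2L) {
    abort("Need at least 2 distinct positive doses.")
  }
  if (diff(range(df$response)) == 0) {
    abort("EC50 unidentifiable: all responses are equal.")
  }

  ylo <- min(df$response)
  yhi <- max(df$response)
  half <- (ylo + yhi) / 2
  pos <- df %>% filter(.data$dose > 0)
  ec50_0 <- pos$dose[which.min(abs(pos$response - half))]
  init <- list(ybottom = ylo, ytop = yhi, n = 1, ec50 = ec50_0)
  if (!is.null(start)) init <- utils::modifyList(init, start)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ fourpl_model(dose, ybottom, ytop, n, log10_ec50),
      data = df,
      start = list(ybottom = init$ybottom, ytop = init$ytop, n = init$n,
                   log10_ec50 = log10(init$ec50)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  converged <- !inherits(fit, "error")
  if (!converged) {
    warn(paste0("4PL fit did not converge: ", conditionMessage(fit)))
    return(structure(list(params = NULL, se = NULL, n_points = nrow(df),
                          converged = FALSE, data = df, fit = NULL),
                     class = "fourpl_fit"))
  }

  est <- coef(fit)
  se_int <- sqrt(diag(vcov(fit)))
  ec50 <- 10^est[["log10_ec50"]]
  # delta method: SE(EC50) = ln(10) * EC50 * SE(log10 EC50)
  ec50_se <- log(10) * ec50 * se_int[["log10_ec50"]]
  params <- c(ybottom = unname(est[["ybottom"]]),
              ytop = unname(est[["ytop"]]),
              n = unname(est[["n"]]),
              ec50 = unname(ec50))
  se <- c(ybottom = unname(se_int[["ybottom"]]),
          ytop = unname(se_int[["ytop"]]),
          n = unname(se_int[["n"]]),
          ec50 = unname(ec50_se))
  structure(list(params = params, se = se, n_points = nrow(df),
                 converged = TRUE, data = df, fit = fit),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter dose-response fit\n")
  if (!x$converged) {
    cat("  (did not converge)\n")
    return(invisible(x))
  }
  cat(sprintf("  ybottom = %.4g   ytop = %.4g   n = %.3g\n",
              x$params[["ybottom"]], x$params[["ytop"]], x$params[["n"]]))
  cat(sprintf("  EC50 = %.4g M (SE %.3g), %d points\n",
              x$params[["ec50"]], x$se[["ec50"]], x$n_points))
  invisible(x)
}

#' @export
tidy.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = character(), estimate = numeric(),
                  std.error = numeric()))
  }
  tibble(term = names(x$params),
         estimate = unname(x$params),
         std.error = unname(x$se[names(x$params)]))
}

#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(ec50 = if (x$converged) x$params[["ec50"]] else NA_real_,
         ec50_se = if (x$converged) x$se[["ec50"]] else NA_real_,
         n_points = x$n_points,
         df_residual = x$n_points - 4L,
         converged = x$converged)
}

#' Confidence interval for a fitted EC50
#'
#' Interval `EC50 +/- t(level, N - 4) * SE(EC50)`, with N the number of
#' fitted points.
#'
#' @param fit A converged [fit_4pl()] object.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `ec50`, `lower`, `upper`, `level`, `df`.
#' @export
ec50_confidence_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) abort("Cannot form a CI for a non-converged fit.")
  df <- fit$n_points - 4L
  if (df < 1L) abort("CI undefined: need more than 4 points.")
  tq <- qt(1 - (1 - level) / 2, df = df)
  ec50 <- fit$params[["ec50"]]
  se <- fit$se[["ec50"]]
  tibble(ec50 = ec50, lower = ec50 - tq * se, upper = ec50 + tq * se,
         level = level, df = df)
}

#' Two-tailed t-test for a difference in EC50
#'
#' Tests H0: identical EC50 using
#' `t = (EC50_1 - EC50_2) / sqrt(SE_1^2 + SE_2^2)` with
#' `df = N_1 + N_2 - 8` degrees of freedom.
#'
#' @param fit1,fit2 Converged [fit_4pl()] objects.
#' @return One-row tibble: `estimate` (difference), `statistic`, `df`,
#'   `p_value`, `ratio` (EC50_1 / EC50_2).
#' @export
compare_ec50 <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "fourpl_fit"), inherits(fit2, "fourpl_fit"))
  if (!fit1$converged || !fit2$converged) {
    abort("Both fits must be converged.")
  }
  e1 <- fit1$params[["ec50"]]
  e2 <- fit2$params[["ec50"]]
  pooled <- sqrt(fit1$se[["ec50"]]^2 + fit2$se[["ec50"]]^2)
  df <- fit1$n_points + fit2$n_points - 8L
  if (pooled == 0) {
    if (e1 == e2) {
      p <- 1
      stat <- 0
    } else {
      warn("Zero pooled standard error with unequal estimates; p set to 0.")
      p <- 0
      stat <- Inf
    }
  } else {
    stat <- (e1 - e2) / pooled
    p <- 2 * pt(-abs(stat), df = df)
  }
  tibble(estimate = e1 - e2, statistic = stat, df = df, p_value = p,
         ratio = e1 / e2)
}
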