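#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an adaptive track
#'
#' Level by trial with reversals highlighted and the run's SRT as a dashed
#' line.
#'
#' @param run a `run_result` with trial data.
#' @return a ggplot.
#' @export
plot_track <- function(run) {
  if (is.null(run$trials)) stop("run has no trial data", call. = FALSE)
  df <- run$trials
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$level_db)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct,
                                     colour = .data$reversal), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30")) +
    ggplot2::labs(x = "Trial", y = "Level (dB)",
                  title = paste0(run$condition, " adaptive track"),
                  shape = "Correct", colour = "Reversal") +
    ggplot2::theme_minimal()
  if (isTRUE(run$valid)) {
    p <- p + ggplot2::geom_hline(yintercept = run$srt, linetype = "dashed")
  }
  p
}

#' Plot a prediction band with observations
#'
#' @param object a `prediction_band`.
#' @param observations optional data frame with `age`, `srt` columns;
#'   flagged points are circled.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.prediction_band <- function(object, observations = NULL, ...) {
  xr <- object$mean_x + c(-2.2, 2.2) * sqrt(object$sxx / object$n)
  if (!is.null(observations)) {
    xr <- range(c(xr, observations$age))
  }
  grid <- predict(object, seq(xr[1], xr[2], length.out = 100))
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = "Age (years)", y = "SRT (dB)") +
    ggplot2::theme_minimal()
  if (!is.null(observations)) {
    obs <- flag_outliers(object, observations)
    p <- p +
      ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$srt)) +
      ggplot2::geom_point(data = dplyr::filter(obs, .data$flagged),
                          ggplot2::aes(y = .data$srt), shape = 1, size = 4,
                          colour = "firebrick")
  }
  p
}

#' Day-to-day reliability scatter
#'
#' Day-1 values against a later day's, with the identity line and the
#' consistency ICC annotated.
#'
#' @param sessions tibble from [session_summary()].
#' @param measure one of `"srt_m0t0"`, `"srt_m0tpi"`, `"bild"`,
#'   `"quiet_srt"`.
#' @param days length-2 day pair, e.g. `c(1, 2)`.
#' @return a ggplot.
#' @export
plot_reliability <- function(sessions, measure = "srt_m0t0", days = c(1, 2)) {
  wide <- sessions |>
    dplyr::filter(.data$day %in% days) |>
    dplyr::select("id", "group", "day",
                  value = dplyr::all_of(measure)) |>
    tidyr::pivot_wider(names_from = "day", values_from = "value",
                       names_prefix = "day") |>
    stats::na.omit()
  cols <- paste0("day", days)
  icc <- icc_consistency(as.matrix(wide[, cols]))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[cols[1]]],
                                     y = .data[[cols[2]]],
                                     colour = .data$group)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = sprintf("ICC = %.2f (%.2f-%.2f)", icc$estimate,
                                      icc$ci_low, icc$ci_high)) +
    ggplot2::labs(x = sprintf("Day %d (dB)", days[1]),
                  y = sprintf("Day %d (dB)", days[2]), title = measure) +
    ggplot2::theme_minimal()
}
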