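#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_line
#'   geom_abline geom_col labs coord_cartesian theme_minimal
#' @export
ggplot2::autoplot

#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- bind_rows(
    tibble(time = 0, estimate = 1),
    as_tibble(object)[c("time", "estimate")]
  )
  ggplot(df, aes(x = .data$time, y = .data$estimate)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Years since ART initiation", y = "Survival probability") +
    theme_minimal()
}

#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$mean_predicted, y = .data$observed_km)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_point() +
    geom_line() +
    coord_cartesian(xlim = c(min(df$mean_predicted, df$observed_km,
                                 na.rm = TRUE), 1),
                    ylim = c(min(df$mean_predicted, df$observed_km,
                                 na.rm = TRUE), 1)) +
    labs(
      x = sprintf("Predicted %s-year survival", attr(object, "horizon")),
      y = "Observed (Kaplan-Meier) survival",
      title = sprintf("Calibration at %s years (mean obs - pred = %+.3f)",
                      attr(object, "horizon"),
                      attr(object, "mean_difference"))
    ) +
    theme_minimal()
}

#' @method autoplot timedep_c_grid
#' @export
autoplot.timedep_c_grid <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$horizon, y = .data$estimate)) +
    geom_line() +
    geom_point() +
    coord_cartesian(ylim = c(0.4, 1)) +
    labs(x = "Years since ART initiation", y = "Time-dependent C-statistic") +
    theme_minimal()
}

#' Histogram of the prognostic-index distribution
#'
#' @param data A scored cohort (see [score_cohort()]) with a `pi` column.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_pi_distribution <- function(data, bins = 30) {
  ggplot(as_tibble(data), aes(x = .data$pi)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    labs(x = "Prognostic index (linear predictor)", y = "Patients") +
    theme_minimal()
}
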