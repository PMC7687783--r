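#' Calibration table at a fixed horizon
#'
#' Bins subjects by quantiles of predicted survival at the horizon and
#' compares, per bin, the mean predicted survival with the Kaplan-Meier
#' observed survival at the same horizon. The difference is
#' `observed - predicted`: positive values mean the model underestimates
#' survival (overestimates mortality).
#'
#' @param data Data frame with one row per subject.
#' @param predicted Name of the column of predicted survival probabilities
#'   at `horizon`.
#' @param horizon Horizon in years.
#' @param n_bins Number of quantile bins (>= 2; default 10).
#' @param time,event Follow-up time and event columns.
#' @return A tibble of class `calibration_table` with columns `bin`, `n`,
#'   `mean_predicted`, `observed_km`, `difference`, `flagged` (no subject at
#'   risk at the horizon). Attributes: `horizon`, `mean_difference` (bin
#'   average), `mean_difference_patient` (patient-weighted),
#'   `max_difference` (signed value of largest magnitude); [generics::glance()]
#'   returns them as a one-row tibble.
#' @export
calibration_table <- function(data, predicted, horizon, n_bins = 10,
                              time = "time", event = "event") {
  check_surv_cols(data, time, event)
  if (!predicted %in% names(data)) {
    abort(sprintf("column '%s' not found", predicted))
  }
  if (n_bins < 2) abort("`n_bins` must be at least 2")
  p <- data[[predicted]]
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("predicted survival must be complete and within [0, 1]")
  }
  df <- tibble(
    .pred = p,
    .time = data[[time]],
    .event = as_event01(data[[event]]),
    .bin = dplyr::ntile(p, n_bins)
  )
  rows <- map(seq_len(n_bins), function(b) {
    sub <- df[df$.bin == b, ]
    km <- km_estimate(tibble(time = sub$.time, event = sub$.event))
    at_risk <- any(sub$.time >= horizon)
    obs <- if (at_risk) surv_at(km, horizon) else NA_real_
    tibble(
      bin = b, n = nrow(sub),
      mean_predicted = mean(sub$.pred),
      observed_km = obs,
      difference = obs - mean(sub$.pred),
      flagged = !at_risk
    )
  })
  out <- list_rbind(rows)
  if (any(out$flagged)) {
    warn(sprintf("%d bin(s) have no subject at risk at %s y; observed KM undefined",
                 sum(out$flagged), horizon))
  }
  # patient-level observed uses the bin KM for every member of the bin
  ok <- !out$flagged
  attr(out, "horizon") <- horizon
  attr(out, "mean_difference") <- mean(out$difference[ok])
  attr(out, "mean_difference_patient") <-
    sum(out$n[ok] * out$difference[ok]) / sum(out$n[ok])
  attr(out, "max_difference") <-
    out$difference[ok][which.max(abs(out$difference[ok]))]
  class(out) <- c("calibration_table", class(out))
  out
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration at %s y: mean difference (obs - pred) = %+.4f, extreme = %+.4f\n",
              attr(x, "horizon"), attr(x, "mean_difference"),
              attr(x, "max_difference")))
  NextMethod()
}
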