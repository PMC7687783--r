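#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric survival estimate \eqn{\hat S(t) = \prod_{t_j \le t}
#' (1 - d_j / n_j)} over distinct event times, computed from first
#' principles. Evaluate the curve at arbitrary times with [surv_at()]
#' (right-continuous step lookup).
#'
#' @param data Data frame with one row per subject.
#' @param time,event Names of the follow-up time (years, > 0) and event
#'   columns. Events may be 0/1, logical, or `"died"`/`"censored"`.
#' @return A tibble of class `km_estimate` with columns `time` (distinct
#'   event times), `n_risk`, `n_event`, `n_censor` (censorings in
#'   `(previous event time, time]`), and `estimate`; the cohort size is kept
#'   in attribute `n`.
#' @export
km_estimate <- function(data, time = "time", event = "event") {
  if (nrow(data) == 0) abort("cannot estimate a survival curve from an empty sample")
  check_surv_cols(data, time, event)
  tm <- data[[time]]
  ev <- as_event01(data[[event]])
  tab <- surv_risk_table(tm, ev)
  tab$estimate <- cumprod(1 - tab$n_event / tab$n_risk)
  structure(tab, class = c("km_estimate", class(tab)), n = length(tm))
}

# risk table over distinct event times (censorings folded into n_censor)
surv_risk_table <- function(tm, ev) {
  o <- order(tm)
  tm <- tm[o]
  ev <- ev[o]
  n <- length(tm)
  etimes <- sort(unique(tm[ev == 1]))
  if (length(etimes) == 0) {
    return(tibble(time = numeric(0), n_risk = integer(0),
                  n_event = integer(0), n_censor = integer(0)))
  }
  # at risk at t: observed time >= t
  n_risk <- vapply(etimes, function(t) sum(tm >= t), numeric(1))
  n_event <- vapply(etimes, function(t) sum(tm == t & ev == 1), numeric(1))
  prev <- c(-Inf, etimes[-length(etimes)])
  n_censor <- vapply(seq_along(etimes), function(i) {
    sum(tm > prev[i] & tm <= etimes[i] & ev == 0)
  }, numeric(1))
  tibble(time = etimes, n_risk = as.integer(n_risk),
         n_event = as.integer(n_event), n_censor = as.integer(n_censor))
}

#' Evaluate a step estimate at arbitrary times
#'
#' Right-continuous lookup: the value after the largest jump time `<= t`.
#' Before the first jump, [surv_at()] returns 1 and [cumhaz_at()] returns 0.
#'
#' @param fit A `km_estimate` or `na_estimate` object.
#' @param times Numeric vector of evaluation times.
#' @return Numeric vector of estimates.
#' @export
surv_at <- function(fit, times) {
  step_lookup(fit$time, fit$estimate, times, before = 1)
}

#' @rdname surv_at
#' @export
cumhaz_at <- function(fit, times) {
  step_lookup(fit$time, fit$cumhaz, times, before = 0)
}

step_lookup <- function(jump_times, values, times, before) {
  idx <- findInterval(times, jump_times)
  out <- c(before, values)[idx + 1]
  out
}

#' Nelson-Aalen cumulative hazard estimate
#'
#' \eqn{\hat H(t) = \sum_{t_j \le t} d_j / n_j} over distinct event times.
#'
#' @inheritParams km_estimate
#' @return A tibble of class `na_estimate` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `cumhaz`.
#' @export
nelson_aalen <- function(data, time = "time", event = "event") {
  if (nrow(data) == 0) abort("cannot estimate a cumulative hazard from an empty sample")
  check_surv_cols(data, time, event)
  tm <- data[[time]]
  ev <- as_event01(data[[event]])
  tab <- surv_risk_table(tm, ev)
  tab$cumhaz <- cumsum(tab$n_event / tab$n_risk)
  structure(tab, class = c("na_estimate", class(tab)), n = length(tm))
}

#' Append each subject's Nelson-Aalen cumulative hazard
#'
#' Adds a column with the cohort's Nelson-Aalen cumulative hazard evaluated
#' at each subject's own follow-up time. Together with the event indicator
#' this is the standard outcome representation for imputation models on
#' censored data.
#'
#' @inheritParams km_estimate
#' @param col Name of the column to add.
#' @return The input as a tibble with the extra column.
#' @export
add_nelson_aalen <- function(data, time = "time", event = "event",
                             col = "na_cumhaz") {
  na <- nelson_aalen(data, time, event)
  out <- as_tibble(data)
  out[[col]] <- cumhaz_at(na, data[[time]])
  out
}

#' Follow-up quantiles by the reverse Kaplan-Meier method
#'
#' Flips the event indicator so that censoring becomes the event and reads
#' the median (and IQR) potential follow-up off the resulting curve: the
#' smallest observed time where the reverse-KM curve drops to or below the
#' target level. Degenerate samples whose curve never reaches a level yield
#' `NA` with `defined = FALSE`.
#'
#' @inheritParams km_estimate
#' @param probs Curve levels to invert; default `c(0.75, 0.5, 0.25)` giving
#'   the first quartile, median and third quartile of follow-up.
#' @return A tibble with columns `prob`, `time`, `defined`.
#' @export
median_followup <- function(data, time = "time", event = "event",
                            probs = c(0.75, 0.5, 0.25)) {
  ev <- as_event01(data[[event]])
  flipped <- tibble(time = data[[time]], event = 1L - ev)
  km <- km_estimate(flipped)
  tibble(
    prob = probs,
    time = vapply(probs, function(p) {
      i <- which(km$estimate <= p + 1e-12)
      if (length(i) == 0) NA_real_ else km$time[min(i)]
    }, numeric(1)),
    defined = !is.na(vapply(probs, function(p) {
      i <- which(km$estimate <= p + 1e-12)
      if (length(i) == 0) NA_real_ else km$time[min(i)]
    }, numeric(1)))
  )
}

#' Cumulative mortality at fixed horizons
#'
#' `1 - KM` at the requested horizons, as percentages. Horizons beyond the
#' longest observed follow-up are reported as `NA` with a notice.
#'
#' @inheritParams km_estimate
#' @param horizons Horizons in years.
#' @return A tibble with columns `horizon`, `cumulative_mortality_pct`.
#' @export
cumulative_mortality <- function(data, horizons = c(3, 5, 10, 15),
                                 time = "time", event = "event") {
  km <- km_estimate(data, time, event)
  maxt <- max(data[[time]])
  beyond <- horizons > maxt
  if (any(beyond)) {
    inform(sprintf("horizons beyond observed follow-up (%.2f y) skipped: %s",
                   maxt, paste(horizons[beyond], collapse = ", ")))
  }
  vals <- 100 * (1 - surv_at(km, horizons))
  vals[beyond] <- NA_real_
  tibble(horizon = horizons, cumulative_mortality_pct = vals)
}

#' Exact Poisson rate and confidence interval
#'
#' Event rate per `per` person-years with the exact (chi-square quantile)
#' Poisson interval: lower \eqn{\chi^2_{\alpha/2}(2k)/2}, upper
#' \eqn{\chi^2_{1-\alpha/2}(2k+2)/2}, divided by the exposure.
#'
#' @param events Event count.
#' @param exposure Person-years at risk (> 0).
#' @param level Confidence level.
#' @param per Rate denominator (default per 1000 person-years).
#' @return A tibble of class `rate_estimate` with columns `events`,
#'   `exposure`, `rate`, `ci_low`, `ci_high`, `per`, `level`.
#' @examples
#' poisson_rate_ci(743, 65037) # 11.42 (10.62, 12.28) per 1000 PY
#' @export
poisson_rate_ci <- function(events, exposure, level = 0.95, per = 1000) {
  if (length(events) != 1 || length(exposure) != 1) {
    abort("`events` and `exposure` must be scalars")
  }
  if (exposure <= 0) abort("`exposure` must be positive")
  if (events < 0 || events != round(events)) abort("`events` must be a count")
  a <- (1 - level) / 2
  lo <- if (events == 0) 0 else qchisq(a, 2 * events) / 2
  hi <- qchisq(1 - a, 2 * events + 2) / 2
  out <- tibble(
    events = as.integer(events), exposure = exposure,
    rate = per * events / exposure,
    ci_low = per * lo / exposure, ci_high = per * hi / exposure,
    per = per, level = level
  )
  class(out) <- c("rate_estimate", class(out))
  out
}
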