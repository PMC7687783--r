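#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) {
  tibble(
    horizon = as.character(x$horizon),
    estimate = x$estimate, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high,
    n = x$n, n_usable_pairs = x$n_usable_pairs
  )
}

#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tidy.concordance_result(x)
}

#' @method tidy calibration_table
#' @export
tidy.calibration_table <- function(x, ...) {
  out <- as_tibble(x)
  out$horizon <- attr(x, "horizon")
  out
}

#' @method glance calibration_table
#' @export
glance.calibration_table <- function(x, ...) {
  tibble(
    horizon = attr(x, "horizon"),
    mean_difference = attr(x, "mean_difference"),
    mean_difference_patient = attr(x, "mean_difference_patient"),
    max_difference = attr(x, "max_difference"),
    n = sum(x$n), n_bins = nrow(x)
  )
}

#' @method tidy ph_fit
#' @export
tidy.ph_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "coef"],
    std.error = s[, "se(coef)"],
    statistic = s[, "z"],
    p.value = s[, "Pr(>|z|)"]
  )
}

#' @method glance ph_fit
#' @export
glance.ph_fit <- function(x, ...) {
  tibble(
    n = x$fit$n, n_events = x$fit$nevent,
    converged = x$converged,
    s0_1 = unname(x$baseline_survival[["1"]]),
    s0_2 = unname(x$baseline_survival[["2"]]),
    s0_3 = unname(x$baseline_survival[["3"]])
  )
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  x$concordance
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    tibble(scenario = x$provenance$scenario, m = x$provenance$m,
           seed = x$provenance$seed)
  )
}

#' @method tidy imputed_cohort_set
#' @export
tidy.imputed_cohort_set <- function(x, ...) {
  out <- x$audit
  out$method <- unname(x$methods[out$variable])
  out
}
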