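#' Harrell's overall C-statistic for censored data
#'
#' Probability, over usable pairs, that the subject with the worse score
#' (higher = worse prognosis) fails first. A pair is usable when the member
#' with the shorter observed time has an event, or the times are tied with
#' exactly one event (the event member is taken to fail first); pairs tied on
#' time with two events are not usable. Tied scores contribute 1/2. The
#' standard error and confidence interval come from a seeded nonparametric
#' bootstrap over subjects.
#'
#' @param data Data frame with one row per subject.
#' @param score Name of the risk-score column (higher = worse prognosis).
#' @param time,event Follow-up time and event columns, as in
#'   [km_estimate()].
#' @param conf_level Confidence level for the bootstrap percentile interval.
#' @param boot Number of bootstrap replicates (0 disables the interval).
#' @param seed Optional integer seed for the bootstrap.
#' @return A `concordance_result`: list with `estimate`, `se`, `ci_low`,
#'   `ci_high`, `n`, `n_usable_pairs`, `horizon` (`"overall"`), `boot`.
#'   Use [generics::tidy()]/[generics::glance()] to get a tibble.
#' @export
harrell_c <- function(data, score = "score", time = "time", event = "event",
                      conf_level = 0.95, boot = 200, seed = NULL) {
  check_surv_cols(data, time, event)
  if (!score %in% names(data)) abort(sprintf("column '%s' not found", score))
  tm <- data[[time]]
  ev <- as_event01(data[[event]])
  sc <- data[[score]]
  if (anyNA(sc)) abort("scores must not be missing")
  core <- harrell_core(tm, ev, sc)
  if (core$usable == 0) abort("no usable pairs: concordance is undefined")
  est <- core$c
  se <- ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set_seed_if(seed)
    n <- length(tm)
    reps <- vapply(seq_len(boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      harrell_core(tm[idx], ev[idx], sc[idx])$c
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    se <- sd(reps)
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(reps, c(a, 1 - a)))
    # percentile intervals are not guaranteed to bracket the point estimate
    ci <- c(min(ci[1], est), max(ci[2], est))
  } else {
    se <- NA_real_
  }
  new_concordance_result(est, se, ci[1], ci[2], length(tm), core$usable,
                         "overall", boot)
}

new_concordance_result <- function(estimate, se, ci_low, ci_high, n,
                                   n_usable_pairs, horizon, boot) {
  structure(
    list(estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
         n = n, n_usable_pairs = n_usable_pairs, horizon = horizon,
         boot = boot),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  hz <- if (identical(x$horizon, "overall")) "overall" else
    sprintf("at %s y", x$horizon)
  cat(sprintf("C-statistic (%s): %.4f", hz, x$estimate))
  if (!is.na(x$ci_low)) cat(sprintf(" (%.4f-%.4f)", x$ci_low, x$ci_high))
  cat(sprintf(" [n = %d, usable pairs = %.0f]\n", x$n, x$n_usable_pairs))
  invisible(x)
}

# vectorised over comparators; loops only over subjects with events
harrell_core <- function(tm, ev, sc) {
  conc <- tied <- usable <- 0
  for (i in which(ev == 1L)) {
    comp <- tm > tm[i] | (tm == tm[i] & ev == 0L)
    nc <- sum(comp)
    if (nc == 0) next
    s <- sc[comp]
    conc <- conc + sum(s < sc[i])
    tied <- tied + sum(s == sc[i])
    usable <- usable + nc
  }
  list(c = if (usable > 0) (conc + 0.5 * tied) / usable else NA_real_,
       usable = usable)
}

#' IPCW time-dependent C-statistic at a fixed horizon
#'
#' Truncated concordance at horizon `t`: cases are subjects with an event by
#' `t`, comparators are subjects still at risk at `t` (observed time > `t`),
#' and a pair is concordant when the case has the higher score (score ties
#' count 1/2). Pairs are weighted by the inverse probability of the case
#' remaining uncensored, \eqn{1/\hat G(X_i^-)}, with \eqn{\hat G} the
#' Kaplan-Meier estimate of the censoring distribution (the comparator
#' weight \eqn{1/\hat G(t)} is common to all pairs and cancels). With no
#' censoring before `t` all weights are equal and the estimate reduces to
#' the unweighted truncated concordance.
#'
#' @inheritParams harrell_c
#' @param horizon Horizon in years, within the observed follow-up range.
#' @return A `concordance_result` with `horizon` set to the evaluation time.
#' @export
timedep_c <- function(data, horizon, score = "score", time = "time",
                      event = "event", conf_level = 0.95, boot = 0,
                      seed = NULL) {
  check_surv_cols(data, time, event)
  tm <- data[[time]]
  ev <- as_event01(data[[event]])
  sc <- data[[score]]
  if (anyNA(sc)) abort("scores must not be missing")
  if (horizon <= 0 || horizon > max(tm)) {
    abort(sprintf("horizon %.3g outside observed follow-up (0, %.3g]",
                  horizon, max(tm)))
  }
  core <- ipcw_core(tm, ev, sc, horizon)
  if (is.na(core$c)) {
    abort(sprintf("no cases or no at-risk comparators at horizon %s", horizon))
  }
  se <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set_seed_if(seed)
    n <- length(tm)
    reps <- vapply(seq_len(boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(ipcw_core(tm[idx], ev[idx], sc[idx], horizon)$c,
               error = function(e) NA_real_)
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    se <- sd(reps)
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(reps, c(a, 1 - a)))
    ci <- c(min(ci[1], core$c), max(ci[2], core$c))
  }
  new_concordance_result(core$c, se, ci[1], ci[2], length(tm),
                         core$n_pairs, horizon, boot)
}

ipcw_core <- function(tm, ev, sc, horizon) {
  cases <- which(ev == 1L & tm <= horizon)
  comps <- which(tm > horizon)
  if (length(cases) == 0 || length(comps) == 0) {
    return(list(c = NA_real_, n_pairs = 0))
  }
  # censoring-distribution KM (reverse KM), evaluated just before each case
  gkm <- km_estimate(tibble(time = tm, event = 1L - ev))
  g_at <- function(t_minus) {
    # left limit: value after the last censoring time strictly < t
    step_lookup(gkm$time, gkm$estimate, t_minus - 1e-10, before = 1)
  }
  g <- g_at(tm[cases])
  if (any(g <= 0)) {
    abort("censoring-distribution estimate is zero at a case's event time")
  }
  w <- 1 / g
  sc_comp <- sort(sc[comps])
  nc <- length(sc_comp)
  # for each case: comparators with strictly smaller score, and score ties
  n_less <- findInterval(sc[cases], sc_comp, left.open = TRUE)
  n_le <- findInterval(sc[cases], sc_comp)
  n_tie <- n_le - n_less
  num <- sum(w * (n_less + 0.5 * n_tie))
  den <- sum(w * nc)
  list(c = num / den, n_pairs = length(cases) * nc)
}

#' Time-dependent C-statistic over a grid of horizons
#'
#' Convenience wrapper over [timedep_c()]; horizons beyond the observed
#' follow-up, or at which no cases or comparators exist, are skipped with a
#' notice and returned as `NA`.
#'
#' @inheritParams timedep_c
#' @param horizons Numeric vector of horizons in years.
#' @return A tibble of class `timedep_c_grid` with columns `horizon`,
#'   `estimate`, `n_usable_pairs`.
#' @export
timedep_c_grid <- function(data, horizons = c(0.5, 1:10), score = "score",
                           time = "time", event = "event") {
  rows <- map(horizons, function(h) {
    res <- tryCatch(
      timedep_c(data, h, score = score, time = time, event = event),
      error = function(e) {
        inform(sprintf("horizon %s skipped: %s", h, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      tibble(horizon = h, estimate = NA_real_, n_usable_pairs = NA_real_)
    } else {
      tibble(horizon = h, estimate = res$estimate,
             n_usable_pairs = res$n_usable_pairs)
    }
  })
  out <- list_rbind(rows)
  class(out) <- c("timedep_c_grid", class(out))
  out
}

#' Pool estimates across imputed datasets with Rubin's rules
#'
#' Pooled estimate is the mean of the per-dataset estimates; total variance
#' is `within + (1 + 1/m) * between`; the confidence interval uses a t
#' reference with Barnard-Rubin degrees of freedom (reducing to the classic
#' \eqn{(m-1)(1 + 1/r)^2} when `df_com = Inf`). Bounded statistics such as
#' C-statistics should be pooled on the logit scale
#' (`transform = "logit"`): estimates and variances are transformed (delta
#' method), pooled, and the estimate and interval back-transformed.
#'
#' @param estimates Numeric vector of per-imputation estimates (length m).
#' @param variances Numeric vector of per-imputation (squared-SE) variances.
#' @param conf_level Confidence level.
#' @param transform `"identity"` or `"logit"`.
#' @param df_com Complete-data degrees of freedom (default `Inf`).
#' @return A tibble of class `pooled_estimate` with columns `estimate`,
#'   `ci_low`, `ci_high`, `within`, `between`, `total_variance`, `df`, `m`
#'   (variances on the working scale).
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95,
                       transform = c("identity", "logit"), df_com = Inf) {
  transform <- match.arg(transform)
  m <- length(estimates)
  if (m == 0) abort("cannot pool zero imputations")
  if (length(variances) != m) {
    abort("`estimates` and `variances` must have the same length")
  }
  if (transform == "logit") {
    variances <- variances / (estimates * (1 - estimates))^2
    estimates <- qlogis(estimates)
  }
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- if (m > 1) var(estimates) else 0
  total <- ubar + (1 + 1 / m) * b
  if (m == 1 || b == 0) {
    df <- if (is.infinite(df_com)) Inf else df_com
  } else {
    r <- (1 + 1 / m) * b / ubar
    df_old <- (m - 1) * (1 + 1 / r)^2
    if (is.infinite(df_com)) {
      df <- df_old
    } else {
      lambda <- (1 + 1 / m) * b / total
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    }
  }
  a <- (1 - conf_level) / 2
  tq <- if (is.infinite(df)) qnorm(1 - a) else qt(1 - a, df)
  ci <- qbar + c(-1, 1) * tq * sqrt(total)
  est <- qbar
  if (transform == "logit") {
    est <- plogis(est)
    ci <- plogis(ci)
  }
  out <- tibble(
    estimate = est, ci_low = ci[1], ci_high = ci[2],
    within = ubar, between = b, total_variance = total,
    df = df, m = m
  )
  class(out) <- c("pooled_estimate", class(out))
  out
}

#' Pool C-statistics across imputations
#'
#' Applies [pool_rubin()] on the logit scale to a list of
#' `concordance_result` objects (the conventional choice for estimates
#' bounded in (0, 1)).
#'
#' @param results List of `concordance_result` objects with bootstrap SEs.
#' @param conf_level Confidence level.
#' @return A `pooled_estimate` tibble.
#' @export
pool_concordance <- function(results, conf_level = 0.95) {
  est <- map_dbl(results, "estimate")
  se <- map_dbl(results, "se")
  if (anyNA(se)) abort("all concordance results need a bootstrap SE to pool")
  pool_rubin(est, se^2, conf_level = conf_level, transform = "logit")
}
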