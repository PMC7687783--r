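#' Read and filter a cohort file
#'
#' Reads a delimited (CSV) patient-level cohort, derives standard fields,
#' and applies the study inclusion criteria: combination ART with at least
#' three drugs (when an `art_drugs` column is present), age above 15 years,
#' and at least one follow-up record (when an `n_followup` column is
#' present). Derivations: `vl_category` from `vl_copies` (boundaries
#' \[0,200), \[200,1000), \[1000,Inf)) when absent, and `bmi` =
#' weight/height^2 when `weight` and `height` are present (heights above 3
#' are taken as centimetres). Excluded rows are counted per criterion in the
#' attached exclusion log. Nonpositive or missing follow-up times are a
#' schema error reported with row numbers.
#'
#' @param path CSV file path, or a data frame (already-parsed cohorts pass
#'   through the same checks, making the operation idempotent).
#' @param time,event Follow-up time and event columns.
#' @return A tibble of retained records; attribute `exclusions` is a tibble
#'   with columns `criterion`, `n_excluded`.
#' @export
ingest_cohort <- function(path, time = "time", event = "event") {
  data <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(data) == 0) abort("cohort file is empty")
  required <- c("age", "gender", "cd4", "hemoglobin", time, event)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("required column(s) absent: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!("vl_category" %in% names(data)) && !("vl_copies" %in% names(data))) {
    abort("need a 'vl_category' or 'vl_copies' column")
  }
  tm <- data[[time]]
  bad_time <- which(is.na(tm) | tm <= 0)
  if (length(bad_time) > 0) {
    abort(sprintf("nonpositive or missing follow-up time in row(s): %s",
                  paste(head(bad_time, 10), collapse = ", ")))
  }
  data[[event]] <- as_event01(data[[event]])
  if (!"vl_category" %in% names(data)) {
    data$vl_category <- vl_category_from_copies(data$vl_copies)
  } else {
    data$vl_category <- as_vl_category(data$vl_category)
  }
  if (all(c("weight", "height") %in% names(data)) &&
      !"bmi" %in% names(data)) {
    h <- ifelse(data$height > 3, data$height / 100, data$height)
    data$bmi <- data$weight / h^2
  }

  exclusions <- list()
  keep <- rep(TRUE, nrow(data))
  if ("art_drugs" %in% names(data)) {
    drop <- !is.na(data$art_drugs) & data$art_drugs < 3
    exclusions[["ART regimen with fewer than 3 drugs"]] <- sum(drop & keep)
    keep <- keep & !drop
  }
  drop <- is.na(data$age) | data$age <= 15
  exclusions[["age 15 years or younger"]] <- sum(drop & keep)
  keep <- keep & !drop
  if ("n_followup" %in% names(data)) {
    drop <- is.na(data$n_followup) | data$n_followup < 1
    exclusions[["no follow-up record"]] <- sum(drop & keep)
    keep <- keep & !drop
  }
  out <- data[keep, ]
  attr(out, "exclusions") <- tibble(
    criterion = names(exclusions),
    n_excluded = as.integer(unlist(exclusions, use.names = FALSE))
  )
  out
}

#' Run the full external-validation pipeline on a cohort
#'
#' Reproduces the published analysis flow: descriptive summaries (events,
#' person-years, exact Poisson mortality rate, reverse Kaplan-Meier median
#' follow-up, cumulative mortality at 3/5/10/15 years), then - under the
#' selected missing-data scenario - log-transformation of labs,
#' Nelson-Aalen outcome augmentation, chained-equation multiple imputation,
#' per-imputation scoring and metrics, Rubin pooling of Harrell's C (logit
#' scale), time-dependent C over a horizon grid (pooled as the
#' across-imputation mean), and calibration at 1/2/3 years against
#' imputation-averaged predictions.
#'
#' Scenarios: `"mi"` (multiple imputation, the main analysis;
#' collapses to m = 1 when the cohort is complete), `"complete-case"`
#' (drop records with any missing predictor), `"vl-low"` (missing viral
#' loads assumed < 200 copies/mL, remaining missing values imputed), and
#' `"vl-reference"` (missing viral loads drawn from
#' [wenzhou_vl_distribution()]).
#'
#' @param data Cohort data frame (e.g. from [ingest_cohort()] or
#'   [simulate_cohort()]).
#' @param params [model_params()] to validate.
#' @param m Number of imputations (study default 50).
#' @param seed Integer seed controlling imputation and bootstrap stages.
#' @param scenario Missing-data scenario, see Details.
#' @param horizons_td Horizon grid for the time-dependent C-statistic.
#' @param calib_horizons Calibration horizons (must be supported by
#'   `params$baseline_survival`).
#' @param n_bins Calibration bins.
#' @param boot Bootstrap replicates for the overall C-statistic per
#'   imputation.
#' @param maxit Chained-equation iterations.
#' @param extended Also validate the extended (age/gender) variant when the
#'   columns are present.
#' @param vl_reference_dist Reference distribution for the
#'   `"vl-reference"` scenario.
#' @return A list of class `validation_report` with elements `summary`,
#'   `followup`, `cumulative_mortality`, `concordance`, `timedep`,
#'   `calibration` (list of [calibration_table()]s), `calibration_summary`,
#'   `risk_groups` (when cutoffs are configured), `pi_distribution`, and
#'   `provenance`.
#' @export
run_validation <- function(data, params = wenzhou_params(), m = 50,
                           seed = 1,
                           scenario = c("mi", "complete-case", "vl-low",
                                        "vl-reference"),
                           horizons_td = c(0.5, 1:10),
                           calib_horizons = c(1, 2, 3), n_bins = 10,
                           boot = 200, maxit = 10, extended = TRUE,
                           vl_reference_dist = wenzhou_vl_distribution()) {
  scenario <- match.arg(scenario)
  data <- as_tibble(data)
  check_surv_cols(data, "time", "event")
  ev <- as_event01(data$event)
  predictor_cols <- c("cd4", "hemoglobin", "vl_category")
  extended <- extended && all(c("age", "gender") %in% names(data))

  summary_tbl <- tibble(
    n = nrow(data),
    n_events = sum(ev),
    died_pct = 100 * mean(ev),
    person_years = sum(data$time)
  )
  rate <- poisson_rate_ci(sum(ev), sum(data$time))
  followup <- median_followup(data)
  cum_mort <- suppressMessages(
    cumulative_mortality(data, horizons = c(3, 5, 10, 15))
  )

  work <- data
  if (scenario == "complete-case") {
    work <- work[complete.cases(work[predictor_cols]), ]
    if (nrow(work) == 0) abort("no complete cases")
  } else if (scenario == "vl-low") {
    work <- scenario_vl_all_low(work)
  } else if (scenario == "vl-reference") {
    work <- scenario_vl_reference(work, dist = vl_reference_dist,
                                  seed = seed + 1L)
  }

  any_missing <- anyNA(work[predictor_cols])
  m_eff <- if (any_missing) m else 1L
  logged <- log_transform_labs(work)
  log_vars <- attr(logged, "log_vars")
  imp <- chained_imputation(logged, m = m_eff, seed = seed, maxit = maxit)
  completed <- map(imp$cohorts, exp_transform_labs, vars = log_vars)

  variants <- c("original", if (extended) "extended")
  conc_rows <- list()
  for (v in variants) {
    res <- map(seq_along(completed), function(i) {
      scored <- score_cohort(completed[[i]], params, variant = v,
                             horizons = calib_horizons)
      harrell_c(scored, boot = boot, seed = seed + 1000L + i)
    })
    if (m_eff == 1) {
      r <- res[[1]]
      conc_rows[[v]] <- tibble(
        variant = v, estimate = r$estimate, ci_low = r$ci_low,
        ci_high = r$ci_high, se = r$se, m = 1L
      )
    } else {
      pooled <- pool_concordance(res)
      conc_rows[[v]] <- tibble(
        variant = v, estimate = pooled$estimate, ci_low = pooled$ci_low,
        ci_high = pooled$ci_high, se = sqrt(pooled$total_variance), m = m_eff
      )
    }
  }
  concordance <- list_rbind(conc_rows)

  scored_sets <- map(completed, function(co) {
    score_cohort(co, params, variant = "original", horizons = calib_horizons)
  })

  td <- map(scored_sets, function(sc) {
    suppressMessages(timedep_c_grid(sc, horizons = horizons_td))
  })
  td_est <- map(td, "estimate")
  timedep <- tibble(
    horizon = horizons_td,
    estimate = rowMeans(do.call(cbind, td_est), na.rm = FALSE)
  )
  if (extended) {
    td_ext <- map(completed, function(co) {
      sc <- score_cohort(co, params, variant = "extended",
                         horizons = calib_horizons)
      suppressMessages(timedep_c_grid(sc, horizons = horizons_td))$estimate
    })
    timedep$estimate_extended <- rowMeans(do.call(cbind, td_ext),
                                          na.rm = FALSE)
  }

  # imputation-averaged predictions per patient, then one calibration table
  calibration <- list()
  for (h in calib_horizons) {
    colname <- paste0("pred_surv_", h)
    pbar <- rowMeans(do.call(cbind, map(scored_sets, colname)))
    cal_df <- work
    cal_df[[colname]] <- pbar
    calibration[[as.character(h)]] <-
      calibration_table(cal_df, colname, horizon = h, n_bins = n_bins)
  }
  calibration_summary <- list_rbind(map(calibration, function(ct) {
    tibble(
      horizon = attr(ct, "horizon"),
      mean_difference = attr(ct, "mean_difference"),
      mean_difference_patient = attr(ct, "mean_difference_patient"),
      max_difference = attr(ct, "max_difference")
    )
  }))

  pi_bar <- rowMeans(do.call(cbind, map(scored_sets, "pi")))
  pi_hist <- graphics::hist(pi_bar, breaks = 30, plot = FALSE)
  pi_distribution <- tibble(
    mid = pi_hist$mids, count = pi_hist$counts
  )

  risk_groups <- NULL
  if (!is.null(params$risk_cutoffs)) {
    grp <- assign_risk_group(risk_score(pi_bar, params), params)
    risk_groups <- tibble(
      risk_group = levels(grp),
      n = as.integer(table(grp)),
      pct = 100 * as.integer(table(grp)) / length(grp)
    )
  }

  structure(
    list(
      summary = dplyr::bind_cols(summary_tbl, rate[c("rate", "ci_low",
                                                     "ci_high")]),
      followup = followup,
      cumulative_mortality = cum_mort,
      concordance = concordance,
      timedep = timedep,
      calibration = calibration,
      calibration_summary = calibration_summary,
      risk_groups = risk_groups,
      pi_distribution = pi_distribution,
      provenance = list(
        seed = seed, m = m_eff, scenario = scenario, n = nrow(work),
        boot = boot, maxit = maxit, n_bins = n_bins,
        config_hash = rlang::hash(list(params, m, seed, scenario, n_bins,
                                       boot, maxit, horizons_td,
                                       calib_horizons))
      )
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  s <- x$summary
  cat("<validation_report>\n")
  cat(sprintf("  n = %d, deaths = %d (%.2f%%), %.0f person-years\n",
              s$n, s$n_events, s$died_pct, s$person_years))
  cat(sprintf("  mortality rate %.2f (%.2f-%.2f) per 1000 PY\n",
              s$rate, s$ci_low, s$ci_high))
  med <- x$followup$time[x$followup$prob == 0.5]
  cat(sprintf("  median follow-up %.2f y\n", med))
  for (i in seq_len(nrow(x$concordance))) {
    r <- x$concordance[i, ]
    cat(sprintf("  Harrell's C (%s): %.3f (%.3f-%.3f)\n", r$variant,
                r$estimate, r$ci_low, r$ci_high))
  }
  cs <- x$calibration_summary
  cat("  calibration mean (obs - pred):",
      paste(sprintf("%+.4f @ %gy", cs$mean_difference, cs$horizon),
            collapse = ", "), "\n")
  cat(sprintf("  scenario %s, m = %d, seed = %d\n",
              x$provenance$scenario, x$provenance$m, x$provenance$seed))
  invisible(x)
}

#' Write and read a validation report
#'
#' `write_report()` serialises a report to machine-readable JSON (numbers at
#' full precision) or to a directory of delimited tables;
#' `read_report()` reads the JSON form back. The JSON round-trip preserves
#' numeric values to full double printing precision (15 significant digits).
#'
#' @param report A `validation_report`.
#' @param path Output file (JSON) or directory (delimited).
#' @param format `"json"` or `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "delimited")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      summary = report$summary,
      followup = report$followup,
      cumulative_mortality = report$cumulative_mortality,
      concordance = report$concordance,
      timedep = report$timedep,
      calibration = map(report$calibration, function(ct) {
        list(table = as_tibble(ct), horizon = attr(ct, "horizon"),
             mean_difference = attr(ct, "mean_difference"),
             mean_difference_patient = attr(ct, "mean_difference_patient"),
             max_difference = attr(ct, "max_difference"))
      }),
      calibration_summary = report$calibration_summary,
      risk_groups = report$risk_groups,
      pi_distribution = report$pi_distribution,
      provenance = report$provenance
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    readr::write_csv(report$summary, file.path(path, "summary.csv"))
    readr::write_csv(report$followup, file.path(path, "followup.csv"))
    readr::write_csv(report$cumulative_mortality,
                     file.path(path, "cumulative_mortality.csv"))
    readr::write_csv(report$concordance, file.path(path, "concordance.csv"))
    readr::write_csv(report$timedep, file.path(path, "timedep_c.csv"))
    readr::write_csv(report$calibration_summary,
                     file.path(path, "calibration_summary.csv"))
    for (h in names(report$calibration)) {
      readr::write_csv(as_tibble(report$calibration[[h]]),
                       file.path(path, sprintf("calibration_%sy.csv", h)))
    }
    if (!is.null(report$risk_groups)) {
      readr::write_csv(report$risk_groups, file.path(path, "risk_groups.csv"))
    }
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    summary = as_tibble(raw$summary),
    followup = as_tibble(raw$followup),
    cumulative_mortality = as_tibble(raw$cumulative_mortality),
    concordance = as_tibble(raw$concordance),
    timedep = as_tibble(raw$timedep),
    calibration = lapply(raw$calibration, function(ct) {
      tab <- as_tibble(ct$table)
      attr(tab, "horizon") <- ct$horizon
      attr(tab, "mean_difference") <- ct$mean_difference
      attr(tab, "mean_difference_patient") <- ct$mean_difference_patient
      attr(tab, "max_difference") <- ct$max_difference
      class(tab) <- c("calibration_table", class(tab))
      tab
    }),
    calibration_summary = as_tibble(raw$calibration_summary),
    risk_groups = if (is.null(raw$risk_groups)) NULL else
      as_tibble(raw$risk_groups),
    pi_distribution = as_tibble(raw$pi_distribution),
    provenance = raw$provenance
  )
  class(out) <- "validation_report"
  out
}

#' Display rounding used in reported tables
#'
#' Rates and percentages are displayed to two decimal places while stored
#' values keep full precision.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_rate <- function(x) {
  formatC(x, format = "f", digits = 2)
}
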