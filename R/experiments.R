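#' Simulation experiment: calibration bias from case-control model
#' development
#'
#' Replays, on synthetic cohorts with known truth, the consequence of
#' developing an absolute-risk model on an event-enriched matched
#' case-control sample without re-anchoring the baseline hazard. Two
#' development arms share the same development cohort: (a) a 1:`ratio`
#' matched nested case-control subsample (event fraction about
#' 1/(1+`ratio`)), and (b) a random subcohort of the same size. A
#' three-predictor hazards model is fitted in each arm as if the subsample
#' were a cohort, and its predictions are evaluated on an independently
#' generated population cohort. The case-control arm inflates the Breslow
#' baseline hazard, so predicted survival is too low and the calibration
#' mean difference (observed - predicted) is positive; the random arm is
#' unbiased.
#'
#' @param config A [cohort_config()] for both cohorts (the development
#'   cohort uses `config$n`, the validation cohort `n_validation`).
#' @param ratio Controls per case in the matched arm.
#' @param n_validation Size of the independent validation cohort.
#' @param horizon Calibration horizon in years.
#' @param n_bins Calibration bins.
#' @param seed Integer seed; development and validation cohorts use seeds
#'   derived from it, identical across arms except for the sampler.
#' @return A tibble of class `bias_experiment` with one row per arm:
#'   `arm`, `n_dev`, `events_dev`, `event_fraction_dev`, `mean_difference`,
#'   `max_difference`.
#' @export
experiment_case_control_bias <- function(config = cohort_config(n = 6000),
                                         ratio = 4, n_validation = 10000,
                                         horizon = 3, n_bins = 10,
                                         seed = 1) {
  dev <- simulate_cohort(config, seed = seed)
  val_config <- config
  val_config$n <- as.integer(n_validation)
  val <- simulate_cohort(val_config, seed = seed + 100003L)

  ncc <- nested_case_control_sample(dev, ratio = ratio, seed = seed + 7L)
  rnd_idx <- withr_free_sample(nrow(dev), nrow(ncc), seed = seed + 13L)
  rnd <- dev[rnd_idx, ]

  arm_row <- function(name, sub) {
    fit <- fit_proportional_hazards(sub)
    params <- ph_to_params(fit)
    scored <- score_cohort(val, params, horizons = horizon)
    cal <- calibration_table(scored, paste0("pred_surv_", horizon),
                             horizon = horizon, n_bins = n_bins)
    ev <- as_event01(sub$event)
    tibble(
      arm = name, n_dev = nrow(sub), events_dev = sum(ev),
      event_fraction_dev = mean(ev),
      mean_difference = attr(cal, "mean_difference"),
      max_difference = attr(cal, "max_difference")
    )
  }
  out <- bind_rows(
    arm_row("case_control", ncc),
    arm_row("random_subcohort", rnd)
  )
  attr(out, "seed") <- seed
  attr(out, "horizon") <- horizon
  class(out) <- c("bias_experiment", class(out))
  out
}

withr_free_sample <- function(n, size, seed) {
  set_seed_if(seed)
  sample.int(n, size)
}

#' Simulation experiment: added predictive value of matched-away covariates
#'
#' When the data-generating model carries real age and gender effects,
#' a model whose development matched on age and gender (and therefore
#' excluded them as predictors) discriminates worse than the same model
#' extended with those effects. This experiment generates a population
#' cohort with the configured age/gender effects, scores it with the
#' original (three-predictor) and extended linear predictors, and compares
#' Harrell's C.
#'
#' @param config A [cohort_config()]; its `ext_coef` should be nonzero for
#'   the experiment to carry signal. The default uses the published
#'   extension coefficients as the generating truth.
#' @param seed Integer seed.
#' @return A tibble of class `added_value_experiment` with rows for the
#'   original and extended models (`model`, `c_statistic`,
#'   `n_usable_pairs`) and attribute `c_difference` (extended - original).
#' @export
experiment_added_value <- function(config = cohort_config(
                                     n = 20000,
                                     ext_coef = c(age_mid = 0.2382292,
                                                  age_high = 0.5866749,
                                                  female = -0.3566749)),
                                   seed = 1) {
  cohort <- simulate_cohort(config, seed = seed)
  params <- generator_model_params(config)
  # the extension uses the literature coefficients (as a validator would),
  # whatever effects actually generated the data
  params$ext_coef_age_mid <- 0.2382292
  params$ext_coef_age_high <- 0.5866749
  params$ext_coef_female <- -0.3566749
  orig <- score_cohort(cohort, params, variant = "original")
  ext <- score_cohort(cohort, params, variant = "extended")
  c_orig <- harrell_c(orig, boot = 0)
  c_ext <- harrell_c(ext, boot = 0)
  out <- tibble(
    model = c("original", "extended"),
    c_statistic = c(c_orig$estimate, c_ext$estimate),
    n_usable_pairs = c(c_orig$n_usable_pairs, c_ext$n_usable_pairs)
  )
  attr(out, "c_difference") <- c_ext$estimate - c_orig$estimate
  attr(out, "seed") <- seed
  class(out) <- c("added_value_experiment", class(out))
  out
}
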