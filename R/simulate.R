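#' Configuration for the synthetic registry-like cohort generator
#'
#' Describes a cohort emulating a large ART-program registry: covariates
#' (CD4 and hemoglobin log-normal and moment-matched to the published
#' medians/IQRs, a three-level viral-load category, log-normal age truncated
#' above 15 years, gender), a proportional-hazards event-time model
#' \eqn{S(t \mid x) = S_0(t)^{\exp(\mathrm{PI}(x))}} with Weibull or
#' exponential baseline, and censoring from a calendar enrolment process
#' (administrative cut-off at the assessment date) plus an exponential
#' dropout hazard.
#'
#' Defaults reproduce the validation cohort's published profile: CD4 median
#' 209 (IQR 72-319) cells/uL, hemoglobin 137 (116-150) g/L, viral-load
#' categories 1.6/2.4/96.0% among observed values, age median 34.3 (IQR
#' 27.2-44.0), 81.5% male, enrolment-era shares 3.4/13.3/34.7/48.6% across
#' 2004-07/08-11/12-15/16-19, and a Weibull baseline (shape 0.75, declining
#' hazard) whose scale was calibrated once so that population 3-year
#' cumulative mortality is 3.72%.
#'
#' @param n Cohort size.
#' @param cd4_meanlog,cd4_sdlog,hb_meanlog,hb_sdlog,age_meanlog,age_sdlog
#'   Log-normal parameters of CD4, hemoglobin and age.
#' @param vl_probs Named probabilities of the viral-load categories.
#' @param p_male Proportion male.
#' @param coef Named true log-hazard coefficients `cd4`, `hb`, `vl_mid`,
#'   `vl_high`; defaults are the published model values.
#' @param ext_coef Named true `age_mid`, `age_high`, `female` effects
#'   (default 0: the three-predictor model generates the data).
#' @param baseline List: `family` (`"weibull"` or `"exponential"`) with
#'   `shape`/`scale`, or `rate` for the exponential; `rate = 0` means no
#'   events.
#' @param dropout_rate Exponential dropout hazard per year.
#' @param entry_probs Enrolment-era probabilities for the four calendar
#'   bands 2004-07, 2008-11, 2012-15, 2016-19.
#' @param assessment_year Administrative censoring date (calendar years).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 10000,
                          cd4_meanlog = log(209),
                          cd4_sdlog = (log(319) - log(72)) / (2 * qnorm(0.75)),
                          hb_meanlog = log(137),
                          hb_sdlog = (log(150) - log(116)) / (2 * qnorm(0.75)),
                          vl_probs = c(lt200 = 39, mid = 57,
                                       ge1000 = 2301) / 2397,
                          age_meanlog = log(34.3),
                          age_sdlog = (log(44) - log(27.2)) / (2 * qnorm(0.75)),
                          p_male = 0.815,
                          coef = c(cd4 = -0.005580907, hb = -0.005368102,
                                   vl_mid = 1.019669556,
                                   vl_high = 2.608969326),
                          ext_coef = c(age_mid = 0, age_high = 0, female = 0),
                          baseline = list(family = "weibull", shape = 0.75,
                                          scale = 652.9857386),
                          dropout_rate = 0.01,
                          entry_probs = c(0.034, 0.133, 0.347, 0.486),
                          assessment_year = 2020) {
  if (n < 1) abort("`n` must be at least 1")
  if (any(vl_probs < 0) || abs(sum(vl_probs) - 1) > 1e-9) {
    abort("`vl_probs` must be probabilities summing to 1")
  }
  if (abs(sum(entry_probs) - 1) > 1e-9) {
    abort("`entry_probs` must sum to 1")
  }
  fam <- baseline$family
  if (!fam %in% c("weibull", "exponential")) {
    abort("baseline family must be 'weibull' or 'exponential'")
  }
  if (fam == "weibull" && (baseline$shape <= 0 || baseline$scale <= 0)) {
    abort("Weibull baseline needs positive shape and scale")
  }
  if (fam == "exponential" && baseline$rate < 0) {
    abort("exponential baseline rate must be nonnegative")
  }
  if (dropout_rate < 0) abort("`dropout_rate` must be nonnegative")
  structure(
    list(n = as.integer(n), cd4_meanlog = cd4_meanlog, cd4_sdlog = cd4_sdlog,
         hb_meanlog = hb_meanlog, hb_sdlog = hb_sdlog, vl_probs = vl_probs,
         age_meanlog = age_meanlog, age_sdlog = age_sdlog, p_male = p_male,
         coef = coef, ext_coef = ext_coef, baseline = baseline,
         dropout_rate = dropout_rate, entry_probs = entry_probs,
         assessment_year = assessment_year),
    class = "cohort_config"
  )
}

#' Well-conditioned design for coefficient-recovery experiments
#'
#' A [cohort_config()] variant intended for checking that the hazards
#' fitter recovers generating coefficients, rather than for emulating the
#' registry: balanced viral-load mix (60/20/20%), a wider hemoglobin spread,
#' a higher exponential baseline hazard and no dropout, so that every
#' coefficient -- including the weakly identified hemoglobin effect -- is
#' estimated with adequate precision at moderate cohort sizes.
#'
#' @param n Cohort size.
#' @param rate Exponential baseline hazard per year.
#' @return A `cohort_config`.
#' @export
recovery_config <- function(n = 20000, rate = 0.15) {
  cohort_config(
    n = n,
    vl_probs = c(lt200 = 0.6, mid = 0.2, ge1000 = 0.2),
    hb_sdlog = 0.45,
    baseline = list(family = "exponential", rate = rate),
    dropout_rate = 0,
    entry_probs = c(0.25, 0.25, 0.25, 0.25)
  )
}

# baseline cumulative hazard H0(t) and its inverse, at PI = 0
baseline_cumhaz <- function(baseline, t) {
  if (baseline$family == "weibull") {
    (t / baseline$scale)^baseline$shape
  } else {
    baseline$rate * t
  }
}

baseline_cumhaz_inv <- function(baseline, h) {
  if (baseline$family == "weibull") {
    baseline$scale * h^(1 / baseline$shape)
  } else {
    if (baseline$rate == 0) rep(Inf, length(h)) else h / baseline$rate
  }
}

#' Model parameters implied by a generator configuration
#'
#' The true scoring model of a synthetic cohort: the configuration's
#' coefficients together with the generator's baseline survival
#' \eqn{S_0(t) = \exp(-H_0(t))} at 1, 2 and 3 years. Scoring a generated
#' cohort with these parameters reproduces the stored truth exactly.
#'
#' @param config A [cohort_config()].
#' @param horizons Horizons for the baseline-survival map.
#' @return A [model_params()] object.
#' @export
generator_model_params <- function(config, horizons = c(1, 2, 3)) {
  s0 <- exp(-baseline_cumhaz(config$baseline, horizons))
  model_params(
    coef_cd4 = unname(config$coef[["cd4"]]),
    coef_hb = unname(config$coef[["hb"]]),
    coef_vl_mid = unname(config$coef[["vl_mid"]]),
    coef_vl_high = unname(config$coef[["vl_high"]]),
    baseline_survival = setNames(s0, horizons),
    score_intercept = 108.3333333, score_slope = 19.90914787,
    ext_coef_age_mid = unname(config$ext_coef[["age_mid"]]),
    ext_coef_age_high = unname(config$ext_coef[["age_high"]]),
    ext_coef_female = unname(config$ext_coef[["female"]])
  )
}

#' Generate a synthetic cohort with known truth
#'
#' Draws covariates, event times from the configured proportional-hazards
#' model (by inverting \eqn{S(t \mid x) = \exp(-e^{\mathrm{PI}}H_0(t))}),
#' and censoring times from the enrolment process and dropout hazard. The
#' generating truth is retained per record: `true_pi` (the full generating
#' linear predictor, including any age/gender effects) and `true_surv_1/2/3`
#' (true survival probabilities at 1/2/3 years). Auxiliary labs (CD8, white
#' cells, platelets, creatinine) correlated with CD4 are included so that
#' imputation models have signal.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   exactly.
#' @return A tibble with columns `id`, `entry_year`, `age`, `gender`,
#'   `cd4`, `hemoglobin`, `vl_category`, `cd8`, `wbc`, `platelet`,
#'   `creatinine`, `time`, `event`, `true_pi`, `true_surv_1/2/3`; the
#'   configuration is attached as attribute `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config")
  set_seed_if(seed)
  n <- config$n
  cd4 <- rlnorm(n, config$cd4_meanlog, config$cd4_sdlog)
  hb <- rlnorm(n, config$hb_meanlog, config$hb_sdlog)
  vl <- factor(sample(vl_levels, n, replace = TRUE,
                      prob = config$vl_probs[vl_levels]),
               levels = vl_levels)
  # log-normal truncated below 16 (ingest excludes age <= 15); truncation
  # mass is ~1.6% so the median stays at the target
  p16 <- plnorm(16, config$age_meanlog, config$age_sdlog)
  age <- qlnorm(runif(n, p16, 1), config$age_meanlog, config$age_sdlog)
  age <- pmin(age, 95)
  gender <- ifelse(runif(n) < config$p_male, "male", "female")
  # auxiliary labs, correlated with CD4 on the log scale
  cd8 <- rlnorm(n, log(786) + 0.30 * (log(cd4) - config$cd4_meanlog), 0.45)
  wbc <- rlnorm(n, log(5.1) + 0.15 * (log(cd4) - config$cd4_meanlog), 0.30)
  platelet <- rlnorm(n, log(200) + 0.10 * (log(cd4) - config$cd4_meanlog),
                     0.28)
  creatinine <- rlnorm(n, log(74), 0.20)

  pi_true <- config$coef[["cd4"]] * cd4 + config$coef[["hb"]] * hb +
    config$coef[["vl_mid"]] * (vl == "mid") +
    config$coef[["vl_high"]] * (vl == "ge1000") +
    config$ext_coef[["age_mid"]] * (age >= 40 & age < 60) +
    config$ext_coef[["age_high"]] * (age >= 60) +
    config$ext_coef[["female"]] * (gender == "female")

  u <- runif(n)
  t_event <- baseline_cumhaz_inv(config$baseline, -log(u) / exp(pi_true))
  bands <- rbind(c(2004.1, 2008), c(2008, 2012), c(2012, 2016),
                 c(2016, config$assessment_year - 0.07))
  bi <- sample.int(4, n, replace = TRUE, prob = config$entry_probs)
  entry <- runif(n, bands[bi, 1], bands[bi, 2])
  admin <- config$assessment_year - entry
  dropout <- if (config$dropout_rate > 0) {
    rexp(n, config$dropout_rate)
  } else {
    rep(Inf, n)
  }
  cens <- pmin(admin, dropout)
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)

  s0 <- exp(-baseline_cumhaz(config$baseline, c(1, 2, 3)))
  out <- tibble(
    id = sprintf("S%06d", seq_len(n)),
    entry_year = entry, age = age, gender = gender,
    cd4 = cd4, hemoglobin = hb, vl_category = vl,
    cd8 = cd8, wbc = wbc, platelet = platelet, creatinine = creatinine,
    time = time, event = event,
    true_pi = pi_true,
    true_surv_1 = s0[1]^exp(pi_true),
    true_surv_2 = s0[2]^exp(pi_true),
    true_surv_3 = s0[3]^exp(pi_true)
  )
  attr(out, "config") <- config
  out
}

#' Mask covariates under a missing-at-random mechanism
#'
#' Sets covariate values to `NA` with a probability that depends on an
#' observed covariate (by default the enrolment year: earlier enrolment,
#' higher missingness, emulating limited early viral-load testing). The
#' intercept of the logistic missingness model is solved so that the
#' expected missing fraction equals `target`; the realised fraction then
#' concentrates around it.
#'
#' @param data Cohort data frame.
#' @param target Target missing fraction in \[0, 1\].
#' @param vars Columns to mask (default `vl_category`).
#' @param driver Observed numeric column driving missingness.
#' @param strength Log-odds change per standard deviation of the driver
#'   (negative: larger driver values, less missingness).
#' @param seed Optional integer seed.
#' @return The input as a tibble with masked values.
#' @export
impose_missingness <- function(data, target, vars = "vl_category",
                               driver = "entry_year", strength = -1.5,
                               seed = NULL) {
  if (target < 0 || target > 1) abort("`target` must be within [0, 1]")
  out <- as_tibble(data)
  if (target == 0) return(out)
  z <- out[[driver]]
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  lp <- strength * z # default negative: earlier enrolment, more missingness
  f <- function(a) mean(plogis(a + lp)) - target
  a <- uniroot(f, c(-50, 50))$root
  p_miss <- plogis(a + lp)
  set_seed_if(seed)
  for (v in vars) {
    mask <- runif(nrow(out)) < p_miss & !is.na(out[[v]])
    out[[v]][mask] <- NA
  }
  out
}

#' Nested case-control subsample with matching
#'
#' Retains every case (subject with an event) and matches `ratio` controls
#' per case without replacement from the non-cases, requiring exact
#' agreement on categorical matching variables and agreement within a
#' caliper on continuous ones (default: gender exact, age within +/- 5
#' years). Cases with no eligible control are dropped and reported.
#'
#' @param data Cohort data frame.
#' @param ratio Controls per case (>= 1).
#' @param match_vars Matching variables.
#' @param calipers Named calipers for continuous matching variables.
#' @param seed Optional integer seed.
#' @param time,event Follow-up time and event columns.
#' @return A tibble of matched cases and controls; attributes
#'   `n_cases_matched`, `n_cases_dropped`.
#' @export
nested_case_control_sample <- function(data, ratio = 4,
                                       match_vars = c("gender", "age"),
                                       calipers = c(age = 5), seed = NULL,
                                       time = "time", event = "event") {
  if (ratio < 1) abort("`ratio` must be at least 1")
  data <- as_tibble(data)
  ev <- as_event01(data[[event]])
  case_idx <- which(ev == 1L)
  if (length(case_idx) == 0) abort("no cases in the cohort")
  pool <- which(ev == 0L)
  set_seed_if(seed)
  available <- rep(TRUE, nrow(data))
  keep <- integer(0)
  dropped <- 0L
  for (i in sample(case_idx)) {
    elig <- pool[available[pool]]
    for (v in match_vars) {
      if (length(elig) == 0) break
      if (is.numeric(data[[v]]) && !is.null(calipers[[v]])) {
        elig <- elig[abs(data[[v]][elig] - data[[v]][i]) <= calipers[[v]]]
      } else {
        elig <- elig[data[[v]][elig] == data[[v]][i]]
      }
    }
    if (length(elig) == 0) {
      dropped <- dropped + 1L
      next
    }
    ctrl <- if (length(elig) <= ratio) elig else sample(elig, ratio)
    available[ctrl] <- FALSE
    keep <- c(keep, i, ctrl)
  }
  if (dropped > 0) {
    inform(sprintf("%d case(s) had no eligible matched control and were dropped",
                   dropped))
  }
  out <- data[sort(keep), ]
  attr(out, "n_cases_matched") <- length(case_idx) - dropped
  attr(out, "n_cases_dropped") <- dropped
  out
}

#' Fit a proportional-hazards model and extract a scoring model
#'
#' Cox partial-likelihood fit (Breslow tie handling) with the Breslow
#' baseline survival at 1/2/3 years, packaged so the result can score
#' cohorts through [score_cohort()]. When the covariates are the standard
#' predictor set (`cd4`, `hemoglobin`, `vl_category`), the fitted
#' coefficients map onto a [model_params()] object.
#'
#' @param data Cohort data frame.
#' @param covariates Character vector of covariate columns.
#' @param time,event Follow-up time and event columns.
#' @return A list of class `ph_fit` with elements `coefficients`,
#'   `baseline_survival` (named by horizon), `fit` (the underlying `coxph`
#'   object), `converged`.
#' @export
fit_proportional_hazards <- function(data, covariates = c("cd4", "hemoglobin",
                                                          "vl_category"),
                                     time = "time", event = "event") {
  data <- as_tibble(data)
  ev <- as_event01(data[[event]])
  if (sum(ev) < 1) abort("need at least one event to fit a hazards model")
  df <- data[covariates]
  df$.time <- data[[time]]
  df$.event <- ev
  fml <- as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  if (!is.null(fit$info) && any(grepl("infinite", fit$info))) {
    warn("possible separation in the hazards fit")
  }
  # Breslow baseline survival at the reference covariate values
  ref <- df[1, covariates, drop = FALSE]
  for (v in covariates) {
    x <- df[[v]]
    ref[[v]] <- if (is.numeric(x)) 0 else {
      lv <- levels(factor(x))
      factor(lv[1], levels = lv)
    }
  }
  sf <- survival::survfit(fit, newdata = ref, ctype = 1, stype = 2)
  horizons <- c(1, 2, 3)
  s0 <- vapply(horizons, function(h) {
    i <- which(sf$time <= h)
    if (length(i) == 0) 1 else sf$surv[max(i)]
  }, numeric(1))
  structure(
    list(coefficients = coef(fit),
         baseline_survival = setNames(s0, horizons),
         fit = fit,
         converged = fit$iter < fit$control$iter.max),
    class = "ph_fit"
  )
}

#' @export
print.ph_fit <- function(x, ...) {
  cat("<ph_fit> coefficients:\n")
  print(round(x$coefficients, 6))
  cat("baseline survival:",
      paste(sprintf("%s y = %.5f", names(x$baseline_survival),
                    x$baseline_survival), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a fitted hazards model to scoring parameters
#'
#' Maps a [fit_proportional_hazards()] result on the standard predictor set
#' to a [model_params()] object usable by [score_cohort()].
#'
#' @param fit A `ph_fit` object fitted with covariates `cd4`, `hemoglobin`,
#'   `vl_category`.
#' @return A [model_params()] object.
#' @export
ph_to_params <- function(fit) {
  co <- fit$coefficients
  need <- c("cd4", "hemoglobin", "vl_categorymid", "vl_categoryge1000")
  if (!all(need %in% names(co))) {
    abort("fit does not use the standard predictor set (cd4, hemoglobin, vl_category)")
  }
  model_params(
    coef_cd4 = unname(co[["cd4"]]),
    coef_hb = unname(co[["hemoglobin"]]),
    coef_vl_mid = unname(co[["vl_categorymid"]]),
    coef_vl_high = unname(co[["vl_categoryge1000"]]),
    baseline_survival = fit$baseline_survival,
    score_intercept = 108.3333333, score_slope = 19.90914787
  )
}
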