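#' Model parameters for a nomogram-derived proportional-hazards model
#'
#' Container for the coefficients, baseline survival probabilities, risk-score
#' mapping, extension coefficients and risk-group cutoffs of a
#' proportional-hazards prognostic model of the form
#' \eqn{S_i(t) = S_0(t)^{\exp(\mathrm{PI}_i)}}.
#'
#' @param coef_cd4 Log-hazard per CD4 cell/uL.
#' @param coef_hb Log-hazard per g/L hemoglobin.
#' @param coef_vl_mid Log-hazard for viral load in \[200, 1000) copies/mL
#'   versus < 200.
#' @param coef_vl_high Log-hazard for viral load >= 1000 copies/mL versus
#'   < 200.
#' @param baseline_survival Named numeric vector mapping horizon in years
#'   (names) to baseline survival \eqn{S_0(t)} in (0, 1); must be strictly
#'   decreasing in the horizon.
#' @param score_intercept,score_slope Affine mapping from prognostic index to
#'   nomogram risk score.
#' @param ext_coef_age_mid Extension coefficient for age in \[40, 60) years.
#' @param ext_coef_age_high Extension coefficient for age >= 60 years.
#' @param ext_coef_female Extension coefficient for female gender.
#' @param risk_cutoffs Two ascending risk-score thresholds separating
#'   low/intermediate/high groups, or `NULL` when unknown (the default;
#'   [assign_risk_group()] then fails fast).
#'
#' @return An object of class `model_params`.
#' @seealso [wenzhou_params()] for the published default values.
#' @export
model_params <- function(coef_cd4, coef_hb, coef_vl_mid, coef_vl_high,
                         baseline_survival,
                         score_intercept = NA_real_, score_slope = NA_real_,
                         ext_coef_age_mid = 0, ext_coef_age_high = 0,
                         ext_coef_female = 0,
                         risk_cutoffs = NULL) {
  s0 <- baseline_survival
  if (is.null(names(s0)) || anyNA(suppressWarnings(as.numeric(names(s0))))) {
    abort("`baseline_survival` must be named by horizon in years")
  }
  hz <- as.numeric(names(s0))
  s0 <- s0[order(hz)]
  hz <- sort(hz)
  if (any(s0 <= 0) || any(s0 >= 1)) {
    abort("baseline survival values must lie strictly in (0, 1)")
  }
  if (length(s0) > 1 && any(diff(s0) >= 0)) {
    abort("baseline survival must be strictly decreasing in the horizon")
  }
  if (!is.null(risk_cutoffs)) {
    if (length(risk_cutoffs) != 2 || diff(risk_cutoffs) <= 0) {
      abort("`risk_cutoffs` must be two ascending thresholds")
    }
  }
  structure(
    list(
      coef_cd4 = coef_cd4, coef_hb = coef_hb,
      coef_vl_mid = coef_vl_mid, coef_vl_high = coef_vl_high,
      baseline_survival = setNames(as.numeric(s0), hz),
      score_intercept = score_intercept, score_slope = score_slope,
      ext_coef_age_mid = ext_coef_age_mid,
      ext_coef_age_high = ext_coef_age_high,
      ext_coef_female = ext_coef_female,
      risk_cutoffs = risk_cutoffs
    ),
    class = "model_params"
  )
}

#' Published parameters of the Wenzhou HIV/AIDS prognostic model
#'
#' Returns the reconstructed parameters of the Wenzhou nomogram model for
#' survival of people living with HIV/AIDS on antiretroviral therapy: the
#' three-predictor coefficients (CD4 count, hemoglobin, HIV viral-load
#' category), baseline survival at 1/2/3 years, the linear prognostic-index to
#' risk-score mapping, and literature-based extension coefficients for age
#' band and gender. All values are stored at full published precision.
#'
#' The development study's risk-score thresholds for the low/intermediate/high
#' groups were not published; `risk_cutoffs` therefore defaults to `NULL` and
#' must be supplied before [assign_risk_group()] can be used.
#'
#' @inheritParams model_params
#' @return A [model_params()] object.
#' @examples
#' p <- wenzhou_params()
#' risk_score(0, p) # 108.3333333
#' predict_survival(0, 3, p) # 0.964896148
#' @export
wenzhou_params <- function(risk_cutoffs = NULL) {
  model_params(
    coef_cd4 = -0.005580907,
    coef_hb = -0.005368102,
    coef_vl_mid = 1.019669556,
    coef_vl_high = 2.608969326,
    baseline_survival = c(
      "1" = 0.980222074, "2" = 0.972736744, "3" = 0.964896148
    ),
    score_intercept = 108.3333333,
    score_slope = 19.90914787,
    ext_coef_age_mid = 0.2382292,
    ext_coef_age_high = 0.5866749,
    ext_coef_female = -0.3566749,
    risk_cutoffs = risk_cutoffs
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  PI = %.9f*cd4 + %.9f*hb + %.9f[VL mid] + %.9f[VL high]\n",
              x$coef_cd4, x$coef_hb, x$coef_vl_mid, x$coef_vl_high))
  cat("  S0:", paste(sprintf("%s y = %.9f", names(x$baseline_survival),
                             x$baseline_survival), collapse = ", "), "\n")
  cat(sprintf("  score = %.7f + %.8f * PI\n", x$score_intercept, x$score_slope))
  cat(sprintf("  extension: age 40-60 %+.7f, age >=60 %+.7f, female %+.7f\n",
              x$ext_coef_age_mid, x$ext_coef_age_high, x$ext_coef_female))
  if (is.null(x$risk_cutoffs)) {
    cat("  risk cutoffs: <unset>\n")
  } else {
    cat("  risk cutoffs:", paste(x$risk_cutoffs, collapse = ", "), "\n")
  }
  invisible(x)
}

vl_levels <- c("lt200", "mid", "ge1000")

#' Categorise HIV viral load in copies/mL
#'
#' Maps viral-load measurements to the model's three categories with
#' half-open boundaries \[0, 200), \[200, 1000), \[1000, Inf): exactly 1000
#' copies/mL falls in the high category.
#'
#' @param copies Numeric vector of copies/mL (`NA` allowed).
#' @return Factor with levels `lt200`, `mid`, `ge1000`.
#' @export
vl_category_from_copies <- function(copies) {
  if (any(copies < 0, na.rm = TRUE)) abort("viral load cannot be negative")
  out <- cut(copies, c(-Inf, 200, 1000, Inf), right = FALSE,
             labels = vl_levels)
  factor(as.character(out), levels = vl_levels)
}

as_vl_category <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) abort("viral load must be a category; see vl_category_from_copies()")
  bad <- !(x %in% vl_levels) & !is.na(x)
  if (any(bad)) {
    abort(sprintf("unknown viral-load category: %s",
                  paste(unique(x[bad]), collapse = ", ")))
  }
  factor(x, levels = vl_levels)
}

check_no_missing <- function(value, field) {
  if (anyNA(value)) {
    abort(sprintf(
      "cannot score records with missing '%s' (%d missing); impute or apply a scenario first",
      field, sum(is.na(value))
    ))
  }
  invisible(TRUE)
}

#' Prognostic index (linear predictor) of the three-predictor model
#'
#' Computes \eqn{\mathrm{PI}_i = \beta_{cd4}\,\mathrm{CD4}_i +
#' \beta_{hb}\,\mathrm{Hb}_i + \beta_{vl}} where the viral-load term is 0,
#' `coef_vl_mid` or `coef_vl_high` by category. Scoring never imputes: any
#' missing predictor raises an error naming the field.
#'
#' @param cd4 CD4 count, cells/uL.
#' @param hemoglobin Hemoglobin, g/L.
#' @param vl_category Viral-load category (`lt200`/`mid`/`ge1000`).
#' @param params A [model_params()] object.
#' @return Numeric vector of prognostic indices.
#' @export
prognostic_index <- function(cd4, hemoglobin, vl_category,
                             params = wenzhou_params()) {
  check_no_missing(cd4, "cd4")
  check_no_missing(hemoglobin, "hemoglobin")
  vl <- as_vl_category(vl_category)
  check_no_missing(vl, "vl_category")
  params$coef_cd4 * cd4 + params$coef_hb * hemoglobin +
    params$coef_vl_mid * (vl == "mid") +
    params$coef_vl_high * (vl == "ge1000")
}

#' Extension of a prognostic index with age-band and gender terms
#'
#' Adds the literature-based age band (\[40, 60) and \[60, Inf) versus < 40)
#' and female-gender terms to an existing prognostic index. Males under 40
#' are the reference and leave the index unchanged.
#'
#' @param pi_value Numeric prognostic index (original variant).
#' @param age Age in years.
#' @param gender `"male"` or `"female"`.
#' @inheritParams prognostic_index
#' @return Numeric vector of extended prognostic indices.
#' @export
extend_index <- function(pi_value, age, gender, params = wenzhou_params()) {
  check_no_missing(age, "age")
  check_no_missing(gender, "gender")
  gender <- as.character(gender)
  if (!all(gender %in% c("male", "female"))) {
    abort("`gender` must be 'male' or 'female'")
  }
  pi_value +
    params$ext_coef_age_mid * (age >= 40 & age < 60) +
    params$ext_coef_age_high * (age >= 60) +
    params$ext_coef_female * (gender == "female")
}

#' Predicted survival probability at a fixed horizon
#'
#' \eqn{\hat S_i(t) = \hat S_0(t)^{\exp(\mathrm{PI}_i)}}. Only horizons with a
#' published baseline survival are supported.
#'
#' @param pi_value Numeric prognostic index.
#' @param horizon Horizon in years; must be one of
#'   `names(params$baseline_survival)`.
#' @inheritParams prognostic_index
#' @return Survival probabilities in (0, 1).
#' @export
predict_survival <- function(pi_value, horizon, params = wenzhou_params()) {
  s0 <- params$baseline_survival
  key <- as.character(horizon)
  if (length(key) != 1 || !key %in% names(s0)) {
    abort(sprintf("unsupported horizon %s; supported horizons: %s years",
                  paste(horizon, collapse = ","),
                  paste(names(s0), collapse = ", ")))
  }
  unname(s0[[key]])^exp(pi_value)
}

#' Nomogram risk score from a prognostic index
#'
#' Affine mapping `score = intercept + slope * PI` as printed on the
#' nomogram; [index_from_score()] inverts it.
#'
#' @inheritParams predict_survival
#' @return Numeric risk scores (nomogram points).
#' @export
risk_score <- function(pi_value, params = wenzhou_params()) {
  if (any(!is.finite(pi_value))) abort("prognostic index must be finite")
  params$score_intercept + params$score_slope * pi_value
}

#' @rdname risk_score
#' @param score Numeric risk score.
#' @export
index_from_score <- function(score, params = wenzhou_params()) {
  (score - params$score_intercept) / params$score_slope
}

#' Risk-group assignment from a risk score
#'
#' Classifies scores as `low` (< first cutoff), `intermediate` (\[first,
#' second)) or `high` (>= second cutoff). Cutoffs are configuration: the
#' source publication references risk groups without printing the thresholds,
#' so this fails fast when `params$risk_cutoffs` is `NULL`.
#'
#' @inheritParams risk_score
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
assign_risk_group <- function(score, params = wenzhou_params()) {
  if (is.null(params$risk_cutoffs)) {
    abort(paste("risk-group cutoffs are not configured;",
                "supply `risk_cutoffs` to model_params()/wenzhou_params()"))
  }
  cut(score, c(-Inf, params$risk_cutoffs, Inf), right = FALSE,
      labels = c("low", "intermediate", "high"))
}

#' Score a cohort with a prognostic model
#'
#' Adds prognostic index, risk score, predicted survival at the supported
#' horizons and (when cutoffs are configured) risk group to a cohort table.
#'
#' @param data Cohort data frame with columns `cd4`, `hemoglobin`,
#'   `vl_category`, and for `variant = "extended"` also `age` and `gender`.
#' @param params A [model_params()] object.
#' @param variant `"original"` (three predictors) or `"extended"` (plus age
#'   band and gender).
#' @param horizons Horizons (years) at which to add predicted survival
#'   columns `pred_surv_<h>`; defaults to all supported horizons.
#' @return The input as a tibble with columns `pi`, `score`,
#'   `pred_surv_<h>`, and `risk_group` when cutoffs are configured.
#' @export
score_cohort <- function(data, params = wenzhou_params(),
                         variant = c("original", "extended"),
                         horizons = NULL) {
  variant <- match.arg(variant)
  horizons <- horizons %||% as.numeric(names(params$baseline_survival))
  pi_val <- prognostic_index(data$cd4, data$hemoglobin, data$vl_category,
                             params)
  if (variant == "extended") {
    pi_val <- extend_index(pi_val, data$age, data$gender, params)
  }
  out <- as_tibble(data)
  out$pi <- pi_val
  out$score <- risk_score(pi_val, params)
  for (h in horizons) {
    out[[paste0("pred_surv_", h)]] <- predict_survival(pi_val, h, params)
  }
  if (!is.null(params$risk_cutoffs)) {
    out$risk_group <- assign_risk_group(out$score, params)
  }
  out
}

#' Read and write model parameters as flat JSON
#'
#' Serialises a [model_params()] object to a flat key-value JSON file
#' (baseline survival stored as `s0_<horizon>` keys) so that alternative
#' nomogram extractions can be swapped in.
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @return `write_model_params()` returns `path` invisibly;
#'   `read_model_params()` returns a [model_params()] object.
#' @export
write_model_params <- function(params, path) {
  flat <- params[c("coef_cd4", "coef_hb", "coef_vl_mid", "coef_vl_high",
                   "score_intercept", "score_slope", "ext_coef_age_mid",
                   "ext_coef_age_high", "ext_coef_female")]
  for (h in names(params$baseline_survival)) {
    flat[[paste0("s0_", h)]] <- unname(params$baseline_survival[[h]])
  }
  if (!is.null(params$risk_cutoffs)) flat$risk_cutoffs <- params$risk_cutoffs
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  s0_keys <- grep("^s0_", names(flat), value = TRUE)
  s0 <- setNames(
    vapply(flat[s0_keys], as.numeric, numeric(1)),
    sub("^s0_", "", s0_keys)
  )
  model_params(
    coef_cd4 = flat$coef_cd4, coef_hb = flat$coef_hb,
    coef_vl_mid = flat$coef_vl_mid, coef_vl_high = flat$coef_vl_high,
    baseline_survival = s0,
    score_intercept = flat$score_intercept %||% NA_real_,
    score_slope = flat$score_slope %||% NA_real_,
    ext_coef_age_mid = flat$ext_coef_age_mid %||% 0,
    ext_coef_age_high = flat$ext_coef_age_high %||% 0,
    ext_coef_female = flat$ext_coef_female %||% 0,
    risk_cutoffs = flat$risk_cutoffs
  )
}
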