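default_lab_vars <- c(
  "cd4", "hemoglobin", "cd8", "wbc", "platelet", "creatinine",
  "triglyceride", "cholesterol", "glucose", "ast", "alt", "bilirubin"
)

#' Log-transform laboratory measurements
#'
#' Laboratory indexes are positive and right-skewed; imputation models work
#' on the natural-log scale. [exp_transform_labs()] inverts the transform
#' (round-trips to better than 1e-12).
#'
#' @param data Cohort data frame.
#' @param vars Lab columns to transform; defaults to the intersection of the
#'   standard lab set (`cd4`, `hemoglobin`, `cd8`, `wbc`, `platelet`,
#'   `creatinine`, ...) with the columns present.
#' @return The input as a tibble with transformed columns; the set of
#'   transformed columns is recorded in attribute `log_vars`.
#' @export
log_transform_labs <- function(data, vars = NULL) {
  vars <- vars %||% intersect(default_lab_vars, names(data))
  out <- as_tibble(data)
  for (v in vars) {
    x <- out[[v]]
    if (any(x <= 0, na.rm = TRUE)) {
      abort(sprintf("nonpositive value in lab column '%s'; cannot log-transform", v))
    }
    out[[v]] <- log(x)
  }
  attr(out, "log_vars") <- vars
  out
}

#' @rdname log_transform_labs
#' @export
exp_transform_labs <- function(data, vars = NULL) {
  vars <- vars %||% attr(data, "log_vars") %||%
    intersect(default_lab_vars, names(data))
  out <- as_tibble(data)
  for (v in vars) out[[v]] <- exp(out[[v]])
  attr(out, "log_vars") <- NULL
  out
}

#' Multiple imputation by chained equations
#'
#' Generates `m` completed copies of a cohort by iterated univariate
#' imputation: continuous variables by predictive-mean matching against a
#' Bayesian linear-model draw (donor pool of `donors` nearest predicted
#' means), categorical variables by a draw from multinomial-regression
#' predicted probabilities. Following standard practice for censored
#' outcomes, the Nelson-Aalen cumulative hazard at each subject's follow-up
#' time and the event indicator are appended to the predictor set before
#' imputation (and dropped from the returned cohorts if they were absent
#' from the input).
#'
#' Observed values are never altered; constant predictor columns are dropped
#' with a notice; a fully missing column is an error. With no missing values
#' the input is returned unchanged `m` times.
#'
#' @param data Cohort data frame.
#' @param m Number of completed datasets (the study default is 50).
#' @param seed Integer seed; the whole procedure is reproducible from it.
#' @param maxit Chained-equation iterations per dataset (default 10).
#' @param donors Donor-pool size for predictive-mean matching (default 5).
#' @param impute_vars Columns to impute; defaults to all columns with
#'   missing values except identifiers, outcome columns and generator truth
#'   columns.
#' @param predictors Columns used as predictors; defaults to all candidate
#'   covariates plus the appended Nelson-Aalen hazard and event indicator.
#' @param time,event Follow-up time and event columns.
#' @return An `imputed_cohort_set`: list with `cohorts` (list of `m`
#'   complete tibbles), `m`, `seed`, `methods` (named character vector of
#'   per-variable methods), and `audit` (per-variable missing counts).
#' @export
chained_imputation <- function(data, m = 50, seed = NULL, maxit = 10,
                               donors = 5, impute_vars = NULL,
                               predictors = NULL,
                               time = "time", event = "event") {
  data <- as_tibble(data)
  reserved <- c("id", time, event, "na_cumhaz",
                grep("^(true_|pred_surv_)", names(data), value = TRUE),
                "pi", "score", "risk_group")
  candidates <- setdiff(names(data), reserved)
  impute_vars <- impute_vars %||%
    candidates[vapply(data[candidates], anyNA, logical(1))]
  fully_missing <- impute_vars[vapply(data[impute_vars],
                                      function(x) all(is.na(x)), logical(1))]
  if (length(fully_missing) > 0) {
    abort(sprintf("column(s) with zero observed values cannot be imputed: %s",
                  paste(fully_missing, collapse = ", ")))
  }
  audit <- tibble(
    variable = impute_vars,
    n_missing_before = unname(vapply(data[impute_vars],
                                     function(x) sum(is.na(x)), integer(1)))
  )
  if (length(impute_vars) == 0) {
    return(structure(
      list(cohorts = rep(list(data), m), m = m, seed = seed,
           methods = character(0), audit = audit),
      class = "imputed_cohort_set"
    ))
  }

  had_na_col <- "na_cumhaz" %in% names(data)
  work <- if (had_na_col) data else add_nelson_aalen(data, time, event)
  work[[".event01"]] <- as_event01(work[[event]])
  predictors <- predictors %||%
    unique(c(candidates, "na_cumhaz", ".event01"))
  predictors <- intersect(predictors, names(work))
  # predictors outside the imputed set must be complete, else the design
  # matrix would silently drop rows
  incomplete <- setdiff(
    predictors[vapply(work[predictors], anyNA, logical(1))], impute_vars
  )
  if (length(incomplete) > 0) {
    inform(sprintf("incomplete non-imputed column(s) dropped from predictors: %s",
                   paste(incomplete, collapse = ", ")))
    predictors <- setdiff(predictors, incomplete)
  }

  # drop constant predictors (degenerate columns break the design matrix)
  const <- predictors[vapply(work[predictors], function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) < 2
  }, logical(1))]
  const <- setdiff(const, impute_vars)
  if (length(const) > 0) {
    inform(sprintf("constant column(s) dropped from imputation predictors: %s",
                   paste(const, collapse = ", ")))
    predictors <- setdiff(predictors, const)
  }

  methods <- vapply(impute_vars, function(v) {
    if (is.numeric(work[[v]])) "pmm" else "multinom"
  }, character(1))

  set_seed_if(seed)
  miss_idx <- lapply(work[impute_vars], function(x) which(is.na(x)))
  cohorts <- map(seq_len(m), function(chain) {
    cur <- work
    # initial fill: random draw from observed values
    for (v in impute_vars) {
      obs <- cur[[v]][!is.na(cur[[v]])]
      cur[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                        replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in impute_vars) {
        mis <- miss_idx[[v]]
        if (length(mis) == 0) next
        rhs <- setdiff(predictors, v)
        x_all <- model.matrix(
          ~ ., data = cur[rhs]
        )
        # drop aliased columns so the normal equations are full rank
        qr_x <- qr(x_all[-mis, , drop = FALSE])
        keep <- qr_x$pivot[seq_len(qr_x$rank)]
        x_all <- x_all[, sort(keep), drop = FALSE]
        if (methods[[v]] == "pmm") {
          cur[[v]][mis] <- impute_pmm(
            y_obs = work[[v]][-mis],
            x_obs = x_all[-mis, , drop = FALSE],
            x_mis = x_all[mis, , drop = FALSE],
            donors = donors
          )
        } else {
          cur[[v]][mis] <- impute_multinom(
            y = cur[[v]], obs = setdiff(seq_len(nrow(cur)), mis),
            df = cur[rhs], mis = mis, work_y = work[[v]]
          )
        }
      }
    }
    if (!had_na_col) cur$na_cumhaz <- NULL
    cur$.event01 <- NULL
    cur
  })
  structure(
    list(cohorts = cohorts, m = m, seed = seed, methods = methods,
         audit = audit),
    class = "imputed_cohort_set"
  )
}

# Bayesian linear regression draw + type-1 predictive-mean matching
impute_pmm <- function(y_obs, x_obs, x_mis, donors) {
  n <- length(y_obs)
  p <- ncol(x_obs)
  xtx <- crossprod(x_obs)
  ridge <- diag(p) * max(diag(xtx)) * 1e-8
  v <- solve(xtx + ridge)
  beta_hat <- v %*% crossprod(x_obs, y_obs)
  res <- y_obs - x_obs %*% beta_hat
  df <- max(n - p, 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  beta_star <- beta_hat +
    t(chol((v + t(v)) / 2 * sigma2)) %*% rnorm(p)
  yhat_obs <- drop(x_obs %*% beta_hat)
  yhat_mis <- drop(x_mis %*% beta_star)
  # match each missing prediction to its `donors` nearest observed
  # predictions and draw one donor's observed value
  o <- order(yhat_obs)
  srt <- yhat_obs[o]
  y_srt <- y_obs[o]
  vapply(yhat_mis, function(yh) {
    pos <- findInterval(yh, srt)
    lo <- max(1, pos - donors)
    hi <- min(n, pos + donors)
    cand <- lo:hi
    d <- abs(srt[cand] - yh)
    pool <- cand[order(d)][seq_len(min(donors, length(cand)))]
    y_srt[sample(pool, 1)]
  }, numeric(1))
}

# multinomial-scoring draw: fit on observed rows, draw categories from
# predicted probabilities for the missing rows
impute_multinom <- function(y, obs, df, mis, work_y) {
  lv <- levels(factor(work_y))
  fit_df <- df
  fit_df$.y <- factor(as.character(y), levels = lv)
  obs_real <- obs[!is.na(work_y[obs])]
  fit <- nnet::multinom(.y ~ ., data = fit_df[obs_real, , drop = FALSE],
                        trace = FALSE, maxit = 200)
  pr <- predict(fit, newdata = fit_df[mis, , drop = FALSE], type = "probs")
  if (is.null(dim(pr))) {
    if (length(lv) == 2) {
      pr <- cbind(1 - pr, pr)
    } else {
      pr <- matrix(pr, nrow = 1)
    }
  }
  cls <- colnames(pr) %||% lv
  drawn <- apply(pr, 1, function(p) sample(cls, 1, prob = p))
  factor(drawn, levels = lv)
}

#' @export
print.imputed_cohort_set <- function(x, ...) {
  cat(sprintf("<imputed_cohort_set> m = %d, seed = %s\n", x$m,
              x$seed %||% "NULL"))
  if (length(x$methods) > 0) {
    cat("  methods:", paste(names(x$methods), x$methods, sep = "=",
                            collapse = ", "), "\n")
  } else {
    cat("  no missing values; copies of the input\n")
  }
  invisible(x)
}

#' Write the imputation audit log
#'
#' Per-variable missing counts before imputation (all are zero after, by
#' construction), as tab-delimited text.
#'
#' @param set An `imputed_cohort_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_imputation_audit <- function(set, path) {
  audit <- set$audit
  audit$n_missing_after <- 0L
  readr::write_tsv(audit, path)
  invisible(path)
}

#' Sensitivity scenario: all missing viral loads set to the lowest category
#'
#' Implements the assumption that every missing HIV viral load was < 200
#' copies/mL. Observed categories are untouched.
#'
#' @param data Cohort data frame with a `vl_category` column.
#' @return The input as a tibble with no missing `vl_category`.
#' @export
scenario_vl_all_low <- function(data) {
  out <- as_tibble(data)
  vl <- as_vl_category(out$vl_category)
  vl[is.na(vl)] <- "lt200"
  out$vl_category <- vl
  out
}

#' Viral-load category distribution of the model's derivation cohort
#'
#' The published derivation-cohort distribution over `lt200`/`mid`/`ge1000`
#' (78.7% / 3.0% / 18.3%), used by the reference-distribution sensitivity
#' scenario.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
wenzhou_vl_distribution <- function() {
  c(lt200 = 0.787, mid = 0.030, ge1000 = 0.183)
}

#' Sensitivity scenario: missing viral loads drawn from a reference
#' distribution
#'
#' Fills missing viral-load categories with independent draws from `dist`,
#' so the empirical distribution of the filled values converges to `dist` as
#' the number of missing entries grows. Observed categories are untouched.
#'
#' @inheritParams scenario_vl_all_low
#' @param dist Named probability vector over `lt200`, `mid`, `ge1000`
#'   summing to 1 (default [wenzhou_vl_distribution()]).
#' @param seed Optional integer seed.
#' @return The input as a tibble with no missing `vl_category`.
#' @export
scenario_vl_reference <- function(data, dist = wenzhou_vl_distribution(),
                                  seed = NULL) {
  if (!all(sort(names(dist)) == sort(vl_levels)) ||
      any(dist < 0) || abs(sum(dist) - 1) > 1e-9) {
    abort("`dist` must be nonnegative probabilities over lt200/mid/ge1000 summing to 1")
  }
  out <- as_tibble(data)
  vl <- as_vl_category(out$vl_category)
  mis <- which(is.na(vl))
  set_seed_if(seed)
  vl[mis] <- sample(vl_levels, length(mis), replace = TRUE,
                    prob = dist[vl_levels])
  out$vl_category <- vl
  out
}
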