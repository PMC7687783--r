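test_that("nested case-control sampling fixes the event fraction by design", {
  cfg <- cohort_config(n = 4000)
  co <- simulate_cohort(cfg, seed = 15)
  sub <- nested_case_control_sample(co, ratio = 4, seed = 16)
  n_cases <- sum(co$event)
  expect_equal(attr(sub, "n_cases_matched") + attr(sub, "n_cases_dropped"),
               n_cases)
  # ample controls: every case gets its full set of 4
  expect_equal(attr(sub, "n_cases_dropped"), 0)
  expect_equal(mean(as_tibble(sub)$event), 1 / 5, tolerance = 1e-12)
  # matching on gender: case and control gender distributions identical
  s <- as_tibble(sub)
  expect_equal(prop.table(table(s$gender[s$event == 1])),
               prop.table(table(s$gender[s$event == 0])), tolerance = 1e-12)
  # age caliper respected for every matched control set is implied by the
  # matched construction; check the marginal shift is small
  expect_lt(abs(median(s$age[s$event == 1]) - median(s$age[s$event == 0])), 5)
})

test_that("a zero caliper on a continuous variable matches nothing", {
  co <- simulate_cohort(cohort_config(n = 300), seed = 17)
  expect_message(
    sub <- nested_case_control_sample(co, ratio = 2, calipers = c(age = 0),
                                      seed = 18),
    "dropped"
  )
  expect_equal(attr(sub, "n_cases_dropped"), sum(co$event))
  expect_equal(nrow(sub), 0)
})

test_that("a caseless cohort cannot be sampled", {
  co <- simulate_cohort(cohort_config(n = 50,
                                      baseline = list(family = "exponential",
                                                      rate = 0),
                                      dropout_rate = 0), seed = 1)
  expect_error(nested_case_control_sample(co), "no cases")
})

test_that("the hazards fitter maximises the Breslow partial likelihood", {
  # single binary covariate, no tied times: compare against a grid search
  set.seed(55)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  tm <- round(rexp(n, 0.2 * exp(0.8 * x)), 6)
  d <- tibble::tibble(time = tm, event = 1L, x = x)
  fit <- fit_proportional_hazards(d, covariates = "x")
  grid <- seq(-1, 3, by = 1e-4)
  ll <- vapply(grid, oracle_partial_loglik, numeric(1),
               time = d$time, event = d$event, x = d$x)
  expect_equal(unname(fit$coefficients), grid[which.max(ll)],
               tolerance = 2.5e-4)
})

test_that("a covariate unrelated to the outcome gets a near-zero coefficient", {
  set.seed(56)
  n <- 2000
  d <- tibble::tibble(
    time = rexp(n, 0.3),
    event = 1L,
    x = rnorm(n)
  )
  fit <- fit_proportional_hazards(d, covariates = "x")
  se <- sqrt(diag(vcov(fit$fit)))
  expect_lt(abs(fit$coefficients[["x"]]), 3 * se)
})

test_that("the fitted model converts to scoring parameters on the standard predictors", {
  co <- simulate_cohort(recovery_config(n = 4000), seed = 57)
  fit <- fit_proportional_hazards(co)
  params <- ph_to_params(fit)
  expect_s3_class(params, "model_params")
  expect_equal(unname(params$coef_cd4), unname(fit$coefficients[["cd4"]]))
  sc <- score_cohort(co, params)
  # extreme low-risk outliers can push exp(PI) to ~0 and the prediction to 1
  expect_true(all(sc$pred_surv_3 > 0 & sc$pred_surv_3 <= 1))
  # baseline survival decreasing over horizons
  expect_true(all(diff(params$baseline_survival) < 0))
  fit2 <- fit_proportional_hazards(co, covariates = c("cd4", "hemoglobin"))
  expect_error(ph_to_params(fit2), "standard predictor set")
})

test_that("coefficient bias shrinks as the cohort grows", {
  truth <- c(-0.005580907, -0.005368102, 1.019669556, 2.608969326)
  err_at <- function(n) {
    errs <- vapply(1:3, function(s) {
      co <- simulate_cohort(recovery_config(n = n), seed = 700 + s)
      fit <- fit_proportional_hazards(co)
      sqrt(mean(((fit$coefficients - truth) / truth)^2))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(16000), err_at(1000))
})

test_that("fitting demands at least one event", {
  d <- tibble::tibble(time = 1:5, event = 0L, cd4 = rnorm(5))
  expect_error(fit_proportional_hazards(d, covariates = "cd4"), "event")
})
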