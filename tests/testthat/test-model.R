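test_that("prognostic index reproduces the published arithmetic", {
  p <- wenzhou_params()
  # all terms vanish at the reference category
  expect_identical(prognostic_index(0, 0, "lt200", p), 0)
  # high viral load alone contributes its coefficient
  expect_equal(prognostic_index(0, 0, "ge1000", p), 2.608969326)
  expect_equal(prognostic_index(0, 0, "mid", p), 1.019669556)
  # derivation-cohort median patient
  expect_equal(prognostic_index(208.3, 136.7, "lt200", p),
               -0.005580907 * 208.3 - 0.005368102 * 136.7,
               tolerance = 1e-12)
  expect_equal(prognostic_index(208.3, 136.7, "lt200", p), -1.8963225,
               tolerance = 1e-7)
})

test_that("extended index adds age-band and gender terms over a male-under-40 reference", {
  p <- wenzhou_params()
  expect_identical(extend_index(-1.23, age = 30, gender = "male", p), -1.23)
  expect_equal(extend_index(0, age = 65, gender = "female", p), 0.23,
               tolerance = 1e-12)
  expect_equal(extend_index(-1, age = 45, gender = "male", p), -0.7617708,
               tolerance = 1e-12)
  # half-open band edges
  expect_equal(extend_index(0, 40, "male", p), 0.2382292)
  expect_equal(extend_index(0, 60, "male", p), 0.5866749)
  expect_equal(extend_index(0, 39.999, "male", p), 0)
})

test_that("survival predictions exponentiate the baseline survival", {
  p <- wenzhou_params()
  expect_equal(predict_survival(0, 3, p), 0.964896148)
  expect_equal(predict_survival(0, 1, p), 0.980222074)
  expect_equal(predict_survival(0, 2, p), 0.972736744)
  expect_equal(predict_survival(2.608969326, 1, p), 0.7623294,
               tolerance = 1e-7)
  # monotone decreasing in PI at every horizon, and equal to S0 at PI = 0
  pis <- seq(-3, 4, by = 0.5)
  for (h in 1:3) {
    s <- predict_survival(pis, h, p)
    expect_true(all(diff(s) < 0))
    expect_true(all(s > 0 & s < 1))
  }
  # decreasing in horizon for a fixed patient
  s_by_h <- vapply(1:3, function(h) predict_survival(0.7, h, p), numeric(1))
  expect_true(all(diff(s_by_h) < 0))
})

test_that("risk-score mapping matches the nomogram line and inverts to 1e-9", {
  p <- wenzhou_params()
  expect_equal(risk_score(0, p), 108.3333333)
  expect_equal(risk_score(2, p) - risk_score(1, p), 19.90914787)
  expect_equal(risk_score(-1.8963225, p), 70.579, tolerance = 1e-4)
  pis <- runif(50, -4, 4)
  expect_equal(index_from_score(risk_score(pis, p), p), pis,
               tolerance = 1e-9)
  expect_error(risk_score(Inf, p), "finite")
})

test_that("viral-load categorisation uses half-open boundaries", {
  expect_equal(as.character(vl_category_from_copies(c(0, 199.99, 200, 999.9, 1000, 1e6))),
               c("lt200", "lt200", "mid", "mid", "ge1000", "ge1000"))
  expect_true(is.na(vl_category_from_copies(NA_real_)))
  expect_error(vl_category_from_copies(-5), "negative")
})

test_that("scoring refuses to run with missing predictors, naming the field", {
  p <- wenzhou_params()
  expect_error(prognostic_index(NA, 100, "lt200", p), "cd4")
  expect_error(prognostic_index(100, NA, "lt200", p), "hemoglobin")
  expect_error(prognostic_index(100, 100, NA, p), "vl_category")
  expect_error(extend_index(0, NA, "male", p), "age")
  expect_error(extend_index(0, 30, NA, p), "gender")
})

test_that("unsupported horizons are rejected with the supported list", {
  p <- wenzhou_params()
  expect_error(predict_survival(0, 5, p), "1, 2, 3")
})

test_that("risk groups need configured cutoffs and respect the half-open convention", {
  expect_error(assign_risk_group(100, wenzhou_params()), "cutoffs")
  p <- wenzhou_params(risk_cutoffs = c(90, 120))
  expect_equal(as.character(assign_risk_group(c(89.9, 90, 119.9, 120), p)),
               c("low", "intermediate", "intermediate", "high"))
  sc <- sort(runif(100, 50, 160))
  grp <- as.integer(assign_risk_group(sc, p))
  expect_true(all(diff(grp) >= 0))
})

test_that("score_cohort attaches index, score and predictions; extended equals original for reference patients", {
  p <- wenzhou_params()
  co <- tibble::tibble(
    cd4 = c(100, 350), hemoglobin = c(120, 140),
    vl_category = c("ge1000", "lt200"),
    age = c(35, 30), gender = c("male", "male"),
    time = c(2, 4), event = c(1, 0)
  )
  orig <- score_cohort(co, p)
  ext <- score_cohort(co, p, variant = "extended")
  expect_equal(orig$pi, ext$pi)
  expect_named(orig, c(names(co), "pi", "score", "pred_surv_1",
                       "pred_surv_2", "pred_surv_3"))
  expect_equal(orig$pred_surv_3, predict_survival(orig$pi, 3, p))
})

test_that("model parameters survive a JSON round-trip", {
  p <- wenzhou_params(risk_cutoffs = c(95, 125))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_params(p, path)
  q <- read_model_params(path)
  expect_equal(q$coef_cd4, p$coef_cd4, tolerance = 1e-15)
  expect_equal(q$baseline_survival, p$baseline_survival, tolerance = 1e-15)
  expect_equal(q$risk_cutoffs, p$risk_cutoffs)
  expect_equal(q$ext_coef_female, p$ext_coef_female)
})

test_that("degenerate baseline-survival maps are rejected", {
  expect_error(model_params(0, 0, 0, 0,
                            baseline_survival = c("1" = 0.9, "2" = 0.95)),
               "decreasing")
  expect_error(model_params(0, 0, 0, 0, baseline_survival = c("1" = 1.2)),
               "0, 1")
})
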