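small_mar_cohort <- function(n = 400, seed = 1, mask_cd4 = 0.3) {
  co <- simulate_cohort(cohort_config(n = n), seed = seed)
  # MAR: mask CD4 depending on the observed enrolment year
  impose_missingness(co, target = mask_cd4, vars = "cd4", seed = seed + 1)
}

test_that("log transform of labs round-trips and rejects nonpositive values", {
  d <- tibble::tibble(cd4 = c(1, exp(1)), hemoglobin = c(100, 150),
                      other = c(-5, 2))
  lg <- log_transform_labs(d)
  expect_equal(lg$cd4, c(0, 1))
  expect_false("other" %in% attr(lg, "log_vars"))
  set.seed(3)
  d2 <- tibble::tibble(cd4 = rlnorm(50, 5, 1), hemoglobin = rlnorm(50, 4.9, 0.2))
  expect_equal(exp_transform_labs(log_transform_labs(d2)), d2,
               tolerance = 1e-12)
  d2$cd4[1] <- 0
  expect_error(log_transform_labs(d2), "cd4")
})

test_that("a complete cohort passes through imputation untouched", {
  co <- simulate_cohort(cohort_config(n = 120), seed = 5)
  imp <- chained_imputation(co, m = 3, seed = 9)
  expect_equal(imp$m, 3)
  expect_length(imp$cohorts, 3)
  expect_identical(imp$cohorts[[1]], imp$cohorts[[3]])
  expect_equal(as.data.frame(imp$cohorts[[2]]), as.data.frame(co))
})

test_that("imputation fills every hole, never touches observed cells, and is seeded", {
  co <- small_mar_cohort(n = 300, seed = 2)
  co$vl_category[c(3, 10)] <- NA
  obs_cd4 <- which(!is.na(co$cd4))
  imp1 <- chained_imputation(co, m = 2, seed = 77, maxit = 3)
  imp2 <- chained_imputation(co, m = 2, seed = 77, maxit = 3)
  expect_identical(imp1$cohorts, imp2$cohorts)
  for (k in 1:2) {
    comp <- imp1$cohorts[[k]]
    expect_false(anyNA(comp$cd4))
    expect_false(anyNA(comp$vl_category))
    expect_identical(comp$cd4[obs_cd4], co$cd4[obs_cd4])
    expect_identical(comp$hemoglobin, co$hemoglobin)
  }
  # the two completed copies differ where values were imputed
  expect_false(identical(imp1$cohorts[[1]]$cd4, imp1$cohorts[[2]]$cd4))
  expect_equal(imp1$methods[["cd4"]], "pmm")
  expect_equal(imp1$methods[["vl_category"]], "multinom")
})

test_that("imputed CD4 under MAR recovers the generating distribution", {
  co <- simulate_cohort(cohort_config(n = 2500), seed = 31)
  true_mean <- mean(log(co$cd4))
  masked <- impose_missingness(co, target = 0.35, vars = "cd4", seed = 32)
  lg <- log_transform_labs(masked)
  imp <- chained_imputation(lg, m = 5, seed = 33, maxit = 5)
  imp_means <- vapply(imp$cohorts, function(d) mean(d$cd4), numeric(1))
  # PMM draws should reproduce the complete-data mean within a few percent
  expect_equal(mean(imp_means), true_mean, tolerance = 0.03)
})

test_that("degenerate imputation inputs are handled", {
  co <- small_mar_cohort(n = 150, seed = 4)
  co$allmiss <- NA_real_
  expect_error(chained_imputation(co, m = 1, seed = 1), "allmiss")
  co$allmiss <- NULL
  co$constant <- 1
  expect_message(imp <- chained_imputation(co, m = 1, seed = 1, maxit = 2),
                 "constant")
  expect_false(anyNA(imp$cohorts[[1]]$cd4))
})

test_that("the audit log records missingness and writes as TSV", {
  co <- small_mar_cohort(n = 200, seed = 6)
  imp <- chained_imputation(co, m = 1, seed = 2, maxit = 2)
  audit <- tidy(imp)
  expect_equal(audit$n_missing_before[audit$variable == "cd4"],
               sum(is.na(co$cd4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_imputation_audit(imp, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$n_missing_after, rep(0, nrow(back)))
})

test_that("the all-low scenario fills every missing viral load with lt200", {
  co <- simulate_cohort(cohort_config(n = 200), seed = 8)
  expect_equal(scenario_vl_all_low(co)$vl_category, co$vl_category)
  masked <- impose_missingness(co, target = 0.6, seed = 9)
  filled <- scenario_vl_all_low(masked)
  expect_equal(sum(is.na(filled$vl_category)), 0)
  was_missing <- is.na(masked$vl_category)
  expect_true(all(filled$vl_category[was_missing] == "lt200"))
  expect_equal(filled$vl_category[!was_missing],
               masked$vl_category[!was_missing])
})

test_that("the reference-distribution scenario converges to the target mix", {
  co <- tibble::tibble(vl_category = factor(rep(NA_character_, 1e5),
                                            levels = c("lt200", "mid", "ge1000")))
  dist <- wenzhou_vl_distribution()
  filled <- scenario_vl_reference(co, dist, seed = 10)
  props <- prop.table(table(filled$vl_category))
  expect_equal(as.numeric(props[names(dist)]), as.numeric(dist),
               tolerance = 0.01)
  # a degenerate distribution reproduces the all-low scenario
  d2 <- tibble::tibble(vl_category = c("ge1000", NA, NA))
  f2 <- scenario_vl_reference(d2, c(lt200 = 1, mid = 0, ge1000 = 0), seed = 1)
  expect_equal(f2$vl_category, scenario_vl_all_low(d2)$vl_category)
  expect_error(scenario_vl_reference(d2, c(lt200 = 0.5, mid = 0.2, ge1000 = 0.2)),
               "summing to 1")
})
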