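test_that("Harrell's C handles the canonical hand examples", {
  # perfect ranking of event times
  d <- tibble::tibble(time = 1:5, event = 1, score = 5:1)
  expect_equal(harrell_c(d, boot = 0)$estimate, 1)
  # identical scores: every usable pair is a tie
  d$score <- 2
  expect_equal(harrell_c(d, boot = 0)$estimate, 0.5)
  # 4 subjects, all events, times 1..4, scores (4,3,1,2): 5 of 6 pairs
  d4 <- tibble::tibble(time = 1:4, event = 1, score = c(4, 3, 1, 2))
  res <- harrell_c(d4, boot = 0)
  expect_equal(res$estimate, 5 / 6)
  expect_equal(res$n_usable_pairs, 6)
})

test_that("Harrell's C equals exhaustive pair enumeration on random samples", {
  set.seed(314)
  for (rep in 1:60) {
    d <- random_censored_sample(sample(5:50, 1))
    if (sum(d$event) == 0) next
    ours <- harrell_c(d, boot = 0)
    orac <- oracle_harrell_c(d$time, d$event, d$score)
    expect_equal(ours$estimate, orac$c, tolerance = 1e-12)
    expect_equal(ours$n_usable_pairs, orac$usable)
  }
})

test_that("Harrell's C agrees with survival::concordance", {
  set.seed(2718)
  for (rep in 1:10) {
    d <- random_censored_sample(80)
    ours <- harrell_c(d, boot = 0)$estimate
    ref <- survival::concordance(
      survival::Surv(time, event) ~ score, data = d, reverse = TRUE
    )$concordance
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("concordance is undefined without usable pairs", {
  d <- tibble::tibble(time = c(1, 2), event = 0, score = c(1, 2))
  expect_error(harrell_c(d, boot = 0), "usable")
})

test_that("bootstrap interval brackets the estimate and is seed-reproducible", {
  set.seed(99)
  d <- random_censored_sample(120)
  r1 <- harrell_c(d, boot = 60, seed = 4)
  r2 <- harrell_c(d, boot = 60, seed = 4)
  expect_identical(r1, r2)
  expect_true(r1$ci_low <= r1$estimate && r1$estimate <= r1$ci_high)
  expect_true(r1$se > 0)
})

test_that("time-dependent C reduces to truncated concordance without censoring", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 60
    d <- tibble::tibble(
      time = rexp(n, 0.4) + 0.01,
      event = 1L,
      score = rnorm(n)
    )
    h <- unname(quantile(d$time, 0.5))
    ours <- timedep_c(d, h)$estimate
    expect_equal(ours, oracle_truncated_c(d$time, d$event, d$score, h),
                 tolerance = 1e-12)
  }
})

test_that("time-dependent C is 1 under perfect separation of cases and survivors", {
  d <- tibble::tibble(
    time = c(0.5, 0.8, 2, 3, 4),
    event = c(1, 1, 0, 0, 0),
    score = c(9, 8, 1, 2, 3)
  )
  expect_equal(timedep_c(d, 1)$estimate, 1)
})

test_that("time-dependent C approaches 0.5 as the generating effect vanishes", {
  # proportional-hazards cohorts with shrinking effect of the score
  c_at_effect <- function(beta, seed) {
    set.seed(seed)
    n <- 4000
    x <- rnorm(n)
    tm <- rexp(n, 0.2 * exp(beta * x))
    cens <- runif(n, 0, 8)
    d <- tibble::tibble(time = pmin(tm, cens),
                        event = as.integer(tm <= cens), score = x)
    timedep_c(d, 2)$estimate
  }
  cs <- vapply(c(1, 0.3, 0), c_at_effect, numeric(1), seed = 77)
  expect_true(all(diff(cs) < 0))
  expect_equal(cs[3], 0.5, tolerance = 0.03)
  expect_gt(cs[1], 0.7)
})

test_that("time-dependent C rejects out-of-range horizons and caseless horizons", {
  d <- tibble::tibble(time = c(1, 2, 3), event = c(0, 0, 1), score = 1:3)
  expect_error(timedep_c(d, 10), "follow-up")
  expect_error(timedep_c(d, 0.5), "cases")
})

test_that("the horizon grid skips infeasible horizons with a notice", {
  d <- tibble::tibble(time = c(0.4, 1, 2, 3), event = c(1, 1, 0, 1),
                      score = c(4, 3, 2, 1))
  expect_message(grid <- timedep_c_grid(d, horizons = c(0.5, 1, 5)))
  expect_equal(nrow(grid), 3)
  expect_true(is.na(grid$estimate[grid$horizon == 5]))
  expect_false(anyNA(grid$estimate[grid$horizon < 5]))
})
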