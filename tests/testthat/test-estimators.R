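test_that("Kaplan-Meier matches hand-computed product limits", {
  # all censored: curve stays at 1
  allc <- tibble::tibble(time = c(1, 2, 5), event = 0)
  km <- km_estimate(allc)
  expect_equal(nrow(km), 0)
  expect_equal(surv_at(km, c(0.5, 10)), c(1, 1))
  # n = 3: event at 1, censored at 2, event at 3 -> S(1) = 2/3, S(3) = 0
  d3 <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
  km3 <- km_estimate(d3)
  expect_equal(surv_at(km3, 1), 2 / 3)
  expect_equal(surv_at(km3, 2.5), 2 / 3)
  expect_equal(surv_at(km3, 3), 0)
  expect_equal(km3$n_risk, c(3L, 1L))
  # scale invariance: doubling every record leaves the curve unchanged
  dbl <- d3[rep(1:3, each = 2), ]
  expect_equal(km_estimate(dbl)$estimate, km3$estimate)
})

test_that("Kaplan-Meier agrees with survival::survfit on random censored data", {
  set.seed(101)
  for (rep in 1:5) {
    d <- random_censored_sample(60)
    km <- km_estimate(d)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    grid <- sort(unique(c(d$time, 0.5, 1, 2)))
    expect_equal(surv_at(km, grid),
                 summary(sf, times = grid, extend = TRUE)$surv,
                 tolerance = 1e-12)
  }
})

test_that("Nelson-Aalen is the running sum of d/n", {
  expect_equal(nrow(nelson_aalen(tibble::tibble(time = 1:4, event = 0))), 0)
  one <- tibble::tibble(time = c(2, rep(3, 9)), event = c(1, rep(0, 9)))
  na1 <- nelson_aalen(one)
  expect_equal(cumhaz_at(na1, 2), 1 / 10)
  # brute-force oracle on a mixed sample
  set.seed(7)
  d <- random_censored_sample(40)
  na <- nelson_aalen(d)
  brute <- function(t) {
    ev_times <- sort(unique(d$time[d$event == 1 & d$time <= t]))
    sum(vapply(ev_times, function(s) {
      sum(d$time == s & d$event == 1) / sum(d$time >= s)
    }, numeric(1)))
  }
  for (t in c(0.2, 1, 3, max(d$time))) {
    expect_equal(cumhaz_at(na, t), brute(t), tolerance = 1e-12)
  }
})

test_that("KM and Nelson-Aalen satisfy S ~ exp(-H) on large low-hazard samples", {
  set.seed(42)
  n <- 5000
  d <- tibble::tibble(
    time = pmin(rexp(n, 0.02), runif(n, 1, 10)),
    event = rbinom(n, 1, 0.15) # low event fraction
  )
  km <- km_estimate(d)
  na <- nelson_aalen(d)
  for (t in c(1, 3, 5)) {
    expect_equal(surv_at(km, t), exp(-cumhaz_at(na, t)), tolerance = 1e-3)
  }
})

test_that("reverse Kaplan-Meier summarises follow-up", {
  # all censored at 5 years: median potential follow-up is 5
  allc <- tibble::tibble(time = rep(5, 4), event = 0)
  fu <- median_followup(allc)
  expect_equal(fu$time[fu$prob == 0.5], 5)
  # all died: the reverse curve never drops; flagged undefined
  alld <- tibble::tibble(time = 1:4, event = 1)
  fu2 <- median_followup(alld)
  expect_true(all(!fu2$defined))
  # mixed sample against the hand-computed reverse product limit
  d <- tibble::tibble(time = c(1, 2, 3, 4, 6), event = c(1, 0, 1, 0, 0))
  # censor events at 2, 4, 6 with risk sets 4, 2, 1:
  # S_rev(2) = 3/4, S_rev(4) = 3/8, S_rev(6) = 0 -> median 4, q75 4, q25 6
  fu3 <- median_followup(d)
  expect_equal(fu3$time[fu3$prob == 0.5], 4)
  expect_equal(fu3$time[fu3$prob == 0.25], 6)
})

test_that("cumulative mortality equals direct counting when censoring is absent", {
  set.seed(11)
  tm <- rexp(400, 0.2)
  d <- tibble::tibble(time = tm, event = 1)
  cm <- suppressMessages(cumulative_mortality(d, horizons = c(1, 3, 5)))
  direct <- 100 * vapply(c(1, 3, 5), function(h) mean(tm <= h), numeric(1))
  expect_equal(cm$cumulative_mortality_pct, direct, tolerance = 1e-12)
})

test_that("exact Poisson rate interval reproduces the published mortality rate", {
  r0 <- poisson_rate_ci(0, 100)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  r <- poisson_rate_ci(743, 65037)
  expect_equal(r$rate, 11.42, tolerance = 5e-4)
  expect_equal(r$ci_low, 10.62, tolerance = 5e-4)
  expect_equal(r$ci_high, 12.28, tolerance = 5e-4)
  # Byar's approximation agrees closely at large counts
  k <- 743
  byar_low <- k * (1 - 1 / (9 * k) - 1.959964 / (3 * sqrt(k)))^3
  byar_high <- (k + 1) * (1 - 1 / (9 * (k + 1)) + 1.959964 / (3 * sqrt(k + 1)))^3
  expect_equal(r$ci_low, 1000 * byar_low / 65037, tolerance = 1e-3)
  expect_equal(r$ci_high, 1000 * byar_high / 65037, tolerance = 1e-3)
  expect_error(poisson_rate_ci(10, 0), "positive")
})

test_that("empty samples are rejected", {
  empty <- tibble::tibble(time = numeric(0), event = integer(0))
  expect_error(km_estimate(empty), "empty")
  expect_error(nelson_aalen(empty), "empty")
})
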