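# Independent oracles and small fixture builders used across the suite.

# Exhaustive O(n^2) pair enumeration for Harrell's C: a pair is usable when
# the member with the shorter time has an event, or times are tied with
# exactly one event (the event member fails first); tied times with two
# events are unusable. Score ties count 1/2.
oracle_harrell_c <- function(time, event, score) {
  n <- length(time)
  conc <- 0
  usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (time[i] == time[j]) {
        if (event[i] + event[j] != 1) next
        first <- if (event[i] == 1) i else j
        second <- if (event[i] == 1) j else i
      } else {
        first <- if (time[i] < time[j]) i else j
        second <- if (time[i] < time[j]) j else i
        if (event[first] != 1) next
      }
      usable <- usable + 1
      if (score[first] > score[second]) {
        conc <- conc + 1
      } else if (score[first] == score[second]) {
        conc <- conc + 0.5
      }
    }
  }
  list(c = conc / usable, usable = usable)
}

# Censoring-free truncated concordance at a horizon: cases are events by t,
# comparators are subjects with observed time > t.
oracle_truncated_c <- function(time, event, score, horizon) {
  cases <- which(event == 1 & time <= horizon)
  comps <- which(time > horizon)
  conc <- 0
  total <- 0
  for (i in cases) {
    for (j in comps) {
      total <- total + 1
      if (score[i] > score[j]) {
        conc <- conc + 1
      } else if (score[i] == score[j]) {
        conc <- conc + 0.5
      }
    }
  }
  conc / total
}

# Breslow log partial likelihood for a single covariate (no ties assumed in
# the data used with it)
oracle_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

random_censored_sample <- function(n, tie_prob = 0.2) {
  time <- round(rexp(n, 0.3) + 0.05, ifelse(runif(n) < tie_prob, 0, 3))
  time <- pmax(time, 0.01)
  tibble::tibble(
    time = time,
    event = rbinom(n, 1, 0.6),
    score = sample(seq_len(max(2, n %/% 2)), n, replace = TRUE)
  )
}
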