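test_that("Kaplan-Meier curve reproduces hand-computed product limits", {
  # no censoring: empirical survival
  s <- survival_sample(time = c(1, 2, 3), status = c(1, 1, 1),
                       covariates = c(0, 1, 0))
  km <- km_curve(s)
  expect_equal(km_eval(km, 1.5), 2 / 3)
  expect_equal(km_eval(km, 0.5), 1)        # right-continuous, 1 before first jump
  expect_equal(km_eval(km, 3), 0)

  # first subject censored at 1: S(2.5) = (1 - 1/2) = 1/2
  s2 <- survival_sample(time = c(1, 2, 3), status = c(0, 1, 1),
                        covariates = c(0, 1, 0))
  expect_equal(km_eval(km_curve(s2), 2.5), 0.5)

  # all censored: constant-1 curve with a warning flag
  expect_warning(km0 <- pseudoGMM:::km_fit(c(1, 2, 3), c(0, 0, 0)),
                 "no observed events")
  expect_true(km0$no_events)
  expect_equal(km_eval(km0, c(0.5, 2, 10)), c(1, 1, 1))
})

test_that("Kaplan-Meier curve matches survival::survfit on random samples", {
  for (seed in 1:20) {
    s <- random_sample(n = sample(5:40, 1), seed = seed)
    km <- km_curve(s)
    sf <- survival::survfit(survival::Surv(s$time, s$status) ~ 1)
    at <- sort(unique(s$time[s$status == 1]))
    expect_lt(max(abs(km_eval(km, at) -
                      summary(sf, times = at)$surv)), 1e-10)
  }
})

test_that("time grid uses type-1 quantiles of event times at k/(K+1)", {
  s <- survival_sample(time = 1:12, status = rep(1, 12),
                       covariates = rep(0:1, 6))
  g <- select_time_grid(s, 5)
  expect_equal(g$points, c(2, 4, 6, 8, 10))

  s3 <- survival_sample(time = c(1, 2, 3), status = c(1, 1, 1),
                        covariates = c(0, 1, 0))
  expect_equal(select_time_grid(s3, 1)$points, 2)  # median event time

  # too few distinct event times: informative error
  expect_error(select_time_grid(s3, 5), "at least 5 distinct event times")

  # heavy ties collapse the grid and flag the reduction
  s4 <- survival_sample(time = c(1, 1, 1, 2), status = c(1, 1, 1, 1),
                        covariates = c(0, 1, 0, 1))
  expect_warning(g4 <- select_time_grid(s4, 2), "collapsed")
  expect_true(g4$reduced)
  expect_equal(g4$K, 1L)
})

test_that("without censoring pseudo-values are exactly survival indicators", {
  s <- survival_sample(time = c(1, 2, 3), status = c(1, 1, 1),
                       covariates = c(0, 1, 0))
  po <- pseudo_obs_matrix(s, 1.5)
  expect_equal(drop(po$values), c(0, 1, 1))
  for (seed in 1:10) {
    s <- uncensored_sample(n = sample(8:30, 1), seed = seed)
    g <- select_time_grid(s, 3)
    po <- pseudo_obs_matrix(s, g)
    ind <- outer(s$time, g$points, ">") * 1
    expect_lt(max(abs(po$values - ind)), 1e-10)
  }
})

test_that("incremental pseudo-values equal the leave-one-out brute force", {
  for (seed in 1:60) {
    s <- random_sample(n = sample(4:30, 1), seed = 100 + seed,
                       cens = runif(1, 0.1, 0.6))
    K <- min(3, length(unique(s$time[s$status == 1])))
    g <- select_time_grid(s, K)
    fast <- pseudo_obs_matrix(s, g)
    brute <- pseudo_obs_bruteforce(s, g)
    expect_lt(max(abs(fast$values - brute$values)), 1e-10)
  }
})

test_that("pseudo-value signs follow the at-risk / event / censored pattern", {
  s <- random_sample(n = 40, seed = 7, cens = 0.4)
  g <- select_time_grid(s, 4)
  po <- pseudo_obs_matrix(s, g)
  # subjects surviving beyond t_k have pseudo-value > 1 under censoring
  at_risk <- outer(s$time, g$points, ">")
  expect_true(all(po$values[at_risk] > 1))
  # at and after an event, pseudo-values are non-positive (exactly 0 only
  # when no censoring precedes the grid time) and strictly negative
  # somewhere
  evt_after <- outer(s$time, g$points, "<=") & s$status == 1
  expect_true(all(po$values[evt_after] <= 1e-12))
  expect_true(any(po$values[evt_after] < 0))
  # a censored subject keeps positive pseudo-values afterwards
  cens_after <- outer(s$time, g$points, "<") & s$status == 0
  expect_true(all(po$values[cens_after] > 0))
})

test_that("grid points beyond the last event time are rejected", {
  s <- survival_sample(time = c(1, 2, 3, 4), status = c(1, 1, 1, 0),
                       covariates = c(0, 1, 0, 1))
  expect_error(pseudo_obs_matrix(s, 3.5), "largest observed event time")
})
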