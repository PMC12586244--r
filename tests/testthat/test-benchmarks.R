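test_that("Cox fit matches a brute-force partial-likelihood search", {
  # n = 4, no ties: the Breslow partial log-likelihood is a 1-d function of
  # beta that a grid/golden-section search can maximize independently
  s <- survival_sample(time = c(1, 2, 3, 4), status = rep(1, 4),
                       covariates = c(1, 0, 1, 0))
  pl <- function(beta) {
    x <- c(1, 0, 1, 0); t <- c(1, 2, 3, 4)
    sum(vapply(1:4, function(i) {
      risk <- which(t >= t[i])
      x[i] * beta - log(sum(exp(beta * x[risk])))
    }, numeric(1)))
  }
  oracle <- stats::optimize(pl, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  fit <- fit_cox(s)
  expect_equal(unname(fit$beta["treatment"]), oracle, tolerance = 1e-6)

  # large-sample consistency under exponential proportional hazards
  set.seed(61)
  n <- 4000
  trt <- rep(0:1, n / 2)
  tt <- rexp(n, rate = exp(-0.5 * trt))
  s2 <- survival_sample(tt, rep(1, n), trt)
  f2 <- fit_cox(s2)
  expect_lt(abs(f2$beta["treatment"] + 0.5), 3 * f2$se["treatment"])

  # no events in one arm: monotone-likelihood flag
  s3 <- survival_sample(time = c(1, 2, 3, 4, 5, 6),
                        status = c(1, 1, 1, 0, 0, 0),
                        covariates = c(0, 0, 0, 1, 1, 1))
  expect_warning(f3 <- fit_cox(s3))
  expect_true(f3$monotone)
})

test_that("PEM interval rule and hazard-rate MLE follow the event count", {
  mk <- function(r, n_extra_cens = 0) {
    survival_sample(time = c(seq_len(r), rep(r + 1, n_extra_cens)),
                    status = c(rep(1, r), rep(0, n_extra_cens)),
                    covariates = rep_len(0:1, r + n_extra_cens))
  }
  expect_equal(pem_spec(mk(160))$M, 20L)
  expect_equal(pem_spec(mk(30))$M, 5L)
  expect_equal(pem_spec(mk(400))$M, 20L)
  sp <- pem_spec(mk(30))
  expect_length(sp$cutpoints, sp$M - 1L)
  expect_true(all(diff(sp$cutpoints) > 0))
  # h_hat is the exponential-model rate MLE: events / follow-up
  s <- mk(30, 10)
  expect_equal(pem_spec(s)$h_hat, 30 / sum(s$time))
})

test_that("Gibbs conditional for the hazard matches the conjugate closed form", {
  s <- random_sample(n = 60, seed = 71, cens = 0.25)
  # single interval, beta fixed at 0: posterior is Gamma(1 + r, h_hat + total time)
  spec1 <- structure(list(M = 1L, cutpoints = numeric(0),
                          h_hat = sum(s$status) / sum(s$time),
                          beta_sd = sqrt(1e5)), class = "pem_spec")
  pe <- pseudoGMM:::pem_exposure(s$time, s$status, spec1$cutpoints)
  d_m <- sum(s$status)
  fc <- pseudoGMM:::pem_h_conditional(pe, d_m, spec1$h_hat, rep(1, s$n))
  expect_equal(fc$shape, 1 + sum(s$status))
  expect_equal(fc$rate, spec1$h_hat + sum(s$time))
  # distributional check: 10k Gibbs draws reproduce the closed-form moments
  set.seed(2)
  draws <- rgamma(10000, shape = fc$shape, rate = fc$rate)
  m_true <- fc$shape / fc$rate
  sd_true <- sqrt(fc$shape) / fc$rate
  expect_lt(abs(mean(draws) - m_true), 4 * sd_true / sqrt(10000))
  expect_lt(abs(sd(draws) - sd_true), 0.05 * sd_true)

  # multi-interval: conditional rates match a per-subject brute-force
  # exposure computation
  spec <- pem_spec(s)
  pe2 <- pseudoGMM:::pem_exposure(s$time, s$status, spec$cutpoints)
  beta <- 0.3
  exb <- exp(beta * s$covariates[, 1])
  lo <- c(0, spec$cutpoints); hi <- c(spec$cutpoints, Inf)
  brute <- vapply(seq_along(lo), function(m)
    sum(exb * pmax(pmin(s$time, hi[m]) - lo[m], 0)), numeric(1))
  fc2 <- pseudoGMM:::pem_h_conditional(pe2, 0, spec$h_hat, exb)
  expect_equal(unname(fc2$rate), spec$h_hat + brute, tolerance = 1e-12)
})

test_that("Bayesian PEM concentrates near the true log hazard ratio", {
  set.seed(81)
  n <- 800
  trt <- rep(0:1, n / 2)
  T_ev <- rexp(n, rate = exp(-0.4 * trt))
  C <- runif(n, 0, 6)
  s <- survival_sample(pmin(T_ev, C), as.numeric(T_ev <= C), trt)
  f <- fit_pem_bayes(s, chains = 2L, iters = 1500L, warmup = 500L,
                     thin = 3L, seed = 4L, thresholds = 0)
  row <- f$summary[f$summary$coefficient == "treatment", ]
  expect_lt(abs(row$mean + 0.4), 3.5 * row$sd)
  expect_true(row$lower < row$median && row$median < row$upper)
  expect_equal(f$tail$prob, 1, tolerance = 0.02)  # effect clearly below 0
})
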