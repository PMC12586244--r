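test_that("Sigma_n is the moment covariance minus the rank-one correction", {
  p <- trial_pieces(n = 120, seed = 101)
  b <- basis_set("ind", 5)
  set.seed(4)
  for (r in 1:10) {
    beta <- starting_values(p$pseudo, p$design) + rnorm(6, sd = 0.1)
    ms <- moment_state(beta, p$pseudo, p$design, b)
    sn <- sigma_n(beta, p$pseudo, p$design, b)
    expect_lt(max(abs(sn$sigma + tcrossprod(ms$U) / p$design$n - ms$C)), 1e-12)
  }
  # at a root of U the two matrices coincide
  gee <- fit_gee(p$pseudo, p$design, "ind")
  ms <- moment_state(unname(gee$beta), p$pseudo, p$design, b)
  sn <- sigma_n(unname(gee$beta), p$pseudo, p$design, b)
  expect_lt(max(abs(sn$sigma - ms$C)), 1e-14)
  expect_true(sn$ok)

  # far outside the support the linear predictor saturates and the moment
  # covariance collapses: flagged non-invertible
  sn_far <- sigma_n(c(25, rep(0, 5)), p$pseudo, p$design, b)
  expect_false(sn_far$ok)
})

test_that("log pseudo-posterior peaks near the frequentist optimum", {
  p <- trial_pieces(n = 300, seed = 111)
  b <- basis_set("ind", 5)
  pri <- prior_spec("normal", 0, 10)
  f <- fit_gmm(p$pseudo, p$design, "ind")
  bhat <- unname(f$beta)
  lp0 <- log_posterior(bhat, p$pseudo, p$design, b, pri)
  expect_true(is.finite(lp0))
  for (d in c(-0.05, 0.05)) {
    bd <- bhat; bd[2] <- bd[2] + d
    expect_lt(log_posterior(bd, p$pseudo, p$design, b, pri), lp0)
  }
  # singular region maps to -Inf
  expect_identical(log_posterior(c(25, rep(0, 5)), p$pseudo, p$design, b, pri),
                   -Inf)
  # prior term alone at beta = 0 under standard normal priors
  expect_equal(pseudoGMM:::log_prior(rep(0, 6), prior_spec("normal", 0, 1)),
               6 * (-0.5 * log(2 * pi)))
})

test_that("starting values implement truncate-transform-OLS", {
  p <- trial_pieces(n = 80, seed = 121)
  eps <- 0.1
  z <- cloglog(pmin(pmax(as.vector(t(p$pseudo$values)), eps), 1 - eps))
  oracle <- unname(lm.fit(p$design$X, z)$coefficients)
  expect_equal(starting_values(p$pseudo, p$design, eps), oracle,
               tolerance = 1e-12)
  expect_error(starting_values(p$pseudo, p$design, 0.7), "in \\(0, 0.5\\)")
  # a no-censoring sample still yields finite OLS values
  s <- uncensored_sample(40, 5)
  g <- select_time_grid(s, 3)
  po <- pseudo_obs_matrix(s, g)
  des <- build_design(s, g)
  expect_true(all(is.finite(starting_values(po, des, 0.05))))
  # and the starting point lies inside the pseudo-likelihood support
  for (seed in 1:10) {
    pp <- trial_pieces(n = 150, seed = 130 + seed)
    b0 <- starting_values(pp$pseudo, pp$design, 0.05)
    expect_true(is.finite(log_posterior(b0, pp$pseudo, pp$design,
                                        basis_set("ind", 5),
                                        prior_spec("normal", 0, 10))))
  }
})

test_that("sampler is deterministic given the seed", {
  p <- trial_pieces(n = 120, seed = 141)
  pri <- prior_spec("normal", 0, 10)
  d1 <- sample_posterior(p$pseudo, p$design, "ind", pri, chains = 2L,
                         iters = 200L, warmup = 100L, thin = 2L, seed = 9L,
                         epsilons = c(0.05, 0.1))
  d2 <- sample_posterior(p$pseudo, p$design, "ind", pri, chains = 2L,
                         iters = 200L, warmup = 100L, thin = 2L, seed = 9L,
                         epsilons = c(0.05, 0.1))
  expect_identical(d1$draws, d2$draws)
  d3 <- sample_posterior(p$pseudo, p$design, "ind", pri, chains = 2L,
                         iters = 200L, warmup = 100L, thin = 2L, seed = 10L,
                         epsilons = c(0.05, 0.1))
  expect_false(identical(d1$draws, d3$draws))
})

test_that("the adaptive Metropolis engine recovers a known Gaussian target", {
  mu <- c(-1, 0.5, 0, 2, -0.3, 1)
  S <- diag(c(1, 0.5, 0.2, 1.5, 0.3, 0.8))
  S[1, 2] <- S[2, 1] <- 0.4
  Sinv <- solve(S)
  lp <- function(b) -0.5 * drop(t(b - mu) %*% Sinv %*% (b - mu))
  am <- pseudoGMM:::adaptive_metropolis(lp, list(mu, mu + 0.5, mu - 0.5),
                                        iters = 6000L, warmup = 1500L,
                                        thin = 2L, seed = 3L)
  flat <- apply(am$draws, 3, as.vector)
  expect_lt(max(abs(colMeans(flat) - mu)), 0.12)
  expect_lt(max(abs(cov(flat) - S)), 0.25)
})

test_that("split-Rhat and ESS flag disagreement between chains", {
  mk <- function(draws_mat) {
    structure(list(draws = array(draws_mat, c(nrow(draws_mat),
                                              ncol(draws_mat), 1)),
                   labels = "treatment", chains = ncol(draws_mat),
                   iters = nrow(draws_mat), warmup = 0L, thin = 1L,
                   seed = 1L, epsilons = NULL, accept = NULL,
                   support_rejections = 0L),
              class = "posterior_draws")
  }
  # constant identical chains: exactly 1
  d <- diagnostics(mk(matrix(0.7, 400, 3)))
  expect_equal(d$rhat, 1, tolerance = 1e-12)
  # well-mixed iid chains: near 1
  set.seed(8)
  d2 <- diagnostics(mk(matrix(rnorm(1200), 400, 3)))
  expect_lt(abs(d2$rhat - 1), 0.02)
  expect_gt(d2$ess, 600)
  # chains centered at -1 and +1: clearly above the 1.1 alarm level
  d3 <- diagnostics(mk(cbind(rnorm(400, -1, 0.1), rnorm(400, 1, 0.1))))
  expect_gt(d3$rhat, 1.1)
})

test_that("posterior summaries are the empirical quantile functionals", {
  mk <- function(x, chains = 2) {
    m <- matrix(x, length(x) / chains, chains)
    structure(list(draws = array(m, c(nrow(m), chains, 1)),
                   labels = "treatment", chains = chains, iters = nrow(m),
                   warmup = 0L, thin = 1L, seed = 1L, epsilons = NULL,
                   accept = NULL, support_rejections = 0L),
              class = "posterior_draws")
  }
  # degenerate draws
  f <- posterior_summary(mk(rep(0.5, 400)), thresholds = 0)
  expect_equal(f$summary$mean, 0.5)
  expect_equal(f$summary$median, 0.5)
  expect_equal(c(f$summary$lower, f$summary$upper), c(0.5, 0.5))
  expect_equal(f$tail$prob, 0)
  # standard normal draws: tail probability at 0 is about one half,
  # interval endpoints are the stacked empirical percentiles
  set.seed(31)
  x <- rnorm(4000)
  f2 <- posterior_summary(mk(x), thresholds = c(0, 10))
  expect_equal(f2$tail$prob[1], 0.5, tolerance = 0.05)
  expect_equal(f2$tail$prob[2], 1)
  expect_equal(f2$summary$lower, unname(quantile(x, 0.025)))
  expect_equal(f2$summary$upper, unname(quantile(x, 0.975)))
  expect_true(all(f2$tail$mcse >= 0))
})

test_that("posterior agrees with the frequentist GMM under weak priors", {
  p <- trial_pieces(n = 400, seed = 151)
  f <- fit_gmm(p$pseudo, p$design, "ind")
  fb <- fit_gmm_bayes(p$pseudo, p$design, "ind",
                      priors = prior_spec("normal", 0, 10),
                      chains = 3L, iters = 2500L, warmup = 1000L, thin = 2L,
                      seed = 17L)
  s <- fb$summary[fb$summary$coefficient == "treatment", ]
  expect_lt(abs(s$mean - f$beta["treatment"]), 2 * s$sd)
  expect_true(all(fb$summary$rhat < 1.1))
  expect_true(s$lower < s$median && s$median < s$upper)
})
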