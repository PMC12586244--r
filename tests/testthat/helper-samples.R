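# Small randomized fixtures built in code.

# Random right-censored sample with mixed censoring (exponential events,
# uniform censoring), guaranteed to contain at least one event.
random_sample <- function(n, seed, cens = 0.3, two_arm = TRUE) {
  set.seed(seed)
  repeat {
    trt <- if (two_arm) rbinom(n, 1, 0.5) else rep(0, n)
    T_ev <- rexp(n, rate = exp(0.4 * trt))
    # exponential censoring with rate chosen so P(C < T) is about `cens`
    C <- if (cens > 0) rexp(n, rate = cens / (1 - cens)) else rep(Inf, n)
    time <- pmin(T_ev, C)
    status <- as.numeric(T_ev <= C)
    if (sum(status) >= max(2, n %/% 4) && (!two_arm || length(unique(trt)) == 2))
      return(survival_sample(time = time, status = status, covariates = trt))
  }
}

# A no-censoring sample: pseudo-values must equal survival indicators.
uncensored_sample <- function(n, seed) {
  set.seed(seed)
  survival_sample(time = rexp(n) + 0.01, status = rep(1, n),
                  covariates = rbinom(n, 1, 0.5))
}

# One simulated core-style trial plus its pseudo-observation pieces.
trial_pieces <- function(n = 200, seed = 1, K = 5, beta1 = -0.3, cr = 0.2) {
  sc <- scenario(n = n, beta1 = beta1, target_cr = cr, K = K, nsim = 1,
                 base_seed = seed)
  smp <- generate_trial(sc, seed)
  grid <- select_time_grid(smp, K)
  list(sample = smp, grid = grid,
       pseudo = pseudo_obs_matrix(smp, grid),
       design = build_design(smp, grid))
}
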