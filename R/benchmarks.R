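#' Cox proportional hazards benchmark
#'
#' Partial-likelihood fit with Breslow tie handling, delegated to
#' \code{survival::coxph}; Wald standard errors from the inverse observed
#' information. The fit is flagged (`monotone = TRUE`, not an error) when
#' one arm has no events, where the partial likelihood is monotone in the
#' treatment coefficient.
#'
#' @param sample A [survival_sample()].
#' @return A `"pgmm_fit"` with one coefficient per covariate column.
#' @export
fit_cox <- function(sample) {
  stop_if_not_sample(sample)
  X <- sample$covariates
  monotone <- FALSE
  trt <- X[, 1L]
  if (all(trt %in% c(0, 1))) {
    ev_by_arm <- tapply(sample$status, trt, sum)
    if (any(ev_by_arm == 0) || length(ev_by_arm) < 2L) monotone <- TRUE
  }
  fit <- survival::coxph(survival::Surv(sample$time, sample$status) ~ X,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  labels <- colnames(X)
  new_frequentist_fit(
    method = "cox", labels = labels, beta = beta,
    cov = unname(stats::vcov(fit)),
    converged = is.finite(fit$loglik[2]) && !monotone,
    n_iter = fit$iter, objective = fit$loglik[2],
    extra = list(monotone = monotone))
}

#' Piecewise exponential model specification
#'
#' Interval count by the event-count rule `M = max{5, min(floor(r/8), 20)}`
#' with `r` observed events; interior cutpoints at event-time quantiles so
#' each interval holds about equal numbers of events; baseline-hazard
#' priors `h_m ~ Gamma(1, h_hat)` (shape-rate) with `h_hat = r / total
#' follow-up`, the rate MLE of the exponential proportional hazards model;
#' coefficient prior N(0, variance 1e5).
#'
#' @param sample A [survival_sample()].
#' @return Object of class `"pem_spec"`: `M`, `cutpoints` (M - 1 interior
#'   boundaries), `h_hat`, `beta_sd`.
#' @export
pem_spec <- function(sample) {
  stop_if_not_sample(sample)
  r <- sum(sample$status)
  M <- max(5L, min(as.integer(floor(r / 8)), 20L))
  ev <- sample$time[sample$status == 1]
  cut <- if (M > 1L) {
    unique(unname(stats::quantile(ev, probs = seq_len(M - 1L) / M, type = 1)))
  } else numeric(0)
  M <- length(cut) + 1L
  h_hat <- r / sum(sample$time)
  structure(list(M = M, cutpoints = cut, h_hat = h_hat,
                 beta_sd = sqrt(1e5)),
            class = "pem_spec")
}

# Full-conditional Gamma parameters of the interval hazards given beta:
# shape 1 + d_m, rate h_hat + sum_i E_im exp(x_i' beta).
pem_h_conditional <- function(pe, d_m, h_hat, exb) {
  list(shape = 1 + d_m, rate = h_hat + drop(t(pe$expos) %*% exb))
}

# Events and exposure per subject x interval for a cutpoint vector.
pem_exposure <- function(time, status, cutpoints) {
  lo <- c(0, cutpoints)
  hi <- c(cutpoints, Inf)
  M <- length(lo)
  expos <- vapply(seq_len(M), function(m)
    pmax(pmin(time, hi[m]) - lo[m], 0), numeric(length(time)))
  interval <- findInterval(time, cutpoints, left.open = TRUE) + 1L
  list(expos = expos, interval = interval, M = M)
}

#' Bayesian piecewise exponential model
#'
#' Piecewise-constant baseline hazard with a proportional covariate effect
#' exp(X beta). Sampling interleaves conjugate Gibbs updates for the
#' interval hazards,
#' `h_m | beta ~ Gamma(1 + d_m, h_hat + sum_i E_im exp(x_i' beta))`
#' with `d_m` events and `E_im` exposure in interval m, with adaptive
#' random-walk Metropolis updates for beta under its N(0, 1e5) prior.
#' Intervals left without exposure are merged with their left neighbour
#' (with a message).
#'
#' @param sample A [survival_sample()].
#' @param spec A [pem_spec()]; computed from the sample when NULL.
#' @param chains,iters,warmup,thin,seed Sampler settings as in
#'   [sample_posterior()].
#' @param thresholds Tail-probability thresholds for the treatment effect.
#' @return A `"pgmm_bayes_fit"` for the covariate coefficients (the
#'   interval hazards are integrated out of the report).
#' @export
fit_pem_bayes <- function(sample, spec = NULL, chains = 3L, iters = 5000L,
                          warmup = 1000L, thin = 5L, seed = 1L,
                          thresholds = numeric(0)) {
  stop_if_not_sample(sample)
  if (is.null(spec)) spec <- pem_spec(sample)
  X <- sample$covariates
  P <- ncol(X)
  pe <- pem_exposure(sample$time, sample$status, spec$cutpoints)
  # merge empty-exposure intervals with the left neighbour
  tot_expos <- colSums(pe$expos)
  if (any(tot_expos <= 0)) {
    empty <- which(tot_expos <= 0)
    message("merging ", length(empty), " empty interval(s) with their neighbour")
    cut <- spec$cutpoints[-unique(pmax(empty - 1L, 1L))]
    pe <- pem_exposure(sample$time, sample$status, cut)
  }
  M <- pe$M
  d_m <- vapply(seq_len(M), function(m)
    sum(sample$status[pe$interval == m]), numeric(1))
  status <- sample$status

  loglik_beta <- function(beta, h) {
    xb <- drop(X %*% beta)
    H0 <- drop(pe$expos %*% h)
    sum(status * xb) - sum(exp(xb) * H0)
  }

  kept <- floor(iters / thin)
  draws <- array(NA_real_, c(kept, chains, P))
  accept <- numeric(chains)
  for (c in seq_len(chains)) {
    set.seed((seed + 7919L * c) %% .Machine$integer.max)
    beta <- numeric(P)
    h <- rep(spec$h_hat, M)
    ls <- log(0.2)
    n_acc <- 0L; ki <- 0L
    for (t in seq_len(warmup + iters)) {
      # Gibbs: conjugate Gamma update of the interval hazards
      fc <- pem_h_conditional(pe, d_m, spec$h_hat, exp(drop(X %*% beta)))
      h <- stats::rgamma(M, shape = fc$shape, rate = fc$rate)
      # Metropolis update of beta
      prop <- beta + exp(ls) * stats::rnorm(P)
      la <- loglik_beta(prop, h) - loglik_beta(beta, h) +
        sum(stats::dnorm(prop, 0, spec$beta_sd, log = TRUE)) -
        sum(stats::dnorm(beta, 0, spec$beta_sd, log = TRUE))
      a <- min(1, exp(la))
      moved <- stats::runif(1) < a
      if (moved) beta <- prop
      if (t <= warmup) {
        ls <- ls + t^(-0.6) * (a - 0.234)
      } else {
        if (moved) n_acc <- n_acc + 1L
        if ((t - warmup) %% thin == 0L) {
          ki <- ki + 1L
          draws[ki, c, ] <- beta
        }
      }
    }
    accept[c] <- n_acc / iters
  }
  labels <- colnames(X)
  dimnames(draws) <- list(NULL, NULL, labels)
  pd <- structure(list(draws = draws, labels = labels, chains = chains,
                       iters = iters, warmup = warmup, thin = thin,
                       seed = seed, epsilons = NULL, accept = accept,
                       support_rejections = 0L),
                  class = "posterior_draws")
  out <- posterior_summary(pd, thresholds = thresholds)
  out$spec <- spec
  out
}
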