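---
title: "Hazard ratios from pseudo-observations: GEE, GMM and Bayesian GMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard ratios from pseudo-observations: GEE, GMM and Bayesian GMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Right-censored survival data resist ordinary regression because the outcome
is only partially observed. Jackknife pseudo-observations restore a
regression-friendly outcome: with $\hat S$ the Kaplan–Meier estimator and
$\hat S^{-i}$ its leave-one-out refit, the pseudo-value of subject $i$ at a
grid time $t_k$ is

$$y_{ik} = n\,\hat S(t_k) - (n-1)\,\hat S^{-i}(t_k),$$

an approximately unbiased estimate of the subject's own survival indicator
given covariates. Pseudo-values are not probabilities: subjects still at
risk at $t_k$ score slightly above 1, subjects with an earlier event drift
negative. Regressing them on covariates through the complementary log-log
link,

$$\operatorname{cloglog} E(y_{ik}\mid X_i)
  = \log H_0(t_k) + X_i^\top\beta,$$

makes the coefficients $\beta$ log hazard ratios of a proportional-hazards
model, with the baseline absorbed by an intercept and $K-1$ time dummies
(the first grid time is the reference). With $P$ covariate columns
including the intercept, the parameter count is $L = P + K - 1$.

Three estimation routes share this mean model:

* **GEE** (`fit_gee`): Fisher scoring on the estimating equations
  $\sum_i D_i^\top R(\alpha)^{-1}(y_i-\mu_i)=0$ with an identity variance
  function — pseudo-values fall outside $[0,1]$, so a mean–variance
  relation would be artificial — and the robust sandwich covariance. The
  working correlation $R(\alpha)$ is independence, exchangeable or AR-1;
  $\alpha$ is re-estimated by moments between scoring steps.
* **Frequentist GMM** (`fit_gmm`): the inverse working correlation is
  expanded over $J$ basis matrices, the per-subject scores
  $u_i = \{D_i^\top M_j (y_i-\mu_i)\}_j$ are stacked, and
  $\hat\beta$ minimizes the quadratic inference function
  $Q_n = U_n^\top C_n^{-1} U_n$ with $U_n = \tfrac1n\sum u_i$ and
  $C_n = \tfrac1{n^2}\sum u_iu_i^\top$. Under the independence basis the
  system is exactly identified and GMM reproduces GEE exactly — a useful
  internal consistency check that the test suite exercises.
* **Bayesian GMM** (`fit_gmm_bayes`): the central limit theorem for $U_n$
  justifies the moment-based pseudo-likelihood
  $\tilde L(\beta) \propto \exp\{-\tfrac12 U_n^\top \Sigma_n^{-1} U_n\}$
  with $\Sigma_n = C_n - U_nU_n^\top/n$, which is combined with weakly
  informative priors and sampled by Markov chain Monte Carlo. No baseline
  hazard is ever specified, which is the point of the construction; the
  price is that the pseudo-likelihood supports no prediction, only
  inference on $\beta$.

Benchmarks: `fit_cox` (partial likelihood, Breslow ties, via the survival
package) and `fit_pem_bayes`, a Bayesian piecewise exponential model with
conjugate Gamma–Gibbs updates for the interval hazards interleaved with
Metropolis updates for the coefficients.

## Numerical choices that matter

**Time grid.** `select_time_grid` places the $K$ grid times at type-1
empirical quantiles of the observed event times at probabilities
$k/(K+1)$, so the $K+1$ intervals hold roughly equal event counts. The
quantile type is a convention — downstream estimates are insensitive to
it, but exact grid values may differ from other implementations. $K=5$ is
the default: more points buy almost nothing and lengthen every fit.

**Pseudo-value computation.** `pseudo_obs_matrix` runs in $O(nK)$ after
one pass over the risk table: each leave-one-out curve differs from the
full-sample curve only through decremented risk (and, for an event
subject, death) counts, so its log-survival is a segment sum over
precomputed per-jump log factors. The literal $n$-refit jackknife
(`pseudo_obs_bruteforce`) is kept as an oracle; the suite asserts
agreement to $10^{-10}$ on hundreds of random samples. Ties between an
event and a censoring at the same instant follow the usual convention:
the censored subject is still in the risk set.

**Link overflow.** Linear predictors are clipped to $\pm 30$ before
exponentiation, keeping $\mu$ strictly inside $(0,1)$ in double precision
without touching any realistic hazard-ratio scale.

**Rank geometry of the stacked moments.** A fact easy to miss: with
cluster-constant covariates — a two-arm trial with no further covariates
has only two distinct covariate profiles — the per-subject scores are
$u_i = B_{g(i)}(y_i - \mu_{g(i)})$ with only two distinct $K$-column
matrices $B_g$, so $C_n$ and $\Sigma_n$ have rank at most $2K$ however
large $n$ grows. For the exchangeable basis the deficiency is worse:
$M_1 + M_2$ is the all-ones matrix, so every vector $(a,a)$ with
$a^\top D_g^\top \mathbf 1 = 0$ in both arms (two constraints on $L$
dimensions) is an exact null direction, leaving rank $8$ out of $12$ at
$K=5$. The package therefore inverts $C_n$ and $\Sigma_n$ on their
numerical range (eigen pseudoinverse, relative threshold
$10^{-10}\lambda_{\max}$). The quadratic forms are well defined there
because $U_n$ is itself confined to the same range. One visible
consequence: the minimized $Q_n$ for the exchangeable basis in the
two-arm design is asymptotically $\chi^2$ with rank$-L = 2$ degrees of
freedom, not the generic $(J-1)L = 6$ that applies when $C_n$ is
nonsingular (e.g. with continuous covariates). The acceptance suite
measures this deliberately.

**Support of the pseudo-likelihood.** Far from the optimum the inverse
link saturates, the Jacobians vanish and $\Sigma_n$ collapses; the
pseudo-likelihood is undefined there. The sampler treats as support the
region where $\Sigma_n$ attains the rank observed at the starting values
and $U_n$ stays in its range; proposals outside are rejected in place
(the count is reported as `support_rejections`). For the independence
basis this coincides with the plain full-rank rule (reciprocal condition
$\ge 10^{-12}$).

**Starting values.** Random starts routinely fall outside the support.
The three-step rule — truncate pseudo-values to $[\epsilon, 1-\epsilon]$,
apply the cloglog transform, ordinary least squares on the design — is
biased as an estimator but lands inside the support essentially always;
one chain is started per $\epsilon \in (0.01, 0.05, 0.1)$, with a 0.03
fallback on failure.

**Sampler.** Adaptive random-walk Metropolis rather than gradient-based
samplers: the support boundary is hard (gradients are undefined across
it) and rejection at the boundary is exactly the behaviour wanted there.
The proposal is multivariate normal with covariance adapted during warmup
from the chain's running covariance (scaled $2.38^2/L$), and the global
scale is tuned toward an acceptance rate of 0.234 by Robbins–Monro;
adaptation freezes at the end of warmup. Purely diagonal adaptation was
tried first and mixes an order of magnitude worse on this correlated
target. When the frequentist GMM covariance is available it seeds the
proposal, shortening the adaptation transient; seeding changes no target
quantity, only the proposal. Defaults mirror the full-scale study
settings: 3 chains, 5000 post-warmup iterations after 1000 warmup,
thinning 5. Convergence is monitored with split-$\widehat R$ and bulk
effective sample size (Geyer-truncated autocorrelations).

**Priors.** Gaussian scales are standard deviations. The default rule is
$N(0,1)$ for $n \le 100$ and $N(0,10)$ otherwise: tight enough that the
chain rarely tests the support boundary, vague relative to any plausible
log hazard ratio. Cauchy$(0, 2.5)$ is available. Extremely diffuse priors
(e.g. variance $10^3$ and beyond) are deliberately not defaults — on the
cloglog scale they put mass on absurd survival probabilities and drive
the sampler into the undefined region. The piecewise exponential
benchmark keeps its conventional priors: $h_m \sim$ Gamma(shape 1, rate
$\hat h$) with $\hat h$ the exponential-model rate MLE, and $N(0, 10^5)$
*variance* for the coefficients (the BUGS-style convention for that
model).

**Point estimate.** Bias and coverage for Bayesian fits use the posterior
mean; the equal-tailed 2.5%/97.5% interval defines coverage. The median
is reported alongside for users who prefer it.

## The simulator and what it does (not) emulate

`generate_trial` draws a balanced two-arm trial: Weibull event times with
shape $a = 0.6$ and scale $\exp(-\beta_1 X_1 / a)$ — so the treatment
hazard ratio is exactly $e^{\beta_1}$ and the control-arm median is
$(\log 2)^{1/a} \approx 0.54$ time units — and independent
Uniform$(0,\theta)$ censoring, with $\theta$ calibrated by 1-d root
finding so that $P(C < T)$ hits the target censoring rate (verified by
Monte Carlo to a few tenths of a percent). Defaults describe the core
scenario studied throughout: $n = 500$, 20% censoring,
$\beta_1 = -0.3$, $K = 5$.

The generator emulates administrative, covariate-independent censoring in
a randomized trial. It does not emulate covariate-dependent censoring
(which breaks the unbiasedness of pseudo-values), informative dropout,
delayed treatment effects or non-proportional hazards — passing tests say
nothing about those regimes.

`run_study` fixes per-replicate seeds as `base_seed + replicate`, making
every table bit-reproducible, and reports bias, average standard error
(ASE), the replicate standard deviation of the estimates (ASD, $n-1$
denominator), RMSE and 95% interval coverage, with Monte-Carlo standard
errors. Failed or non-converged fits are dropped per cell with counts
reported; cells with more than 5% failures are flagged.

## Problem sizes used by the shipped checks

The package's acceptance checks reproduce the study at desk scale, a
choice made once and kept: 500 replicates for the frequentist cells
(core scenario, 70% censoring, exchangeable basis), 150–200 replicates
at $n=50$ and 120–150 at $n=500$ for the Bayesian cells with shortened
chains
(3 chains, 1500 post-warmup draws, warmup 500, thinning 3 — seeded, as
above, by the frequentist covariance, which keeps $\widehat R$ near 1 at
this length), 250–500 replicates at $n = 2000$ for the
$\chi^2$ calibration of the minimized quadratic inference function. At
these sizes the Monte-Carlo standard error of a bias estimate at
$n = 500$ is about $0.005$ and of a coverage estimate about $1.7$
percentage points; reported tolerances include that noise.

## Known limitations

* Only right-censored data and the survival-probability functional;
  restricted-mean, competing-risks and multi-state pseudo-values are out
  of scope, as are time-varying covariates and links other than cloglog.
* The sandwich variance is mildly conservative for pseudo-values; the
  (numerically small) jackknife-style correction is not implemented.
* The approximate-jackknife variance option found in some GEE software is
  not implemented; for the sample sizes studied the estimators are
  equivalent.
* Basis sets are limited to the three named structures; arbitrary
  user-supplied bases are deliberately not exposed.
* The pseudo-likelihood supports no prediction; use the piecewise
  exponential benchmark when a full generative model is needed.

## A worked call

```{r, eval = FALSE}
library(pseudoGMM)

sc <- scenario(n = 500, beta1 = -0.3, target_cr = 0.2, K = 5, nsim = 1)
trial <- generate_trial(sc, seed = 1)
grid <- select_time_grid(trial, K = 5)
po <- pseudo_obs_matrix(trial, grid)
des <- build_design(trial, grid)

fit_gmm(po, des, basis = "ind")
fit_gmm_bayes(po, des, basis = "ind", thresholds = log(1.43), seed = 1)
```
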