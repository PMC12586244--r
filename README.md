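# pseudoGMM

Hazard-ratio inference from right-censored survival data via jackknife
Kaplan–Meier **pseudo-observations** and the **generalized method of
moments (GMM)** — frequentist (quadratic inference functions) and
Bayesian (moment-based pseudo-likelihood MCMC) — with the standard
benchmarks (Cox proportional hazards, pseudo-observation GEE, Bayesian
piecewise exponential model) and a calibrated clinical-trial simulator.

## Who this is for

Biostatisticians who want Bayesian inference on a hazard ratio *without
specifying a baseline hazard*. The usual Bayesian survival models carry
the baseline as nuisance parameters (piecewise-constant, splines, Gamma
process, ...). Pseudo-observations remove it instead: the censored outcome
is transformed, once, into per-subject per-time jackknife values

y_ik = n·Ŝ(t_k) − (n−1)·Ŝ^{−i}(t_k),

where Ŝ is the Kaplan–Meier estimator and Ŝ^{−i} its leave-one-out refit.
Regressing the y_ik on covariates under the complementary log-log link,

cloglog E(y_ik | X_i) = log H₀(t_k) + X_iᵀβ,

turns β into Cox-model log hazard ratios, with the baseline absorbed by
an intercept and K−1 time dummies. The marginal model is classically fit
by GEE, which has no likelihood; this package additionally fits it by GMM,
whose quadratic inference function

Q_n(β) = U_nᵀ C_n⁻¹ U_n,  U_n = (1/n) Σᵢ uᵢ(β),  C_n = (1/n²) Σᵢ uᵢuᵢᵀ,

behaves asymptotically like −2 log L and therefore *does* admit a Bayesian
version: the pseudo-likelihood exp{−½ U_nᵀ Σ_n⁻¹ U_n} with
Σ_n = C_n − U_nU_nᵀ/n, combined with weakly informative priors and sampled
by adaptive random-walk Metropolis with carefully built starting values
(the support of the pseudo-likelihood is restricted; see the vignette).

## Worked example

Simulate one core-scenario trial (n = 500, 20% censoring, true log
HR = −0.3), transform it, and fit:

```r
library(pseudoGMM)

sc    <- scenario(n = 500, beta1 = -0.3, target_cr = 0.2, K = 5, nsim = 1)
trial <- generate_trial(sc, seed = 1)
grid  <- select_time_grid(trial, K = 5)
po    <- pseudo_obs_matrix(trial, grid)
des   <- build_design(trial, grid)

fit_gmm(po, des, basis = "ind")
#> gmm fit [ind] (6 iterations, converged)
#>           estimate     se  ci_low ci_high
#> intercept  -1.8329 0.1352 -2.0979 -1.5679
#> treatment  -0.1989 0.1138 -0.4219  0.0241
#> time2       0.7691 0.0935  0.5858  0.9524
#> time3       1.2892 0.1090  1.0755  1.5028
#> time4       1.7315 0.1171  1.5019  1.9611
#> time5       2.1871 0.1234  1.9453  2.4290
```

The `treatment` row is the log hazard ratio: −0.199 (HR ≈ 0.82) with
robust SE 0.114 — one draw from a design whose truth is −0.3. The time
rows are log cumulative-baseline-hazard contrasts against the first grid
time and are adjustment-only. The Bayesian fit adds the posterior and
tail probabilities for decision thresholds, here a non-inferiority margin
of HR = 1.43:

```r
fit_gmm_bayes(po, des, basis = "ind", thresholds = log(1.43), seed = 1,
              chains = 3, iters = 2000, warmup = 1000, thin = 2)
#> Bayesian GMM fit (pseudo-likelihood, adaptive Metropolis)
#>   coefficient    mean  median     sd   lower   upper   rhat      ess
#> 1   intercept -1.8803 -1.8688 0.1520 -2.2048 -1.6092 1.0102 177.3181
#> 2   treatment -0.1950 -0.1977 0.1187 -0.4422  0.0476 1.0128 256.3242
#> ...
#> tail probabilities for treatment :
#>   threshold prob mcse
#> 1    0.3577    1    0
```

P(log HR < log 1.43) = 1 to Monte-Carlo precision: the treatment is
non-inferior with near certainty in this draw. `fit_cox(trial)` gives
−0.212 (SE 0.100) on the same data, and `fit_gee(po, des, "ind")`
reproduces the GMM point estimates exactly (the independence basis is
exactly identified — a built-in cross-check).

Simulation studies run through `run_study(scenario(...), methods =
c("cox", "gee", "gmm", "pem", "bayes-gmm"))`, which returns a
per-method table of bias, ASE, ASD, RMSE and coverage with Monte-Carlo
standard errors.

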