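#' Working correlation matrix
#'
#' Builds the K x K working correlation used by the GEE fitter:
#' independence (identity), exchangeable (1 on the diagonal, alpha
#' elsewhere) or first-order autoregressive (alpha^|k-l|).
#'
#' @param kind One of `"ind"`, `"exch"`, `"ar1"`.
#' @param K Cluster size (number of grid times).
#' @param alpha Correlation nuisance parameter (ignored for `"ind"`).
#' @return K x K correlation matrix.
#' @export
working_correlation <- function(kind = c("ind", "exch", "ar1"), K, alpha = 0) {
  kind <- match.arg(kind)
  switch(kind,
         ind = diag(K),
         exch = {
           R <- matrix(alpha, K, K); diag(R) <- 1; R
         },
         ar1 = alpha^abs(outer(seq_len(K), seq_len(K), "-")))
}

alpha_bounds <- function(kind, K) {
  if (kind == "exch") c(-1 / (K - 1), 1) else c(-1, 1)
}

#' Moment estimator of the working correlation parameter
#'
#' Estimates alpha from raw residuals under an identity variance function:
#' the residual scale is the mean squared residual over all cells, and
#' alpha is the average standardized cross-product over all within-subject
#' pairs (exchangeable) or lag-1 pairs (AR-1). Estimates outside the valid
#' range of the structure are clamped (with a warning) just inside it.
#'
#' @param residuals n x K matrix of raw residuals y - mu.
#' @param kind `"exch"` or `"ar1"`.
#' @return Scalar alpha estimate.
#' @export
estimate_alpha <- function(residuals, kind = c("exch", "ar1")) {
  kind <- match.arg(kind)
  K <- ncol(residuals)
  if (K < 2L) stop("alpha estimation needs at least two time points")
  sigma2 <- mean(residuals^2)
  if (sigma2 <= 0) return(0)
  if (kind == "exch") {
    cp <- crossprod(residuals)             # K x K sums over subjects
    num <- (sum(cp) - sum(diag(cp))) / 2   # all pairs k < l
    alpha <- num / (nrow(residuals) * K * (K - 1) / 2) / sigma2
  } else {
    num <- sum(residuals[, -K] * residuals[, -1L])
    alpha <- num / (nrow(residuals) * (K - 1)) / sigma2
  }
  b <- alpha_bounds(kind, K)
  eps <- 1e-6
  if (alpha >= b[2]) {
    warning(sprintf("alpha estimate %.3f at/above upper bound; clamped", alpha))
    alpha <- b[2] - eps
  } else if (alpha <= b[1]) {
    warning(sprintf("alpha estimate %.3f at/below lower bound; clamped", alpha))
    alpha <- b[1] + eps
  }
  alpha
}

#' Fit the marginal cloglog model to pseudo-observations by GEE
#'
#' Solves the generalized estimating equations
#' \deqn{\sum_i D_i^\top R(\alpha)^{-1} (y_i - \mu_i(\beta)) = 0}
#' by Fisher scoring with step-halving, alternating with moment estimation
#' of the correlation nuisance parameter alpha for the exchangeable and
#' AR-1 working structures. The variance function is the identity (raw
#' residuals), the standard choice for pseudo-values, which lie outside
#' `[0, 1]`. Standard errors come from the robust sandwich covariance
#' \eqn{\Gamma_0^{-1}\Gamma_1\Gamma_0^{-1}/n} with empirical
#' \eqn{\Gamma_0,\Gamma_1}; 95% confidence limits use normal quantiles.
#'
#' @param pseudo A `"pseudo_obs"` object.
#' @param design The matching `"design_set"`.
#' @param structure Working correlation: `"ind"`, `"exch"` or `"ar1"`.
#' @param start Optional starting coefficients; defaults to the
#'   truncated-cloglog least-squares values of [starting_values()].
#' @param tol Convergence tolerance on `max |delta beta|` (default 1e-8).
#' @param maxit Maximum Fisher-scoring iterations (default 100).
#' @return A `"pgmm_fit"`: coefficients, sandwich covariance, SEs, Wald
#'   95% CIs, convergence flag, iteration count, final score norm
#'   (`objective`) and the estimated `alpha`.
#' @export
fit_gee <- function(pseudo, design, structure = c("ind", "exch", "ar1"),
                    start = NULL, tol = 1e-8, maxit = 100L) {
  structure <- match.arg(structure)
  Y <- po_values(pseudo, design)
  n <- design$n; K <- design$K; L <- design$L
  if (structure != "ind" && K < 2L) stop("'exch'/'ar1' require K >= 2")
  Xk <- design_slices(design)
  yvec <- as.vector(t(Y))                  # subject-major, matching design rows
  beta <- if (is.null(start)) starting_values(pseudo, design) else as.numeric(start)
  alpha <- 0

  gee_pieces <- function(beta, Rinv) {
    mm <- mean_and_jacobian(beta, design)
    rmat <- Y - mm$mu
    wmat <- matrix(mm$w, n, K, byrow = TRUE)
    rR <- rmat %*% Rinv
    # per-subject scores s_i = D_i' Rinv r_i, rows of s
    s <- matrix(0, n, L)
    for (k in seq_len(K)) s <- s + Xk[[k]] * (wmat[, k] * rR[, k])
    # A = sum_i D_i' Rinv D_i
    A <- matrix(0, L, L)
    for (k in seq_len(K)) for (l in seq_len(K)) {
      if (Rinv[k, l] != 0) {
        A <- A + Rinv[k, l] * crossprod(Xk[[k]] * wmat[, k], Xk[[l]] * wmat[, l])
      }
    }
    list(s = s, A = A, rmat = rmat, score = colSums(s))
  }

  converged <- FALSE
  it <- 0L
  Rinv <- diag(K)
  pieces <- NULL
  for (it in seq_len(maxit)) {
    if (structure != "ind") {
      mm <- mean_and_jacobian(beta, design)
      alpha <- suppressWarnings(estimate_alpha(Y - mm$mu, structure))
      Rinv <- solve(working_correlation(structure, K, alpha))
    }
    pieces <- gee_pieces(beta, Rinv)
    sol <- tryCatch(solve(pieces$A, pieces$score), error = function(e) NULL)
    if (is.null(sol)) stop("design rank deficient: singular GEE information matrix")
    score_norm <- sqrt(sum(pieces$score^2))
    step <- 1
    for (h in 0:20) {
      cand <- beta + step * sol
      cand_norm <- sqrt(sum(gee_pieces(cand, Rinv)$score^2))
      if (cand_norm <= score_norm || h == 20L) break
      step <- step / 2
    }
    delta <- step * sol
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("GEE did not converge in ", maxit, " iterations")

  pieces <- gee_pieces(beta, Rinv)
  Ainv <- solve(pieces$A)
  cov <- Ainv %*% crossprod(pieces$s) %*% Ainv
  new_frequentist_fit(
    method = "gee", labels = design$labels, beta = beta, cov = cov,
    converged = converged, n_iter = it,
    objective = sqrt(sum(pieces$score^2)),
    extra = list(structure = structure,
                 alpha = if (structure == "ind") NA_real_ else alpha))
}
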