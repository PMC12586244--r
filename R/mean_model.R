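#' Complementary log-log link and its inverse
#'
#' `cloglog(x) = log(-log(x))` maps survival probabilities to the linear
#' predictor scale on which regression coefficients are Cox log hazard
#' ratios; `inv_cloglog(x) = exp(-exp(x))` maps back.
#'
#' @param x Numeric vector; for `cloglog`, values strictly inside (0, 1).
#' @return Numeric vector.
#' @examples
#' cloglog(exp(-1))      # 0
#' inv_cloglog(0)        # exp(-1)
#' @export
cloglog <- function(x) {
  if (any(x <= 0 | x >= 1)) stop("cloglog is defined on (0, 1) only")
  log(-log(x))
}

#' @rdname cloglog
#' @export
inv_cloglog <- function(x) exp(-exp(x))

#' Marginal model design over subjects and grid times
#'
#' Expands a survival sample into the regression design of the marginal
#' cloglog model for pseudo-observations: each subject contributes K rows
#' (one per grid time) holding an intercept, the treatment indicator, K - 1
#' time dummies with the first grid time as reference (its log cumulative
#' baseline hazard is absorbed by the intercept), and any extra baseline
#' covariates repeated across times. With P covariate columns including the
#' intercept, the parameter count is L = P + K - 1.
#'
#' @param sample A [survival_sample()]; the first covariate column must be a
#'   0/1 treatment indicator.
#' @param grid A `"time_grid"` or numeric vector of grid times.
#' @return Object of class `"design_set"`: list with `X` ((n K) x L matrix,
#'   subject-major row order), `subject` (row-to-subject index), `n`, `K`,
#'   `L`, `P` and `labels`.
#' @export
build_design <- function(sample, grid) {
  stop_if_not_sample(sample)
  grid <- as_time_grid(grid)
  trt <- sample$covariates[, 1L]
  if (!all(trt %in% c(0, 1))) stop("treatment column must be coded 0/1")
  n <- sample$n
  K <- grid$K
  P <- 1L + ncol(sample$covariates)
  L <- P + K - 1L
  nK <- n * K
  subject <- rep(seq_len(n), each = K)
  kidx <- rep(seq_len(K), times = n)
  X <- matrix(0, nK, L)
  X[, 1L] <- 1
  X[, 2L] <- trt[subject]
  if (K >= 2L) {
    for (k in 2:K) X[kidx == k, 1L + k] <- 1
  }
  extra_labels <- character(0)
  if (ncol(sample$covariates) > 1L) {
    extras <- sample$covariates[, -1L, drop = FALSE]
    X[, (K + 2L):L] <- extras[subject, , drop = FALSE]
    extra_labels <- colnames(sample$covariates)[-1L]
  }
  labels <- c("intercept", "treatment",
              if (K >= 2L) paste0("time", 2:K), extra_labels)
  colnames(X) <- labels
  structure(list(X = X, subject = subject, time_index = kidx,
                 n = n, K = K, L = L, P = P, labels = labels, grid = grid),
            class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat(sprintf("design_set: n = %d subjects x K = %d times, L = %d parameters (%s)\n",
              x$n, x$K, x$L, paste(x$labels, collapse = ", ")))
  invisible(x)
}

# Linear predictors are clipped to +/- ETA_CLIP before exponentiation so the
# mean stays strictly inside (0, 1) in double precision; the bound is far
# outside any realistic hazard-ratio scale.
ETA_CLIP <- 30

#' Model means and Jacobian under the inverse cloglog link
#'
#' Evaluates mu_ik = exp(-exp(eta_ik)) with eta = X beta, and the analytic
#' Jacobian d mu / d beta whose row for cell (i, k) is
#' `-exp(eta_ik) * mu_ik * X_ik`. Linear predictors are clipped to +/- 30
#' before exponentiation (documented numerical guard).
#'
#' @param beta Coefficient vector of length `design$L`.
#' @param design A `"design_set"` from [build_design()].
#' @return List with `mu` (n x K matrix), `D` ((n K) x L matrix stacking the
#'   per-subject K x L Jacobians in subject-major order), `eta` and `w`
#'   (the d mu / d eta weights).
#' @export
mean_and_jacobian <- function(beta, design) {
  if (length(beta) != design$L) stop("beta length must equal design$L")
  eta <- pmin(pmax(drop(design$X %*% beta), -ETA_CLIP), ETA_CLIP)
  ee <- exp(eta)
  mu_vec <- exp(-ee)
  w <- -ee * mu_vec
  D <- design$X * w
  mu <- matrix(mu_vec, nrow = design$n, ncol = design$K, byrow = TRUE)
  list(mu = mu, D = D, eta = eta, w = w)
}
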