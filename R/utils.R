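# Internal numerical helpers.

# Symmetric PSD inverse with a reciprocal-condition guard. Returns
# list(inv, ok): ok = FALSE when the matrix is numerically singular
# (rcond below `guard`) or not positive definite.
psd_inverse <- function(M, guard = 1e-12) {
  M <- (M + t(M)) / 2
  if (!all(is.finite(M))) return(list(inv = NULL, ok = FALSE))
  rc <- tryCatch(rcond(M), error = function(e) 0)
  if (!is.finite(rc) || rc < guard) return(list(inv = NULL, ok = FALSE))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(list(inv = NULL, ok = FALSE))
  list(inv = chol2inv(ch), ok = TRUE)
}

# Range-space (eigen) pseudoinverse of a symmetric PSD matrix. Eigenvalues
# below `rel_tol` times the largest are treated as exact zeros: with
# cluster-constant covariates the stacked moment covariance is structurally
# rank-deficient (the per-subject scores span at most K dimensions per
# distinct covariate profile), and the QIF / pseudo-likelihood quadratic
# forms are evaluated on the range space. Returns the eigen pieces so
# callers can project and count rank.
pinv_psd <- function(M, rel_tol = 1e-10) {
  M <- (M + t(M)) / 2
  if (!all(is.finite(M))) {
    return(list(inv = NULL, rank = 0L, lmax = NA_real_, ok = FALSE))
  }
  e <- eigen(M, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (lmax <= 0) {
    return(list(inv = NULL, rank = 0L, lmax = lmax, ok = FALSE))
  }
  keep <- e$values > rel_tol * lmax
  V <- e$vectors[, keep, drop = FALSE]
  inv <- V %*% (t(V) / e$values[keep])
  list(inv = inv, rank = sum(keep), lmax = lmax, ok = TRUE,
       vectors = e$vectors, values = e$values, keep = keep)
}

# Quadratic form U' M^+ U with an out-of-range guard: Inf when a
# non-negligible component of U lies in the null space of M (the moment
# vector cannot be weighted there) or when M is numerically zero.
quad_form_pinv <- function(U, pv, range_tol = 1e-8) {
  if (!pv$ok) return(structure(Inf, singular = TRUE))
  proj <- drop(crossprod(pv$vectors, U))
  out_mass <- sum(proj[!pv$keep]^2)
  if (out_mass > range_tol * max(sum(proj^2), .Machine$double.xmin)) {
    return(structure(Inf, singular = TRUE))
  }
  sum(proj[pv$keep]^2 / pv$values[pv$keep])
}

# Pseudo-observation values as an n x K matrix, validating conformity
# with a design built on the same sample and grid.
po_values <- function(pseudo, design) {
  if (!inherits(pseudo, "pseudo_obs")) stop("expected a 'pseudo_obs' object")
  Y <- pseudo$values
  if (nrow(Y) != design$n || ncol(Y) != design$K) {
    stop("pseudo-observation matrix and design are not conformable")
  }
  Y
}

# Split the stacked (nK) x L design into a list of K per-time n x L slices.
design_slices <- function(design) {
  lapply(seq_len(design$K), function(k)
    design$X[design$time_index == k, , drop = FALSE])
}

wald_ci <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(low = beta - z * se, high = beta + z * se)
}

new_frequentist_fit <- function(method, labels, beta, cov, converged,
                                n_iter, objective, extra = list()) {
  cov <- unname(as.matrix(cov))
  dimnames(cov) <- list(labels, labels)
  se <- sqrt(pmax(diag(cov), 0))
  ci <- wald_ci(beta, se)
  out <- c(list(method = method, labels = labels,
                beta = stats::setNames(beta, labels), cov = cov,
                se = stats::setNames(se, labels),
                ci_low = stats::setNames(ci$low, labels),
                ci_high = stats::setNames(ci$high, labels),
                converged = converged, n_iter = n_iter,
                objective = objective),
           extra)
  class(out) <- "pgmm_fit"
  out
}

#' @export
print.pgmm_fit <- function(x, ...) {
  cat(sprintf("%s fit%s (%d iterations, %s)\n", x$method,
              if (!is.null(x$structure)) paste0(" [", x$structure, "]") else "",
              x$n_iter,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  tab <- data.frame(estimate = x$beta, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, 4))
  invisible(x)
}
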