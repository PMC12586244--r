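#' Basis matrices for the inverse working correlation
#'
#' The generalized method of moments expands the inverse working
#' correlation as a linear combination of J symmetric 0/1 basis matrices.
#' Independence uses the identity alone (J = 1); exchangeable adds the
#' matrix with 0 on the diagonal and 1 elsewhere; AR-1 adds the matrix
#' with 1 on the first sub- and super-diagonals (J = 2). The combination
#' coefficients are never estimated: the quadratic-inference-function
#' weighting absorbs them.
#'
#' @param kind `"ind"`, `"exch"` or `"ar1"`.
#' @param K Number of grid times (>= 2 for `"exch"`/`"ar1"`).
#' @return Object of class `"basis_set"`: list with `kind`, `K`, `J` and
#'   `matrices` (list of K x K matrices, the first being the identity).
#' @export
basis_set <- function(kind = c("ind", "exch", "ar1"), K) {
  kind <- match.arg(kind)
  K <- as.integer(K)
  if (kind != "ind" && K < 2L) stop("'exch'/'ar1' bases require K >= 2")
  mats <- list(diag(K))
  if (kind == "exch") {
    mats[[2]] <- matrix(1, K, K) - diag(K)
  } else if (kind == "ar1") {
    M2 <- matrix(0, K, K)
    M2[cbind(1:(K - 1), 2:K)] <- 1
    M2[cbind(2:K, 1:(K - 1))] <- 1
    mats[[2]] <- M2
  }
  structure(list(kind = kind, K = K, J = length(mats), matrices = mats),
            class = "basis_set")
}

# Per-subject stacked scores u_i = {D_i' M_j (y_i - mu_i)}_j as rows of an
# n x (J L) matrix, plus U, C and the Gauss-Newton moment Jacobian
# Ghat = dU/dbeta' = -(1/n) sum_i {D_i' M_j D_i}_j.
moment_pieces <- function(beta, Y, design, basis, Xk, want_jacobian = TRUE) {
  n <- design$n; K <- design$K; L <- design$L; J <- basis$J
  mm <- mean_and_jacobian(beta, design)
  rmat <- Y - mm$mu
  wmat <- matrix(mm$w, n, K, byrow = TRUE)
  s <- matrix(0, n, J * L)
  G <- if (want_jacobian) matrix(0, J * L, L) else NULL
  for (j in seq_len(J)) {
    M <- basis$matrices[[j]]
    rM <- rmat %*% M
    block <- matrix(0, n, L)
    for (k in seq_len(K)) block <- block + Xk[[k]] * (wmat[, k] * rM[, k])
    cols <- ((j - 1) * L + 1):(j * L)
    s[, cols] <- block
    if (want_jacobian) {
      Gj <- matrix(0, L, L)
      for (k in seq_len(K)) for (l in seq_len(K)) {
        if (M[k, l] != 0) {
          Gj <- Gj + M[k, l] * crossprod(Xk[[k]] * wmat[, k], Xk[[l]] * wmat[, l])
        }
      }
      G[cols, ] <- -Gj / n
    }
  }
  list(s = s, U = colSums(s) / n, C = crossprod(s) / n^2, G = G)
}

#' Stacked moment vector and empirical moment covariance
#'
#' Evaluates the GMM moment state at `beta`: the stacked score vector
#' `U = (1/n) sum_i u_i` over the basis-matrix moment conditions, and the
#' empirical covariance `C = (1/n^2) sum_i u_i u_i'`.
#'
#' @param beta Coefficient vector.
#' @param pseudo A `"pseudo_obs"` object.
#' @param design The matching `"design_set"`.
#' @param basis A [basis_set()].
#' @return List with `U` (length J L), `C` ((J L) x (J L)) and `scores`
#'   (n x (J L) per-subject score matrix).
#' @export
moment_state <- function(beta, pseudo, design, basis) {
  Y <- po_values(pseudo, design)
  mp <- moment_pieces(beta, Y, design, basis, design_slices(design),
                      want_jacobian = FALSE)
  list(U = mp$U, C = mp$C, scores = mp$s)
}

#' Quadratic inference function
#'
#' `Q(beta) = U' C^{-1} U`, the GMM objective. The empirical moment
#' covariance is inverted on its numerical range: with cluster-constant
#' covariates (e.g. a two-arm trial with no further covariates) the stacked
#' scores of the exchangeable and AR-1 bases are structurally confined to
#' a subspace, and the quadratic form is well defined there because the
#' moment vector lies in the same subspace. Returns `+Inf` (with attribute
#' `singular = TRUE`) when the covariance is numerically zero or the
#' moment vector leaves its range, signalling that `beta` is outside the
#' support.
#'
#' @inheritParams moment_state
#' @return Non-negative scalar, or `+Inf` outside the support.
#' @export
qif <- function(beta, pseudo, design, basis) {
  ms <- moment_state(beta, pseudo, design, basis)
  quad_form_pinv(ms$U, pinv_psd(ms$C))
}

#' Fit the marginal cloglog model by frequentist GMM
#'
#' Minimizes the quadratic inference function over the stacked basis-matrix
#' moment conditions with a Gauss-Newton/Fisher-type algorithm: at each
#' outer iteration the empirical moment covariance C is refreshed and held
#' fixed, the step solves the weighted least-squares linearization of U,
#' and step-halving enforces descent of Q. Under the independence basis the
#' system is exactly identified and the estimates coincide with GEE under
#' independence. The covariance of the estimates is the GMM sandwich
#' `[G' C^{-1} G]^{-1}` with `G = dU/dbeta'` evaluated analytically at the
#' optimum.
#'
#' @inheritParams fit_gee
#' @param basis A [basis_set()], or a structure name passed to [basis_set()].
#' @param start Starting coefficients; default [starting_values()] with
#'   `epsilon = 0.05`. Must lie inside the support (finite Q).
#' @param tol_q Convergence tolerance on `|delta Q|` (default 1e-10).
#' @return A `"pgmm_fit"` whose `objective` is the minimized Q value.
#' @export
fit_gmm <- function(pseudo, design, basis = "ind", start = NULL,
                    tol = 1e-8, tol_q = 1e-10, maxit = 100L) {
  if (is.character(basis)) basis <- basis_set(basis, design$K)
  Y <- po_values(pseudo, design)
  Xk <- design_slices(design)
  beta <- if (is.null(start)) starting_values(pseudo, design, epsilon = 0.05)
          else as.numeric(start)

  q_at <- function(b) {
    mp <- moment_pieces(b, Y, design, basis, Xk, want_jacobian = FALSE)
    as.numeric(quad_form_pinv(mp$U, pinv_psd(mp$C)))
  }

  q_cur <- q_at(beta)
  if (!is.finite(q_cur)) {
    stop("starting values outside the QIF support; supply 'start' from ",
         "starting_values() with a different epsilon")
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    mp <- moment_pieces(beta, Y, design, basis, Xk)
    inv <- pinv_psd(mp$C)
    if (!inv$ok) break
    H <- t(mp$G) %*% inv$inv %*% mp$G
    g <- t(mp$G) %*% inv$inv %*% mp$U
    dir <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(dir)) stop("design rank deficient: singular GMM Hessian")
    if (max(abs(dir)) < tol) { converged <- TRUE; break }
    # the fixed point of the fixed-C iteration sits within O(tol_q) of the
    # exact minimum of Q; allow that much slack in the descent check
    slack <- 1e-5 * (1 + abs(q_cur))
    step <- 1
    q_new <- Inf
    for (h in 0:20) {
      cand <- beta + step * dir
      q_new <- q_at(cand)
      if (is.finite(q_new) && q_new <= q_cur + slack) break
      step <- step / 2
    }
    if (!is.finite(q_new) || q_new > q_cur + slack) break  # no usable step
    delta <- step * dir
    beta <- beta + delta
    dq <- q_cur - q_new
    q_cur <- q_new
    if (abs(dq) < tol_q || max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("GMM did not converge in ", it, " iterations")

  mp <- moment_pieces(beta, Y, design, basis, Xk)
  inv <- pinv_psd(mp$C)
  if (!inv$ok) stop("moment covariance degenerate at the optimum")
  cov_inv <- t(mp$G) %*% inv$inv %*% mp$G
  cov <- tryCatch(solve(cov_inv), error = function(e)
    stop("design rank deficient: singular GMM covariance"))
  new_frequentist_fit(
    method = "gmm", labels = design$labels, beta = drop(beta),
    cov = (cov + t(cov)) / 2, converged = converged, n_iter = it,
    objective = q_cur,
    extra = list(structure = basis$kind, J = basis$J))
}
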