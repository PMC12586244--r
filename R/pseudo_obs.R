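#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function. Deaths tied at a time
#' all use the risk set just before that time; when an event and a censoring
#' share a time, the event is counted first (the censored subject is still
#' at risk). The returned step function is right-continuous and equals 1
#' before the first jump.
#'
#' @param sample A [survival_sample()].
#' @return An object of class `"km_curve"` with elements `jump_times`
#'   (ascending distinct event times), `surv` (survival at and after each
#'   jump), `n` and `no_events` (TRUE, with a warning, when the sample has
#'   no observed event so the curve is constant 1).
#' @seealso [km_eval()] to evaluate the curve.
#' @export
km_curve <- function(sample) {
  stop_if_not_sample(sample)
  km_fit(sample$time, sample$status)
}

# Internal product-limit fit from raw vectors; tolerates zero events because
# leave-one-out refits can remove the only event.
km_fit <- function(time, status) {
  n <- length(time)
  ev <- time[status == 1]
  if (length(ev) == 0L) {
    warning("no observed events: Kaplan-Meier curve is constant 1")
    return(structure(list(jump_times = numeric(0), surv = numeric(0),
                          n = n, no_events = TRUE),
                     class = "km_curve"))
  }
  jt <- sort(unique(ev))
  d <- vapply(jt, function(t) sum(time == t & status == 1), numeric(1))
  # risk set just before t: everyone with follow-up >= t
  r <- vapply(jt, function(t) sum(time >= t), numeric(1))
  surv <- cumprod(1 - d / r)
  structure(list(jump_times = jt, surv = surv, n = n, no_events = FALSE),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous evaluation: `km_eval(curve, t)` returns the survival
#' probability at `t`, equal to 1 strictly before the first jump.
#'
#' @param curve A `"km_curve"` object.
#' @param t Numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_eval <- function(curve, t) {
  if (!inherits(curve, "km_curve")) stop("expected a 'km_curve' object")
  if (curve$no_events || length(curve$jump_times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$jump_times)
  c(1, curve$surv)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, %d jump times", x$n, length(x$jump_times)))
  if (x$no_events) cat(" (no events; constant 1)")
  cat("\n")
  invisible(x)
}

#' Quantile-based time grid over the observed event times
#'
#' Selects `K` time points as type-1 empirical quantiles of the observed
#' event times at probabilities k/(K+1), k = 1..K, so that the K+1 intervals
#' they induce hold approximately equal numbers of events. Duplicate grid
#' points created by heavily tied event times are collapsed, reducing K
#' (flagged via the `reduced` element and a warning).
#'
#' @param sample A [survival_sample()].
#' @param K Number of time points (default 5).
#' @return An object of class `"time_grid"`: list with `points`
#'   (strictly increasing), `K` and `reduced`.
#' @export
select_time_grid <- function(sample, K = 5L) {
  stop_if_not_sample(sample)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  ev <- sample$time[sample$status == 1]
  n_distinct <- length(unique(ev))
  if (n_distinct < K) {
    stop(sprintf("grid needs at least %d distinct event times; sample has %d",
                 K, n_distinct))
  }
  pts <- unname(stats::quantile(ev, probs = seq_len(K) / (K + 1), type = 1))
  upts <- unique(pts)
  reduced <- length(upts) < K
  if (reduced) {
    warning(sprintf("tied event times collapsed the grid from %d to %d points",
                    K, length(upts)))
  }
  structure(list(points = upts, K = length(upts), reduced = reduced),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: K = %d points: %s\n", x$K,
              paste(signif(x$points, 5), collapse = ", ")))
  invisible(x)
}

as_time_grid <- function(x) {
  if (inherits(x, "time_grid")) return(x)
  x <- sort(as.numeric(x))
  if (any(x <= 0) || anyDuplicated(x)) stop("grid points must be positive and distinct")
  structure(list(points = x, K = length(x), reduced = FALSE), class = "time_grid")
}

#' Jackknife Kaplan-Meier pseudo-observations
#'
#' Computes, for every subject i and grid time t_k, the pseudo-value
#' \deqn{y_{ik} = n \hat S(t_k) - (n - 1) \hat S^{-i}(t_k),}
#' where \eqn{\hat S} is the full-sample Kaplan-Meier estimator and
#' \eqn{\hat S^{-i}} its leave-one-out refit. Without censoring the
#' pseudo-values reduce exactly to the survival indicators
#' \eqn{1\{T_i > t_k\}}; under censoring they spread outside `[0, 1]`
#' (subjects still at risk at t_k score above 1, subjects with an earlier
#' event score negative at later grid times).
#'
#' The computation is an O(n K + n log n) pass over the risk table: each
#' leave-one-out curve differs from the full curve only through decremented
#' risk (and, for an event subject, death) counts, so its log-survival is a
#' segment sum over precomputed per-jump log factors. It agrees with the
#' literal n-refit oracle [pseudo_obs_bruteforce()] to numerical precision.
#'
#' @param sample A [survival_sample()].
#' @param grid A `"time_grid"` (or numeric vector of times, each at most
#'   the largest observed event time).
#' @return Object of class `"pseudo_obs"`: list with `values` (n x K
#'   matrix), `grid`, `id`.
#' @export
pseudo_obs_matrix <- function(sample, grid) {
  stop_if_not_sample(sample)
  grid <- as_time_grid(grid)
  time <- sample$time
  status <- sample$status
  n <- sample$n
  ev_max <- max(time[status == 1])
  if (any(grid$points > ev_max)) {
    stop("grid points must not exceed the largest observed event time")
  }

  jt <- sort(unique(time[status == 1]))
  m <- length(jt)
  d <- vapply(jt, function(t) sum(time == t & status == 1), numeric(1))
  r <- vapply(jt, function(t) sum(time >= t), numeric(1))

  lf_full <- log1p(-d / r)
  # factor at jump j after removing one at-risk non-event subject; r == 1
  # only happens when that subject is the event itself (handled separately)
  lf_drop <- numeric(m)
  lf_evt <- numeric(m)
  idx <- which(r > 1)
  lf_drop[idx] <- log1p(-pmin(d[idx] / (r[idx] - 1), 1))
  # factor after removing a subject whose event is at jump j
  lf_evt[idx] <- log1p(-(d[idx] - 1) / (r[idx] - 1))

  Cfull <- c(0, cumsum(lf_full))
  Cdrop <- c(0, cumsum(lf_drop))

  idx_t <- findInterval(grid$points, jt)      # jumps <= t_k
  idx_i <- findInterval(time, jt)             # jumps <= T_i (at-risk jumps)
  own <- ifelse(status == 1, match(time, jt), NA_integer_)

  S_full <- exp(Cfull[idx_t + 1L])
  Y <- matrix(NA_real_, n, grid$K)
  for (k in seq_len(grid$K)) {
    b <- pmin(idx_t[k], idx_i)
    logS <- Cdrop[b + 1L] + (Cfull[idx_t[k] + 1L] - Cfull[b + 1L])
    fix <- which(status == 1 & own <= idx_t[k])
    if (length(fix)) {
      logS[fix] <- logS[fix] + lf_evt[own[fix]] - lf_drop[own[fix]]
    }
    # -Inf segments can cancel to NaN in the cumsum differences; resum those
    # few cells directly
    bad <- which(is.nan(logS))
    for (i in bad) {
      bi <- min(idx_t[k], idx_i[i])
      lf <- lf_drop[seq_len(bi)]
      if (status[i] == 1 && !is.na(own[i]) && own[i] <= bi) lf[own[i]] <- lf_evt[own[i]]
      tail_sum <- if (idx_t[k] > bi) sum(lf_full[(bi + 1L):idx_t[k]]) else 0
      logS[i] <- sum(lf) + tail_sum
    }
    Y[, k] <- n * S_full[k] - (n - 1) * exp(logS)
  }
  structure(list(values = Y, grid = grid, id = sample$id),
            class = "pseudo_obs")
}

#' Brute-force pseudo-observations (leave-one-out oracle)
#'
#' Literal implementation of the jackknife definition: n full Kaplan-Meier
#' refits, each excluding one subject. O(n^2) and intended as the reference
#' oracle for [pseudo_obs_matrix()] on small samples.
#'
#' @inheritParams pseudo_obs_matrix
#' @return Same structure as [pseudo_obs_matrix()].
#' @export
pseudo_obs_bruteforce <- function(sample, grid) {
  stop_if_not_sample(sample)
  grid <- as_time_grid(grid)
  n <- sample$n
  full <- km_fit(sample$time, sample$status)
  S_full <- km_eval(full, grid$points)
  Y <- matrix(NA_real_, n, grid$K)
  for (i in seq_len(n)) {
    loo <- suppressWarnings(km_fit(sample$time[-i], sample$status[-i]))
    Y[i, ] <- n * S_full - (n - 1) * km_eval(loo, grid$points)
  }
  structure(list(values = Y, grid = grid, id = sample$id),
            class = "pseudo_obs")
}

#' @export
print.pseudo_obs <- function(x, ...) {
  cat(sprintf("pseudo_obs: %d subjects x %d time points; value range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}
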