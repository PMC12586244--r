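#' Construct a right-censored survival sample
#'
#' Bundles subject-level follow-up times, event indicators and covariates
#' into a validated container used by every other function in the package.
#' In the two-arm trial setting the first covariate column is the treatment
#' indicator coded 0 (control) / 1 (experimental).
#'
#' @param time Positive numeric vector of event or censoring times.
#' @param status Integer/numeric vector with 1 = event, 0 = censored.
#' @param covariates Numeric matrix (or vector, coerced to a one-column
#'   matrix) with one row per subject. The first column is the treatment
#'   indicator in two-arm analyses.
#' @param id Optional subject labels; defaults to `1:n`.
#'
#' @return An object of class `"survival_sample"`: a list with elements
#'   `id`, `time`, `status`, `covariates` and `n`.
#' @examples
#' s <- survival_sample(time = c(2, 5, 3, 7), status = c(1, 0, 1, 1),
#'                      covariates = c(0, 0, 1, 1))
#' s$n
#' @export
survival_sample <- function(time, status, covariates, id = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  n <- length(time)
  if (n < 1L) stop("empty sample")
  if (length(status) != n) stop("'time' and 'status' lengths differ")
  if (anyNA(time) || anyNA(status)) stop("missing values in time or status")
  if (any(time <= 0)) {
    stop("all times must be > 0; offending row(s): ",
         paste(which(time <= 0), collapse = ", "))
  }
  bad <- which(!(status %in% c(0, 1)))
  if (length(bad)) {
    stop("status must be 0 or 1; offending row(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(dim(covariates))) covariates <- matrix(as.numeric(covariates), ncol = 1L)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n) stop("covariate rows must match number of subjects")
  if (anyNA(covariates)) stop("missing values in covariates")
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- c("treatment",
                              if (ncol(covariates) > 1L)
                                paste0("covariate", seq_len(ncol(covariates) - 1L)))
  }
  if (sum(status) < 1) stop("sample contains no observed events")
  if (is.null(id)) id <- seq_len(n)
  if (length(id) != n) stop("'id' length must match number of subjects")
  structure(list(id = id, time = time, status = status,
                 covariates = covariates, n = n),
            class = "survival_sample")
}

#' @export
print.survival_sample <- function(x, ...) {
  cat(sprintf("survival_sample: %d subjects, %d events (%.1f%% censored), %d covariate(s)\n",
              x$n, sum(x$status), 100 * mean(x$status == 0), ncol(x$covariates)))
  invisible(x)
}

is_survival_sample <- function(x) inherits(x, "survival_sample")

stop_if_not_sample <- function(x) {
  if (!is_survival_sample(x)) stop("expected a 'survival_sample' object")
  invisible(x)
}
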