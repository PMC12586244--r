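#' Read a survival sample from CSV
#'
#' Expects a header with columns `id`, `time`, `status`, `arm` (0/1
#' treatment indicator); any further columns become additional baseline
#' covariates in header order. Malformed rows are reported by number.
#'
#' @param path CSV file path.
#' @return A [survival_sample()] whose first covariate column is `arm`
#'   relabelled `treatment`.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time", "status", "arm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$time)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$time))))
    stop("non-numeric time in row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(!(df$status %in% c(0, 1)))
  if (length(bad)) {
    stop("status outside {0,1} in row(s): ", paste(bad, collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  cov <- as.matrix(cbind(treatment = df$arm,
                         df[, extra, drop = FALSE]))
  survival_sample(time = df$time, status = df$status, covariates = cov,
                  id = df$id)
}

#' Write a simulated or imported sample to CSV
#'
#' @param sample A [survival_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(sample, path) {
  stop_if_not_sample(sample)
  df <- data.frame(id = sample$id, time = sample$time, status = sample$status,
                   arm = sample$covariates[, 1L])
  if (ncol(sample$covariates) > 1L) {
    df <- cbind(df, sample$covariates[, -1L, drop = FALSE])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write pseudo-observations to CSV
#'
#' @param pseudo A `"pseudo_obs"` object.
#' @param path Output path.
#' @param format `"long"` (id, t_index, t_value, pseudo) or `"wide"`
#'   (one row per subject, one column per grid time).
#' @return `path`, invisibly.
#' @export
write_pseudo_csv <- function(pseudo, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!inherits(pseudo, "pseudo_obs")) stop("expected a 'pseudo_obs' object")
  K <- pseudo$grid$K
  if (format == "long") {
    df <- data.frame(id = rep(pseudo$id, each = K),
                     t_index = rep(seq_len(K), times = nrow(pseudo$values)),
                     t_value = rep(pseudo$grid$points, times = nrow(pseudo$values)),
                     pseudo = as.vector(t(pseudo$values)))
  } else {
    df <- data.frame(id = pseudo$id, pseudo$values)
    names(df)[-1] <- paste0("t", seq_len(K))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

fit_to_report <- function(fit, config = list()) {
  if (inherits(fit, "pgmm_fit")) {
    list(method = fit$method,
         structure = if (!is.null(fit$structure)) fit$structure else NULL,
         coefficients = data.frame(
           label = fit$labels, estimate = unname(fit$beta),
           se = unname(fit$se), ci_low = unname(fit$ci_low),
           ci_high = unname(fit$ci_high)),
         converged = fit$converged, n_iter = fit$n_iter,
         objective = fit$objective, config = config)
  } else if (inherits(fit, "pgmm_bayes_fit")) {
    d <- fit$draws
    list(method = "bayes",
         coefficients = data.frame(
           label = fit$summary$coefficient, estimate = fit$summary$mean,
           median = fit$summary$median, se = fit$summary$sd,
           ci_low = fit$summary$lower, ci_high = fit$summary$upper,
           rhat = fit$summary$rhat, ess = fit$summary$ess),
         tail_probabilities = fit$tail,
         sampler = list(chains = d$chains, iters = d$iters,
                        warmup = d$warmup, thin = d$thin, seed = d$seed,
                        epsilons = d$epsilons, accept = d$accept,
                        support_rejections = d$support_rejections),
         config = config)
  } else {
    stop("unsupported fit object")
  }
}

#' Write a fit report to JSON
#'
#' Serializes a frequentist or Bayesian fit, with full numeric precision
#' and a config echo sufficient to rerun the analysis, to a JSON file that
#' round-trips losslessly through [read_report()].
#'
#' @param fit A `"pgmm_fit"` or `"pgmm_bayes_fit"`.
#' @param path Output path.
#' @param config Optional named list echoed verbatim into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, config = list()) {
  jsonlite::write_json(fit_to_report(fit, config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
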