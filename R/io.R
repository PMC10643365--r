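# Plain-text interchange: BOLD series as TSV, designs and network specs as
# JSON, fits as structured JSON.

#' Read / write a regional BOLD time series
#'
#' TSV with header `time_s, A1, pSTS, pOp, M1`, one row per volume.
#'
#' @param path File path.
#' @param data BOLD tibble (as from [predict_bold()]).
#' @param TR Repetition time recorded alongside (attribute; inferred from
#'   `time_s` spacing on read if absent).
#' @return `read_bold_tsv()` returns the tibble with attribute `TR`;
#'   `write_bold_tsv()` returns `path` invisibly.
#' @export
read_bold_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("time_s", "A1", "pSTS", "pOp", "M1")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df[need])
  if (anyNA(out)) stop("missing values in ", path, call. = FALSE)
  attr(out, "TR") <- if (nrow(out) > 1) diff(out$time_s[1:2]) else NA_real_
  out
}

#' @rdname read_bold_tsv
#' @export
write_bold_tsv <- function(data, path, TR = attr(data, "TR")) {
  utils::write.table(data, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a stimulus design as JSON
#'
#' @param design A [stimulus_design()].
#' @param path File path.
#' @return The design (read) or `path` invisibly (write).
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_design(
    block_onsets = x$block_onsets, block_durations = x$block_durations,
    TR = x$TR, n_volumes = x$n_volumes,
    microtime_bins_per_TR = x$microtime_bins_per_TR %||% 16L,
    event_onsets = x$event_onsets, event_durations = x$event_durations
  )
}

#' Serialise a DCM fit to JSON
#'
#' Stores the flattened posterior mean, the covariance (row-major), the noise
#' log-precisions, the free energy and the accepted-step trace.
#'
#' @param fit A `dcm_fit`.
#' @param path File path.
#' @return `path` invisibly; `read_fit_json()` returns a list with a
#'   reconstructed `belief`, `lambda`, `free_energy`, `trace`.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      mean = as.list(setNames(unname(fit$belief$mean), names(fit$belief$mean))),
      covariance = as.vector(t(fit$belief$cov)),
      dimension = length(fit$belief$mean),
      lambda = fit$lambda,
      lambda_var = fit$lambda_var,
      free_energy = fit$free_energy,
      trace = fit$trace,
      n_iterations = fit$n_iterations,
      converged = fit$converged,
      scale = fit$scale
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$dimension
  mean <- unlist(x$mean)
  cov <- matrix(x$covariance, p, p, byrow = TRUE)
  list(
    belief = gaussian_belief(mean, cov),
    lambda = x$lambda, lambda_var = x$lambda_var,
    free_energy = x$free_energy, trace = x$trace,
    n_iterations = x$n_iterations, converged = x$converged, scale = x$scale
  )
}
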