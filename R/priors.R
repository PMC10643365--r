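#' Gaussian belief over a parameter vector
#'
#' @param mean Named numeric vector.
#' @param cov Symmetric positive-definite covariance matrix of matching
#'   dimension (a numeric vector is taken as a diagonal).
#' @return An object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, cov) {
  if (!is.matrix(cov)) cov <- diag(x = rep_len(cov, length(mean)), nrow = length(mean))
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  if (max(abs(cov - t(cov))) > 1e-10) {
    stop("covariance is not symmetric", call. = FALSE)
  }
  cov <- (cov + t(cov)) / 2
  ev <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("covariance is not positive definite", call. = FALSE)
  dimnames(cov) <- list(names(mean), names(mean))
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("<gaussian_belief> dimension", length(x$mean), "\n")
  invisible(x)
}

#' Default shrinkage priors for the speech repetition DCM
#'
#' Every parameter has prior mean 0, so at the prior mean all extrinsic
#' connections are absent, the effective self-connections sit at their
#' -0.5 Hz default (precluding run-away excitation), and the hemodynamics are
#' at their nominal constants. Prior variances: extrinsic rates 0.25
#' (sd 0.5 Hz, >95% mass in [-1, 1] Hz), self log-scalings 1/16, input gain 1,
#' hemodynamic log-scalings 1/64. The per-region noise log-precisions have a
#' Gaussian hyperprior with mean 0 (unit noise variance) and variance 1/8.
#'
#' @param spec A [network_spec()].
#' @return A list with elements `belief` (a [gaussian_belief()]) and `lambda`
#'   (hyperprior `mean` and `var` for the noise log-precisions).
#' @export
default_priors <- function(spec) {
  nm <- param_names(spec)
  n_ext <- length(nm) - 13L
  v <- c(rep(0.25, n_ext), rep(1 / 16, 4), 1, rep(1 / 64, 8))
  list(
    belief = gaussian_belief(setNames(numeric(length(nm)), nm), v),
    lambda = list(mean = 0, var = 1 / 8)
  )
}
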