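#' Hemodynamic model constants
#'
#' Fixed constants of the balloon-Windkessel observation model at 3 T with a
#' 30 ms echo time: signal decay kappa0 = 0.64 1/s, autoregulation
#' gamma = 0.32 1/s, transit time tau0 = 2.0 s, Grubb exponent alpha = 0.32,
#' resting oxygen extraction E0 = 0.4, resting venous volume fraction
#' V0 = 0.04, and BOLD coefficients k1 = 4.3 * nu0 * E0 * TE
#' (nu0 = 40.3 1/s), k2 = epsilon * r0 * E0 * TE (r0 = 25 1/s, epsilon = 1),
#' k3 = 1 - epsilon. Only the per-region decay and transit log-scalings are
#' estimated; everything here is fixed.
#'
#' @param TE Echo time in seconds.
#' @return A named list of constants.
#' @export
hemo_constants <- function(TE = 0.030) {
  nu0 <- 40.3; r0 <- 25; epsilon <- 1
  list(
    kappa0 = 0.64, gamma = 0.32, tau0 = 2.0, alpha = 0.32,
    E0 = 0.4, V0 = 0.04, TE = TE,
    k1 = 4.3 * nu0 * 0.4 * TE,
    k2 = epsilon * r0 * 0.4 * TE,
    k3 = 1 - epsilon
  )
}

#' Integrate the neural state equation
#'
#' Solves dx/dt = A x + C u exactly on each microtime bin (matrix exponential
#' propagation with the input held constant within a bin), from x(0) = 0.
#'
#' @param A 4x4 (or R x R) rate matrix in Hz; must be stable (eigenvalues with
#'   negative real part) for bounded output.
#' @param C Input gain vector (Hz per unit input), one entry per region.
#' @param u Input on the microtime grid, e.g. from [build_input()].
#' @param dt Bin width in seconds (defaults to `attr(u, "dt")`).
#' @return Matrix of neural states, `(length(u) + 1) x R`, on the grid
#'   t = 0, dt, ..., with attribute `dt`.
#' @export
integrate_neural <- function(A, C, u, dt = attr(u, "dt")) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), length(C) == nrow(A), dt > 0)
  res <- neural_states_cpp(A, as.numeric(C), as.numeric(u), dt)
  if (!res$ok) {
    stop("neural integration failed (", res$reason, "); A = [",
         paste(signif(A, 3), collapse = ", "), "], C = [",
         paste(signif(C, 3), collapse = ", "), "]", call. = FALSE)
  }
  x <- res$states
  colnames(x) <- colnames(A)
  attr(x, "dt") <- dt
  x
}

#' Balloon-Windkessel hemodynamics
#'
#' Maps neural states to BOLD via the standard per-region ODEs for the
#' vasodilatory signal s, inflow f, venous volume v and deoxyhemoglobin q:
#' ds/dt = x - kappa s - gamma (f - 1); df/dt = s; tau dv/dt = f - v^(1/alpha);
#' tau dq/dt = f (1 - (1 - E0)^(1/f)) / E0 - v^(1/alpha) q / v; with BOLD
#' y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)). Initial condition
#' (s, f, v, q) = (0, 1, 1, 1), the fixed point at rest, at which y = 0.
#' Integration is RK4 on the microtime grid.
#'
#' @param x Neural states from [integrate_neural()] (`(n + 1) x R`).
#' @param h Optional list with per-region `decay_scaling` and
#'   `transit_scaling` (log-scalings of kappa0 and tau0) and a `constants`
#'   element; defaults to zero scalings and [hemo_constants()].
#' @param dt Bin width in seconds.
#' @return BOLD matrix on the same grid as `x`, attribute `dt`.
#' @export
hemodynamics <- function(x, h = NULL, dt = attr(x, "dt")) {
  R <- ncol(x)
  h <- h %||% list()
  cst <- h$constants %||% hemo_constants()
  decay <- rep_len(h$decay_scaling %||% 0, R)
  transit <- rep_len(h$transit_scaling %||% 0, R)
  kappa <- cst$kappa0 * exp(decay)
  tau <- cst$tau0 * exp(transit)
  res <- hemodynamics_cpp(unclass(x), kappa, tau, cst$gamma, cst$alpha,
                          cst$E0, cst$V0, cst$k1, cst$k2, cst$k3, dt)
  if (!res$ok) {
    stop("hemodynamic integration failed (", res$reason,
         "); try a smaller microtime step", call. = FALSE)
  }
  y <- res$bold
  colnames(y) <- colnames(x)
  attr(y, "dt") <- dt
  y
}

#' Predict regional BOLD time series
#'
#' The deterministic forward model: build the driving input, integrate the
#' neural equation, run it through the balloon-Windkessel model, sample at the
#' end of each volume (t = TR, 2 TR, ...) and mean-centre each region.
#'
#' @param params A [dcm_params()] object.
#' @param design A [stimulus_design()].
#' @param input_mode Passed to [build_input()].
#' @param centre Mean-centre each region (default TRUE).
#' @return A tibble with columns `time_s` and one column per region label,
#'   `n_volumes` rows; attribute `TR`.
#' @export
#' @examples
#' spec <- network_spec()
#' y <- predict_bold(dcm_params(spec, input_gain = 1), make_design("word"))
#' nrow(y) # 66
predict_bold <- function(params, design, input_mode = "block", centre = TRUE) {
  stopifnot(inherits(params, "dcm_params"), inherits(design, "stimulus_design"))
  spec <- params$spec
  A <- build_effective_A(params)
  C <- numeric(4)
  C[spec$input_region] <- params$input_gain
  u <- build_input(design, mode = input_mode)
  x <- integrate_neural(A, C, u, attr(u, "dt"))
  y <- hemodynamics(x, list(decay_scaling = params$decay_scaling,
                            transit_scaling = params$transit_scaling),
                    attr(u, "dt"))
  keep <- 1 + design$microtime_bins_per_TR * seq_len(design$n_volumes)
  ys <- y[keep, , drop = FALSE]
  if (centre) ys <- scale(ys, center = TRUE, scale = FALSE)
  out <- tibble::as_tibble(as.data.frame(ys))
  names(out) <- spec$region_labels
  out <- tibble::add_column(out, time_s = design$TR * seq_len(design$n_volumes),
                            .before = 1)
  attr(out, "TR") <- design$TR
  out
}

# n x 4 numeric matrix of region columns from a BOLD tibble
bold_matrix <- function(data, labels = c("A1", "pSTS", "pOp", "M1")) {
  stopifnot(all(labels %in% names(data)))
  m <- as.matrix(data[labels])
  if (anyNA(m)) stop("BOLD series contains missing values", call. = FALSE)
  m
}
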