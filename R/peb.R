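# Parametric empirical Bayes: a linear-Gaussian hierarchy over subject-level
# posteriors, theta_i = X_i beta + eps_i, eps_i ~ N(0, Sigma_b). Each
# subject's contribution is re-weighted from its original prior to the
# empirical prior N(X_i beta, Sigma_b) by Bayesian model reduction, which
# makes the beta posterior closed-form for a fixed between-subject scaling.

#' Specify a PEB model
#'
#' @param design_matrix Subjects x covariates matrix; default a single column
#'   of ones (the group mean). Must have full column rank.
#' @param fields Which first-level parameters enter the hierarchy; default the
#'   16 connectivity parameters (11 extrinsic + 4 self + input gain);
#'   hemodynamic scalings stay first-level.
#' @param beta_prior Optional [gaussian_belief()] over the group effects;
#'   default inherits the first-level prior over `fields` (per covariate).
#' @param gamma_grid Search grid for the between-subject log-scaling
#'   `gamma_b`; the between-subject covariance is
#'   `exp(gamma_b) / 16 * prior_cov(fields)`.
#' @return A list of class `peb_model`.
#' @export
peb_model <- function(design_matrix = NULL, fields = NULL, beta_prior = NULL,
                      gamma_grid = seq(-4, 4, by = 0.5)) {
  structure(
    list(design_matrix = design_matrix, fields = fields,
         beta_prior = beta_prior, gamma_grid = gamma_grid),
    class = "peb_model"
  )
}

# Marginal belief over a named subset of parameters
marginal_belief <- function(belief, fields) {
  ix <- match(fields, names(belief$mean))
  stopifnot(!anyNA(ix))
  gaussian_belief(belief$mean[ix], belief$cov[ix, ix, drop = FALSE])
}

# beta posterior and second-level free energy for a fixed between-subject
# covariance Sb. Subject i contributes a quadratic in beta obtained from the
# BMR evidence of replacing prior (m0, S0) with N(X_i beta, Sb).
peb_solve_fixed <- function(mus, Sigmas, m0, S0, Sb, X, beta_prior) {
  q <- length(m0)
  N <- length(mus)
  k <- ncol(X)
  P0 <- inv_sym(S0)
  Pb <- inv_sym(Sb)
  ld_P0 <- ldet_chol(P0)
  ld_Pb <- ldet_chol(Pb)
  Pbeta0 <- inv_sym(beta_prior$cov)

  Aacc <- matrix(0, q * k, q * k)
  bacc <- numeric(q * k)
  cacc <- 0
  for (i in seq_len(N)) {
    Pi <- inv_sym(Sigmas[[i]])
    Pti <- Pi + Pb - P0
    ev <- min(eigen((Pti + t(Pti)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("reduced subject precision not positive definite",
                      call. = FALSE)
    ri <- drop(Pi %*% mus[[i]] - P0 %*% m0)
    Pti_inv <- inv_sym(Pti)
    # delta_F_i(beta) = c_i - b_i' (X_i beta) - 1/2 (X_i beta)' A_i (X_i beta)
    Ai <- Pb - Pb %*% Pti_inv %*% Pb
    bi <- -drop(Pb %*% Pti_inv %*% ri)
    ci <- 0.5 * (ld_Pb - ld_P0 + ldet_chol(Pi) - ldet_chol(Pti)) +
      0.5 * (drop(t(m0) %*% P0 %*% m0) -
               drop(t(mus[[i]]) %*% Pi %*% mus[[i]]) +
               drop(t(ri) %*% Pti_inv %*% ri))
    Xi <- kronecker(t(X[i, , drop = FALSE]), diag(q))  # maps vec(beta) -> X_i beta
    Aacc <- Aacc + t(Xi) %*% Ai %*% Xi
    bacc <- bacc + drop(t(Xi) %*% bi)
    cacc <- cacc + ci
  }
  Pbeta <- Pbeta0 + Aacc
  rhs <- drop(Pbeta0 %*% beta_prior$mean) - bacc
  Sbeta <- inv_sym(Pbeta)
  mbeta <- drop(Sbeta %*% rhs)
  # log evidence of the hierarchy (up to terms constant in gamma_b):
  Fe <- cacc + 0.5 * drop(t(rhs) %*% Sbeta %*% rhs) -
    0.5 * drop(t(beta_prior$mean) %*% Pbeta0 %*% beta_prior$mean) +
    0.5 * ldet_chol(Pbeta0) - 0.5 * ldet_chol(Pbeta)
  list(mean = mbeta, cov = Sbeta, F = Fe)
}

#' Fit a parametric empirical Bayes model over subject fits
#'
#' For a fixed between-subject log-scaling `gamma_b` the group-effect
#' posterior is closed-form; `gamma_b` is optimised by maximising the
#' second-level free energy over a grid with one local refinement pass.
#'
#' @param fits List of `dcm_fit` objects (or lists with `belief`), all fitted
#'   under the same first-level prior, length >= 2.
#' @param prior The shared first-level prior list (default: first fit's).
#' @param model A [peb_model()].
#' @return An object of class `peb_fit`: `beta_belief` (a [gaussian_belief()]
#'   over group effects, terms named `field` for the group-mean column),
#'   `gamma_b`, `free_energy`, `free_energy_trace` (best-so-far over the
#'   refinement), `fields`, `design_matrix`, `beta_prior`, `spec`.
#' @export
fit_peb <- function(fits, prior = NULL, model = peb_model()) {
  stopifnot(length(fits) >= 2)
  prior <- prior %||% fits[[1]]$prior
  spec <- fits[[1]]$spec
  dims <- vapply(fits, function(f) length(f$belief$mean), 0L)
  if (length(unique(dims)) != 1) stop("subject fits differ in dimension",
                                      call. = FALSE)
  fields <- model$fields %||% connectivity_names(spec)
  X <- model$design_matrix %||% matrix(1, length(fits), 1)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient",
                                 call. = FALSE)
  k <- ncol(X)
  q <- length(fields)

  m0_full <- prior$belief
  m0 <- marginal_belief(m0_full, fields)
  mus <- lapply(fits, function(f) marginal_belief(f$belief, fields)$mean)
  Sigmas <- lapply(fits, function(f) marginal_belief(f$belief, fields)$cov)

  beta_prior <- model$beta_prior %||% {
    bm <- rep(m0$mean, k)
    names(bm) <- if (k == 1) fields else
      paste(rep(fields, k), rep(seq_len(k), each = q), sep = ".cov")
    gaussian_belief(bm, kronecker(diag(k), m0$cov))
  }

  eval_gamma <- function(g) {
    Sb <- exp(g) / 16 * m0$cov
    peb_solve_fixed(mus, Sigmas, m0$mean, m0$cov, Sb, X, beta_prior)
  }
  grid <- model$gamma_grid
  Fs <- vapply(grid, function(g) eval_gamma(g)$F, 0)
  if (length(grid) == 1L) {  # fixed between-subject scaling
    gamma_b <- grid
    trace <- Fs
  } else {
    best <- grid[which.max(Fs)]
    fine <- seq(best - 0.5, best + 0.5, by = 0.05)
    Ffine <- vapply(fine, function(g) eval_gamma(g)$F, 0)
    gamma_b <- fine[which.max(Ffine)]
    trace <- cummax(c(max(Fs), max(Ffine)))
  }
  sol <- eval_gamma(gamma_b)

  structure(
    list(
      beta_belief = gaussian_belief(setNames(sol$mean, names(beta_prior$mean)),
                                    sol$cov),
      gamma_b = gamma_b,
      free_energy = sol$F,
      free_energy_trace = trace,
      fields = fields,
      design_matrix = X,
      beta_prior = beta_prior,
      spec = spec
    ),
    class = "peb_fit"
  )
}

#' @export
print.peb_fit <- function(x, ...) {
  cat("<peb_fit>", length(x$fields), "fields;",
      nrow(x$design_matrix), "subjects; gamma_b =", round(x$gamma_b, 2),
      "; F =", round(x$free_energy, 2), "\n")
  invisible(x)
}

#' @describeIn fit_peb Group-effect posterior, one row per term.
#' @param x,... A `peb_fit` and unused arguments.
#' @export
tidy.peb_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta_belief$mean),
    estimate = unname(x$beta_belief$mean),
    std.error = sqrt(diag(x$beta_belief$cov))
  )
}

#' @describeIn fit_peb One-row summary of the hierarchy.
#' @export
glance.peb_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$design_matrix),
    n_fields = length(x$fields),
    gamma_b = x$gamma_b,
    free_energy = x$free_energy
  )
}

#' Second-level model search over group effects
#'
#' Applies the nested model space ([enumerate_model_space()] +
#' [score_model_space()]) to the group-mean effects of a fitted PEB model:
#' each reduced model switches off a subset of the switchable connections at
#' the group level, and the per-connection presence probabilities and
#' model-averaged group means are aggregated by Bayesian model averaging.
#'
#' @param peb A `peb_fit` (group-mean design only for the search).
#' @param spec A [network_spec()] (default: the PEB fit's).
#' @param shrink_var Prior variance of switched-off group effects.
#' @return A `model_space_result` over the group effects.
#' @export
peb_model_search <- function(peb, spec = NULL, shrink_var = 1e-8) {
  stopifnot(inherits(peb, "peb_fit"))
  spec <- spec %||% peb$spec
  if (ncol(peb$design_matrix) != 1) {
    stop("second-level search expects a group-mean-only design", call. = FALSE)
  }
  pseudo_fit <- list(belief = peb$beta_belief,
                     prior = list(belief = peb$beta_prior), spec = spec)
  score_model_space(pseudo_fit, prior = peb$beta_prior, spec = spec,
                    shrink_var = shrink_var)
}
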