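# Variational Laplace: Gaussian fixed-form variational Bayes with a
# Gauss-Newton / Levenberg-Marquardt ascent on the free energy, interleaved
# with Newton updates of the per-region noise log-precisions.

#' Optimiser settings for variational Laplace
#'
#' @param max_iter Maximum number of Levenberg-Marquardt steps (accepted or
#'   rejected). `0` returns the prior as posterior.
#' @param tol Convergence: the run stops after `patience` consecutive accepted
#'   steps each improving the free energy by less than `tol` nats.
#' @param patience See `tol`.
#' @param damping Initial LM damping; doubled on a rejected step, halved on an
#'   accepted one.
#' @param max_damping Abort the ascent when damping exceeds this (treated as
#'   converged to a local optimum).
#' @param fd_step Relative central finite-difference step for the Jacobian:
#'   `fd_step * max(1, |theta_i|)`.
#' @param lambda_iter Newton iterations for the noise log-precisions per
#'   free-energy evaluation.
#' @param rescale Standardise the data (one pooled factor applied to data and
#'   prediction alike) before fitting; the factor is reported in the fit.
#' @param target_sd Pooled standard deviation the data are scaled to when
#'   `rescale` is on. The default of 4 follows the convention of scaling BOLD
#'   to a few "percent"-sized units, which places the residuals of a typical
#'   run on the unit-variance scale the noise hyperprior is centred on.
#' @return A list of control settings.
#' @export
vl_control <- function(max_iter = 64L, tol = 0.01, patience = 4L,
                       damping = 1 / 8, max_damping = 1e7, fd_step = 1e-3,
                       lambda_iter = 8L, rescale = TRUE, target_sd = 4) {
  list(max_iter = max_iter, tol = tol, patience = patience, damping = damping,
       max_damping = max_damping, fd_step = fd_step, lambda_iter = lambda_iter,
       rescale = rescale, target_sd = target_sd)
}

ldet_chol <- function(M) 2 * sum(log(diag(chol((M + t(M)) / 2))))

inv_sym <- function(M) {
  out <- chol2inv(chol((M + t(M)) / 2))
  dimnames(out) <- dimnames(M)
  out
}

# KL(N(mu_q, S_q) || N(mu_0, S_0)) in nats
kl_gaussian <- function(mu_q, S_q, mu_0, S_0, P_0 = inv_sym(S_0)) {
  d <- mu_q - mu_0
  0.5 * (sum(P_0 * S_q) + drop(t(d) %*% P_0 %*% d) - length(mu_q) +
           ldet_chol(S_0) - ldet_chol(S_q))
}

# Central finite-difference Jacobian of predict_fun (n x R output) at theta.
# Returns an n*R x p matrix (regions stacked), plus per-region index list.
fd_jacobian <- function(predict_fun, theta, fd_step) {
  g0 <- predict_fun(theta)
  n <- nrow(g0); R <- ncol(g0); p <- length(theta)
  J <- matrix(0, n * R, p)
  for (i in seq_len(p)) {
    h <- fd_step * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    J[, i] <- (as.vector(predict_fun(tp)) - as.vector(predict_fun(tm))) / (2 * h)
  }
  list(g = g0, J = J, n = n, R = R)
}

# One full free-energy evaluation at mean `mu`: Jacobian, noise update,
# Gauss-Newton curvature. Returns everything the outer loop needs.
vl_eval <- function(mu, lam, y, predict_fun, mu0, P0, ldetS0, lam0, hvar,
                    fix_lambda, control) {
  jb <- fd_jacobian(predict_fun, mu, control$fd_step)
  n <- jb$n; R <- jb$R; p <- length(mu)
  e <- as.vector(y) - as.vector(jb$g)
  ridx <- unname(split(seq_len(n * R), rep(seq_len(R), each = n)))
  JtJ <- lapply(ridx, function(ix) crossprod(jb$J[ix, , drop = FALSE]))
  Jte <- lapply(ridx, function(ix) crossprod(jb$J[ix, , drop = FALSE], e[ix]))
  sse <- vapply(ridx, function(ix) sum(e[ix]^2), 0)

  if (!is.null(fix_lambda)) lam <- rep_len(fix_lambda, R)
  curv <- rep(1, R)
  for (rep_i in seq_len(3)) {
    P <- P0
    for (r in seq_len(R)) P <- P + exp(lam[r]) * JtJ[[r]]
    Sigma <- inv_sym(P)
    trc <- vapply(seq_len(R), function(r) sum(JtJ[[r]] * Sigma), 0)
    if (!is.null(fix_lambda)) break
    for (it in seq_len(control$lambda_iter)) {
      s <- sse + trc
      gr <- -0.5 * exp(lam) * s + n / 2 - (lam - lam0) / hvar
      hs <- -0.5 * exp(lam) * s - 1 / hvar
      step <- gr / hs
      lam <- lam - step
      if (max(abs(step)) < 1e-6) break
    }
    curv <- 0.5 * exp(lam) * (sse + trc) + 1 / hvar
  }
  lam_var <- 1 / curv

  accuracy <- sum(-0.5 * exp(lam) * (sse + trc) + 0.5 * n * lam -
                    0.5 * n * log(2 * pi))
  d <- mu - mu0
  kl_theta <- 0.5 * (sum(P0 * Sigma) + drop(t(d) %*% P0 %*% d) - p +
                       ldetS0 + ldet_chol(P))
  kl_lambda <- if (is.null(fix_lambda)) {
    sum(0.5 * ((lam - lam0)^2 / hvar + lam_var / hvar - 1 +
                 log(hvar) - log(lam_var)))
  } else 0
  Fe <- accuracy - kl_theta - kl_lambda

  grad <- -P0 %*% d
  for (r in seq_len(R)) grad <- grad + exp(lam[r]) * Jte[[r]]
  list(F = Fe, mu = mu, lam = lam, lam_var = lam_var, Sigma = Sigma, P = P,
       grad = drop(grad), sse = sse, accuracy = accuracy,
       kl_theta = kl_theta, kl_lambda = kl_lambda)
}

# Generic VL engine over an arbitrary smooth forward model. `y` is an n x R
# matrix, `predict_fun(theta)` returns an n x R matrix.
vl_engine <- function(y, predict_fun, prior, lambda_prior = list(mean = 0, var = 1 / 8),
                      fix_lambda = NULL, control = vl_control()) {
  mu0 <- prior$mean
  S0 <- prior$cov
  P0 <- inv_sym(S0)
  ldetS0 <- ldet_chol(S0)
  R <- ncol(y)
  lam0 <- rep_len(lambda_prior$mean, R)
  hvar <- lambda_prior$var

  if (control$max_iter == 0L) {
    ev <- vl_eval(mu0, lam0, y, predict_fun, mu0, P0, ldetS0, lam0, hvar,
                  fix_lambda, control)
    return(list(belief = prior, lambda = ev$lam, lambda_var = ev$lam_var,
                free_energy = ev$F, trace = ev$F, n_iterations = 0L,
                converged = TRUE))
  }

  cur <- vl_eval(mu0, lam0, y, predict_fun, mu0, P0, ldetS0, lam0, hvar,
                 fix_lambda, control)
  trace <- cur$F
  nu <- control$damping
  streak <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    H <- cur$P + nu * diag(diag(cur$P), nrow = nrow(cur$P))
    step <- drop(solve(H, cur$grad))
    cand <- tryCatch(
      vl_eval(cur$mu + step, cur$lam, y, predict_fun, mu0, P0, ldetS0,
              lam0, hvar, fix_lambda, control),
      error = function(e) NULL
    )
    if (is.null(cand) || !is.finite(cand$F) || cand$F < cur$F) {
      nu <- nu * 2
      if (nu > control$max_damping) { converged <- TRUE; break }
    } else {
      dF <- cand$F - cur$F
      cur <- cand
      trace <- c(trace, cur$F)
      nu <- max(nu * 0.5, 1e-8)
      streak <- if (dF < control$tol) streak + 1L else 0L
      if (streak >= control$patience) { converged <- TRUE; break }
    }
  }
  belief <- gaussian_belief(setNames(cur$mu, names(mu0)), cur$Sigma)
  list(belief = belief, lambda = cur$lam, lambda_var = cur$lam_var,
       free_energy = cur$F, trace = trace, n_iterations = iter,
       converged = converged)
}

#' Variational free energy of a belief
#'
#' Evaluates the evidence bound F = accuracy - complexity for a Gaussian
#' belief over the DCM parameters: the expected log-likelihood of the
#' residuals under the i.i.d.-per-region noise model (with the curvature
#' correction from the forward-model Jacobian), minus the closed-form
#' KL divergence from the belief to the prior, minus the KL of the noise
#' log-precisions from their hyperprior.
#'
#' @param belief A [gaussian_belief()] over the parameters.
#' @param lambda Per-region noise log-precisions (recycled to 4).
#' @param data BOLD tibble (columns `A1`, `pSTS`, `pOp`, `M1`).
#' @param design A [stimulus_design()].
#' @param spec A [network_spec()].
#' @param prior Prior list from [default_priors()].
#' @param lambda_var Optional posterior variances of `lambda`; when `NULL`
#'   the noise hyperparameters are treated as fixed and their KL term is 0.
#' @param fd_step Finite-difference step for the Jacobian.
#' @return Scalar free energy in nats, with attributes `accuracy`,
#'   `complexity_parameters`, `complexity_noise`.
#' @export
free_energy <- function(belief, lambda, data, design, spec,
                        prior = default_priors(spec), lambda_var = NULL,
                        fd_step = 1e-3) {
  y <- bold_matrix(data, spec$region_labels)
  pf <- make_dcm_predictor(design, spec)
  jb <- fd_jacobian(pf, belief$mean, fd_step)
  n <- jb$n; R <- jb$R
  lam <- rep_len(lambda, R)
  e <- as.vector(y) - as.vector(jb$g)
  ridx <- split(seq_len(n * R), rep(seq_len(R), each = n))
  sse <- vapply(ridx, function(ix) sum(e[ix]^2), 0)
  trc <- vapply(ridx, function(ix) {
    Jr <- jb$J[ix, , drop = FALSE]
    sum(crossprod(Jr) * belief$cov)
  }, 0)
  accuracy <- sum(-0.5 * exp(lam) * (sse + trc) + 0.5 * n * lam -
                    0.5 * n * log(2 * pi))
  kl_theta <- kl_gaussian(belief$mean, belief$cov, prior$belief$mean,
                          prior$belief$cov)
  kl_lambda <- if (is.null(lambda_var)) 0 else {
    lv <- rep_len(lambda_var, R)
    l0 <- rep_len(prior$lambda$mean, R)
    sum(0.5 * ((lam - l0)^2 / prior$lambda$var + lv / prior$lambda$var - 1 +
                 log(prior$lambda$var) - log(lv)))
  }
  structure(accuracy - kl_theta - kl_lambda, accuracy = accuracy,
            complexity_parameters = kl_theta, complexity_noise = kl_lambda)
}

# Fast path for repeated forward evaluations: precompute input and sampling
# indices, return an n_volumes x 4 centred matrix from a flat parameter vector.
make_dcm_predictor <- function(design, spec, input_mode = "block",
                               scale = 1) {
  u <- build_input(design, mode = input_mode)
  dt <- attr(u, "dt")
  keep <- 1 + design$microtime_bins_per_TR * seq_len(design$n_volumes)
  cst <- hemo_constants()
  n_ext <- n_params(spec) - 13L
  input_region <- spec$input_region
  labels <- spec$region_labels
  conn_idx <- {
    idx <- matrix(0L, length(extrinsic_names(spec)), 2)
    for (i in seq_along(extrinsic_names(spec))) {
      st <- parse_connection(extrinsic_names(spec)[i], labels)
      idx[i, ] <- c(match(st[2], labels), match(st[1], labels))
    }
    idx
  }
  function(theta) {
    A <- matrix(0, 4, 4)
    diag(A) <- -0.5 * exp(theta[n_ext + 1:4])
    A[conn_idx] <- theta[seq_len(n_ext)]
    C <- numeric(4)
    C[input_region] <- theta[n_ext + 5L]
    xs <- neural_states_cpp(A, C, u, dt)
    if (!xs$ok) stop("neural integration failed (", xs$reason, ")",
                     call. = FALSE)
    kappa <- cst$kappa0 * exp(theta[n_ext + 5L + 1:4])
    tau <- cst$tau0 * exp(theta[n_ext + 9L + 1:4])
    hb <- hemodynamics_cpp(xs$states, kappa, tau, cst$gamma, cst$alpha,
                           cst$E0, cst$V0, cst$k1, cst$k2, cst$k3, dt)
    if (!hb$ok) stop("hemodynamic integration failed (", hb$reason, ")",
                     call. = FALSE)
    ys <- hb$bold[keep, , drop = FALSE]
    sweep(ys, 2, colMeans(ys)) / scale
  }
}

#' Fit a DCM to one regional BOLD time series
#'
#' Bayesian inversion by variational Laplace: a Gauss-Newton /
#' Levenberg-Marquardt ascent on the free energy with a central
#' finite-difference Jacobian of the forward model, interleaved with Newton
#' updates of the per-region noise log-precisions. The free-energy trace over
#' accepted steps is non-decreasing by construction; non-convergence within
#' the iteration budget returns the current estimate with `converged = FALSE`
#' and a warning.
#'
#' @param data BOLD tibble with columns `A1`, `pSTS`, `pOp`, `M1` (and
#'   optionally `time_s`), one row per volume; at least 8 volumes.
#' @param design A [stimulus_design()].
#' @param spec A [network_spec()].
#' @param prior Prior list from [default_priors()].
#' @param control A [vl_control()] list.
#' @param input_mode Passed to [build_input()].
#' @return An object of class `dcm_fit`: posterior `belief`, noise
#'   log-precisions `lambda` (+`lambda_var`), `free_energy`, the accepted-step
#'   `trace`, `n_iterations`, `converged`, the data `scale` used internally,
#'   and the `prior`, `spec`, `design`.
#' @export
fit_dcm <- function(data, design, spec, prior = default_priors(spec),
                    control = vl_control(), input_mode = "block") {
  y <- bold_matrix(data, spec$region_labels)
  if (nrow(y) < 8) stop("need at least 8 volumes", call. = FALSE)
  if (nrow(y) != design$n_volumes) {
    stop("data rows do not match the design's volume count", call. = FALSE)
  }
  y <- sweep(y, 2, colMeans(y))
  scale <- if (isTRUE(control$rescale)) {
    sqrt(mean(apply(y, 2, stats::var))) / control$target_sd
  } else 1
  if (!is.finite(scale) || scale <= 0) scale <- 1
  pf <- make_dcm_predictor(design, spec, input_mode, scale = scale)
  res <- vl_engine(y / scale, pf, prior$belief, prior$lambda,
                   control = control)
  if (!res$converged) {
    warning("variational Laplace did not converge within ",
            control$max_iter, " iterations", call. = FALSE)
  }
  structure(
    c(res, list(scale = scale, prior = prior, spec = spec, design = design)),
    class = "dcm_fit"
  )
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("<dcm_fit> F =", round(x$free_energy, 2), "nats;",
      x$n_iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @describeIn fit_dcm Posterior summary, one row per parameter: `term`,
#'   `estimate`, `std.error`, and the prior mean/sd.
#' @param x,... A `dcm_fit` and unused arguments (tidier interface).
#' @export
tidy.dcm_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$belief$mean),
    estimate = unname(x$belief$mean),
    std.error = sqrt(diag(x$belief$cov)),
    prior.mean = unname(x$prior$belief$mean),
    prior.sd = sqrt(diag(x$prior$belief$cov))
  )
}

#' @describeIn fit_dcm One-row fit summary: free energy, iterations,
#'   convergence flag, noise log-precisions.
#' @export
glance.dcm_fit <- function(x, ...) {
  tibble::tibble(
    free_energy = x$free_energy,
    n_iterations = x$n_iterations,
    converged = x$converged,
    mean_log_precision = mean(x$lambda),
    scale = x$scale
  )
}
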