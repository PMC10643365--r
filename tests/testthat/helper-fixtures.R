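# Fixtures are built in code: one noisy synthetic run, and linear-Gaussian
# surrogate models with their exact conjugate solutions.

# A single subject run from known parameters with white noise at
# `noise_frac` of each region's signal sd.
noisy_run <- function(params, design = make_design("word"), noise_frac = 0.25,
                      seed = 1) {
  set.seed(seed)
  y <- predict_bold(params, design)
  m <- as.matrix(y[params$spec$region_labels])
  if (noise_frac > 0) {
    sds <- apply(m, 2, stats::sd)
    m <- m + sweep(matrix(rnorm(length(m)), nrow(m)), 2, noise_frac * sds, "*")
  }
  y[params$spec$region_labels] <- as.data.frame(m)
  y
}

# Linear-Gaussian surrogate y = X theta + eps, eps ~ N(0, sigma2 I), with the
# exact conjugate posterior and log marginal likelihood.
linear_surrogate <- function(n = 30, p = 3, sigma2 = 0.04, seed = 42,
                             prior_var = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  theta_true <- rnorm(p)
  y <- drop(X %*% theta_true) + rnorm(n, 0, sqrt(sigma2))
  m0 <- setNames(numeric(p), paste0("b", seq_len(p)))
  S0 <- diag(prior_var, p)
  P0 <- diag(1 / prior_var, p)
  Pq <- P0 + crossprod(X) / sigma2
  Sq <- solve(Pq)
  mq <- drop(Sq %*% (crossprod(X, y) / sigma2))
  Sy <- sigma2 * diag(n) + X %*% S0 %*% t(X)
  log_evidence <- as.numeric(
    -0.5 * n * log(2 * pi) - 0.5 * determinant(Sy)$modulus -
      0.5 * drop(t(y) %*% solve(Sy, y))
  )
  list(X = X, y = y, theta_true = theta_true, sigma2 = sigma2,
       prior = gaussian_belief(m0, S0),
       post_mean = mq, post_cov = Sq, log_evidence = log_evidence)
}

# Exact log marginal likelihood of a linear-Gaussian model under an arbitrary
# Gaussian prior (used as the evidence oracle for model reduction).
linear_log_evidence <- function(X, y, sigma2, prior) {
  n <- length(y)
  Sy <- sigma2 * diag(n) + X %*% prior$cov %*% t(X)
  mu_y <- drop(X %*% prior$mean)
  as.numeric(-0.5 * n * log(2 * pi) - 0.5 * determinant(Sy)$modulus -
               0.5 * drop(t(y - mu_y) %*% solve(Sy, y - mu_y)))
}

# RK4 integration of dx/dt = A x + C u at a refinement of the microtime grid
# (oracle for the matrix-exponential propagator).
rk4_neural <- function(A, C, u, dt, refine = 100) {
  R <- nrow(A)
  n <- length(u)
  X <- matrix(0, n + 1, R)
  x <- numeric(R)
  h <- dt / refine
  f <- function(x, uk) drop(A %*% x) + C * uk
  for (k in seq_len(n)) {
    for (s in seq_len(refine)) {
      k1 <- f(x, u[k]); k2 <- f(x + h / 2 * k1, u[k])
      k3 <- f(x + h / 2 * k2, u[k]); k4 <- f(x + h * k3, u[k])
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    X[k + 1, ] <- x
  }
  X
}

# Random stable rate matrix: strongly negative diagonal, modest couplings.
random_stable_A <- function(R = 4) {
  repeat {
    A <- matrix(rnorm(R * R, 0, 0.3), R, R)
    diag(A) <- -runif(R, 0.4, 1)
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -0.05) return(A)
  }
}

# Subject-level posterior constructed directly from a planted parameter
# vector: posterior precision = prior precision + data_prec * I over the
# connectivity fields (fast stand-in for a full fit in group-level tests).
constructed_fit <- function(theta_planted, spec = network_spec(),
                            prior = default_priors(spec), data_prec = 50) {
  m <- prior$belief$mean
  full <- m
  full[names(theta_planted)] <- theta_planted
  P0 <- solve(prior$belief$cov)
  Pd <- diag(data_prec, length(m))
  Pq <- P0 + Pd
  mu <- drop(solve(Pq, Pd %*% full))
  list(belief = gaussian_belief(setNames(mu, names(m)), solve(Pq)),
       prior = prior, spec = spec)
}
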