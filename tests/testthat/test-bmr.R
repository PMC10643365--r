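test_that("reducing with the unchanged prior is the identity", {
  set.seed(21)
  p <- 5
  S0 <- diag(runif(p, 0.5, 2))
  Sq <- crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.1
  prior <- gaussian_belief(setNames(numeric(p), letters[1:p]), S0)
  post <- gaussian_belief(setNames(rnorm(p), letters[1:p]), Sq)
  red <- bayesian_model_reduce(prior, post, prior)
  expect_equal(red$delta_F, 0, tolerance = 1e-10)
  expect_equal(red$posterior$mean, post$mean, tolerance = 1e-10)
  expect_equal(red$posterior$cov, post$cov, tolerance = 1e-8)
})

test_that("reduction delta-F equals exact evidence differences (conjugate oracle)", {
  ls <- linear_surrogate(n = 25, p = 2, sigma2 = 0.09, seed = 31)
  post <- gaussian_belief(setNames(ls$post_mean, names(ls$prior$mean)),
                          ls$post_cov)
  # shrink the second coefficient
  rp <- repdcm:::reduced_prior_for_mask(ls$prior, "b2")
  red <- bayesian_model_reduce(ls$prior, post, rp)
  exact_full <- linear_log_evidence(ls$X, ls$y, ls$sigma2, ls$prior)
  exact_reduced <- linear_log_evidence(ls$X, ls$y, ls$sigma2, rp)
  expect_equal(red$delta_F, exact_reduced - exact_full, tolerance = 1e-8)

  # reduced posterior matches the conjugate posterior under the shrink prior
  P0r <- solve(rp$cov)
  Pqr <- P0r + crossprod(ls$X) / ls$sigma2
  mqr <- drop(solve(Pqr, crossprod(ls$X, ls$y) / ls$sigma2))
  expect_equal(unname(red$posterior$mean), unname(mqr), tolerance = 1e-6)
})

test_that("pruning a strongly supported parameter loses evidence", {
  ls <- linear_surrogate(n = 60, p = 2, sigma2 = 0.01, seed = 33)
  post <- gaussian_belief(setNames(ls$post_mean, names(ls$prior$mean)),
                          ls$post_cov)
  # ensure the pruned coefficient is many posterior sd from zero
  expect_gt(abs(ls$post_mean[2]) / sqrt(ls$post_cov[2, 2]), 5)
  rp <- repdcm:::reduced_prior_for_mask(ls$prior, "b2")
  expect_lt(bayesian_model_reduce(ls$prior, post, rp)$delta_F, 0)
})

test_that("reduction is transitive for nested priors", {
  ls <- linear_surrogate(n = 25, p = 3, sigma2 = 0.04, seed = 35)
  post <- gaussian_belief(setNames(ls$post_mean, names(ls$prior$mean)),
                          ls$post_cov)
  rp1 <- repdcm:::reduced_prior_for_mask(ls$prior, "b3")
  rp2 <- repdcm:::reduced_prior_for_mask(ls$prior, c("b2", "b3"))
  direct <- bayesian_model_reduce(ls$prior, post, rp2)
  step1 <- bayesian_model_reduce(ls$prior, post, rp1)
  step2 <- bayesian_model_reduce(rp1, step1$posterior, rp2)
  expect_equal(step1$delta_F + step2$delta_F, direct$delta_F,
               tolerance = 1e-8)
  expect_equal(step2$posterior$mean, direct$posterior$mean, tolerance = 1e-6)
})

test_that("the default model space enumerates 2^8 unique masks", {
  spec <- network_spec()
  space <- enumerate_model_space(spec)
  expect_equal(nrow(space), 256)
  sw <- repdcm:::switchable_connections(spec)
  expect_length(sw, 8)
  key <- apply(as.matrix(space[sw]), 1, paste, collapse = "")
  expect_equal(length(unique(key)), 256)
  expect_equal(space$n_on[1], 8)  # full model present

  # empty switchable set: exactly one model
  spec0 <- network_spec(switchable = character(0))
  expect_equal(nrow(enumerate_model_space(spec0)), 1)
})

test_that("model probabilities are a softmax of delta-F (brute-force oracle)", {
  spec <- network_spec(switchable = c("pSTS->M1", "pOp->M1", "pSTS->pOp"))
  pr <- default_priors(spec)
  set.seed(41)
  # a posterior shifted on the switchable connections
  mu <- pr$belief$mean
  mu[c("pSTS->M1", "pOp->M1", "pSTS->pOp")] <- c(0.5, 0.1, -0.3)
  Sq <- pr$belief$cov * 0.2
  fit <- list(belief = gaussian_belief(mu, Sq), prior = pr, spec = spec)
  res <- score_model_space(fit)
  expect_equal(nrow(res$models), 8)
  expect_equal(sum(res$models$probability), 1, tolerance = 1e-10)

  # oracle: direct reduction + normalised exponentials
  sw <- repdcm:::switchable_connections(spec)
  dF <- vapply(seq_len(8), function(m) {
    off <- sw[!unlist(res$models[m, sw])]
    if (!length(off)) return(0)
    rp <- repdcm:::reduced_prior_for_mask(pr$belief, off)
    bayesian_model_reduce(pr$belief, fit$belief, rp)$delta_F
  }, 0)
  pr_oracle <- exp(dF) / sum(exp(dF))
  expect_equal(res$models$probability, pr_oracle, tolerance = 1e-8)

  # Pp oracle: summed probability of models containing each connection
  for (cn in sw) {
    expect_equal(res$connections$Pp[res$connections$connection == cn],
                 sum(pr_oracle[unlist(res$models[, cn])]), tolerance = 1e-8)
  }
  expect_true(all(res$connections$Pp >= 0 & res$connections$Pp <= 1))
})

test_that("an uninformative posterior gives symmetric model probabilities", {
  spec <- network_spec(switchable = "pSTS->M1")
  pr <- default_priors(spec)
  fit <- list(belief = pr$belief, prior = pr, spec = spec)
  res <- score_model_space(fit)
  expect_equal(nrow(res$models), 2)
  # posterior = prior: pruning changes nothing except the prior-mass terms,
  # which cancel at mean zero, so both models tie and Pp = 0.5
  expect_equal(res$models$probability, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(res$connections$Pp, 0.5, tolerance = 1e-6)
})

test_that("reduced evidence agrees with a full refit within a nat", {
  spec <- network_spec()
  d <- make_design("word")
  truth <- archetype_params("B", spec)  # pOp->M1 truly absent
  dat <- noisy_run(truth, d, noise_frac = 0.25, seed = 44)
  full <- suppressWarnings(fit_dcm(dat, d, spec))
  rp <- repdcm:::reduced_prior_for_mask(full$prior$belief, "pOp->M1")
  bmr_dF <- bayesian_model_reduce(full$prior$belief, full$belief, rp)$delta_F
  refit <- suppressWarnings(
    fit_dcm(dat, d, spec, prior = list(belief = rp, lambda = full$prior$lambda))
  )
  expect_lt(abs(bmr_dF - (refit$free_energy - full$free_energy)), 1)
})
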