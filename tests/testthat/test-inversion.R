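test_that("default priors keep the network stable and weakly informed", {
  spec <- network_spec()
  pr <- default_priors(spec)
  expect_equal(unname(pr$belief$mean), rep(0, 24))

  # self-connections sit at -0.5 Hz at the prior mean
  A <- build_effective_A(unflatten_params(pr$belief$mean, spec))
  expect_equal(unname(diag(A)), rep(-0.5, 4))
  expect_lt(max(Re(eigen(A, only.values = TRUE)$values)), 0)

  # prior mean predicts a finite (all-zero input response) series
  y <- predict_bold(unflatten_params(pr$belief$mean, spec), make_design("word"))
  expect_true(all(is.finite(as.matrix(y[spec$region_labels]))))

  # >95% of extrinsic prior mass within the +/-1 Hz plotting range
  sd_ext <- sqrt(pr$belief$cov["pSTS->M1", "pSTS->M1"])
  expect_equal(sd_ext, 0.5)
  expect_gt(pnorm(1, 0, sd_ext) - pnorm(-1, 0, sd_ext), 0.95)
})

test_that("free energy separates accuracy and complexity correctly", {
  spec <- network_spec()
  d <- make_design("word")
  pr <- default_priors(spec)
  truth <- archetype_params("A", spec)
  dat <- noisy_run(truth, d, noise_frac = 0.2, seed = 5)

  # belief = prior: zero parameter complexity
  F0 <- free_energy(pr$belief, lambda = 0, dat, d, spec, pr)
  expect_equal(attr(F0, "complexity_parameters"), 0, tolerance = 1e-10)

  # shrinking residuals at fixed complexity increases F
  clean <- predict_bold(truth, d)
  b_truth <- gaussian_belief(flatten_params(truth), pr$belief$cov)
  mix <- function(w) {
    out <- clean
    out[spec$region_labels] <- as.data.frame(
      w * as.matrix(dat[spec$region_labels]) +
        (1 - w) * as.matrix(clean[spec$region_labels]))
    out
  }
  F_far <- free_energy(b_truth, lambda = 4, mix(1.0), d, spec, pr)
  F_mid <- free_energy(b_truth, lambda = 4, mix(0.5), d, spec, pr)
  F_near <- free_energy(b_truth, lambda = 4, mix(0.1), d, spec, pr)
  expect_gt(F_mid, F_far)
  expect_gt(F_near, F_mid)
})

test_that("variational Laplace equals the conjugate closed form on a linear model", {
  ls <- linear_surrogate(n = 30, p = 3, sigma2 = 0.04)
  pf <- function(theta) matrix(ls$X %*% theta, ncol = 1)
  res <- repdcm:::vl_engine(
    matrix(ls$y, ncol = 1), pf, ls$prior,
    fix_lambda = log(1 / ls$sigma2),
    control = vl_control(max_iter = 200, tol = 1e-10, patience = 3,
                         rescale = FALSE)
  )
  expect_lt(max(abs(res$belief$mean - ls$post_mean)) /
              max(abs(ls$post_mean)), 1e-6)
  expect_lt(max(abs(res$belief$cov - ls$post_cov)) / max(abs(ls$post_cov)),
            1e-6)
  expect_equal(res$free_energy, ls$log_evidence, tolerance = 1e-6)
})

test_that("a zero-iteration fit returns the prior as posterior", {
  spec <- network_spec()
  d <- make_design("word")
  dat <- noisy_run(archetype_params("A", spec), d, seed = 6)
  fit <- fit_dcm(dat, d, spec, control = vl_control(max_iter = 0L))
  pr <- default_priors(spec)
  expect_identical(fit$belief$mean, pr$belief$mean)
  expect_identical(fit$belief$cov, pr$belief$cov)
  expect_equal(fit$n_iterations, 0L)
})

test_that("fitting a synthetic subject recovers the strongest planted connections", {
  spec <- network_spec()
  d <- make_design("word")
  truth <- archetype_params("A", spec)
  dat <- noisy_run(truth, d, noise_frac = 0.25, seed = 1)
  fit <- fit_dcm(dat, d, spec)

  # the two strongest planted extrinsic rates: pSTS->M1 = 0.66, A1->pSTS = 0.51
  est <- fit$belief$mean
  expect_gt(est[["pSTS->M1"]], 0)
  expect_gt(est[["A1->pSTS"]], 0)
  expect_lt(abs(est[["pSTS->M1"]] - 0.66) / 0.66, 0.5)
  expect_lt(abs(est[["A1->pSTS"]] - 0.51) / 0.51, 0.5)

  # free-energy trace non-decreasing over accepted steps
  expect_true(all(diff(fit$trace) >= 0))
  # posterior covariance positive definite
  expect_true(all(eigen(fit$belief$cov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  # symmetric to numerical tolerance
  expect_lt(max(abs(fit$belief$cov - t(fit$belief$cov))), 1e-10)

  # tidier surfaces
  td <- tidy(fit)
  expect_equal(nrow(td), 24)
  expect_true(all(td$std.error > 0))
  expect_equal(nrow(glance(fit)), 1)
})

test_that("identical data and options give bit-identical estimates", {
  spec <- network_spec()
  d <- make_design("word")
  dat <- noisy_run(archetype_params("B", spec), d, seed = 8)
  f1 <- suppressWarnings(fit_dcm(dat, d, spec))
  f2 <- suppressWarnings(fit_dcm(dat, d, spec))
  expect_identical(f1$belief$mean, f2$belief$mean)
  expect_identical(f1$free_energy, f2$free_energy)
  expect_identical(f1$trace, f2$trace)
})

test_that("parameter recovery improves as noise falls", {
  spec <- network_spec()
  d <- make_design("word")
  truth <- archetype_params("A", spec)
  tv <- flatten_params(truth)[repdcm:::extrinsic_names(spec)]
  cors <- vapply(c(0.5, 0.05), function(nf) {
    dat <- noisy_run(truth, d, noise_frac = nf, seed = 9)
    fit <- suppressWarnings(fit_dcm(dat, d, spec))
    cor(tv, fit$belief$mean[names(tv)], method = "spearman")
  }, 0)
  expect_gt(cors[2], cors[1])
  expect_gt(cors[2], 0.8)
})
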