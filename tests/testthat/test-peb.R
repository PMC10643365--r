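test_that("two subjects, one parameter: beta posterior matches the analytic hierarchy", {
  spec <- network_spec()
  pr <- default_priors(spec)
  field <- "pSTS->M1"
  f1 <- constructed_fit(c("pSTS->M1" = 0.6), data_prec = 40)
  f2 <- constructed_fit(c("pSTS->M1" = 0.4), data_prec = 25)
  g0 <- 0.8  # fixed between-subject scaling
  peb <- fit_peb(list(f1, f2), pr,
                 peb_model(fields = field, gamma_grid = g0))

  # oracle: subjects reduce to observations theta_hat_i ~ N(beta, vb + vd_i)
  s0 <- pr$belief$cov[field, field]
  p0 <- 1 / s0
  vb <- exp(g0) / 16 * s0
  oracle <- function(fit) {
    pi_i <- 1 / fit$belief$cov[field, field]
    mu_i <- fit$belief$mean[[field]]
    pd <- pi_i - p0
    list(mu_d = (pi_i * mu_i) / pd, w = 1 / (vb + 1 / pd))
  }
  o1 <- oracle(f1); o2 <- oracle(f2)
  prec <- p0 + o1$w + o2$w  # beta prior inherits the first-level prior
  mean_beta <- (o1$w * o1$mu_d + o2$w * o2$mu_d) / prec
  expect_equal(peb$beta_belief$mean[[field]], mean_beta, tolerance = 1e-8)
  expect_equal(peb$beta_belief$cov[field, field], 1 / prec, tolerance = 1e-8)
  expect_equal(peb$gamma_b, g0)
})

test_that("identical precise subjects collapse the hierarchy onto their shared mean", {
  pr <- default_priors(network_spec())
  f <- constructed_fit(c("pSTS->M1" = 0.45, "A1->pSTS" = 0.5),
                       data_prec = 1e4)
  peb <- fit_peb(list(f, f, f), pr,
                 peb_model(gamma_grid = -15))  # vanishing between-subject var
  expect_equal(peb$beta_belief$mean[["pSTS->M1"]],
               f$belief$mean[["pSTS->M1"]], tolerance = 1e-2)
  expect_equal(peb$beta_belief$mean[["A1->pSTS"]],
               f$belief$mean[["A1->pSTS"]], tolerance = 1e-2)
})

test_that("the group posterior is invariant to subject order", {
  set.seed(51)
  pr <- default_priors(network_spec())
  fits <- lapply(1:5, function(i) {
    constructed_fit(c("pSTS->M1" = rnorm(1, 0.5, 0.2),
                      "pOp->M1" = rnorm(1, 0.2, 0.1)),
                    data_prec = 30 + 5 * i)
  })
  p1 <- fit_peb(fits, pr)
  p2 <- fit_peb(rev(fits), pr)
  expect_equal(p1$beta_belief$mean, p2$beta_belief$mean, tolerance = 1e-10)
  expect_equal(p1$gamma_b, p2$gamma_b)
})

test_that("a planted group effect is recovered within its posterior uncertainty", {
  set.seed(52)
  pr <- default_priors(network_spec())
  beta_true <- 0.5
  fits <- lapply(1:20, function(i) {
    constructed_fit(c("pSTS->M1" = rnorm(1, beta_true, 0.2)), data_prec = 60)
  })
  peb <- fit_peb(fits, pr)
  est <- peb$beta_belief$mean[["pSTS->M1"]]
  sd_est <- sqrt(peb$beta_belief$cov["pSTS->M1", "pSTS->M1"])
  expect_lt(abs(est - beta_true), 2 * sd_est + 0.1)
  expect_gt(est, 0.3)
})

test_that("90% posterior intervals cover the planted group mean in most cohorts", {
  set.seed(53)
  pr <- default_priors(network_spec())
  beta_true <- 0.4
  covered <- vapply(1:20, function(rep_i) {
    fits <- lapply(1:8, function(i) {
      constructed_fit(c("pSTS->M1" = rnorm(1, beta_true, 0.2)), data_prec = 50)
    })
    peb <- fit_peb(fits, pr)
    est <- peb$beta_belief$mean[["pSTS->M1"]]
    sd_est <- sqrt(peb$beta_belief$cov["pSTS->M1", "pSTS->M1"])
    abs(est - beta_true) <= 1.645 * sd_est
  }, NA)
  expect_gte(mean(covered), 0.7)
})

test_that("second-level search reports a planted bidirectional inhibitory pair", {
  set.seed(54)
  pr <- default_priors(network_spec())
  fits <- lapply(1:12, function(i) {
    constructed_fit(c("pSTS->pOp" = rnorm(1, -0.2, 0.05),
                      "pOp->pSTS" = rnorm(1, -0.2, 0.05),
                      "A1->pSTS" = rnorm(1, 0.5, 0.05)),
                    data_prec = 80)
  })
  peb <- fit_peb(fits, pr)
  sr <- peb_model_search(peb)
  expect_equal(sum(sr$models$probability), 1, tolerance = 1e-10)
  conn <- sr$connections
  for (cn in c("pSTS->pOp", "pOp->pSTS")) {
    expect_gt(conn$Pp[conn$connection == cn], 0.75)
    expect_lt(conn$bma_mean[conn$connection == cn], 0)
  }
  # absent connections are not endorsed
  expect_lt(conn$Pp[conn$connection == "pOp->M1"], 0.75)
})

test_that("degenerate inputs are rejected", {
  pr <- default_priors(network_spec())
  f <- constructed_fit(c("pSTS->M1" = 0.5))
  expect_error(fit_peb(list(f), pr), "length")
  X_bad <- cbind(1, c(2, 2, 2))  # second column collinear with the first
  expect_error(fit_peb(list(f, f, f), pr,
                       peb_model(design_matrix = X_bad)),
               "rank")
})
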