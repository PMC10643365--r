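# Bayesian model reduction: analytic posteriors and evidence changes for
# models whose priors are shrunk versions of the fitted full model's prior.

#' Reduce a fitted posterior under a new (nested) prior
#'
#' Given the full model's prior, its fitted posterior and a reduced prior
#' (typically with some connections' prior variance shrunk to ~0), returns the
#' posterior the reduced model would have obtained and the log evidence change
#' `delta_F`, both in closed form. With precisions `P = solve(cov)`:
#' reduced posterior precision `Pq~ = Pq + P0~ - P0`, mean
#' `mq~ = solve(Pq~, Pq mq + P0~ m0~ - P0 m0)`, and
#' `delta_F = 1/2 (ln det P0~ - ln det P0 + ln det Pq - ln det Pq~)
#'  + 1/2 (m0' P0 m0 - m0~' P0~ m0~ - mq' Pq mq + mq~' Pq~ mq~)`
#' (the evidence ratio equals the prior ratio times the posterior ratio,
#' evaluated at any parameter value; here at zero).
#'
#' @param prior,posterior,reduced_prior [gaussian_belief()] objects of one
#'   common dimension.
#' @return A list with `posterior` (the reduced-model [gaussian_belief()]) and
#'   `delta_F` (nats, relative to the full model).
#' @export
bayesian_model_reduce <- function(prior, posterior, reduced_prior) {
  stopifnot(length(prior$mean) == length(posterior$mean),
            length(prior$mean) == length(reduced_prior$mean))
  P0 <- inv_sym(prior$cov)
  Pq <- inv_sym(posterior$cov)
  Pr0 <- inv_sym(reduced_prior$cov)
  Prq <- Pq + Pr0 - P0
  ev <- eigen((Prq + t(Prq)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("reduced posterior precision is not positive definite", call. = FALSE)
  }
  m0 <- prior$mean; mq <- posterior$mean; mr0 <- reduced_prior$mean
  rhs <- drop(Pq %*% mq + Pr0 %*% mr0 - P0 %*% m0)
  mrq <- drop(solve(Prq, rhs))
  dF <- 0.5 * (ldet_chol(Pr0) - ldet_chol(P0) + ldet_chol(Pq) - ldet_chol(Prq)) +
    0.5 * (drop(t(m0) %*% P0 %*% m0) - drop(t(mr0) %*% Pr0 %*% mr0) -
             drop(t(mq) %*% Pq %*% mq) + drop(t(mrq) %*% Prq %*% mrq))
  list(
    posterior = gaussian_belief(setNames(mrq, names(posterior$mean)),
                                inv_sym(Prq)),
    delta_F = dF
  )
}

#' Enumerate the nested model space
#'
#' All on/off combinations over the switchable connections of the network
#' (default: the 8 extrinsic connections excluding the three afferents to A1,
#' giving the 256-model space). The full model (all on) is included;
#' self-connections and non-switchable parameters are present in every model.
#'
#' @param spec A [network_spec()].
#' @return A tibble with one row per model: `model` (id), one logical column
#'   per switchable connection, and `n_on`.
#' @export
enumerate_model_space <- function(spec) {
  sw <- switchable_connections(spec)
  k <- length(sw)
  if (k > 16) {
    stop("refusing to enumerate > 2^16 models (", k,
         " switchable connections)", call. = FALSE)
  }
  if (k == 0) {
    return(tibble::tibble(model = 1L, n_on = 0L))
  }
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), k))  # row 1 = full model
  names(grid) <- sw
  out <- tibble::as_tibble(grid)
  out$n_on <- rowSums(out)
  tibble::add_column(out, model = seq_len(nrow(out)), .before = 1)
}

switchable_connections <- function(spec) {
  idx <- which(spec$switchable_mask, arr.ind = TRUE)
  if (!nrow(idx)) return(character(0))
  nm <- connection_name(spec$region_labels[idx[, 2]],   # col = source
                        spec$region_labels[idx[, 1]])   # row = target
  intersect(extrinsic_names(spec), nm)  # canonical order
}

# Reduced prior for one mask: switched-off connections get mean 0 and
# variance `shrink_var` (1e-8; exact zeros would break the determinants).
reduced_prior_for_mask <- function(prior_belief, off_terms, shrink_var = 1e-8) {
  S <- prior_belief$cov
  m <- prior_belief$mean
  ix <- match(off_terms, names(m))
  stopifnot(!anyNA(ix))
  m[ix] <- 0
  S[ix, ] <- 0
  S[, ix] <- 0
  S[cbind(ix, ix)] <- shrink_var
  gaussian_belief(m, S)
}

#' Score a nested model space by Bayesian model reduction
#'
#' Computes each reduced model's log-evidence change from the fitted full
#' model, converts the changes to posterior model probabilities (softmax under
#' uniform model priors), and aggregates to per-connection presence
#' probabilities Pp and Bayesian-model-averaged posterior means.
#'
#' @param fit A `dcm_fit` (or any list with `belief`), fitted under `prior`.
#' @param prior The full model's prior [gaussian_belief()] (default: the
#'   fit's own prior).
#' @param space Model space from [enumerate_model_space()] (default: the
#'   spec's own space).
#' @param spec The [network_spec()] (default: the fit's).
#' @param shrink_var Prior variance assigned to switched-off connections.
#' @return An object of class `model_space_result`: the scored `models` tibble
#'   (mask bits, `delta_F`, `probability`), the per-connection `connections`
#'   tibble (`connection`, `Pp`, `bma_mean`, `full_mean`), `best_model`
#'   (argmax evidence row id) and the full BMA parameter means `bma_theta`.
#' @export
score_model_space <- function(fit, prior = NULL, space = NULL, spec = NULL,
                              shrink_var = 1e-8) {
  spec <- spec %||% fit$spec
  prior <- prior %||% fit$prior$belief
  space <- space %||% enumerate_model_space(spec)
  belief <- fit$belief
  sw <- switchable_connections(spec)
  sw <- intersect(sw, names(belief$mean))

  n_m <- nrow(space)
  dF <- numeric(n_m)
  means <- matrix(0, n_m, length(belief$mean),
                  dimnames = list(NULL, names(belief$mean)))
  for (m in seq_len(n_m)) {
    off <- sw[!unlist(space[m, sw])]
    if (!length(off)) {
      dF[m] <- 0
      means[m, ] <- belief$mean
    } else {
      rp <- reduced_prior_for_mask(prior, off, shrink_var)
      red <- bayesian_model_reduce(prior, belief, rp)
      dF[m] <- red$delta_F
      means[m, ] <- red$posterior$mean
    }
  }
  prob <- exp(dF - max(dF))
  prob <- prob / sum(prob)

  on_mat <- if (length(sw)) as.matrix(space[, sw]) else matrix(0, n_m, 0)
  Pp <- drop(prob %*% on_mat)
  bma_theta <- drop(prob %*% means)
  conn <- tibble::tibble(
    connection = sw,
    Pp = unname(Pp[sw]),
    bma_mean = unname(bma_theta[sw]),
    full_mean = unname(belief$mean[sw])
  )
  models <- space
  models$delta_F <- dF
  models$probability <- prob
  structure(
    list(models = models, connections = conn,
         best_model = models$model[which.max(dF)],
         bma_theta = bma_theta, spec = spec),
    class = "model_space_result"
  )
}

#' @export
print.model_space_result <- function(x, ...) {
  cat("<model_space_result>", nrow(x$models), "models; best =", x$best_model, "\n")
  print(x$connections, n = Inf)
  invisible(x)
}

#' @describeIn score_model_space Per-connection presence probabilities and
#'   model-averaged means as a tibble.
#' @param x,... A `model_space_result` and unused arguments.
#' @export
tidy.model_space_result <- function(x, ...) x$connections

#' @describeIn score_model_space One-row summary: model count, best model,
#'   evidence range.
#' @export
glance.model_space_result <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$models),
    best_model = x$best_model,
    best_delta_F = max(x$models$delta_F),
    min_delta_F = min(x$models$delta_F)
  )
}

#' Connection verdicts from a scored model space
#'
#' @param result A `model_space_result`.
#' @param threshold Presence-probability threshold (strict `>`).
#' @param use `"bma"` (model-averaged means, default) or `"full"` (full-model
#'   means) for the excitatory sign.
#' @return A tibble `connection`, `posterior_mean`, `Pp`, `excitatory`.
#' @export
connection_verdicts <- function(result, threshold = 0.75, use = c("bma", "full")) {
  use <- match.arg(use)
  conn <- result$connections
  mean_col <- if (use == "bma") conn$bma_mean else conn$full_mean
  tibble::tibble(
    connection = conn$connection,
    posterior_mean = mean_col,
    Pp = conn$Pp,
    excitatory = mean_col > 0 & conn$Pp > threshold
  )
}
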