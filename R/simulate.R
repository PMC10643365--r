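# Synthetic cohorts with known ground-truth architectures, emulating the
# study design: 2 tasks (word/pseudoword), up to 4 subregional configurations,
# block design at TR 3.085 s with 66 volumes per run.

#' Archetype base connectivity
#'
#' Group-level base parameters per degeneracy archetype. Non-defining
#' connections follow the word-repetition M1-f & dpOp group estimates
#' (excitatory A1 efferents, inhibitory pSTS<->pOp, inhibitory M1 feedback);
#' the two M1 afferents are set by the archetype: A has both pSTS->M1 and
#' pOp->M1 positive, B only pSTS->M1, C only pOp->M1, D neither.
#'
#' @param archetype `"A"`, `"B"`, `"C"` or `"D"`.
#' @param spec A [network_spec()].
#' @param overrides Named numeric vector of extrinsic rates replacing the
#'   defaults (applied after the archetype zeroing, except that archetype-off
#'   afferents stay 0).
#' @return A [dcm_params()] object.
#' @export
archetype_params <- function(archetype = c("A", "B", "C", "D"),
                             spec = network_spec(), overrides = NULL) {
  archetype <- match.arg(archetype)
  ext <- c(
    "A1->pSTS" = 0.51, "A1->pOp" = 0.42,
    "pSTS->A1" = -0.28, "pSTS->pOp" = -0.27, "pSTS->M1" = 0.66,
    "pOp->A1" = 0.00, "pOp->pSTS" = -0.22, "pOp->M1" = 0.31,
    "M1->A1" = -0.40, "M1->pSTS" = -0.11, "M1->pOp" = -0.13
  )
  if (!is.null(overrides)) ext[names(overrides)] <- overrides
  if (archetype %in% c("C", "D")) ext["pSTS->M1"] <- 0
  if (archetype %in% c("B", "D")) ext["pOp->M1"] <- 0
  self <- c(A1 = 0.00, pSTS = -0.06, pOp = -0.49, M1 = 0.41)
  dcm_params(spec, extrinsic = ext, self_scaling = self, input_gain = 1)
}

#' Specify a synthetic cohort
#'
#' Defaults are the desk-scale study conditions: a mixture of archetypes
#' (0.55 A, 0.2 B, 0.05 C, 0.2 D) close to the reported cohort composition,
#' between-subject variation of 0.2 Hz on the extrinsic rates, 0.1 Hz
#' within-subject configuration jitter (which places models near the
#' excitatory threshold, so cohorts show nonzero membership entropy by
#' construction), and white measurement noise at 25% of each region's signal
#' standard deviation.
#'
#' @param n_subjects Number of subjects.
#' @param tasks Subset of `c("word", "pseudoword")`.
#' @param configurations Subset of the 4 subregional pairings
#'   (`"M1f_dpOp"`, `"M1f_vpOp"`, `"M1tl_dpOp"`, `"M1tl_vpOp"`).
#' @param archetype_mixture Named probabilities over archetypes A-D (sums
#'   to 1).
#' @param base_overrides Named extrinsic overrides passed to
#'   [archetype_params()] (e.g. to plant a specific group effect).
#' @param between_subject_sd Between-subject sd (Hz) added to the archetype-on
#'   extrinsic rates, per subject x task.
#' @param config_jitter_sd Within-subject, per-configuration sd (Hz) on the
#'   same rates.
#' @param noise_sd Measurement noise as a fraction of per-region signal sd.
#' @param seed Mandatory integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12L,
                        tasks = c("word", "pseudoword"),
                        configurations = c("M1f_dpOp", "M1f_vpOp",
                                           "M1tl_dpOp", "M1tl_vpOp"),
                        archetype_mixture = c(A = 0.55, B = 0.2,
                                              C = 0.05, D = 0.2),
                        base_overrides = NULL,
                        between_subject_sd = 0.2,
                        config_jitter_sd = 0.1,
                        noise_sd = 0.25,
                        seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(abs(sum(archetype_mixture) - 1) < 1e-8,
            all(archetype_mixture >= 0),
            between_subject_sd >= 0, config_jitter_sd >= 0, noise_sd >= 0,
            all(names(archetype_mixture) %in% c("A", "B", "C", "D")))
  tasks <- match.arg(tasks, several.ok = TRUE)
  configurations <- match.arg(configurations,
                              c("M1f_dpOp", "M1f_vpOp", "M1tl_dpOp",
                                "M1tl_vpOp"), several.ok = TRUE)
  structure(
    list(n_subjects = as.integer(n_subjects), tasks = tasks,
         configurations = configurations,
         archetype_mixture = archetype_mixture,
         base_overrides = base_overrides,
         between_subject_sd = between_subject_sd,
         config_jitter_sd = config_jitter_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

config_network_spec <- function(configuration) {
  switch(configuration,
         M1f_dpOp = network_spec("dpOp", "M1f"),
         M1f_vpOp = network_spec("vpOp", "M1f"),
         M1tl_dpOp = network_spec("dpOp", "M1tl"),
         M1tl_vpOp = network_spec("vpOp", "M1tl"),
         stop("unknown configuration: ", configuration, call. = FALSE))
}

# Connections perturbed by between-subject deviation / configuration jitter:
# every extrinsic connection the archetype leaves on. Archetype-off M1
# afferents stay exactly 0 so the planted label is well defined.
archetype_on_connections <- function(archetype, spec) {
  base <- archetype_params(archetype, spec)
  names(base$extrinsic)[base$extrinsic != 0 |
                          !(names(base$extrinsic) %in%
                              c("pSTS->M1", "pOp->M1"))]
}

#' Sample one subject's true parameters
#'
#' Starts from the archetype base, adds Gaussian between-subject deviation
#' (and later per-configuration jitter) to the archetype-on extrinsic rates,
#' and resamples (up to `max_retries`) if the resulting rate matrix is not
#' stable.
#'
#' @param archetype Archetype label.
#' @param cohort A [cohort_spec()].
#' @param spec A [network_spec()].
#' @param max_retries Bound on stability resampling.
#' @return A [dcm_params()] object (uses the current RNG state).
#' @export
sample_subject <- function(archetype, cohort, spec = network_spec(),
                           max_retries = 20L) {
  base <- archetype_params(archetype, spec, cohort$base_overrides)
  on <- archetype_on_connections(archetype, spec)
  for (try_i in seq_len(max_retries)) {
    params <- base
    if (cohort$between_subject_sd > 0) {
      params$extrinsic[on] <- params$extrinsic[on] +
        rnorm(length(on), 0, cohort$between_subject_sd)
    }
    A <- build_effective_A(params)
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -0.05) return(params)
  }
  warning("resampling failed to find a stable subject; using the archetype base",
          call. = FALSE)
  base
}

jitter_params <- function(params, archetype, sd) {
  if (sd <= 0) return(params)
  spec <- params$spec
  on <- archetype_on_connections(archetype, spec)
  out <- params
  out$extrinsic[on] <- out$extrinsic[on] + rnorm(length(on), 0, sd)
  A <- build_effective_A(out)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= -0.05) return(params)
  out
}

#' Simulate a cohort of regional BOLD runs
#'
#' For each subject x task an archetype is drawn from the mixture (fixed per
#' subject x task); each configuration perturbs the subject's parameters with
#' configuration jitter, generates the forward prediction under the task's
#' block design, and adds i.i.d. Gaussian noise of sd `noise_sd` times the
#' per-region signal sd. Fully deterministic given the cohort seed.
#'
#' @param cohort A [cohort_spec()].
#' @return A list of class `cohort_data`: `runs`, a tibble with one row per
#'   subject x task x configuration (`subject`, `task`, `configuration`,
#'   `archetype`, list-columns `data` (BOLD tibble) and `truth`
#'   ([dcm_params()])), and `designs`, a named list of the per-task
#'   [stimulus_design()]s.
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cohort$seed)

  designs <- lapply(setNames(cohort$tasks, cohort$tasks), make_design)
  mix <- cohort$archetype_mixture
  rows <- list()
  for (s in seq_len(cohort$n_subjects)) {
    for (task in cohort$tasks) {
      archetype <- sample(names(mix), 1, prob = mix)
      base_spec <- config_network_spec(cohort$configurations[1])
      subj_params <- NULL
      for (try_i in 1:10) {  # subject must support a finite forward run
        cand <- sample_subject(archetype, cohort, base_spec)
        ok <- tryCatch({predict_bold(cand, designs[[task]]); TRUE},
                       error = function(e) FALSE)
        if (ok) { subj_params <- cand; break }
      }
      if (is.null(subj_params)) {
        subj_params <- archetype_params(archetype, base_spec,
                                        cohort$base_overrides)
      }
      for (cfg in cohort$configurations) {
        spec <- config_network_spec(cfg)
        p0 <- subj_params
        p0$spec <- spec
        y <- NULL
        for (try_i in 1:10) {  # jitter can destabilise the hemodynamics
          p <- jitter_params(p0, archetype, cohort$config_jitter_sd)
          y <- tryCatch(predict_bold(p, designs[[task]]), error = function(e) NULL)
          if (!is.null(y)) break
        }
        if (is.null(y)) {
          p <- p0
          y <- predict_bold(p, designs[[task]])
        }
        m <- bold_matrix(y, spec$region_labels)
        if (cohort$noise_sd > 0) {
          sds <- apply(m, 2, stats::sd)
          noise <- matrix(rnorm(length(m)), nrow(m), ncol(m))
          m <- m + sweep(noise, 2, cohort$noise_sd * sds, "*")
        }
        out <- y
        out[spec$region_labels] <- as.data.frame(m)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = s, task = task, configuration = cfg,
          archetype = archetype, data = list(out), truth = list(p)
        )
      }
    }
  }
  structure(list(runs = dplyr::bind_rows(rows), designs = designs,
                 cohort = cohort),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data>", nrow(x$runs), "runs:",
      x$cohort$n_subjects, "subjects x",
      length(x$cohort$tasks), "tasks x",
      length(x$cohort$configurations), "configurations\n")
  invisible(x)
}

#' Ground-truth record of a simulated cohort
#'
#' @param sim A `cohort_data` from [simulate_cohort()].
#' @return A tibble with one row per run: identifiers, the planted archetype
#'   and the true extrinsic rates in wide form.
#' @export
ground_truth <- function(sim) {
  stopifnot(inherits(sim, "cohort_data"))
  truths <- purrr::map(sim$runs$truth, function(p) {
    tibble::as_tibble(as.list(p$extrinsic))
  })
  dplyr::bind_cols(
    sim$runs[c("subject", "task", "configuration", "archetype")],
    dplyr::bind_rows(truths)
  )
}
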