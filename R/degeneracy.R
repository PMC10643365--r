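# Degeneracy taxonomy: classify each fitted model into groups A-D by its
# excitatory motor afferents, check consistency with the classical
# neurological model (pSTS -> pOp -> M1), and quantify within-subject
# variability of group membership as Shannon entropy in nats.

#' Assign a fitted model to group A, B, C or D
#'
#' The taxonomy keys on the presence of significant excitatory connectivity
#' to M1 (posterior mean > 0 and presence probability strictly > `threshold`):
#' A = excitatory pOp->M1 and pSTS->M1; B = pSTS->M1 only; C = pOp->M1 only;
#' D = neither. The function is total and deterministic; definite inhibitory
#' afferents also fall in D since the taxonomy keys on excitation only.
#'
#' @param pOp_to_M1,pSTS_to_M1 Either one-row tibbles from
#'   [connection_verdicts()] or lists/rows with `posterior_mean` and `Pp`.
#' @param threshold Presence-probability threshold (strict `>`).
#' @return A single character, `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
#' @examples
#' assign_group(list(posterior_mean = 0.31, Pp = 0.9),
#'              list(posterior_mean = 0.66, Pp = 0.95)) # "A"
assign_group <- function(pOp_to_M1, pSTS_to_M1, threshold = 0.75) {
  exc <- function(v) isTRUE(v$posterior_mean > 0 && v$Pp > threshold)
  pOp <- exc(as.list(pOp_to_M1))
  pSTS <- exc(as.list(pSTS_to_M1))
  if (pOp && pSTS) "A" else if (pSTS) "B" else if (pOp) "C" else "D"
}

#' Consistency with the neurological model
#'
#' The classical serial account routes auditory repetition through
#' pSTS -> pOp -> M1: a fitted model is consistent with it iff it is in
#' group C (excitatory pOp->M1 without pSTS->M1) with an excitatory
#' pSTS->pOp connection.
#'
#' @param label Group label from [assign_group()].
#' @param pSTS_to_pOp Verdict (list/row with `posterior_mean`, `Pp`).
#' @param threshold Presence-probability threshold.
#' @return Logical flag.
#' @export
neurological_consistent <- function(label, pSTS_to_pOp, threshold = 0.75) {
  v <- as.list(pSTS_to_pOp)
  identical(label, "C") && isTRUE(v$posterior_mean > 0 && v$Pp > threshold)
}

#' Shannon entropy of group membership
#'
#' H = -sum_g p_g ln p_g over the empirical frequencies of the labels, in
#' nats (0 ln 0 = 0). 0 means membership of a single group; the maximum over
#' four groups is ln 4 ~ 1.386.
#'
#' @param labels Non-empty character vector of group labels.
#' @return Entropy in nats.
#' @export
#' @examples
#' membership_entropy(c("A", "A", "A", "A")) # 0
#' membership_entropy(c("A", "B", "C", "D")) # log(4)
membership_entropy <- function(labels) {
  if (!length(labels)) stop("no labels supplied", call. = FALSE)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Classify every fitted model of a cohort
#'
#' Convenience wrapper mapping a table of scored model spaces to group labels
#' and consistency flags.
#'
#' @param results Tibble with columns `subject`, `task`, `configuration` and a
#'   list-column `scored` of `model_space_result` objects.
#' @param threshold Presence-probability threshold.
#' @param use Mean used for the excitatory sign (see [connection_verdicts()]).
#' @return Long-format tibble: `subject`, `task`, `configuration`, `label`,
#'   `consistent`, plus the three verdict means/Pps that drive them.
#' @export
classify_models <- function(results, threshold = 0.75, use = "bma") {
  stopifnot(all(c("subject", "task", "configuration", "scored") %in%
                  names(results)))
  rows <- purrr::pmap(results[c("subject", "task", "configuration", "scored")],
    function(subject, task, configuration, scored) {
      v <- connection_verdicts(scored, threshold, use)
      pick <- function(nm) v[v$connection == nm, ]
      pOp <- pick("pOp->M1"); pSTS <- pick("pSTS->M1"); sp <- pick("pSTS->pOp")
      label <- assign_group(pOp, pSTS, threshold)
      tibble::tibble(
        subject = subject, task = task, configuration = configuration,
        label = label,
        consistent = neurological_consistent(label, sp, threshold),
        pOp_to_M1 = pOp$posterior_mean, pOp_to_M1_Pp = pOp$Pp,
        pSTS_to_M1 = pSTS$posterior_mean, pSTS_to_M1_Pp = pSTS$Pp,
        pSTS_to_pOp = sp$posterior_mean, pSTS_to_pOp_Pp = sp$Pp
      )
    })
  dplyr::bind_rows(rows)
}

#' Cohort-level degeneracy summary
#'
#' Aggregates per-model group labels into the report shape of the analysis:
#' group counts per task and configuration, per-subject membership entropy per
#' task (over configurations), the fraction of subjects assigned to at least
#' two distinct groups, and the fraction of models consistent with the
#' neurological model.
#'
#' @param labels Long-format tibble with columns `subject`, `task`,
#'   `configuration`, `label` and optionally `consistent`.
#' @param across_tasks Also compute per-subject entropy over all task x
#'   configuration cells (off by default; the per-task entropies match the
#'   analysis's word/pseudoword split).
#' @return An object of class `degeneracy_report`: tibbles `group_counts`
#'   (task x configuration x group), `subject_entropy` (subject x task,
#'   `entropy` in nats and the membership counts), `subject_groups`
#'   (distinct-group counts per subject), and a one-row `summary`.
#' @export
summarise_cohort <- function(labels, across_tasks = FALSE) {
  needed <- c("subject", "task", "configuration", "label")
  missing_cols <- setdiff(needed, names(labels))
  if (length(missing_cols)) {
    stop("labels table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(labels[needed])) {
    stop("labels table has missing cells; complete the label set first",
         call. = FALSE)
  }
  lv <- c("A", "B", "C", "D")
  labels <- dplyr::mutate(labels, label = factor(.data$label, levels = lv))

  group_counts <- labels |>
    dplyr::count(.data$task, .data$configuration, .data$label,
                 .drop = FALSE, name = "n")

  subject_entropy <- labels |>
    dplyr::group_by(.data$subject, .data$task) |>
    dplyr::summarise(
      n_models = dplyr::n(),
      n_distinct_groups = dplyr::n_distinct(.data$label),
      entropy = membership_entropy(as.character(.data$label)),
      .groups = "drop"
    )

  subject_groups <- labels |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(n_distinct_groups = dplyr::n_distinct(.data$label),
                     .groups = "drop")

  summary <- tibble::tibble(
    n_subjects = dplyr::n_distinct(labels$subject),
    n_models = nrow(labels),
    fraction_multi_group = mean(subject_groups$n_distinct_groups >= 2),
    fraction_consistent = if ("consistent" %in% names(labels)) {
      mean(labels$consistent)
    } else NA_real_
  )
  mean_entropy <- subject_entropy |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(mean_entropy = mean(.data$entropy), .groups = "drop")

  out <- list(group_counts = group_counts,
              subject_entropy = subject_entropy,
              subject_groups = subject_groups,
              mean_entropy = mean_entropy,
              summary = summary,
              labels = labels)
  if (across_tasks) {
    out$subject_entropy_across_tasks <- labels |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(entropy = membership_entropy(as.character(.data$label)),
                       .groups = "drop")
  }
  structure(out, class = "degeneracy_report")
}

#' @export
print.degeneracy_report <- function(x, ...) {
  cat("<degeneracy_report>", x$summary$n_models, "models over",
      x$summary$n_subjects, "subjects\n")
  cat("  fraction of subjects in >= 2 groups:",
      round(x$summary$fraction_multi_group, 3), "\n")
  print(x$mean_entropy)
  invisible(x)
}

#' Compare group-count distributions between tasks
#'
#' Per group A-D, a two-sided Mann-Whitney-Wilcoxon rank-sum test on the
#' per-subject model counts of the two tasks, Bonferroni-corrected across the
#' four groups (p capped at 1).
#'
#' @param counts_task1,counts_task2 Wide tibbles with columns `subject` and
#'   `A`, `B`, `C`, `D` (counts per subject); identical subject sets.
#' @return Tibble `group`, `statistic`, `p_value`, `p_adjusted`.
#' @export
compare_group_distributions <- function(counts_task1, counts_task2) {
  need <- c("subject", "A", "B", "C", "D")
  stopifnot(all(need %in% names(counts_task1)),
            all(need %in% names(counts_task2)))
  if (!setequal(counts_task1$subject, counts_task2$subject)) {
    stop("the two tasks cover different subject sets", call. = FALSE)
  }
  res <- purrr::map_dfr(c("A", "B", "C", "D"), function(g) {
    wt <- suppressWarnings(
      wilcox.test(counts_task1[[g]], counts_task2[[g]],
                  alternative = "two.sided", exact = FALSE, correct = TRUE)
    )
    tibble::tibble(group = g, statistic = unname(wt$statistic),
                   p_value = wt$p.value)
  })
  res$p_adjusted <- pmin(1, 4 * res$p_value)
  res
}

#' Per-subject group counts in wide form
#'
#' @param labels Long-format label tibble (see [summarise_cohort()]).
#' @param task Which task to tabulate.
#' @return Tibble `subject`, `A`, `B`, `C`, `D`.
#' @export
group_counts_wide <- function(labels, task) {
  labels |>
    dplyr::filter(.data$task == !!task) |>
    dplyr::count(.data$subject, label = factor(.data$label,
                                               levels = c("A", "B", "C", "D")),
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
}
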