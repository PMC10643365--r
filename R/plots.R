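# ggplot2 surfaces for the main result types.

#' Plot a regional BOLD time series
#'
#' @param object BOLD tibble (columns `time_s`, `A1`, `pSTS`, `pOp`, `M1`).
#' @param ... Unused.
#' @return A ggplot: signal against time, one facet line per region.
#' @export
plot_bold <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"time_s", names_to = "region",
                              values_to = "bold")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$bold,
                                     colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "BOLD (a.u., mean-centred)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_bold
#' @export
autoplot.dcm_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "posterior estimate (Hz / log-scaling)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_bold
#' @export
autoplot.model_space_result <- function(object, ...) {
  conn <- object$connections
  ggplot2::ggplot(conn, ggplot2::aes(.data$bma_mean, .data$connection,
                                     fill = .data$Pp > 0.75)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               name = "Pp > 0.75") +
    ggplot2::labs(x = "model-averaged mean (Hz)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Group-count panel of a degeneracy report
#'
#' Model counts per group and configuration, one facet per task -- the shape
#' of the cohort's group-assignment figure.
#'
#' @param report A `degeneracy_report`.
#' @return A ggplot.
#' @export
plot_group_counts <- function(report) {
  ggplot2::ggplot(report$group_counts,
                  ggplot2::aes(.data$label, .data$n,
                               fill = .data$configuration)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "group", y = "models", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Entropy density of a degeneracy report
#'
#' Sample density of per-subject membership entropy (nats), one curve per
#' task.
#'
#' @param report A `degeneracy_report`.
#' @return A ggplot.
#' @export
plot_entropy_density <- function(report) {
  ggplot2::ggplot(report$subject_entropy,
                  ggplot2::aes(.data$entropy, colour = .data$task)) +
    ggplot2::geom_density(bw = 0.15) +
    ggplot2::geom_rug() +
    ggplot2::coord_cartesian(xlim = c(0, log(4))) +
    ggplot2::labs(x = "membership entropy (nats)", y = "sample density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
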