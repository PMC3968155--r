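# ggplot2 views of evaluation results: per-stage contributions, the
# c/p/e breakdown by type multiplicity, and the E-value sweep.

#' Plot per-stage contributions of an evaluation
#'
#' Bars show how many proteins each stage annotated, labelled with the
#' stage's multi-label accuracy.
#'
#' @param object A `memtype_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.memtype_eval <- function(object, ...) {
  ss <- object$stage_summary
  ggplot2::ggplot(ss, ggplot2::aes(x = .data$stage, y = .data$n_annotated,
                                   fill = .data$stage)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("Acc %.2f", .data$acc)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      title = sprintf("Leave-one-out: %s method", object$method),
      subtitle = sprintf("%d of %d annotated", object$n_annotated,
                         object$n),
      x = NULL, y = "proteins annotated (NA)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the c/p/e breakdown by number of actual types
#'
#' Stacked bars of completely correct (`c`), partly correct (`p`) and
#' incorrect (`e`) predictions per type multiplicity.
#'
#' @param x A `memtype_eval` object or a records tibble.
#' @return A ggplot object.
#' @export
plot_type_count_breakdown <- function(x) {
  records <- if (inherits(x, "memtype_eval")) x$records else x
  bd <- breakdown_by_type_count(records)
  long <- tidyr::pivot_longer(bd, c("c", "p", "e"), names_to = "outcome",
                              values_to = "count")
  long$outcome <- factor(long$outcome, levels = c("c", "p", "e"),
                         labels = c("completely correct",
                                    "partly correct", "incorrect"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$n_types),
                                     y = .data$count,
                                     fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "number of actual types", y = "proteins",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an E-value sweep
#'
#' Accuracy and the number of unannotated proteins against the homology
#' E-value cutoff (log scale), showing the strictness/coverage trade-off.
#'
#' @param sweep A tibble from [evalue_sweep()].
#' @return A ggplot object.
#' @export
plot_evalue_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    sweep[, c("cutoff", "acc", "n_unannotated")],
    c("acc", "n_unannotated"), names_to = "quantity",
    values_to = "value"
  )
  long$quantity <- factor(long$quantity, levels = c("acc", "n_unannotated"),
                          labels = c("Acc", "unannotated (NU)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "E-value cutoff", y = NULL) +
    ggplot2::theme_minimal()
}
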