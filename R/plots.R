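#' Plot per-type F1 of a score report
#'
#' @param object an `exoanno_scores` object.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.exoanno_scores <- function(object, ...) {
  ggplot2::ggplot(
    object$per_type,
    ggplot2::aes(x = stats::reorder(.data$type, .data$f1), y = .data$f1)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$macro_f1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "F1",
      title = sprintf("%s F1 by type (dashed: macro %.3f)", toupper(object$task), object$macro_f1)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-category kappa of an agreement report
#'
#' @param object an `exoanno_agreement` object.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.exoanno_agreement <- function(object, ...) {
  ggplot2::ggplot(
    object$kappa_by_category,
    ggplot2::aes(x = stats::reorder(.data$category, .data$kappa), y = .data$kappa)
  ) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = object$macro_kappa, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Cohen's kappa",
      title = sprintf("Agreement by category (dashed: macro %.2f)", object$macro_kappa)
    ) +
    ggplot2::theme_minimal()
}

#' Plot entity/relation type coverage of a corpus
#'
#' @param corpus a corpus tibble.
#' @return a ggplot of [coverage_report()] counts.
#' @export
plot_coverage <- function(corpus) {
  cov <- coverage_report(corpus)
  ggplot2::ggplot(
    cov,
    ggplot2::aes(x = stats::reorder(.data$type, .data$count), y = .data$count, fill = .data$kind)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mentions", fill = NULL, title = "Scheme coverage") +
    ggplot2::theme_minimal()
}
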