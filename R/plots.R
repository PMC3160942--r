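#' Plot an ROC curve
#'
#' @param object A `va_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot va_roc
#' @export
autoplot.va_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, !is.na(.data$cause))) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC (%s), AUC = %.2f%s", object$type, object$auc,
                      if (object$adequate) "" else " - below 0.75")
    ) +
    ggplot2::theme_minimal()
}

#' Compare CSMF tables across methods
#'
#' Side-by-side bar chart of cause-specific mortality fractions, the
#' standard population-level agreement display.
#'
#' @param ... Named CSMF tibbles from [csmf()], e.g.
#'   `plot_csmf(HCOD = gold, InterVA = engine, PCVA = coder)`.
#' @return A ggplot.
#' @export
plot_csmf <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1, !is.null(names(tabs)), all(nzchar(names(tabs))))
  df <- dplyr::bind_rows(tabs, .id = "method")
  df$cause <- factor(df$cause, levels = unique(df$cause))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cause, y = .data$percent,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "CSMF (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a misclassification (contingency) table
#'
#' @param object A `va_contingency`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot va_contingency
#' @export
autoplot.va_contingency <- function(object, ...) {
  df <- tidy.va_contingency(object)
  df$a <- factor(df$a, levels = rev(rownames(object)))
  df$b <- factor(df$b, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Method B", y = "Method A", fill = "deaths") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
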