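# ggplot2 views of the result types. Each autoplot returns the plot object
# unevaluated, ready for further theming.

#' Plot a classification report along the first canonical root
#'
#' Projects every sample on the discriminant axis
#' `pooled_cov^-1 (centroid_case - centroid_control)` and draws it against
#' sample index, colored by true class, with the midpoint decision line —
#' the canonical one-dimensional view of a two-class LDA.
#'
#' @param object A `classification_report` from [lda_forward()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.classification_report <- function(object, ...) {
  if (is.null(object$centroids)) {
    abort("no fitted discriminant to plot (no PCs entered).",
          class = "pdblood_validation_error")
  }
  w <- solve(object$pooled_cov,
             object$centroids["case", ] - object$centroids["control", ])
  root <- as.vector(object$scores %*% w)
  cut <- as.numeric((object$centroids["case", ] + object$centroids["control", ]) %*% w) / 2
  df <- object$samples |>
    dplyr::mutate(root = root, index = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$root,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = cut, linetype = "dashed") +
    ggplot2::labs(x = "sample", y = "first canonical root",
                  title = sprintf("LDA on %d forward-selected PCs (NER %.1f%%)",
                                  nrow(object$selected_pcs),
                                  object$ner_percent)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a differential-expression result
#'
#' @param object A `de_result` tibble.
#' @param ... Ignored.
#' @return A ggplot of the statistic against `-log10(p_like)` with the
#'   significant probes highlighted.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic,
                                   y = -log10(.data$p_like),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = sprintf("%s statistic", df$method[1]),
                  y = "-log10 p-like") +
    ggplot2::theme_minimal()
}

#' Running enrichment-score profile of a GSEA result
#'
#' @param object A `gsea_result` from [gsea_es()].
#' @param ... Ignored.
#' @return A ggplot with the running sum and hit positions.
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- object$running
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$running_es)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b") +
    ggplot2::labs(x = "rank in list", y = "running ES",
                  title = sprintf("ES = %.3f", object$es)) +
    ggplot2::theme_minimal()
}

#' Bar chart of enrichment rows
#'
#' @param enrichment Tibble from [fisher_term_test()].
#' @param top Show at most this many terms (default 15).
#' @return A ggplot of `-log10(p)` per term.
#' @export
plot_enrichment <- function(enrichment, top = 15) {
  df <- head(dplyr::arrange(as_tibble(enrichment), .data$p_value), top)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = stats::reorder(.data$term_name,
                                                      -.data$p_value))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 p", y = NULL) +
    ggplot2::theme_minimal()
}

#' Box plot of relative qPCR expression by group
#'
#' Mirrors the usual validation figure: natural-log normalized quantities
#' per gene, cases vs controls.
#'
#' @param rq Tibble from [relative_expression()].
#' @return A ggplot.
#' @export
plot_relative_expression <- function(rq) {
  ggplot2::ggplot(as_tibble(rq),
                  ggplot2::aes(x = .data$gene, y = .data$log_rq,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = "ln relative quantity") +
    ggplot2::theme_minimal()
}
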