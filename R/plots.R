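# ggplot2 visualizations of feature tables and results.

#' Plot the asymmetry-index profile of a cohort
#'
#' Boxplots of each region pair's AI values, split by lateralization
#' label when present. In a typical mesial-TLE cohort, Left-TLE subjects
#' sit below zero (left hypometabolism) and Right-TLE subjects above, most
#' prominently in mesial temporal regions.
#'
#' @param data Feature table (tibble with AI columns, optional `label`).
#' @return A ggplot object.
#' @export
plot_asymmetry <- function(data) {
  features <- check_feature_table(data)
  long <- tidyr::pivot_longer(
    data, cols = dplyr::all_of(features),
    names_to = "pair_name", values_to = "ai"
  )
  long$pair_name <- factor(long$pair_name, levels = pair_names())
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pair_name, y = .data$ai))
  p <- if ("label" %in% names(long)) {
    p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data$label),
                              outlier.size = 0.6)
  } else {
    p + ggplot2::geom_boxplot(outlier.size = 0.6)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Asymmetry index (AI)", fill = "TLE side") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot ai_cv
#' @export
autoplot.ai_cv <- function(object, ...) {
  folds <- object$folds
  ggplot2::ggplot(folds, ggplot2::aes(x = factor(.data$fold), y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_ratio, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Cross-validation run", y = "Correct lateralization ratio",
      title = sprintf("%s, %d-fold CV (mean %.0f%%)",
                      toupper(object$algo), object$k,
                      100 * object$mean_ratio)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot ai_linear
#' @export
autoplot.ai_linear <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$term, yend = 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Coefficient (class Left score)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
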