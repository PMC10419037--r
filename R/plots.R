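#' Perplexity and coherence curves over candidate topic counts
#'
#' @param object An `lda_k_selection` from [select_k()].
#' @param ... Unused.
#' @return A ggplot with one faceted panel per metric and the selected K
#'   marked.
#' @export
autoplot.lda_k_selection <- function(object, ...) {
  long <- object$summary |>
    tidyr::pivot_longer(c("mean_perplexity", "mean_coherence"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = sub("^mean_", "", .data$metric))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "number of topics K", y = NULL,
                  title = paste0("Model selection: K = ", object$selected_k,
                                 " (highest mean coherence)")) +
    ggplot2::theme_minimal()
}

#' Topic-emotion correlation heat map
#'
#' @param object A `topic_emotion_correlation`.
#' @param ... Unused.
#' @return A ggplot heat map of Pearson r with non-significant cells
#'   hollowed out; undefined (constant) cells are blank.
#' @export
autoplot.topic_emotion_correlation <- function(object, ...) {
  tbl <- tidy(object)
  tbl$subcategory <- factor(tbl$subcategory,
                            levels = emotion_subcategories()$subcategory)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$subcategory, y = .data$category)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r), color = "grey90") +
    ggplot2::geom_point(data = tbl[tbl$significant, , drop = FALSE],
                        size = 0.8) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey95",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "emotion subcategory", y = "demand category",
                  fill = "Pearson r",
                  caption = paste0("dots: p < ", attr(object, "threshold"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-category polarity distribution bars
#'
#' @param data Output of [polarity_distribution()].
#' @return A ggplot of positive/negative document shares per category.
#' @export
plot_polarity_distribution <- function(data) {
  long <- data |>
    dplyr::select("category", "pct_pos", "pct_neg") |>
    tidyr::pivot_longer(c("pct_pos", "pct_neg"), names_to = "tendency",
                        values_to = "pct") |>
    dplyr::mutate(tendency = ifelse(.data$tendency == "pct_pos",
                                    "positive", "negative"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$pct,
                                     fill = .data$tendency)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(positive = "#4393c3",
                                          negative = "#d6604d")) +
    ggplot2::labs(x = NULL, y = "% of non-neutral documents", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
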