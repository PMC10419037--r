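#' Tidy a fitted LDA model
#'
#' @param x An `lda_model`.
#' @param matrix Which component to tidy: `"phi"` (one row per topic-term
#'   pair), `"theta"` (one row per document-topic pair), or
#'   `"assignments"` (one row per token).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lda_model <- function(x, matrix = c("phi", "theta", "assignments"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    phi = tibble::tibble(
      topic = rep(seq_len(x$k), times = nrow(x$vocabulary)),
      term = rep(x$vocabulary$term, each = x$k),
      phi = as.vector(x$phi)),
    theta = tibble::tibble(
      doc_id = rep(x$doc_ids, times = x$k),
      topic = rep(seq_len(x$k), each = length(x$doc_ids)),
      theta = as.vector(x$theta)),
    assignments = tibble::tibble(
      doc_id = rep(x$doc_ids, lengths(x$assignments)),
      position = unlist(lapply(lengths(x$assignments), seq_len), use.names = FALSE),
      term = x$vocabulary$term[x$tokens$word + 1L],
      topic = unlist(x$assignments, use.names = FALSE))
  )
}

#' @rdname tidy.lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_documents = length(x$doc_ids),
                 n_terms = nrow(x$vocabulary),
                 n_tokens = length(x$tokens$word),
                 alpha = x$alpha, beta = x$beta,
                 n_iter = x$n_iter, seed = x$seed)
}

#' Tidy a topic-count selection
#'
#' @param x An `lda_k_selection`.
#' @param ... Unused.
#' @return The per-fit table (`tidy`) or a one-row summary (`glance`).
#' @export
tidy.lda_k_selection <- function(x, ...) x$table

#' @rdname tidy.lda_k_selection
#' @export
glance.lda_k_selection <- function(x, ...) {
  best <- x$summary[x$summary$k == x$selected_k, ]
  tibble::tibble(selected_k = x$selected_k,
                 mean_perplexity = best$mean_perplexity,
                 mean_coherence = best$mean_coherence,
                 n_candidates = length(x$k_grid),
                 replicates = x$replicates)
}

#' Tidy a cross-validation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Per-fold metrics (`tidy`) or the aggregate row (`glance`).
#' @export
tidy.eval_report <- function(x, ...) x$folds

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(x$aggregate,
                   tibble::tibble(n_folds = x$n_folds, seed = x$seed))
}

#' Tidy an optimized topic vector
#'
#' @param x A `topic_embedding`.
#' @param ... Unused.
#' @return The per-word weight table with the topic index attached.
#' @export
tidy.topic_embedding <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(topic = x$topic), x$weights)
}

#' Tidy a topic-emotion correlation result
#'
#' @param x A `topic_emotion_correlation`.
#' @param ... Unused.
#' @return The underlying long tibble.
#' @export
tidy.topic_emotion_correlation <- function(x, ...) {
  tibble::as_tibble(unclass_correlation(x))
}

unclass_correlation <- function(x) {
  class(x) <- setdiff(class(x), "topic_emotion_correlation")
  x
}
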