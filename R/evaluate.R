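#' Macro-averaged classification metrics
#'
#' Per-class precision and recall over the union of observed classes, with
#' the 0-convention for empty denominators (a class never predicted has
#' precision 0; a class absent from the truth has recall 0). Macro
#' precision/recall are the unweighted class means — the right default when
#' category sizes are strongly imbalanced — and F1 is the harmonic mean of
#' the two macro values.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return A one-row tibble with `precision`, `recall`, `f1`; the per-class
#'   confusion summary is attached as attribute `"per_class"`.
#' @export
classification_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (length(truth) == 0) stop("empty label vectors", call. = FALSE)
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  classes <- sort_c(unique(c(predicted, truth)))
  per_class <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn,
                   precision = if (tp + fp == 0) 0 else tp / (tp + fp),
                   recall = if (tp + fn == 0) 0 else tp / (tp + fn))
  })
  p <- mean(per_class$precision)
  r <- mean(per_class$recall)
  out <- tibble::tibble(precision = p, recall = r,
                        f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
  attr(out, "per_class") <- per_class
  out
}

#' Stratified k-fold cross-validation harness
#'
#' Splits documents into `folds` stratified folds (seeded), trains the
#' supplied classifier on the complement of each fold, evaluates on the
#' held-out fold with [classification_metrics()], and aggregates by the
#' mean over folds. The classifier is a pluggable
#' `function(train_data) -> function(test_data) -> predicted labels`, so
#' any pipeline (including the package's own primary-topic classifier) can
#' be benchmarked. Classes with fewer members than folds degrade
#' stratification gracefully with a message.
#'
#' @param data Data frame of documents including the label column.
#' @param classifier `function(train) -> function(test) -> labels`.
#' @param folds Number of folds (>= 2).
#' @param seed Seed for the fold split.
#' @param label_col Name of the label column.
#' @return An object of class `eval_report`: list with `folds` (per-fold
#'   metrics tibble), `aggregate` (one-row tibble of fold means),
#'   `assignment` (row -> fold), `seed`, `n_folds`.
#' @export
crossvalidate <- function(data, classifier, folds = 10L, seed = 1L,
                          label_col = "label") {
  stopifnot(folds >= 2, is.function(classifier))
  if (!label_col %in% names(data)) {
    stop("data lacks label column '", label_col, "'", call. = FALSE)
  }
  labels <- as.character(data[[label_col]])
  n <- nrow(data)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  fold_of <- integer(n)
  small <- character(0)
  for (cl in sort_c(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < folds) small <- c(small, cl)
    fold_of[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  if (length(small) > 0) {
    message("crossvalidate: class(es) with fewer members than folds: ",
            paste(small, collapse = ", "), "; stratification degraded")
  }
  per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
    test <- fold_of == f
    preds <- tryCatch({
      fitted <- classifier(data[!test, , drop = FALSE])
      fitted(data[test, , drop = FALSE])
    }, error = function(e) {
      stop("classifier failed on fold ", f, ": ", conditionMessage(e),
           call. = FALSE)
    })
    m <- classification_metrics(preds, labels[test])
    dplyr::bind_cols(tibble::tibble(fold = f, n_test = sum(test)), m)
  })
  aggregate <- per_fold |>
    dplyr::summarise(precision = mean(.data$precision),
                     recall = mean(.data$recall), f1 = mean(.data$f1))
  structure(list(folds = per_fold, aggregate = aggregate,
                 assignment = tibble::tibble(row = seq_len(n), fold = fold_of),
                 seed = as.integer(seed), n_folds = as.integer(folds)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(x$n_folds, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("macro precision %.3f | macro recall %.3f | F1 %.3f\n",
              x$aggregate$precision, x$aggregate$recall, x$aggregate$f1))
  invisible(x)
}

#' Primary-topic classifier for the evaluation harness
#'
#' Builds the pipeline's own document classifier in the pluggable
#' [crossvalidate()] contract: fit LDA on the training documents, label
#' each fitted topic by the majority training class among documents whose
#' primary topic it is, then classify held-out documents by folding them in
#' (phi frozen) and mapping their primary topic through the learned
#' topic-to-class labelling.
#'
#' @param k Number of topics for the underlying LDA fit.
#' @param alpha,beta,n_iter,seed Passed to [fit_lda()].
#' @param n_sweeps Fold-in sweeps for held-out documents.
#' @param label_col Name of the label column in the training data.
#' @return A classifier function for [crossvalidate()].
#' @export
lda_topic_classifier <- function(k, alpha = 1.0, beta = 0.01, n_iter = 1000L,
                                 seed = 1L, n_sweeps = 50L, label_col = "label") {
  force(k)
  function(train) {
    vocab <- build_vocabulary(train)
    model <- fit_lda(train, k = k, alpha = alpha, beta = beta,
                     n_iter = n_iter, seed = seed, vocabulary = vocab)
    train_topics <- primary_topics(model)
    train_labels <- as.character(train[[label_col]])
    fallback <- names(sort(table(train_labels), decreasing = TRUE))[1]
    topic_label <- vapply(seq_len(k), function(t) {
      members <- train_labels[train_topics$topic == t]
      if (length(members) == 0) return(fallback)
      names(sort(table(members), decreasing = TRUE))[1]
    }, character(1))
    function(test) {
      # held-out tokens outside the training vocabulary carry no signal
      test <- test
      test$tokens <- lapply(test$tokens, function(tok) tok[tok %in% vocab$term])
      keep <- lengths(test$tokens) > 0
      preds <- rep(fallback, nrow(test))
      if (any(keep)) {
        st <- corpus_streams(model, test[keep, , drop = FALSE])
        restore <- local_seed(seed + 97L)
        on.exit(restore(), add = TRUE)
        z0 <- sample.int(k, length(st$word), replace = TRUE) - 1L
        theta <- fold_in_cpp(as.integer(st$word), as.integer(st$doc),
                             sum(keep), model$phi, alpha,
                             as.integer(n_sweeps), z0)
        preds[keep] <- topic_label[max.col(theta, ties.method = "first")]
      }
      preds
    }
  }
}
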