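#' Read a topic-to-category map
#'
#' JSON of the form
#' `{"topics": {"1": "Q1", ...}, "labels": {"Q1": "Causes", ...}}`, mapping
#' every raw topic index to a demand-category code with optional
#' human-readable labels. Category labels are user-supplied interpretation,
#' not computed.
#'
#' @param path JSON file path.
#' @return A tibble with columns `topic` (integer), `category`, `label`.
#' @export
read_category_map <- function(path) {
  raw <- jsonlite::fromJSON(path)
  topics <- raw$topics
  tbl <- tibble::tibble(topic = as.integer(names(topics)),
                        category = as.character(unlist(topics)))
  labels <- raw$labels
  tbl$label <- if (is.null(labels)) tbl$category else {
    lab <- as.character(unlist(labels))[match(tbl$category, names(labels))]
    ifelse(is.na(lab), tbl$category, lab)
  }
  dplyr::arrange(tbl, .data$topic)
}

#' Aggregate primary topics into categories
#'
#' Counts documents per demand category under a topic-to-category map and
#' reports proportions as percentages rounded to two decimals. The counts
#' partition the corpus; every assigned topic must be mapped.
#'
#' @param assignments Tibble with columns `doc_id` and `topic` (e.g. from
#'   [primary_topics()]).
#' @param cmap Tibble with columns `topic` and `category` (see
#'   [read_category_map()]).
#' @return A tibble with `category`, `count`, `proportion` (percent, two
#'   decimals), covering every category in `cmap`.
#' @export
categorize <- function(assignments, cmap) {
  unmapped <- setdiff(unique(assignments$topic), cmap$topic)
  if (length(unmapped) > 0) {
    stop("unmapped topic(s): ", paste(sort(unmapped), collapse = ", "),
         call. = FALSE)
  }
  cats <- unique(cmap$category)
  joined <- dplyr::left_join(assignments, cmap[, c("topic", "category")],
                             by = "topic")
  counts <- table(factor(joined$category, levels = cats))
  total <- nrow(assignments)
  tibble::tibble(category = cats,
                 count = as.integer(counts),
                 proportion = round(100 * as.integer(counts) / total, 2))
}

#' Per-category polarity distribution
#'
#' For each category, counts positive / negative / neutral documents and
#' reports `pct_pos = round(100 * n_pos / (n_pos + n_neg))` (nearest
#' integer) with `pct_neg = 100 - pct_pos`. Neutral documents are counted
#' separately and excluded from the percentages; a category with no
#' non-neutral documents gets `NA` percentages rather than 0.
#'
#' @param data Tibble with columns `category` and `polarity` (per-document
#'   values in \{-1, 0, 1\}).
#' @return A tibble with `category`, `n_pos`, `n_neg`, `n_neutral`,
#'   `pct_pos`, `pct_neg`.
#' @export
polarity_distribution <- function(data) {
  stopifnot(all(c("category", "polarity") %in% names(data)))
  data |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_pos = sum(.data$polarity > 0),
      n_neg = sum(.data$polarity < 0),
      n_neutral = sum(.data$polarity == 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_pos = ifelse(.data$n_pos + .data$n_neg == 0, NA_real_,
                       round(100 * .data$n_pos / (.data$n_pos + .data$n_neg))),
      pct_neg = 100 - .data$pct_pos
    )
}

#' Topic-emotion Pearson correlation
#'
#' For every (category, emotion subcategory) pair, correlates the
#' per-document category indicator variable with the per-document emotion
#' intensity across documents (Pearson r), with a two-sided p-value from
#' the t transform on `M - 2` degrees of freedom. Cells where either
#' variable is constant are recorded as undefined (masked, never
#' NaN-propagated). Significance uses the raw p-value threshold by default;
#' Benjamini-Hochberg adjustment is available.
#'
#' @param data Tibble with a `category` column and the 21 `profile_*`
#'   columns of [emotion_profiles()]; one row per document (>= 3 rows).
#' @param threshold Significance threshold on p.
#' @param adjust `"none"` (raw p, default) or `"BH"`.
#' @return An object of class `topic_emotion_correlation`: a tibble with
#'   `category`, `subcategory`, `r`, `p`, `defined`, `significant`, plus
#'   attributes `threshold` and `n`.
#' @export
topic_emotion_correlation <- function(data, threshold = 0.05,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(data) < 3) stop("need at least 3 documents", call. = FALSE)
  prof_cols <- grep("^profile_", names(data), value = TRUE)
  if (length(prof_cols) == 0) stop("no profile_* columns found", call. = FALSE)
  cats <- sort_c(unique(as.character(data$category)))
  n <- nrow(data)
  grid <- tidyr::expand_grid(category = cats, column = prof_cols)
  res <- purrr::pmap_dfr(grid, function(category, column) {
    ind <- as.numeric(data$category == category)
    y <- data[[column]]
    if (sd(ind) == 0 || sd(y) == 0) {
      return(tibble::tibble(category = category,
                            subcategory = sub("^profile_", "", column),
                            r = NA_real_, p = NA_real_, defined = FALSE))
    }
    r <- cor(ind, y)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(category = category,
                   subcategory = sub("^profile_", "", column),
                   r = r, p = 2 * pt(-abs(tstat), df = n - 2), defined = TRUE)
  })
  p_used <- if (adjust == "BH") stats::p.adjust(res$p, method = "BH") else res$p
  res$significant <- res$defined & !is.na(p_used) & p_used < threshold
  structure(res, class = c("topic_emotion_correlation", class(res)),
            threshold = threshold, n = n, adjust = adjust)
}

#' Wide matrix view of a correlation result
#'
#' @param x A `topic_emotion_correlation`.
#' @param what `"r"` or `"p"`.
#' @return A categories x subcategories matrix.
#' @export
correlation_matrix <- function(x, what = c("r", "p")) {
  what <- match.arg(what)
  wide <- tidyr::pivot_wider(tibble::as_tibble(x)[, c("category", "subcategory", what)],
                             names_from = "subcategory",
                             values_from = dplyr::all_of(what))
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$category
  mat
}

#' Relevance-ranked top words per topic
#'
#' Ranks vocabulary words within each topic by the relevance score
#' `lambda * log(phi_kw) + (1 - lambda) * log(phi_kw / p_w)`, where `p_w`
#' is the empirical corpus frequency of `w` — the interpolation between
#' topic probability (`lambda = 1`) and lift (`lambda = 0`) used by
#' pyLDAvis-style topic browsers. Words with zero corpus frequency are
#' excluded.
#'
#' @param model An `lda_model`.
#' @param lambda Interpolation weight in \[0, 1\].
#' @param top_n Words per topic.
#' @param data Optional corpus tibble for the word frequencies; defaults to
#'   the training corpus.
#' @return A tibble with `topic`, `rank`, `word`, `relevance`.
#' @export
relevance_top_words <- function(model, lambda = 0.6, top_n = 30L, data = NULL) {
  stopifnot(inherits(model, "lda_model"), lambda >= 0, lambda <= 1)
  word <- if (is.null(data)) model$tokens$word else corpus_streams(model, data)$word
  counts <- tabulate(word + 1L, nbins = nrow(model$vocabulary))
  p_w <- counts / sum(counts)
  keep <- p_w > 0
  purrr::map_dfr(seq_len(model$k), function(k) {
    phi_k <- model$phi[k, keep]
    rel <- lambda * log(phi_k) + (1 - lambda) * log(phi_k / p_w[keep])
    terms <- model$vocabulary$term[keep]
    ord <- order(-rel, terms, method = "radix")
    sel <- head(ord, top_n)
    tibble::tibble(topic = k, rank = seq_along(sel),
                   word = terms[sel], relevance = unname(rel[sel]))
  })
}
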