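#' Fit LDA by collapsed Gibbs sampling
#'
#' Estimates a latent Dirichlet allocation model on a tokenized corpus with
#' a fixed number of full collapsed-Gibbs sweeps. A token's topic is
#' resampled with probability proportional to
#' `(n_mk + alpha) * (n_kw + beta) / (n_k + V*beta)` (own count removed),
#' and the returned point estimates are the smoothed
#' `phi_kw = (n_kw + beta) / (n_k + V*beta)` and
#' `theta_mk = (n_mk + alpha) / (n_m + K*alpha)` from the final state.
#' Identical `(data, hyperparameters, seed)` give bit-identical chains.
#'
#' @param data Corpus tibble with columns `doc_id` and `tokens`
#'   (list-column), e.g. from [preprocess_corpus()] or
#'   [generate_corpus()].
#' @param k Number of topics (>= 1).
#' @param alpha Dirichlet concentration of the document-topic prior.
#' @param beta Dirichlet concentration of the topic-word prior.
#' @param n_iter Number of full Gibbs sweeps.
#' @param seed RNG seed for the chain.
#' @param vocabulary Optional vocabulary tibble (`term`, `index`); defaults
#'   to the corpus attribute or to [build_vocabulary()] on `data`. Every
#'   corpus token must be in the vocabulary.
#' @param trace_every If > 0, record the full assignment vector every
#'   `trace_every`-th sweep (for posterior diagnostics on tiny corpora).
#' @return An object of class `lda_model` with elements `phi` (K x V,
#'   row-stochastic), `theta` (M x K, row-stochastic), `assignments`
#'   (per-document integer vectors of 1-based topic labels), `vocabulary`,
#'   `doc_ids`, hyperparameters, and the token stream used for fitting.
#' @seealso [perplexity()], [coherence()], [select_k()], [tidy.lda_model()]
#' @export
fit_lda <- function(data, k, alpha = 1.0, beta = 0.01, n_iter = 1000L,
                    seed = 1L, vocabulary = NULL, trace_every = 0L) {
  check_corpus_tbl(data)
  stopifnot(k >= 1, alpha > 0, beta > 0, n_iter >= 1)
  vocabulary <- vocabulary %||% attr(data, "vocabulary") %||% build_vocabulary(data)
  if (nrow(data) == 0) stop("empty corpus", call. = FALSE)

  idx <- stats::setNames(vocabulary$index, vocabulary$term)
  toks <- unlist(data$tokens, use.names = FALSE)
  if (length(toks) == 0) stop("empty corpus", call. = FALSE)
  word <- unname(idx[toks])
  if (anyNA(word)) {
    bad <- toks[which(is.na(word))[1]]
    stop("token not in vocabulary: '", bad, "'", call. = FALSE)
  }
  doc <- rep(seq_len(nrow(data)) - 1L, lengths(data$tokens))
  if (k > length(word)) {
    warning("k = ", k, " exceeds the total token count (", length(word), ")",
            call. = FALSE)
  }

  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  z_init <- sample.int(k, length(word), replace = TRUE) - 1L
  fit <- gibbs_lda_cpp(as.integer(word), as.integer(doc),
                       nrow(vocabulary), nrow(data), as.integer(k),
                       alpha, beta, as.integer(n_iter), z_init,
                       as.integer(trace_every))

  phi <- fit$phi
  dimnames(phi) <- list(NULL, vocabulary$term)
  theta <- fit$theta
  dimnames(theta) <- list(data$doc_id, NULL)
  structure(list(
    phi = phi,
    theta = theta,
    assignments = split(fit$z + 1L, factor(doc, levels = 0:(nrow(data) - 1L))) |>
      stats::setNames(data$doc_id),
    vocabulary = vocabulary,
    doc_ids = data$doc_id,
    k = as.integer(k), alpha = alpha, beta = beta,
    n_iter = as.integer(n_iter), seed = as.integer(seed),
    tokens = list(word = word, doc = doc),
    trace = if (trace_every > 0) fit$trace else NULL
  ), class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("LDA model (collapsed Gibbs): K =", x$k,
      "| V =", nrow(x$vocabulary),
      "| M =", length(x$doc_ids),
      "| alpha =", x$alpha, "| beta =", x$beta,
      "| sweeps =", x$n_iter, "| seed =", x$seed, "\n")
  invisible(x)
}

# map a token corpus onto a model's vocabulary, erroring on unknown tokens
corpus_streams <- function(model, data) {
  check_corpus_tbl(data)
  idx <- stats::setNames(model$vocabulary$index, model$vocabulary$term)
  toks <- unlist(data$tokens, use.names = FALSE)
  word <- unname(idx[toks])
  if (anyNA(word)) {
    bad <- toks[which(is.na(word))[1]]
    stop("token not in model vocabulary: '", bad, "'", call. = FALSE)
  }
  list(word = word, doc = rep(seq_len(nrow(data)) - 1L, lengths(data$tokens)))
}

#' Corpus perplexity under a fitted model
#'
#' Computes `exp(-sum(log p(w)) / N)` with
#' `p(w) = sum_k theta_dk phi_kw`. On the training corpus (default) the
#' fitted `theta` is used; for held-out documents `theta` is re-estimated by
#' fold-in Gibbs sampling with `phi` frozen (`n_sweeps` seeded sweeps), the
#' stated procedure for evaluating unseen text. Lower is better.
#'
#' @param model An `lda_model`.
#' @param newdata Optional held-out corpus tibble (`doc_id`, `tokens`);
#'   tokens must be in the model vocabulary.
#' @param n_sweeps Fold-in sweeps for held-out documents.
#' @param seed Seed for the fold-in chain.
#' @return A positive scalar.
#' @export
perplexity <- function(model, newdata = NULL, n_sweeps = 50L, seed = NULL) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(newdata)) {
    word <- model$tokens$word
    doc <- model$tokens$doc
    theta <- model$theta
  } else {
    st <- corpus_streams(model, newdata)
    word <- st$word
    doc <- st$doc
    seed <- seed %||% (model$seed + 1L)
    restore <- local_seed(seed)
    on.exit(restore(), add = TRUE)
    z_init <- sample.int(model$k, length(word), replace = TRUE) - 1L
    theta <- fold_in_cpp(as.integer(word), as.integer(doc), nrow(newdata),
                         model$phi, model$alpha, as.integer(n_sweeps), z_init)
  }
  # p for token n: <theta[doc_n, ], phi[, word_n]>
  pw <- rowSums(theta[doc + 1L, , drop = FALSE] *
                  t(model$phi)[word + 1L, , drop = FALSE])
  if (any(pw <= 0)) stop("zero-probability token under the mixture", call. = FALSE)
  exp(-sum(log(pw)) / length(pw))
}

# top_n vocabulary terms of topic k, ranked by phi (ties broken by term)
topic_top_terms <- function(model, k, top_n) {
  phi_k <- model$phi[k, ]
  ord <- order(-phi_k, model$vocabulary$term, method = "radix")
  head(model$vocabulary$term[ord], top_n)
}

#' UMass topic coherence
#'
#' For each topic's `top_n` words ranked by `phi`, sums
#' `log((D(w_i, w_j) + 1) / D(w_j))` over ranked pairs `i < j`, where `D`
#' counts documents containing a word (or both words), and averages the
#' per-topic sums. Corpus-internal and deterministic; higher means more
#' interpretable topics. Pairs whose denominator count is zero are skipped
#' with a message.
#'
#' @param model An `lda_model`.
#' @param data Optional corpus tibble for the co-occurrence counts; defaults
#'   to the training corpus.
#' @param top_n Number of top words per topic (>= 1).
#' @return A scalar (mean over topics).
#' @export
coherence <- function(model, data = NULL, top_n = 10L) {
  stopifnot(inherits(model, "lda_model"), top_n >= 1)
  if (is.null(data)) {
    doc_sets <- split(model$tokens$word, model$tokens$doc)
    doc_sets <- lapply(doc_sets, function(w) unique(model$vocabulary$term[w + 1L]))
  } else {
    check_corpus_tbl(data)
    doc_sets <- lapply(data$tokens, unique)
  }
  n_skipped <- 0L
  per_topic <- vapply(seq_len(model$k), function(k) {
    words <- topic_top_terms(model, k, top_n)
    if (length(words) < 2) return(0)
    contains <- vapply(words, function(w)
      vapply(doc_sets, function(s) w %in% s, logical(1)), logical(length(doc_sets)))
    contains <- matrix(contains, ncol = length(words))
    d_single <- colSums(contains)
    score <- 0
    for (j in 2:length(words)) {
      for (i in seq_len(j - 1)) {
        if (d_single[j] == 0) {
          n_skipped <<- n_skipped + 1L
          next
        }
        d_ij <- sum(contains[, i] & contains[, j])
        score <- score + log((d_ij + 1) / d_single[j])
      }
    }
    score
  }, numeric(1))
  if (n_skipped > 0) {
    message("coherence: skipped ", n_skipped, " pair(s) with zero document frequency")
  }
  mean(per_topic)
}

#' Select the number of topics
#'
#' Fits one model per candidate `k` per replicate (distinct derived seeds),
#' records training perplexity and UMass coherence for each fit, and selects
#' the `k` with the highest mean coherence (ties go to the smallest `k`,
#' favouring parsimony). The full per-fit table supports
#' perplexity/coherence-vs-K curves via [autoplot.lda_k_selection()].
#'
#' @param data Corpus tibble (`doc_id`, `tokens`).
#' @param k_grid Ascending integer vector of candidate topic counts.
#' @param replicates Fits per candidate `k`.
#' @param alpha,beta,n_iter Passed to [fit_lda()].
#' @param seed Base seed; each (k, replicate) fit derives its own seed.
#' @param top_n Top words per topic for [coherence()].
#' @param vocabulary Optional shared vocabulary.
#' @return An object of class `lda_k_selection`: list with `table` (per-fit
#'   tibble), `summary` (per-k means), and `selected_k`.
#' @export
select_k <- function(data, k_grid, replicates = 1L, alpha = 1.0, beta = 0.01,
                     n_iter = 1000L, seed = 1L, top_n = 10L, vocabulary = NULL) {
  if (length(k_grid) == 0) stop("k_grid must be non-empty", call. = FALSE)
  if (is.unsorted(k_grid, strictly = TRUE)) {
    stop("k_grid must be strictly ascending", call. = FALSE)
  }
  vocabulary <- vocabulary %||% attr(data, "vocabulary") %||% build_vocabulary(data)
  grid <- tidyr::expand_grid(k = as.integer(k_grid),
                             replicate = seq_len(replicates))
  grid$seed <- as.integer(seed + 611L * grid$replicate + grid$k)
  rows <- purrr::pmap(grid, function(k, replicate, seed) {
    tryCatch({
      fit <- fit_lda(data, k = k, alpha = alpha, beta = beta,
                     n_iter = n_iter, seed = seed, vocabulary = vocabulary)
      tibble::tibble(k = k, replicate = replicate, seed = seed,
                     perplexity = perplexity(fit),
                     coherence = coherence(fit, top_n = top_n))
    }, error = function(e) {
      message("select_k: fit failed for k = ", k, " (", conditionMessage(e),
              "); skipping")
      NULL
    })
  })
  table <- dplyr::bind_rows(rows)
  if (nrow(table) == 0) stop("all candidate fits failed", call. = FALSE)
  summary <- table |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_perplexity = mean(.data$perplexity),
                     mean_coherence = mean(.data$coherence), .groups = "drop") |>
    dplyr::arrange(.data$k)
  selected_k <- summary$k[which.max(summary$mean_coherence)]
  structure(list(table = table, summary = summary,
                 selected_k = as.integer(selected_k),
                 k_grid = as.integer(k_grid), replicates = as.integer(replicates)),
            class = "lda_k_selection")
}

#' @export
print.lda_k_selection <- function(x, ...) {
  cat("Topic-count selection over k in {", paste(x$k_grid, collapse = ", "),
      "} with", x$replicates, "replicate(s)\n")
  cat("Selected k =", x$selected_k, "(highest mean coherence)\n")
  print(x$summary)
  invisible(x)
}

#' Serialize a fitted LDA model to a directory
#'
#' Writes `phi.csv` (topic x term), `theta.csv` (document x topic),
#' `assignments.csv` (token-level topic labels), and `meta.json`
#' (hyperparameters, seed, vocabulary fingerprint), all full precision.
#'
#' @param model An `lda_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lda <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phi_tbl <- tibble::as_tibble(model$phi)
  phi_tbl <- dplyr::bind_cols(tibble::tibble(topic = seq_len(model$k)), phi_tbl)
  readr::write_csv(phi_tbl, file.path(dir, "phi.csv"))
  theta_tbl <- tibble::as_tibble(model$theta, .name_repair = ~ paste0("topic_", seq_len(model$k)))
  theta_tbl <- dplyr::bind_cols(tibble::tibble(doc_id = model$doc_ids), theta_tbl)
  readr::write_csv(theta_tbl, file.path(dir, "theta.csv"))
  assign_tbl <- tibble::tibble(
    doc_id = rep(model$doc_ids, lengths(model$assignments)),
    position = unlist(lapply(lengths(model$assignments), seq_len), use.names = FALSE),
    term = model$vocabulary$term[model$tokens$word + 1L],
    topic = unlist(model$assignments, use.names = FALSE)
  )
  readr::write_csv(assign_tbl, file.path(dir, "assignments.csv"))
  meta <- list(k = model$k, alpha = model$alpha, beta = model$beta,
               n_iter = model$n_iter, seed = model$seed,
               v = nrow(model$vocabulary), m = length(model$doc_ids),
               vocabulary_hash = sum(hash31(model$vocabulary$term)) %% 2147483647)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a serialized LDA model
#'
#' @param dir Directory written by [write_lda()].
#' @return An `lda_model` (without the Gibbs trace).
#' @export
read_lda <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  phi_tbl <- readr::read_csv(file.path(dir, "phi.csv"), col_types = readr::cols(), progress = FALSE)
  terms <- setdiff(names(phi_tbl), "topic")
  phi <- as.matrix(phi_tbl[, terms])
  theta_tbl <- readr::read_csv(file.path(dir, "theta.csv"), col_types = readr::cols(), progress = FALSE)
  theta <- as.matrix(theta_tbl[, setdiff(names(theta_tbl), "doc_id")])
  dimnames(theta) <- list(theta_tbl$doc_id, NULL)
  assign_tbl <- readr::read_csv(file.path(dir, "assignments.csv"),
                                col_types = readr::cols(), progress = FALSE)
  assign_tbl$topic <- as.integer(assign_tbl$topic)
  vocabulary <- tibble::tibble(term = terms, index = seq_along(terms) - 1L)
  idx <- stats::setNames(vocabulary$index, vocabulary$term)
  doc_ids <- theta_tbl$doc_id
  doc_f <- factor(assign_tbl$doc_id, levels = doc_ids)
  structure(list(
    phi = phi, theta = theta,
    assignments = split(assign_tbl$topic, doc_f) |> stats::setNames(doc_ids),
    vocabulary = vocabulary, doc_ids = doc_ids,
    k = as.integer(meta$k), alpha = meta$alpha, beta = meta$beta,
    n_iter = as.integer(meta$n_iter), seed = as.integer(meta$seed),
    tokens = list(word = unname(idx[assign_tbl$term]),
                  doc = as.integer(doc_f) - 1L),
    trace = NULL
  ), class = "lda_model")
}
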