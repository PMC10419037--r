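#' Embedding providers
#'
#' An embedding provider is a deterministic mapping from tokens to real
#' vectors of a fixed dimension `d` — the contract behind topic-vector
#' refinement and document fusion. Any deterministic source satisfies it;
#' two are shipped:
#'
#' * `embedding_hash()` draws a fixed unit vector per token from a stable
#'   string hash combined with `seed` (no training, no files; the default in
#'   tests and simulations);
#' * `embedding_table()` reads a TSV table with header
#'   `token dim_0 ... dim_{d-1}`, e.g. exported from an external contextual
#'   model.
#'
#' @param dim Embedding dimension.
#' @param seed Seed mixed into each token's hash.
#' @return An object of class `embedding_provider` with fields `name`,
#'   `dim`, and `embed` (a `function(tokens) -> matrix`).
#' @examples
#' p <- embedding_hash(dim = 8, seed = 1)
#' embed_tokens(p, c("fever", "cough"))
#' @export
embedding_hash <- function(dim = 16L, seed = 42L) {
  stopifnot(dim >= 1)
  cache <- new.env(parent = emptyenv())
  embed <- function(tokens) {
    out <- matrix(NA_real_, nrow = length(tokens), ncol = dim,
                  dimnames = list(tokens, NULL))
    for (i in seq_along(tokens)) {
      tok <- tokens[i]
      if (is.null(cache[[tok]])) {
        token_seed <- (hash31(tok) + 2654435.0 * seed) %% 2147483646 + 1
        restore <- local_seed(as.integer(token_seed))
        v <- rnorm(dim)
        restore()
        cache[[tok]] <- v / sqrt(sum(v^2))
      }
      out[i, ] <- cache[[tok]]
    }
    out
  }
  structure(list(name = sprintf("hash:seed=%d,dim=%d", seed, dim),
                 dim = as.integer(dim), embed = embed),
            class = "embedding_provider")
}

#' @rdname embedding_hash
#' @param path TSV file with header `token dim_0 ... dim_{d-1}`.
#' @export
embedding_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (names(tbl)[1] != "token" || ncol(tbl) < 2) {
    stop("embedding table must have header 'token dim_0 ... dim_{d-1}'", call. = FALSE)
  }
  mat <- as.matrix(tbl[, -1])
  rownames(mat) <- tbl$token
  dim <- ncol(mat)
  embed <- function(tokens) {
    missing <- setdiff(tokens, rownames(mat))
    if (length(missing) > 0) {
      stop("no embedding for token(s): ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    mat[tokens, , drop = FALSE]
  }
  structure(list(name = paste0("table:", basename(path)), dim = as.integer(dim),
                 embed = embed),
            class = "embedding_provider")
}

#' @rdname embedding_hash
#' @param provider An `embedding_provider`.
#' @param tokens Character vector.
#' @export
embed_tokens <- function(provider, tokens) {
  stopifnot(inherits(provider, "embedding_provider"))
  provider$embed(tokens)
}

#' Sinusoidal position encoding
#'
#' Fixed deterministic encoding `pe[p, j] = sin(p / 10000^((j-1)/d))` for
#' 0-based positions, so position 0 maps to the zero vector and nearby
#' positions map to nearby vectors. Not learned; no training is in scope.
#'
#' @param positions Integer vector of 0-based token positions.
#' @param dim Encoding dimension.
#' @return A `length(positions)` x `dim` matrix.
#' @export
position_encoding <- function(positions, dim) {
  freq <- 10000^((seq_len(dim) - 1) / dim)
  outer(as.numeric(positions), freq, function(p, f) sin(p / f))
}

#' Initial topic vector from top-word embeddings
#'
#' The embedding-space seed for a topic: the phi-weighted sum of the
#' embeddings of the topic's `top_n` highest-probability words, normalized
#' to unit length.
#'
#' @param model An `lda_model`.
#' @param provider An `embedding_provider`.
#' @param k Topic index (1-based).
#' @param top_n Number of top words.
#' @return A unit-length numeric vector of length `provider$dim`.
#' @export
initial_topic_vector <- function(model, provider, k, top_n = 30L) {
  stopifnot(inherits(model, "lda_model"), top_n >= 1, k >= 1, k <= model$k)
  words <- topic_top_terms(model, k, top_n)
  e <- embed_tokens(provider, words)
  mu <- colSums(model$phi[k, words] * e)
  mu <- unit_norm(mu)
  if (is.null(mu)) stop("degenerate topic embedding", call. = FALSE)
  unname(mu)
}

#' Optimized topic vector
#'
#' Refines the initial topic vector by iteratively re-weighting the topic's
#' top words: weights `u_w` are proportional to `phi_kw * max(0, cos(e_w,
#' mu))` (normalized to sum to 1; negative cosines are clipped so the
#' weights stay a probability vector), then `mu` is replaced by the
#' normalized `u`-weighted sum of the embeddings — a power-iteration-style
#' loop that sharpens the topic direction toward words that are both
#' probable under the topic and semantically aligned with it. Iteration
#' stops when `1 - cos(mu_new, mu_old) < tol` or after `max_iter` rounds.
#' If every cosine is clipped at some iterate, that round falls back to
#' phi-only weights (with a message).
#'
#' @inheritParams initial_topic_vector
#' @param tol Convergence tolerance on `1 - cos(mu_new, mu_old)`.
#' @param max_iter Iteration cap.
#' @return An object of class `topic_embedding`: list with `topic`,
#'   `mu0` (initial vector), `mu_prime` (unit optimized vector), `weights`
#'   (tibble `word`, `weight`), `objective` (weighted-cosine trajectory),
#'   `iterations`, `converged`.
#' @export
optimize_topic_vector <- function(model, provider, k, top_n = 30L,
                                  tol = 1e-6, max_iter = 100L) {
  words <- topic_top_terms(model, k, top_n)
  e <- embed_tokens(provider, words)
  e_norms <- sqrt(rowSums(e^2))
  if (any(e_norms < 1e-12)) stop("zero-length embedding among top words", call. = FALSE)
  phi_w <- model$phi[k, words]
  mu0 <- initial_topic_vector(model, provider, k, top_n)

  mu <- mu0
  objective <- numeric(0)
  converged <- FALSE
  it <- 0L
  u <- phi_w / sum(phi_w)
  while (it < max_iter) {
    it <- it + 1L
    cosines <- as.vector(e %*% mu) / e_norms
    u <- phi_w * pmax(0, cosines)
    if (sum(u) == 0) {
      message("optimize_topic_vector: all cosines non-positive at iteration ",
              it, "; falling back to phi-only weights")
      u <- phi_w
    }
    u <- u / sum(u)
    mu_new <- unname(unit_norm(colSums(u * e)))
    if (is.null(mu_new)) stop("degenerate topic embedding", call. = FALSE)
    objective[it] <- sum(u * (as.vector(e %*% mu_new) / e_norms))
    delta <- 1 - sum(mu_new * mu)
    mu <- mu_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(topic = as.integer(k), mu0 = mu0, mu_prime = mu,
                 weights = tibble::tibble(word = words, weight = unname(u)),
                 objective = objective, iterations = it, converged = converged),
            class = "topic_embedding")
}

#' @export
print.topic_embedding <- function(x, ...) {
  cat("Optimized topic vector for topic", x$topic, "| dim =", length(x$mu_prime),
      "|", x$iterations, "iteration(s)",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

# extract a K x d matrix from a list of topic_embedding objects (or pass a
# matrix through)
topic_vector_matrix <- function(topic_vectors, k) {
  if (is.matrix(topic_vectors)) {
    stopifnot(nrow(topic_vectors) == k)
    return(topic_vectors)
  }
  stopifnot(length(topic_vectors) == k)
  do.call(rbind, lapply(topic_vectors, function(tv) {
    stopifnot(inherits(tv, "topic_embedding"))
    tv$mu_prime
  }))
}

#' Optimize topic vectors for every topic
#'
#' @inheritParams optimize_topic_vector
#' @return A list of `topic_embedding` objects, one per topic.
#' @export
optimize_topic_vectors <- function(model, provider, top_n = 30L,
                                   tol = 1e-6, max_iter = 100L) {
  lapply(seq_len(model$k), function(k)
    optimize_topic_vector(model, provider, k, top_n = top_n,
                          tol = tol, max_iter = max_iter))
}

#' Fused document representations
#'
#' Builds one vector per document by combining, for every token, its word
#' embedding, a sinusoidal position encoding, the document embedding (mean
#' of the document's word embeddings), and the optimized vector of the
#' topic the token was assigned to by the Gibbs chain; the document vector
#' is the mean over its token vectors. All four summands live in the
#' provider's dimension `d`, so "+" is plain vector addition. Deterministic
#' and local to each document.
#'
#' @param data Corpus tibble the model was fitted on (`doc_id`, `tokens`).
#' @param model The `lda_model` fitted on `data`.
#' @param topic_vectors List from [optimize_topic_vectors()] (or a K x d
#'   matrix of topic vectors).
#' @param provider The `embedding_provider` used for the topic vectors.
#' @return A tibble with `doc_id` and `dim_0 ... dim_{d-1}` columns.
#' @export
fuse_corpus <- function(data, model, topic_vectors, provider) {
  check_corpus_tbl(data)
  mu <- topic_vector_matrix(topic_vectors, model$k)
  stopifnot(ncol(mu) == provider$dim)
  vecs <- purrr::map2(data$doc_id, data$tokens, function(id, toks) {
    z <- model$assignments[[id]]
    if (is.null(z) || length(z) != length(toks)) {
      stop("model/corpus mismatch for document '", id, "'", call. = FALSE)
    }
    e <- embed_tokens(provider, toks)
    rho <- position_encoding(seq_along(toks) - 1L, provider$dim)
    delta <- colMeans(e)
    tok_vecs <- e + rho + matrix(delta, nrow = length(toks),
                                 ncol = provider$dim, byrow = TRUE) +
      mu[z, , drop = FALSE]
    colMeans(tok_vecs)
  })
  out <- tibble::as_tibble(do.call(rbind, vecs),
                           .name_repair = ~ paste0("dim_", seq_len(provider$dim) - 1L))
  dplyr::bind_cols(tibble::tibble(doc_id = data$doc_id), out)
}

#' Primary-topic classification
#'
#' Assigns each document the topic with the highest fitted `theta`
#' probability (its hard label); exact ties go to the smallest topic index.
#'
#' @param model An `lda_model`.
#' @return A tibble with columns `doc_id` and `topic` (1-based).
#' @export
primary_topics <- function(model) {
  stopifnot(inherits(model, "lda_model"))
  tibble::tibble(doc_id = model$doc_ids,
                 topic = max.col(model$theta, ties.method = "first"))
}

#' Export optimized topic vectors
#'
#' Writes `topic_vectors.csv` (`topic,converged,iterations,dim_0...`) and
#' `topic_weights.csv` (`topic,word,weight`).
#'
#' @param topic_vectors List of `topic_embedding` objects.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_topic_vectors <- function(topic_vectors, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- length(topic_vectors[[1]]$mu_prime)
  vec_tbl <- purrr::map_dfr(topic_vectors, function(tv) {
    row <- tibble::as_tibble(matrix(tv$mu_prime, nrow = 1),
                             .name_repair = ~ paste0("dim_", seq_len(d) - 1L))
    dplyr::bind_cols(tibble::tibble(topic = tv$topic, converged = tv$converged,
                                    iterations = tv$iterations), row)
  })
  readr::write_csv(vec_tbl, file.path(dir, "topic_vectors.csv"))
  w_tbl <- purrr::map_dfr(topic_vectors, function(tv)
    dplyr::bind_cols(tibble::tibble(topic = tv$topic), tv$weights))
  readr::write_csv(w_tbl, file.path(dir, "topic_weights.csv"))
  invisible(dir)
}
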