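#' Specification for a synthetic planted-topic corpus
#'
#' Describes the generative conditions for [generate_corpus()]: a standard
#' LDA forward process with block-structured topics so that ground truth is
#' known and recoverable. Each topic owns a private contiguous block of the
#' vocabulary; `separation` is the fraction of the topic's probability mass
#' placed on its block (the rest comes from a topic-specific
#' Dirichlet(`beta_gen`) draw over the full vocabulary). Emotion structure
#' is planted separately by [inject_emotions()] via `emotion_design` (per
#' topic x subcategory injection rates) and `polarity_mix` (per-topic
#' probability that an injected emotion word is positive).
#'
#' Defaults emulate a desk-scale corpus of short comments: 200 documents of
#' 50 tokens over a 300-word vocabulary with 3 well-separated topics
#' (`separation = 0.9`), concentrated document-topic draws
#' (`alpha_gen = 0.1`, so most documents are dominated by one topic, as
#' short single-question comments are), a one-hot emotion design at rate
#' 0.1, and a per-topic positive share recycling (0.63, 0.27, 0.56) —
#' the kind of spread real per-category positive rates show.
#'
#' @param K_true Planted topic count.
#' @param V Vocabulary size (>= `K_true`).
#' @param M Number of documents.
#' @param L Tokens per document (>= 1).
#' @param alpha_gen,beta_gen Dirichlet concentrations of the generative
#'   process.
#' @param separation Fraction of each topic's mass on its private block.
#' @param emotion_design `K_true` x 21 matrix of injection rates in
#'   \[0, 1\] (columns in [emotion_subcategories()] order); default one-hot
#'   with rate 0.1, each topic tied to a subcategory of a distinct major
#'   category.
#' @param polarity_mix Per-topic probability that an injected emotion word
#'   is positive; recycled to length `K_true`.
#' @param seed RNG seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(K_true = 3L, V = 300L, M = 200L, L = 50L,
                           alpha_gen = 0.1, beta_gen = 0.1, separation = 0.9,
                           emotion_design = NULL, polarity_mix = NULL,
                           seed = 1L) {
  stopifnot(K_true >= 1, V >= K_true, M >= 1, L >= 1,
            alpha_gen > 0, beta_gen > 0, separation >= 0, separation <= 1)
  subcats <- emotion_subcategories()$subcategory
  if (is.null(emotion_design)) {
    # one subcategory per topic, spread over distinct major categories
    spread <- c("PA", "NB", "NI", "PD", "NE", "PC", "NA")
    spread <- c(spread, setdiff(subcats, spread))
    emotion_design <- matrix(0, nrow = K_true, ncol = length(subcats),
                             dimnames = list(NULL, subcats))
    for (k in seq_len(K_true)) {
      emotion_design[k, spread[(k - 1L) %% length(subcats) + 1L]] <- 0.1
    }
  }
  emotion_design <- as.matrix(emotion_design)
  if (is.null(colnames(emotion_design))) colnames(emotion_design) <- subcats
  stopifnot(nrow(emotion_design) == K_true,
            ncol(emotion_design) == length(subcats),
            all(is.finite(emotion_design)),
            all(emotion_design >= 0), all(emotion_design <= 1))
  polarity_mix <- rep_len(polarity_mix %||% c(0.63, 0.27, 0.56), K_true)
  stopifnot(all(polarity_mix >= 0), all(polarity_mix <= 1))
  structure(list(K_true = as.integer(K_true), V = as.integer(V),
                 M = as.integer(M), L = as.integer(L),
                 alpha_gen = alpha_gen, beta_gen = beta_gen,
                 separation = separation, emotion_design = emotion_design,
                 polarity_mix = polarity_mix, seed = as.integer(seed)),
            class = "generator_spec")
}

# Dirichlet draws by normalized gammas; degenerate all-zero rows (possible
# only for very small concentrations) fall back to uniform
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  s <- rowSums(g)
  zero <- s == 0
  if (any(zero)) {
    g[zero, ] <- 1
    s[zero] <- k
  }
  g / s
}

#' Generate a corpus with planted topic structure
#'
#' Runs the LDA generative process forward under a [generator_spec()]:
#' topic-word rows are a `separation`-weighted blend of a flat Dirichlet
#' draw over the topic's private vocabulary block and a Dirichlet
#' (`beta_gen`) draw over the full vocabulary; document-topic rows are
#' Dirichlet(`alpha_gen`); each token samples a topic from its document's
#' row and a word from that topic's row. Reproducible given the spec seed.
#'
#' @param spec A `generator_spec`.
#' @return An object of class `lda_simulation`: list with `corpus`
#'   (tibble `doc_id`, `tokens` with the vocabulary attached), `truth`
#'   (list: `phi`, `theta`, `labels` tibble of planted primary topics —
#'   the argmax of the true `theta` row —, per-token `z`), and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore(), add = TRUE)

  terms <- sprintf("w%04d", seq_len(spec$V))
  blocks <- split(seq_len(spec$V),
                  rep(seq_len(spec$K_true), length.out = spec$V,
                      each = ceiling(spec$V / spec$K_true))[seq_len(spec$V)])
  base <- rdirichlet(spec$K_true, rep(spec$beta_gen, spec$V))
  phi <- (1 - spec$separation) * base
  for (k in seq_len(spec$K_true)) {
    block <- blocks[[k]]
    within <- rdirichlet(1, rep(1, length(block)))[1, ]
    phi[k, block] <- phi[k, block] + spec$separation * within
  }
  colnames(phi) <- terms
  theta <- rdirichlet(spec$M, rep(spec$alpha_gen, spec$K_true))
  labels <- max.col(theta, ties.method = "first")

  doc_ids <- sprintf("doc%04d", seq_len(spec$M))
  z <- vector("list", spec$M)
  tokens <- vector("list", spec$M)
  for (m in seq_len(spec$M)) {
    zm <- sample.int(spec$K_true, spec$L, replace = TRUE, prob = theta[m, ])
    wm <- integer(spec$L)
    for (k in unique(zm)) {
      sel <- zm == k
      wm[sel] <- sample.int(spec$V, sum(sel), replace = TRUE, prob = phi[k, ])
    }
    z[[m]] <- zm
    tokens[[m]] <- terms[wm]
  }
  corpus <- tibble::tibble(doc_id = doc_ids, tokens = tokens)
  attr(corpus, "vocabulary") <- tibble::tibble(term = sort_c(terms),
                                               index = seq_len(spec$V) - 1L)
  structure(list(
    corpus = corpus,
    truth = list(phi = phi, theta = theta,
                 labels = tibble::tibble(doc_id = doc_ids, topic = labels),
                 z = stats::setNames(z, doc_ids), blocks = blocks),
    spec = spec
  ), class = "lda_simulation")
}

#' @export
print.lda_simulation <- function(x, ...) {
  cat("Synthetic planted-topic corpus: K_true =", x$spec$K_true,
      "| V =", x$spec$V, "| M =", x$spec$M, "| L =", x$spec$L,
      "| separation =", x$spec$separation, "| seed =", x$spec$seed, "\n")
  if (!is.null(x$truth$injections)) {
    cat("Injected emotion words:", nrow(x$truth$injections), "\n")
  }
  invisible(x)
}

#' Inject planted emotion words
#'
#' Appends emotion words to the generated corpus according to the spec's
#' `emotion_design`: for a document with planted topic `k` and subcategory
#' `e`, `Binomial(L, emotion_design[k, e])` words are appended, each drawn
#' from the lexicon's entries of that subcategory, positive (polarity 1)
#' with probability `polarity_mix[k]` and negative (polarity -1) otherwise.
#' Appending (rather than substituting) keeps the topic signal and the
#' emotion signal independently controllable. The injected words are
#' recorded in the returned truth.
#'
#' @param sim An `lda_simulation` from [generate_corpus()].
#' @param lexicon Lexicon tibble; must provide at least one word per
#'   (subcategory, polarity) pair the design requests, otherwise the
#'   gaps are reported as an error.
#' @param seed Seed for the injection draws.
#' @return The updated `lda_simulation` (corpus tokens appended;
#'   `truth$injections` tibble with `doc_id`, `subcategory`, `polarity`,
#'   `word`).
#' @export
inject_emotions <- function(sim, lexicon, seed = sim$spec$seed + 1L) {
  stopifnot(inherits(sim, "lda_simulation"))
  spec <- sim$spec
  design <- spec$emotion_design
  subcats <- colnames(design)

  used <- which(design > 0, arr.ind = TRUE)
  if (nrow(used) > 0) {
    need <- unique(tibble::tibble(subcategory = subcats[used[, "col"]]))
    gaps <- character(0)
    for (e in need$subcategory) {
      for (pol in c(1, -1)) {
        if (!any(lexicon$subcategory == e & lexicon$polarity == pol)) {
          gaps <- c(gaps, paste0(e, "/", pol))
        }
      }
    }
    if (length(gaps) > 0) {
      stop("lexicon lacks (subcategory, polarity) pair(s): ",
           paste(gaps, collapse = ", "), call. = FALSE)
    }
  }

  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  corpus <- sim$corpus
  inj <- list()
  for (m in seq_len(spec$M)) {
    k <- sim$truth$labels$topic[m]
    for (e_i in seq_along(subcats)) {
      rate <- design[k, e_i]
      if (rate == 0) next
      n <- rbinom(1, spec$L, rate)
      if (n == 0) next
      pols <- ifelse(runif(n) < spec$polarity_mix[k], 1, -1)
      words <- vapply(pols, function(pol) {
        pool <- lexicon$word[lexicon$subcategory == subcats[e_i] &
                               lexicon$polarity == pol]
        pool[sample.int(length(pool), 1)]
      }, character(1))
      corpus$tokens[[m]] <- c(corpus$tokens[[m]], words)
      inj[[length(inj) + 1]] <- tibble::tibble(
        doc_id = corpus$doc_id[m], subcategory = subcats[e_i],
        polarity = pols, word = words)
    }
  }
  attr(corpus, "vocabulary") <- NULL
  sim$corpus <- corpus
  sim$truth$injections <- if (length(inj) > 0) dplyr::bind_rows(inj) else
    tibble::tibble(doc_id = character(), subcategory = character(),
                   polarity = numeric(), word = character())
  sim
}

#' Generate a schema-conformant synthetic lexicon
#'
#' Builds a lexicon of ASCII pseudo-words covering all 21 subcategories:
#' per subcategory, `n_words_per_subcategory` positive and negative entries
#' (intensities drawn from \{1, 3, 5, 7, 9\}), plus one neutral and one
#' ambivalent entry (polarity 3 with signed scores in \[-4, 4\] on both
#' annotations). The result validates with zero rejects and round-trips
#' through [write_lexicon()] / [read_lexicon()].
#'
#' @param n_words_per_subcategory Entries per polarity per subcategory.
#' @param seed RNG seed.
#' @return A lexicon tibble.
#' @export
generate_lexicon <- function(n_words_per_subcategory = 3L, seed = 1L) {
  stopifnot(n_words_per_subcategory >= 1)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  grades <- c(1, 3, 5, 7, 9)
  pos_tags <- c("adj", "verb", "noun", "adv")
  n <- n_words_per_subcategory
  rows <- purrr::map_dfr(emotion_subcategories()$subcategory, function(sc) {
    signed <- purrr::map_dfr(c(1, -1), function(pol) {
      tibble::tibble(
        word = sprintf("em%s%s%03d", sc, if (pol > 0) "p" else "n", seq_len(n)),
        pos = sample(pos_tags, n, replace = TRUE),
        subcategory = sc,
        intensity = sample(grades, n, replace = TRUE),
        polarity = pol,
        aux_subcategory = NA_character_, aux_intensity = NA_real_,
        aux_polarity = NA_real_, ambiv_score = NA_real_,
        aux_ambiv_score = NA_real_)
    })
    extra <- tibble::tibble(
      word = sprintf("em%s%s001", sc, c("u", "a")),
      pos = sample(pos_tags, 2, replace = TRUE),
      subcategory = sc,
      intensity = sample(grades, 2, replace = TRUE),
      polarity = c(0, 3),
      aux_subcategory = c(NA_character_, sc),
      aux_intensity = c(NA_real_, sample(grades, 1)),
      aux_polarity = c(NA_real_, 3),
      ambiv_score = c(NA_real_, round(runif(1, -4, 4), 1)),
      aux_ambiv_score = c(NA_real_, round(runif(1, -4, 4), 1)))
    dplyr::bind_rows(signed, extra)
  })
  validate_lexicon(rows)
  rows
}

#' Write a simulation to disk
#'
#' Writes `corpus.jsonl` (tokens joined by spaces as each record's text)
#' and a `truth/` directory with `phi.csv`, `theta.csv`, `labels.csv`, and
#' `injections.csv`.
#'
#' @param sim An `lda_simulation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  lines <- purrr::map2_chr(sim$corpus$doc_id, sim$corpus$tokens, function(id, tok)
    jsonlite::toJSON(list(id = id, text = paste(tok, collapse = " ")),
                     auto_unbox = TRUE))
  writeLines(lines, file.path(dir, "corpus.jsonl"), useBytes = TRUE)
  phi_tbl <- dplyr::bind_cols(tibble::tibble(topic = seq_len(nrow(sim$truth$phi))),
                              tibble::as_tibble(sim$truth$phi))
  readr::write_csv(phi_tbl, file.path(dir, "truth", "phi.csv"))
  theta_tbl <- dplyr::bind_cols(
    tibble::tibble(doc_id = sim$corpus$doc_id),
    tibble::as_tibble(sim$truth$theta,
                      .name_repair = ~ paste0("topic_", seq_len(ncol(sim$truth$theta)))))
  readr::write_csv(theta_tbl, file.path(dir, "truth", "theta.csv"))
  readr::write_csv(sim$truth$labels, file.path(dir, "truth", "labels.csv"))
  if (!is.null(sim$truth$injections)) {
    readr::write_csv(sim$truth$injections, file.path(dir, "truth", "injections.csv"))
  }
  invisible(dir)
}

#' Optimal topic matching between two topic-word matrices
#'
#' Matches estimated topics to reference topics by minimizing the total
#' total-variation distance over all permutations (exhaustive for the small
#' K used in recovery studies), and reports the per-topic TV distances
#' under the best permutation.
#'
#' @param phi_est,phi_ref Row-stochastic matrices with identical column
#'   terms (columns are aligned by name when present).
#' @return A list with `permutation` (index into reference topics for each
#'   estimated topic) and `tv` (per-estimated-topic total variation in
#'   \[0, 1\]).
#' @export
match_topics <- function(phi_est, phi_ref) {
  if (!is.null(colnames(phi_est)) && !is.null(colnames(phi_ref))) {
    phi_ref <- phi_ref[, colnames(phi_est), drop = FALSE]
  }
  k <- nrow(phi_est)
  stopifnot(nrow(phi_ref) == k)
  if (k > 8) stop("exhaustive matching supports K <= 8", call. = FALSE)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    d[i, j] <- 0.5 * sum(abs(phi_est[i, ] - phi_ref[j, ]))
  }
  perms <- permutations_of(k)
  costs <- vapply(perms, function(p) sum(d[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.min(costs)]]
  list(permutation = best, tv = d[cbind(seq_len(k), best)])
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permutations_of(k - 1L)) {
      tail <- seq_len(k)[-i][rest]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}
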