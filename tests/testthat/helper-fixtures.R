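# fixture builders shared across test files; everything is constructed in
# code so the suite needs no data files

# one lexicon row in the TSV schema
make_entry <- function(word, subcategory = "PA", intensity = 5, polarity = 1,
                       aux_subcategory = NA_character_, aux_intensity = NA_real_,
                       aux_polarity = NA_real_, ambiv_score = NA_real_,
                       aux_ambiv_score = NA_real_, pos = "adj") {
  tibble::tibble(word = word, pos = pos, subcategory = subcategory,
                 intensity = intensity, polarity = polarity,
                 aux_subcategory = aux_subcategory,
                 aux_intensity = aux_intensity, aux_polarity = aux_polarity,
                 ambiv_score = ambiv_score, aux_ambiv_score = aux_ambiv_score)
}

# small hand-built lexicon covering positive/negative/neutral entries
toy_lexicon <- function() {
  dplyr::bind_rows(
    make_entry("good", "PA", 5, 1),
    make_entry("fine", "PH", 3, 1),
    make_entry("bad", "NB", 5, -1),
    make_entry("awful", "NE", 9, -1),
    make_entry("plain", "PD", 1, 0)
  )
}

# assemble an lda_model by hand: phi columns define the vocabulary order
fake_lda_model <- function(phi, theta, tokens_list, assignments,
                           doc_ids = sprintf("d%d", seq_along(tokens_list)),
                           alpha = 1, beta = 0.01) {
  vocab <- tibble::tibble(term = colnames(phi), index = seq_len(ncol(phi)) - 1L)
  word <- match(unlist(tokens_list, use.names = FALSE), vocab$term) - 1L
  stopifnot(!anyNA(word))
  doc <- rep(seq_along(tokens_list) - 1L, lengths(tokens_list))
  dimnames(theta) <- list(doc_ids, NULL)
  structure(list(
    phi = phi, theta = theta,
    assignments = stats::setNames(assignments, doc_ids),
    vocabulary = vocab, doc_ids = doc_ids,
    k = nrow(phi), alpha = alpha, beta = beta,
    n_iter = 0L, seed = 0L,
    tokens = list(word = word, doc = doc), trace = NULL
  ), class = "lda_model")
}

# tiny raw-text corpus for preprocessing tests
tiny_raw_corpus <- function() {
  tibble::tibble(
    doc_id = c("a", "b", "c", "d"),
    text = c("<p>fever and cough</p>",
             "oh fever fever!",
             "see https://example.org/page now",
             "!?!")
  )
}
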