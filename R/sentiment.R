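#' Emotion subcategory table
#'
#' The 21 emotion subcategories of the Dalian University of Technology
#' sentiment ontology layout, grouped into its 7 major categories (Joy,
#' Good, Anger, Sadness, Fear, Evil, Surprise). Note that the anger
#' subcategory code is the literal string `"NA"`; all readers in this
#' package treat `"NA"` as a real code, never as a missing value.
#'
#' @return A tibble with columns `subcategory` and `category` in canonical
#'   order.
#' @export
emotion_subcategories <- function() {
  tibble::tibble(
    subcategory = c("PA", "PE",
                    "PD", "PH", "PG", "PB", "PK",
                    "NA",
                    "NB", "NJ", "NH", "PF",
                    "NI", "NC", "NG",
                    "NE", "ND", "NN", "NK", "NL",
                    "PC"),
    category = rep(c("Joy", "Good", "Anger", "Sadness", "Fear", "Evil", "Surprise"),
                   times = c(2, 5, 1, 4, 3, 5, 1))
  )
}

lexicon_columns <- c("word", "pos", "subcategory", "intensity", "polarity",
                     "aux_subcategory", "aux_intensity", "aux_polarity",
                     "ambiv_score", "aux_ambiv_score")

# shared row validation for read_lexicon() and generate_lexicon() output;
# `lines` are source line numbers used in error messages
validate_lexicon <- function(lex, lines = seq_len(nrow(lex)) + 1L) {
  subcats <- emotion_subcategories()$subcategory
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(what, " (line ",
                                      paste(lines[rows], collapse = ", "), ")"))
    }
  }
  note(which(is.na(lex$word) | !nzchar(lex$word)), "missing word")
  note(which(!lex$subcategory %in% subcats), "unknown subcategory")
  note(which(!lex$intensity %in% c(1, 3, 5, 7, 9)), "invalid intensity")
  note(which(!lex$polarity %in% c(0, 1, -1, 3)), "invalid polarity")
  note(which(lex$polarity == 3 & is.na(lex$ambiv_score)),
       "polarity 3 without ambivalent score")
  note(which(lex$polarity != 3 & !is.na(lex$ambiv_score)),
       "ambivalent score on non-ambivalent polarity")
  note(which(!is.na(lex$ambiv_score) & abs(lex$ambiv_score) > 4),
       "ambivalent score outside [-4, 4]")
  has_aux <- !is.na(lex$aux_polarity)
  note(which(has_aux & !lex$aux_subcategory %in% subcats),
       "unknown aux subcategory")
  note(which(has_aux & !lex$aux_intensity %in% c(1, 3, 5, 7, 9)),
       "invalid aux intensity")
  note(which(has_aux & !lex$aux_polarity %in% c(0, 1, -1, 3)),
       "invalid aux polarity")
  note(which(has_aux & lex$aux_polarity == 3 & is.na(lex$aux_ambiv_score)),
       "aux polarity 3 without ambivalent score")
  note(which(has_aux & !is.na(lex$aux_ambiv_score) & lex$aux_polarity != 3),
       "aux ambivalent score on non-ambivalent aux polarity")
  note(which(!is.na(lex$aux_ambiv_score) & abs(lex$aux_ambiv_score) > 4),
       "aux ambivalent score outside [-4, 4]")
  if (length(problems) > 0) {
    stop("invalid lexicon rows: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  invisible(lex)
}

#' Read a sentiment lexicon
#'
#' Reads a TSV lexicon mirroring the DUT ontology layout, with header
#' `word pos subcategory intensity polarity aux_subcategory aux_intensity
#' aux_polarity ambiv_score aux_ambiv_score` (aux/ambivalent columns may be
#' empty). Each entry carries an emotion subcategory, an intensity grade in
#' \{1, 3, 5, 7, 9\}, a polarity code in \{0, 1, -1, 3\} (neutral,
#' positive, negative, ambivalent), optionally a second (auxiliary)
#' annotation, and a signed ambivalent score in \[-4, 4\] exactly when the
#' polarity is 3. Invalid codes abort with the offending line numbers; a
#' word duplicated across rows keeps its first row (later rows are dropped
#' with a message).
#'
#' @param path TSV file path (UTF-8). Empty fields must be empty strings —
#'   the literal string `"NA"` is the anger subcategory code.
#' @return A validated lexicon tibble.
#' @export
read_lexicon <- function(path) {
  lex <- readr::read_tsv(path, na = "", col_types = readr::cols(
    word = readr::col_character(), pos = readr::col_character(),
    subcategory = readr::col_character(), intensity = readr::col_double(),
    polarity = readr::col_double(), aux_subcategory = readr::col_character(),
    aux_intensity = readr::col_double(), aux_polarity = readr::col_double(),
    ambiv_score = readr::col_double(), aux_ambiv_score = readr::col_double()
  ), progress = FALSE)
  if (nrow(lex) == 0) stop("empty lexicon file", call. = FALSE)
  missing_cols <- setdiff(lexicon_columns, names(lex))
  if (length(missing_cols) > 0) {
    stop("lexicon is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  validate_lexicon(lex)
  dup <- duplicated(lex$word)
  if (any(dup)) {
    message("read_lexicon: dropped ", sum(dup),
            " duplicate row(s); first occurrence kept")
    lex <- lex[!dup, ]
  }
  lex
}

# snap a combined ambivalent score to the nearest of {-1, 0, 1}; exact ties
# resolve to 0
snap_sentiment <- function(c) {
  vapply(c, function(ci) {
    cand <- c(-1, 0, 1)
    d <- abs(ci - cand)
    hits <- cand[d == min(d)]
    if (length(hits) > 1) 0 else hits
  }, numeric(1))
}

# scalar core of the sentiment-value calculus
word_value_scalar <- function(polarity, intensity, aux_polarity, aux_intensity,
                              ambiv_score, aux_ambiv_score, ratio) {
  if (is.na(aux_polarity)) {
    if (polarity == 3) {
      if (is.na(ambiv_score)) stop("polarity 3 without ambivalent score", call. = FALSE)
      return(list(value = snap_sentiment(ambiv_score), intensity = intensity,
                  rule = "ambivalent-combination"))
    }
    return(list(value = polarity, intensity = intensity, rule = "single"))
  }
  if (polarity == 3 && aux_polarity == 3) {
    if (is.na(ambiv_score) || is.na(aux_ambiv_score)) {
      stop("polarity 3 without ambivalent score", call. = FALSE)
    }
    comb <- ambiv_score + ratio * aux_ambiv_score
    return(list(value = snap_sentiment(comb), intensity = intensity,
                rule = "ambivalent-combination"))
  }
  if (polarity == 3) {
    # mixed pair: fall back to the non-ambivalent (auxiliary) annotation
    return(list(value = aux_polarity, intensity = aux_intensity, rule = "single"))
  }
  if (aux_polarity == 3) {
    return(list(value = polarity, intensity = intensity, rule = "single"))
  }
  if (polarity == aux_polarity) {
    # two identical polarities: the first [intensity, polarity] pair decides
    return(list(value = polarity, intensity = intensity,
                rule = "identical-polarity-first"))
  }
  # two differing non-ambivalent polarities: the first annotation decides
  list(value = polarity, intensity = intensity, rule = "single")
}

#' Sentiment value of a lexicon entry
#'
#' Applies the rule-based sentiment-value calculus to one lexicon entry and
#' returns its value in \{-1, 0, 1\}:
#'
#' * a single annotation with polarity in \{-1, 0, 1\} passes through;
#' * two annotations with identical polarity take the value of the *first*
#'   `[intensity, polarity]` pair;
#' * two ambivalent annotations (both polarity 3) combine their signed
#'   scores as `c = s_prev + ratio * s_next` (default ratio 0.75, the share
#'   given to the later annotation; configurable) and the value is the
#'   member of \{-1, 0, 1\} at minimal absolute distance from `c`, with
#'   exact ties resolving to 0;
#' * a mixed pair (one ambivalent, one not) falls back to the
#'   non-ambivalent annotation.
#'
#' @param entry A one-row data frame (or named list) with the lexicon
#'   columns of [read_lexicon()].
#' @param ratio Weight of the later ambivalent annotation.
#' @return A one-row tibble with `value`, `intensity` (the contributing
#'   grade), and `rule` (`"single"`, `"identical-polarity-first"`, or
#'   `"ambivalent-combination"`).
#' @examples
#' e <- list(word = "w", pos = "adj", subcategory = "PA", intensity = 5,
#'           polarity = 1, aux_subcategory = "PA", aux_intensity = 3,
#'           aux_polarity = 1, ambiv_score = NA, aux_ambiv_score = NA)
#' word_sentiment_value(e)
#' @export
word_sentiment_value <- function(entry, ratio = 0.75) {
  if (is.data.frame(entry)) {
    stopifnot(nrow(entry) == 1)
    entry <- as.list(entry)
  }
  res <- word_value_scalar(entry$polarity, entry$intensity,
                           entry$aux_polarity %||% NA_real_,
                           entry$aux_intensity %||% NA_real_,
                           entry$ambiv_score %||% NA_real_,
                           entry$aux_ambiv_score %||% NA_real_, ratio)
  tibble::tibble(value = res$value, intensity = res$intensity, rule = res$rule)
}

# lexicon with value/rule columns resolved once (vectorized over rows)
lexicon_values <- function(lexicon, ratio = 0.75) {
  vals <- purrr::pmap(
    lexicon[, c("polarity", "intensity", "aux_polarity", "aux_intensity",
                "ambiv_score", "aux_ambiv_score")],
    function(polarity, intensity, aux_polarity, aux_intensity,
             ambiv_score, aux_ambiv_score) {
      word_value_scalar(polarity, intensity, aux_polarity, aux_intensity,
                        ambiv_score, aux_ambiv_score, ratio)
    })
  lexicon$value <- vapply(vals, `[[`, numeric(1), "value")
  lexicon$value_intensity <- vapply(vals, `[[`, numeric(1), "intensity")
  lexicon$rule <- vapply(vals, `[[`, character(1), "rule")
  lexicon
}

#' Sentence sentiment score
#'
#' Matches tokens against the lexicon (exact match; unmatched tokens
#' contribute 0) and sums `value * intensity` over matched occurrences.
#' The sentence polarity is the sign of this magnitude (0 = neutral). The
#' score has bag semantics: permuting tokens never changes it.
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param lexicon Lexicon tibble from [read_lexicon()] or
#'   [generate_lexicon()].
#' @param ratio Passed to the ambivalent combination rule.
#' @return A one-row tibble with `magnitude` and `polarity`.
#' @export
score_sentence <- function(tokens, lexicon, ratio = 0.75) {
  lex <- lexicon_values(lexicon, ratio)
  m <- match(tokens, lex$word)
  hit <- !is.na(m)
  magnitude <- sum(lex$value[m[hit]] * lex$value_intensity[m[hit]])
  tibble::tibble(magnitude = magnitude, polarity = sign(magnitude))
}

#' Split raw text into sentences
#'
#' Splits on terminal punctuation (`。！？!?.`), which must happen before
#' [clean_text()] removes the punctuation.
#'
#' @param text Character vector.
#' @return List of character vectors of sentences.
#' @export
split_sentences <- function(text) {
  pieces <- stringr::str_split(as.character(text), "[。！？!?.]+")
  lapply(pieces, function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

#' Document sentiment scores for a corpus
#'
#' Splits each document into sentences, preprocesses each sentence with the
#' same pipeline as the topic model, scores the sentences, and sums the
#' sentence magnitudes into a document magnitude whose sign is the document
#' polarity (1 positive, -1 negative, 0 neutral). If `data` already holds a
#' `tokens` list-column and no raw text, each document is scored as a
#' single sentence of tokens.
#'
#' @param data Data frame with `doc_id` and either `text` or `tokens`.
#' @param lexicon Lexicon tibble.
#' @param ratio Ambivalent combination ratio.
#' @param stopwords,tokenizer,segmenter Passed to the per-sentence
#'   preprocessing when raw text is scored.
#' @param text_col Name of the raw-text column.
#' @return A tibble with `doc_id`, `magnitude`, `polarity`.
#' @export
score_documents <- function(data, lexicon, ratio = 0.75,
                            stopwords = character(), tokenizer = "whitespace",
                            segmenter = NULL, text_col = "text") {
  lex <- lexicon_values(lexicon, ratio)
  score_bag <- function(tokens) {
    m <- match(tokens, lex$word)
    hit <- !is.na(m)
    sum(lex$value[m[hit]] * lex$value_intensity[m[hit]])
  }
  if (text_col %in% names(data)) {
    sent_tokens <- lapply(split_sentences(data[[text_col]]), function(sents) {
      if (length(sents) == 0) return(list())
      remove_stopwords(tokenize(clean_text(sents), tokenizer, segmenter), stopwords)
    })
    magnitude <- vapply(sent_tokens, function(sents)
      sum(vapply(sents, score_bag, numeric(1)), 0), numeric(1))
  } else {
    check_corpus_tbl(data)
    magnitude <- vapply(data$tokens, score_bag, numeric(1))
  }
  tibble::tibble(doc_id = as.character(data$doc_id),
                 magnitude = magnitude, polarity = sign(magnitude))
}

#' Per-document emotion profiles
#'
#' For each document, sums the intensity of matched lexicon words per
#' emotion subcategory (the entry's primary annotation), giving the
#' 21-dimension emotion intensity vector used in topic-emotion correlation
#' analysis. Documents with no matched words get the zero vector.
#'
#' @param data Corpus tibble with `doc_id` and `tokens`.
#' @param lexicon Lexicon tibble.
#' @return A tibble with `doc_id` and 21 columns `profile_<code>` in the
#'   canonical subcategory order of [emotion_subcategories()].
#' @export
emotion_profiles <- function(data, lexicon) {
  check_corpus_tbl(data)
  subcats <- emotion_subcategories()$subcategory
  prof <- t(vapply(data$tokens, function(tokens) {
    m <- match(tokens, lexicon$word)
    hit <- !is.na(m)
    out <- stats::setNames(numeric(length(subcats)), subcats)
    if (any(hit)) {
      sums <- tapply(lexicon$intensity[m[hit]], lexicon$subcategory[m[hit]], sum)
      out[names(sums)] <- sums
    }
    out
  }, stats::setNames(numeric(length(subcats)), subcats)))
  colnames(prof) <- paste0("profile_", subcats)
  dplyr::bind_cols(tibble::tibble(doc_id = as.character(data$doc_id)),
                   tibble::as_tibble(prof))
}

#' Write a lexicon TSV
#'
#' @param lexicon Lexicon tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  readr::write_tsv(lexicon[, lexicon_columns], path, na = "")
  invisible(path)
}
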