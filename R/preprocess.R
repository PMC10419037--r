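#' Clean raw comment text
#'
#' Strips markup tag spans (`<...>`), scheme-prefixed URLs, control
#' characters, Unicode punctuation and symbol characters, and digit-only
#' tokens, then collapses runs of whitespace to single spaces. The function
#' is total (any character vector in, character vector out) and idempotent.
#'
#' @param x Character vector of raw texts. `NA` is treated as `""`.
#' @return Character vector of the same length.
#' @examples
#' clean_text("<p>hello</p>")
#' clean_text("fever!!! see https://example.org/x now")
#' @export
clean_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringr::str_replace_all(x, "<[^>]*>", " ")
  x <- stringr::str_replace_all(x, "\\b(?:https?|ftp)://\\S+", " ")
  x <- stringr::str_replace_all(x, "[\\p{Cc}\\p{Cf}]", " ")
  x <- stringr::str_replace_all(x, "[\\p{P}\\p{S}]", " ")
  x <- stringr::str_replace_all(x, "(?<=\\s|^)[0-9]+(?=\\s|$)", " ")
  stringr::str_squish(x)
}

#' Tokenize cleaned text
#'
#' Splits each input string into tokens with a named strategy. The
#' `"whitespace"` strategy splits on runs of whitespace; `"segmenter"`
#' delegates to a user-supplied dictionary segmenter (for example a Chinese
#' word segmenter) which must be a deterministic
#' `function(character(1)) -> character()`.
#'
#' @param text Character vector of cleaned texts.
#' @param tokenizer `"whitespace"` or `"segmenter"`.
#' @param segmenter Function used when `tokenizer = "segmenter"`.
#' @return A list of character vectors, one per input string.
#' @examples
#' tokenize("fever and cough")[[1]]
#' @export
tokenize <- function(text, tokenizer = c("whitespace", "segmenter"),
                     segmenter = NULL) {
  tokenizer <- match.arg(tokenizer)
  text <- as.character(text)
  if (tokenizer == "whitespace") {
    out <- stringr::str_split(text, "\\s+")
  } else {
    if (!is.function(segmenter)) {
      stop("tokenizer 'segmenter' requires a segmenter function", call. = FALSE)
    }
    out <- lapply(text, function(s) as.character(segmenter(s)))
  }
  lapply(out, function(tok) tok[nzchar(tok)])
}

#' Remove stopwords from token sequences
#'
#' Exact-match removal that preserves token order; never adds tokens.
#'
#' @param tokens Character vector of tokens, or a list of such vectors.
#' @param stopwords Character vector of stopwords.
#' @return Same shape as `tokens` with stopword members removed.
#' @examples
#' remove_stopwords(c("oh", "fever"), "oh")
#' @export
remove_stopwords <- function(tokens, stopwords) {
  stopwords <- as.character(stopwords)
  if (is.list(tokens)) {
    lapply(tokens, function(tok) tok[!tok %in% stopwords])
  } else {
    tokens[!tokens %in% stopwords]
  }
}

#' Build a corpus vocabulary
#'
#' Collects every token whose corpus frequency reaches `min_count` and
#' assigns contiguous 0-based indices in C-locale lexicographic order, so
#' the mapping is reproducible across runs and platforms.
#'
#' @param data Corpus tibble with a list-column of tokens, or a bare list of
#'   token vectors.
#' @param min_count Minimum corpus frequency for inclusion (>= 1).
#' @param tokens_col Name of the token list-column.
#' @return A tibble with columns `term` and `index` (0-based).
#' @export
build_vocabulary <- function(data, min_count = 1L, tokens_col = "tokens") {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  toks <- if (is.data.frame(data)) data[[tokens_col]] else data
  if (is.null(toks) || length(toks) == 0) stop("empty corpus", call. = FALSE)
  all_tokens <- unlist(toks, use.names = FALSE)
  if (length(all_tokens) == 0) stop("empty corpus", call. = FALSE)
  freq <- table(all_tokens)
  terms <- names(freq)[freq >= min_count]
  if (length(terms) == 0) {
    stop("no token reaches min_count = ", min_count, call. = FALSE)
  }
  terms <- sort_c(terms)
  tibble::tibble(term = terms, index = seq_along(terms) - 1L)
}

#' Preprocess a raw comment corpus
#'
#' Runs the full cleaning pipeline: [clean_text()], [tokenize()],
#' [remove_stopwords()], vocabulary construction with a frequency floor, and
#' removal of tokens that fall below the floor. Documents left empty after
#' preprocessing carry no topic or sentiment signal and are dropped with a
#' message reporting the count.
#'
#' @param data Data frame with columns `doc_id` and `text` (see
#'   [read_corpus()]).
#' @param stopwords Character vector of stopwords (see [read_stopwords()]).
#' @param tokenizer,segmenter Passed to [tokenize()].
#' @param min_count Vocabulary frequency floor, passed to
#'   [build_vocabulary()].
#' @param text_col Name of the raw-text column.
#' @return A tibble with columns `doc_id` and `tokens` (list-column) and the
#'   vocabulary attached as attribute `"vocabulary"`.
#' @export
preprocess_corpus <- function(data, stopwords = character(),
                              tokenizer = "whitespace", segmenter = NULL,
                              min_count = 1L, text_col = "text") {
  if (!all(c("doc_id", text_col) %in% names(data))) {
    stop("data must have columns 'doc_id' and '", text_col, "'", call. = FALSE)
  }
  if (anyDuplicated(data$doc_id)) stop("doc_id values must be unique", call. = FALSE)
  toks <- tokenize(clean_text(data[[text_col]]), tokenizer, segmenter)
  toks <- remove_stopwords(toks, stopwords)
  tbl <- tibble::tibble(doc_id = as.character(data$doc_id), tokens = toks)

  n0 <- nrow(tbl)
  tbl <- dplyr::filter(tbl, lengths(.data$tokens) > 0)
  vocab <- build_vocabulary(tbl, min_count = min_count)
  if (min_count > 1) {
    tbl$tokens <- lapply(tbl$tokens, function(tok) tok[tok %in% vocab$term])
    tbl <- dplyr::filter(tbl, lengths(.data$tokens) > 0)
  }
  dropped <- n0 - nrow(tbl)
  if (dropped > 0) {
    message("dropped ", dropped, " document(s) empty after preprocessing")
  }
  attr(tbl, "vocabulary") <- vocab
  tbl
}

#' Read a comment corpus
#'
#' Reads JSONL (one object per line with keys `id` and `text`) or headered
#' CSV (`id,text`), both UTF-8.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"jsonl"`, or `"csv"`.
#' @return A tibble with columns `doc_id` (character) and `text`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    tbl <- tibble::tibble(
      doc_id = vapply(recs, function(r) as.character(r$id), character(1)),
      text = vapply(recs, function(r) as.character(r$text %||% ""), character(1))
    )
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(
      id = readr::col_character(), text = readr::col_character()
    ))
    tbl <- tibble::tibble(doc_id = raw$id, text = raw$text %||% "")
    tbl$text[is.na(tbl$text)] <- ""
  }
  if (anyDuplicated(tbl$doc_id)) stop("duplicate doc_id in corpus file", call. = FALSE)
  tbl
}

#' Read a stopword list
#'
#' Plain UTF-8 text, one token per line; `#` starts a comment.
#'
#' @param path File path.
#' @return Character vector of stopwords.
#' @export
read_stopwords <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
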