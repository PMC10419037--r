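# internal helpers

# Run code under a fixed seed without clobbering the caller's RNG stream.
# Usage: restore <- local_seed(seed); on.exit(restore(), add = TRUE)
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Deterministic C-locale lexicographic sort, independent of the session locale.
sort_c <- function(x) sort(x, method = "radix")

# Stable 31-bit string hash (used for per-token embedding seeds and for the
# vocabulary fingerprint in serialized models).
hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(enc2utf8(s))) h <- (h * 31 + c) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

is_token_list <- function(x) is.list(x) && all(vapply(x, is.character, logical(1)))

check_corpus_tbl <- function(data, tokens_col = "tokens") {
  if (!is.data.frame(data) || !all(c("doc_id", tokens_col) %in% names(data))) {
    stop("expected a corpus data frame with columns 'doc_id' and '", tokens_col, "'",
         call. = FALSE)
  }
  if (anyDuplicated(data$doc_id)) stop("doc_id values must be unique", call. = FALSE)
  invisible(data)
}

unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(NULL)
  v / n
}
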