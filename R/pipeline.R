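#' Run the full topic-sentiment pipeline
#'
#' Orchestrates preprocess -> fit (or select-k, then fit at the selected K)
#' -> topic-vector optimization and fusion -> sentiment scoring -> category
#' and correlation analysis, writing every stage's artifacts plus a run log
#' and a `meta.json` to the output directory. Re-running with the same
#' configuration reproduces identical CSV artifacts.
#'
#' Configuration keys (a named list, or the path to a YAML file with the
#' same keys): `corpus` (path, or a data frame with `doc_id`/`text`),
#' `stopwords` (path, optional), `lexicon` (path, or lexicon tibble;
#' defaults to [generate_lexicon()]), `category_map` (path, optional —
#' defaults to the identity map `topic k -> "T<k>"`), `out_dir`
#' (required), and the stage parameters `k` or `k_grid`, `replicates`,
#' `alpha` (1.0), `beta` (0.01), `n_iter` (1000), `seed` (1), `min_count`
#' (1), `tokenizer` ("whitespace"), `embedding_dim` (16), `embedding_seed`
#' (42), `top_n` (30), `tol` (1e-6), `ratio` (0.75), `threshold` (0.05),
#' `lambda` (0.6).
#'
#' @param config Named list or YAML path.
#' @return Invisibly, a list with the fitted objects and the artifact
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  cfg <- utils::modifyList(list(
    alpha = 1.0, beta = 0.01, n_iter = 1000L, seed = 1L, replicates = 1L,
    min_count = 1L, tokenizer = "whitespace", embedding_dim = 16L,
    embedding_seed = 42L, top_n = 30L, tol = 1e-6, ratio = 0.75,
    threshold = 0.05, lambda = 0.6), config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
        file = log_path, append = TRUE)
  }
  t0 <- Sys.time()
  stage <- function(name, expr) {
    log_line("stage", name, "start")
    res <- tryCatch(expr, error = function(e) {
      log_line("stage", name, "FAILED:", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line("stage", name, "done")
    res
  }

  # --- preprocess ---------------------------------------------------------
  corpus <- stage("preprocess", {
    raw <- if (is.data.frame(cfg$corpus)) cfg$corpus else read_corpus(cfg$corpus)
    stop_list <- if (!is.null(cfg$stopwords)) read_stopwords(cfg$stopwords) else character()
    if ("tokens" %in% names(raw) && !"text" %in% names(raw)) {
      vocab <- attr(raw, "vocabulary") %||% build_vocabulary(raw, cfg$min_count)
      attr(raw, "vocabulary") <- vocab
      raw
    } else {
      preprocess_corpus(raw, stopwords = stop_list, tokenizer = cfg$tokenizer,
                        min_count = cfg$min_count)
    }
  })
  readr::write_csv(
    tibble::tibble(doc_id = corpus$doc_id,
                   tokens = vapply(corpus$tokens, paste, character(1),
                                   collapse = " ")),
    file.path(out_dir, "preprocessed.csv"))

  # --- fit / select-k -----------------------------------------------------
  selection <- NULL
  k <- cfg$k
  if (!is.null(cfg$k_grid)) {
    selection <- stage("select-k", select_k(
      corpus, k_grid = cfg$k_grid, replicates = cfg$replicates,
      alpha = cfg$alpha, beta = cfg$beta, n_iter = cfg$n_iter,
      seed = cfg$seed, vocabulary = attr(corpus, "vocabulary")))
    readr::write_csv(selection$table, file.path(out_dir, "select_k.csv"))
    k <- selection$selected_k
  }
  if (is.null(k)) stop("config needs 'k' or 'k_grid'", call. = FALSE)
  model <- stage("fit", fit_lda(
    corpus, k = k, alpha = cfg$alpha, beta = cfg$beta, n_iter = cfg$n_iter,
    seed = cfg$seed, vocabulary = attr(corpus, "vocabulary")))
  write_lda(model, file.path(out_dir, "model"))

  # --- fuse ---------------------------------------------------------------
  provider <- embedding_hash(dim = cfg$embedding_dim, seed = cfg$embedding_seed)
  fused <- stage("fuse", {
    tvs <- optimize_topic_vectors(model, provider, top_n = cfg$top_n,
                                  tol = cfg$tol)
    write_topic_vectors(tvs, out_dir)
    fuse_corpus(corpus, model, tvs, provider)
  })
  readr::write_csv(fused, file.path(out_dir, "fused.csv"))

  # --- sentiment ----------------------------------------------------------
  lexicon <- if (is.null(cfg$lexicon)) generate_lexicon(seed = cfg$seed) else
    if (is.data.frame(cfg$lexicon)) cfg$lexicon else read_lexicon(cfg$lexicon)
  sentiment <- stage("sentiment", {
    scores <- score_documents(corpus, lexicon, ratio = cfg$ratio)
    dplyr::left_join(scores, emotion_profiles(corpus, lexicon), by = "doc_id")
  })
  readr::write_csv(sentiment, file.path(out_dir, "sentiment.csv"))

  # --- analyze ------------------------------------------------------------
  analysis <- stage("analyze", {
    cmap <- if (is.null(cfg$category_map)) {
      tibble::tibble(topic = seq_len(model$k),
                     category = paste0("T", seq_len(model$k)))
    } else if (is.data.frame(cfg$category_map)) cfg$category_map else
      read_category_map(cfg$category_map)
    topics <- primary_topics(model)
    cats <- categorize(topics, cmap)
    docs <- topics |>
      dplyr::left_join(cmap[, c("topic", "category")], by = "topic") |>
      dplyr::left_join(sentiment, by = "doc_id")
    pol <- polarity_distribution(docs)
    corr <- topic_emotion_correlation(docs, threshold = cfg$threshold)
    top_words <- relevance_top_words(model, lambda = cfg$lambda,
                                     top_n = cfg$top_n)
    readr::write_csv(cats, file.path(out_dir, "categories.csv"))
    readr::write_csv(pol, file.path(out_dir, "polarity.csv"))
    write_correlation_csv <- function(what, path) {
      mat <- correlation_matrix(corr, what)
      tbl <- dplyr::bind_cols(tibble::tibble(category = rownames(mat)),
                              tibble::as_tibble(mat))
      readr::write_csv(tbl, path)
    }
    write_correlation_csv("r", file.path(out_dir, "correlation_r.csv"))
    write_correlation_csv("p", file.path(out_dir, "correlation_p.csv"))
    readr::write_csv(top_words, file.path(out_dir, "top_words.csv"))
    list(categories = cats, polarity = pol, correlation = corr,
         top_words = top_words)
  })

  manifest <- c("preprocessed.csv", if (!is.null(selection)) "select_k.csv",
                "model/phi.csv", "model/theta.csv", "model/assignments.csv",
                "model/meta.json", "topic_vectors.csv", "topic_weights.csv",
                "fused.csv", "sentiment.csv", "categories.csv", "polarity.csv",
                "correlation_r.csv", "correlation_p.csv", "top_words.csv",
                "run.log", "meta.json")
  meta <- list(k = k, selected_from_grid = !is.null(selection),
               seed = cfg$seed, alpha = cfg$alpha, beta = cfg$beta,
               n_iter = cfg$n_iter, ratio = cfg$ratio,
               threshold = cfg$threshold, lambda = cfg$lambda,
               embedding = provider$name,
               n_documents = nrow(corpus),
               vocabulary_size = nrow(attr(corpus, "vocabulary") %||%
                                        build_vocabulary(corpus)),
               elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               manifest = manifest)
  jsonlite::write_json(meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("pipeline complete")
  invisible(list(corpus = corpus, selection = selection, model = model,
                 fused = fused, sentiment = sentiment, analysis = analysis,
                 manifest = manifest, out_dir = out_dir))
}
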