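test_that("the subcategory table has 21 codes over the 7 major categories", {
  sc <- emotion_subcategories()
  expect_equal(nrow(sc), 21)
  expect_equal(length(unique(sc$subcategory)), 21)
  expect_setequal(unique(sc$category),
                  c("Joy", "Good", "Anger", "Sadness", "Fear", "Evil", "Surprise"))
  expect_true("NA" %in% sc$subcategory) # anger code is the literal string
})

test_that("lexicon TSVs parse, validate codes, and keep 'NA' literal", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(dplyr::bind_rows(
    toy_lexicon(),
    make_entry("furious", "NA", 7, -1)
  ), path)
  lex <- read_lexicon(path)
  expect_equal(nrow(lex), 6)
  expect_identical(lex$subcategory[lex$word == "furious"], "NA")
  expect_identical(lex$intensity[lex$word == "good"], 5)
  expect_identical(lex$polarity[lex$word == "bad"], -1)

  # invalid polarity aborts and names the line
  bad <- dplyr::bind_rows(toy_lexicon(), make_entry("odd", "PA", 5, 7))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path2, na = "")
  expect_error(read_lexicon(path2), "invalid polarity.*line 7")

  # intensity outside {1,3,5,7,9} aborts
  bad2 <- dplyr::bind_rows(make_entry("odd", "PA", 4, 1))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad2, path3, na = "")
  expect_error(read_lexicon(path3), "invalid intensity")

  # duplicate words: first row kept, later dropped with a message
  dup <- dplyr::bind_rows(make_entry("good", "PA", 5, 1),
                          make_entry("good", "NB", 3, -1))
  path4 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dup, path4, na = "")
  expect_message(lex4 <- read_lexicon(path4), "duplicate")
  expect_equal(nrow(lex4), 1)
  expect_identical(lex4$subcategory, "PA")

  path5 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(toy_lexicon()[0, ], path5, na = "")
  expect_error(read_lexicon(path5), "empty")
})

test_that("the sentiment-value calculus covers every rule branch", {
  # single annotation passes its polarity through
  expect_identical(word_sentiment_value(make_entry("w", "PA", 3, 0))$value, 0)
  expect_identical(word_sentiment_value(make_entry("w", "PA", 5, 1))$value, 1)
  r <- word_sentiment_value(make_entry("w", "PA", 5, -1))
  expect_identical(r$rule, "single")

  # two identical polarities: first [intensity, polarity] pair decides
  e <- make_entry("w", "PA", 5, 1, aux_subcategory = "PH",
                  aux_intensity = 3, aux_polarity = 1)
  r2 <- word_sentiment_value(e)
  expect_identical(r2$value, 1)
  expect_identical(r2$intensity, 5)
  expect_identical(r2$rule, "identical-polarity-first")

  # ambivalent combination: c = s_prev + 0.75 * s_next, snapped to {-1,0,1}
  e3 <- make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 5,
                   aux_polarity = 3, ambiv_score = 2, aux_ambiv_score = -4)
  r3 <- word_sentiment_value(e3)
  expect_identical(r3$value, -1) # 2 - 3 = -1 exactly
  expect_identical(r3$rule, "ambivalent-combination")

  e4 <- make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 5,
                   aux_polarity = 3, ambiv_score = 0.4, aux_ambiv_score = 0)
  expect_identical(word_sentiment_value(e4)$value, 0) # 0.4 snaps to 0

  # exact midpoint ties snap to 0
  e5 <- make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 5,
                   aux_polarity = 3, ambiv_score = 0.5, aux_ambiv_score = 0)
  expect_identical(word_sentiment_value(e5)$value, 0)

  # mixed pair falls back to the non-ambivalent annotation
  e6 <- make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 7,
                   aux_polarity = -1, ambiv_score = 3)
  expect_identical(word_sentiment_value(e6)$value, -1)

  # ambivalent polarity without a score is an error
  expect_error(word_sentiment_value(make_entry("w", "PA", 5, 3)), "ambivalent")

  # the configurable ratio reweights the later annotation
  e7 <- make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 5,
                   aux_polarity = 3, ambiv_score = 0, aux_ambiv_score = 4)
  expect_identical(word_sentiment_value(e7, ratio = 0.75)$value, 1)
  expect_identical(word_sentiment_value(e7, ratio = 0)$value, 0)
})

test_that("negation symmetry: flipping all polarities and scores flips the value", {
  flip <- function(e) {
    e$polarity <- ifelse(e$polarity %in% c(1, -1), -e$polarity, e$polarity)
    if (!is.na(e$aux_polarity)) {
      e$aux_polarity <- ifelse(e$aux_polarity %in% c(1, -1),
                               -e$aux_polarity, e$aux_polarity)
    }
    e$ambiv_score <- -e$ambiv_score
    e$aux_ambiv_score <- -e$aux_ambiv_score
    e
  }
  cases <- list(
    make_entry("w", "PA", 5, 1),
    make_entry("w", "PA", 5, 0),
    make_entry("w", "PA", 5, -1, aux_subcategory = "NB",
               aux_intensity = 3, aux_polarity = -1)
  )
  for (sp in seq(-4, 4, by = 0.5)) {
    for (sn in c(-4, -1, 0, 2.5, 4)) {
      cases[[length(cases) + 1]] <-
        make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 5,
                   aux_polarity = 3, ambiv_score = sp, aux_ambiv_score = sn)
    }
  }
  for (e in cases) {
    v <- word_sentiment_value(e)$value
    v_flipped <- word_sentiment_value(flip(e))$value
    expect_identical(v_flipped, -v)
  }
})

test_that("the snap is monotone in the combined score and ratio 0 degenerates", {
  grid <- seq(-4, 4, by = 0.25)
  vals <- vapply(grid, function(s) {
    e <- make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 5,
                    aux_polarity = 3, ambiv_score = s, aux_ambiv_score = 0)
    word_sentiment_value(e)$value
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  # with ratio 0 the later score is ignored entirely
  for (s in c(-2, -0.3, 0, 0.8, 3)) {
    for (s2 in c(-4, 0, 4)) {
      e <- make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 5,
                      aux_polarity = 3, ambiv_score = s, aux_ambiv_score = s2)
      e0 <- make_entry("w", "PA", 5, 3, aux_subcategory = "NB", aux_intensity = 5,
                       aux_polarity = 3, ambiv_score = s, aux_ambiv_score = 0)
      expect_identical(word_sentiment_value(e, ratio = 0)$value,
                       word_sentiment_value(e0)$value)
    }
  }
})

test_that("sentence scores sum value*intensity with bag semantics", {
  lex <- toy_lexicon()
  r <- score_sentence(c("so", "good", "today"), lex)
  expect_identical(r$magnitude, 5)
  expect_identical(r$polarity, 1)
  # symmetric cancellation
  r2 <- score_sentence(c("good", "bad"), lex)
  expect_identical(r2$magnitude, 0)
  expect_identical(r2$polarity, 0)
  # hand-summed magnitude: good(+5) + fine(+3) + awful(-9) = -1
  r3 <- score_sentence(c("good", "fine", "awful", "unknown"), lex)
  expect_identical(r3$magnitude, -1)
  expect_identical(r3$polarity, -1)
  # permutation invariance
  set.seed(9)
  toks <- c("good", "fine", "awful", "bad", "plain", "mystery")
  base <- score_sentence(toks, lex)$magnitude
  for (i in 1:10) {
    expect_identical(score_sentence(sample(toks), lex)$magnitude, base)
  }
})

test_that("document scores aggregate sentences and match a manual tally", {
  lex <- toy_lexicon()
  docs <- tibble::tibble(
    doc_id = sprintf("d%02d", 1:10),
    text = c("good day. bad night!", # +5 - 5 = 0
             "good good",            # +10
             "awful. awful!",        # -18
             "fine",                 # +3
             "nothing here",         # 0
             "bad bad good",         # -5
             "plain words",          # 0 (neutral word)
             "good! awful?",         # -4
             "fine fine fine",       # +9
             "bad")                  # -5
  )
  out <- score_documents(docs, lex)
  expect_identical(out$magnitude,
                   c(0, 10, -18, 3, 0, -5, 0, -4, 9, -5))
  expect_identical(out$polarity, c(0, 1, -1, 1, 0, -1, 0, -1, 1, -1))
  expect_identical(sum(out$polarity > 0), 3L)
  expect_identical(sum(out$polarity < 0), 4L)

  # pre-tokenized corpora score each document as one bag
  tok_corpus <- tibble::tibble(doc_id = "t1", tokens = list(c("good", "bad")))
  expect_identical(score_documents(tok_corpus, lex)$magnitude, 0)
})

test_that("sentence splitting happens on terminal punctuation before cleaning", {
  s <- split_sentences("好转了。还疼吗?最后一句")
  expect_identical(s[[1]], c("好转了", "还疼吗", "最后一句"))
  expect_identical(split_sentences("no terminal")[[1]], "no terminal")
})

test_that("emotion profiles sum matched intensities per subcategory", {
  lex <- toy_lexicon()
  corp <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    tokens = list(c("nothing", "matched"),
                  c("good", "plain"),
                  c("good", "good", "bad", "awful"))
  )
  prof <- emotion_profiles(corp, lex)
  expect_equal(ncol(prof), 22) # doc_id + 21 subcategories
  expect_true(all(prof[1, -1] == 0))
  expect_identical(prof$profile_PA[2], 5)
  expect_identical(prof$profile_PD[2], 1)
  expect_identical(prof$profile_PA[3], 10)
  expect_identical(prof$profile_NB[3], 5)
  expect_identical(prof$profile_NE[3], 9)
  expect_true(all(prof[, -1] >= 0))
})
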