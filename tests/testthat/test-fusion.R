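# a 2-topic, 3-word model with hand-set phi for topic-vector tests
toy_fusion_model <- function(phi1 = c(x = 0.5, y = 0.3, z = 0.2)) {
  phi <- rbind(phi1, c(0.2, 0.3, 0.5))
  colnames(phi) <- c("x", "y", "z")
  theta <- matrix(c(0.9, 0.1, 0.4, 0.6), 2, 2, byrow = TRUE)
  fake_lda_model(phi, theta, list(c("x", "y"), c("z", "y")),
                 list(c(1L, 1L), c(2L, 2L)))
}

table_provider <- function(mat) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  tbl <- tibble::as_tibble(mat, .name_repair = ~ paste0("dim_", seq_len(ncol(mat)) - 1L))
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(token = rownames(mat)), tbl), path)
  embedding_table(path)
}

test_that("hash embeddings are deterministic unit vectors of the stated dim", {
  p1 <- embedding_hash(dim = 8, seed = 5)
  p2 <- embedding_hash(dim = 8, seed = 5)
  e1 <- embed_tokens(p1, c("fever", "cough", "fever"))
  e2 <- embed_tokens(p2, c("fever", "cough", "fever"))
  expect_identical(e1, e2)
  expect_equal(unname(sqrt(rowSums(e1^2))), rep(1, 3), tolerance = 1e-12)
  expect_identical(e1[1, ], e1[3, ])
  # different seed, different vectors
  e3 <- embed_tokens(embedding_hash(dim = 8, seed = 6), "fever")
  expect_false(isTRUE(all.equal(e1[1, ], e3[1, ])))
})

test_that("table embeddings look up rows and error on missing tokens", {
  mat <- rbind(x = c(1, 0), y = c(0, 1), z = c(1, 1))
  p <- table_provider(mat)
  expect_equal(p$dim, 2L)
  expect_equal(unname(embed_tokens(p, c("y", "x"))),
               rbind(c(0, 1), c(1, 0)), tolerance = 1e-12)
  expect_error(embed_tokens(p, "missing"), "missing")
})

test_that("initial topic vector is the normalized phi-weighted embedding sum", {
  m <- toy_fusion_model()
  # all top words share one embedding direction -> that direction
  shared <- rbind(x = c(2, 0), y = c(2, 0), z = c(2, 0))
  expect_equal(initial_topic_vector(m, table_provider(shared), 1, top_n = 3),
               c(1, 0), tolerance = 1e-12)
  # top_n = 1 -> normalized single top-word embedding
  mat <- rbind(x = c(3, 4), y = c(0, 1), z = c(1, 0))
  expect_equal(initial_topic_vector(m, table_provider(mat), 1, top_n = 1),
               c(3, 4) / 5, tolerance = 1e-12)
  # 3-word toy against hand arithmetic: 0.5*x + 0.3*y + 0.2*z
  mat2 <- rbind(x = c(1, 0), y = c(0, 1), z = c(1, 1))
  expected <- c(0.5 + 0.2, 0.3 + 0.2)
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(initial_topic_vector(m, table_provider(mat2), 1, top_n = 3),
               expected, tolerance = 1e-12)
  # degenerate all-zero sum errors
  zero <- rbind(x = c(0, 0), y = c(0, 0), z = c(0, 0))
  expect_error(initial_topic_vector(m, table_provider(zero), 1, top_n = 3),
               "degenerate")
})

test_that("optimized topic vector matches an independent update loop", {
  m <- toy_fusion_model(phi1 = c(x = 0.4, y = 0.4, z = 0.2))
  # two aligned words, one orthogonal
  mat <- rbind(x = c(1, 0), y = c(1, 0), z = c(0, 1))
  p <- table_provider(mat)
  tv <- optimize_topic_vector(m, p, 1, top_n = 3, tol = 1e-10, max_iter = 200)

  # independent re-implementation of the stated update loop
  e <- mat[c("x", "y", "z"), ]
  phi_w <- c(0.4, 0.4, 0.2)
  mu <- colSums(phi_w * e)
  mu <- mu / sqrt(sum(mu^2))
  for (i in 1:200) {
    cosv <- as.vector(e %*% mu) / sqrt(rowSums(e^2))
    u <- phi_w * pmax(0, cosv)
    u <- u / sum(u)
    mu_new <- colSums(u * e)
    mu_new <- mu_new / sqrt(sum(mu_new^2))
    done <- 1 - sum(mu_new * mu) < 1e-10
    mu <- mu_new
    if (done) break
  }
  expect_equal(tv$mu_prime, mu, tolerance = 1e-9)
  expect_true(tv$converged)
  expect_equal(sum(tv$weights$weight), 1, tolerance = 1e-12)
  expect_true(all(tv$weights$weight >= 0))
  expect_equal(sum(tv$mu_prime^2), 1, tolerance = 1e-9)
  # the orthogonal word's weight strictly decreases from its phi-only start
  expect_lt(tv$weights$weight[tv$weights$word == "z"], 0.2)
})

test_that("fixed points and degenerate top_n behave as stated", {
  m <- toy_fusion_model()
  shared <- rbind(x = c(0, 2), y = c(0, 2), z = c(0, 2))
  tv <- optimize_topic_vector(m, table_provider(shared), 1, top_n = 3)
  expect_true(tv$converged)
  expect_identical(tv$iterations, 1L)
  expect_equal(tv$mu_prime, c(0, 1), tolerance = 1e-12)

  mat <- rbind(x = c(3, 4), y = c(0, 1), z = c(1, 0))
  tv1 <- optimize_topic_vector(m, table_provider(mat), 1, top_n = 1)
  expect_equal(tv1$mu_prime, c(3, 4) / 5, tolerance = 1e-12)
  expect_equal(tv1$weights$weight, 1, tolerance = 1e-12)
})

test_that("each mu update improves the weighted cosine and providers with equal
           embeddings give identical optimized vectors", {
  set.seed(21)
  for (rep in 1:5) {
    g <- stats::rgamma(3, shape = 1)
    phi1 <- stats::setNames(g / sum(g), c("x", "y", "z"))
    m <- toy_fusion_model(phi1 = phi1)
    hash <- embedding_hash(dim = 6, seed = rep)
    tv <- optimize_topic_vector(m, hash, 1, top_n = 3, tol = 1e-9)

    # per iteration, replacing mu by the normalized u-weighted embedding sum
    # maximizes the weighted cosine for the current weights (unit embeddings),
    # so the within-iteration update can never lower it
    e <- embed_tokens(hash, c("x", "y", "z"))
    mu <- initial_topic_vector(m, hash, 1, top_n = 3)
    for (i in seq_len(tv$iterations)) {
      cosv <- as.vector(e %*% mu)
      u <- phi1 * pmax(0, cosv)
      u <- u / sum(u)
      mu_new <- colSums(u * e)
      mu_new <- mu_new / sqrt(sum(mu_new^2))
      expect_gte(sum(u * as.vector(e %*% mu_new)), sum(u * cosv) - 1e-12)
      mu <- mu_new
    }
    expect_equal(unname(mu), tv$mu_prime, tolerance = 1e-9)

    # a table provider frozen from the hash provider agrees everywhere
    frozen <- table_provider(embed_tokens(hash, c("x", "y", "z")))
    tv2 <- optimize_topic_vector(m, frozen, 1, top_n = 3, tol = 1e-9)
    expect_equal(tv$mu_prime, tv2$mu_prime, tolerance = 1e-10)
  }
})

test_that("document fusion does the stated per-token arithmetic", {
  # single-token document: rho(0) = 0, delta = e_w, so fused = 2 e_w + mu'_z
  phi <- matrix(c(0.7, 0.3), 1, 2, dimnames = list(NULL, c("x", "y")))
  m1 <- fake_lda_model(phi, matrix(1, 1, 1), list("x"), list(1L))
  mat <- rbind(x = c(1, 2), y = c(0, 1))
  p <- table_provider(mat)
  mu <- matrix(c(0.5, 0.5), 1, 2)
  fused <- fuse_corpus(tibble::tibble(doc_id = "d1", tokens = list("x")),
                       m1, mu, p)
  expect_equal(unlist(fused[1, c("dim_0", "dim_1")], use.names = FALSE),
               2 * c(1, 2) + c(0.5, 0.5), tolerance = 1e-12)

  # two-document toy against an independent arithmetic script
  m <- toy_fusion_model()
  mat3 <- rbind(x = c(1, 0), y = c(0, 1), z = c(1, 1))
  p3 <- table_provider(mat3)
  muK <- rbind(c(1, 0), c(0, 1))
  corp <- tibble::tibble(doc_id = c("d1", "d2"),
                         tokens = list(c("x", "y"), c("z", "y")))
  fused2 <- fuse_corpus(corp, m, muK, p3)
  manual <- function(tokens, z) {
    e <- mat3[tokens, , drop = FALSE]
    rho <- t(vapply(seq_along(tokens) - 1, function(pos)
      sin(pos / 10000^((0:1) / 2)), numeric(2)))
    delta <- colMeans(e)
    colMeans(e + rho + matrix(delta, length(tokens), 2, byrow = TRUE) +
               muK[z, , drop = FALSE])
  }
  expect_equal(unlist(fused2[1, -1], use.names = FALSE),
               manual(c("x", "y"), c(1, 1)), tolerance = 1e-12)
  expect_equal(unlist(fused2[2, -1], use.names = FALSE),
               manual(c("z", "y"), c(2, 2)), tolerance = 1e-12)

  # permuting corpus rows changes nothing per document
  fused_perm <- fuse_corpus(corp[2:1, ], m, muK, p3)
  expect_equal(fused_perm[fused_perm$doc_id == "d1", ],
               fused2[fused2$doc_id == "d1", ], tolerance = 1e-12)

  # corpus/model mismatch is an error
  bad <- tibble::tibble(doc_id = "d1", tokens = list(c("x", "y", "y")))
  expect_error(fuse_corpus(bad, m, muK, p3), "mismatch")
})

test_that("primary topics take the argmax with ties to the smallest index", {
  phi <- matrix(0.5, 2, 2, dimnames = list(NULL, c("x", "y")))
  theta <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  m <- fake_lda_model(phi, theta, list("x", "y"), list(1L, 2L))
  pt <- primary_topics(m)
  expect_identical(pt$topic, c(1L, 1L))
})

test_that("fused vectors cluster by planted topic on a synthetic corpus", {
  sim <- generate_corpus(generator_spec(M = 60, L = 30, V = 120, seed = 19))
  model <- fit_lda(sim$corpus, k = 3, n_iter = 150, seed = 19)
  provider <- embedding_hash(dim = 12, seed = 3)
  tvs <- optimize_topic_vectors(model, provider, top_n = 15)
  fused <- fuse_corpus(sim$corpus, model, tvs, provider)
  vecs <- as.matrix(fused[, -1])
  vecs <- vecs / sqrt(rowSums(vecs^2))
  labels <- sim$truth$labels$topic
  cosmat <- vecs %*% t(vecs)
  same <- outer(labels, labels, "==") & upper.tri(cosmat)
  diff <- outer(labels, labels, "!=") & upper.tri(cosmat)
  expect_gt(mean(cosmat[same]), mean(cosmat[diff]))
})
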