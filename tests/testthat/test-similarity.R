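test_that("per-context cosine matches hand-derived values", {
  dep <- rbind(w1 = c(A = 0.5, B = 0.5, C = 0),
               w2 = c(A = 0.5, B = 0, C = 0.5),
               w3 = c(A = 0, B = 0, C = 1),
               w4 = c(A = 0.5, B = 0.5, C = 0),
               z0 = c(A = 0, B = 0, C = 0))
  space <- make_space(list(department = dep))
  expect_equal(contextCosine(space, "w1", "w4", "department"), 1)
  # {A,B} vs {A,C}: 1 / (sqrt(2) * sqrt(2))
  expect_equal(contextCosine(space, "w1", "w2", "department"), 0.5)
  expect_equal(contextCosine(space, "w1", "w3", "department"), 0)
  # zero vector (either side) gives 0 by convention
  expect_equal(contextCosine(space, "w1", "z0", "department"), 0)
  expect_equal(contextCosine(space, "z0", "z0", "department"), 0)
  expect_error(contextCosine(space, "w1", "nope", "department"),
               "unknown term")
})

test_that("cosine agrees with a direct dense oracle on random sparse pairs", {
  set.seed(301)
  reg <- defaultContextRegistry()
  for (rep in 1:200) {
    d <- sample(2:20, 1)
    a <- ifelse(runif(d) < 0.5, 0, runif(d))
    b <- ifelse(runif(d) < 0.5, 0, runif(d))
    dims <- paste0("d", seq_len(d))
    m <- rbind(ta = a, tb = b)
    colnames(m) <- dims
    space <- make_space(list(department = m))
    got <- contextCosine(space, "ta", "tb", "department")
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    want <- if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("cosine is symmetric, scale-invariant and bounded", {
  spec <- syntheticSpec(seed = 9L, n_notes = 30L, vocab_size = 40L,
                        n_related_terms = 3L)
  notes <- generateNotes(spec, sampleTermProfiles(spec))
  counts <- accumulateContexts(notes)
  space <- normalizeCounts(counts)
  vocab <- vocabulary(space)
  set.seed(302)
  for (rep in 1:25) {
    pair <- sample(vocab, 2)
    ctx <- sample(contextIds(space), 1)
    s_ab <- contextCosine(space, pair[1], pair[2], ctx)
    expect_equal(s_ab, contextCosine(space, pair[2], pair[1], ctx))
    expect_gte(s_ab, 0); expect_lte(s_ab, 1 + 1e-12)
  }
  # scaling one term's raw counts leaves normalized cosine unchanged
  scaled <- counts
  for (ctx in contextIds(counts))
    scaled@counts[[ctx]][vocab[1], ] <- 3 * scaled@counts[[ctx]][vocab[1], ]
  sp2 <- normalizeCounts(scaled)
  for (ctx in contextIds(space))
    expect_equal(contextCosine(sp2, vocab[1], vocab[2], ctx),
                 contextCosine(space, vocab[1], vocab[2], ctx),
                 tolerance = 1e-12)
})

test_that("similarity vectors cover all contexts in registry order", {
  dep <- rbind(w1 = c(A = 1, B = 0), w2 = c(A = 1, B = 0))
  space <- make_space(list(department = dep))
  sv <- similarityVector(space, "w1", "w2")
  expect_identical(names(sv), contextIds(space))
  expect_equal(unname(sv[["department"]]), 1)
  # all other contexts have zero vectors here
  expect_true(all(sv[-1] == 0))
  expect_equal(similarityVector(space, "w1", "w2"),
               similarityVector(space, "w2", "w1"))
})

test_that("featurize builds a candidates-by-contexts matrix", {
  b <- get_bundle()
  topic <- b$spec$topic_word
  cands <- b$candidates[1:3]
  fm <- featurize(b$space, topic, cands)
  expect_identical(dim(fm), c(3L, 10L))
  expect_identical(rownames(fm), cands)
  expect_identical(colnames(fm), contextIds(b$space))
  # rows agree with the scalar path
  for (ctx in colnames(fm))
    expect_equal(fm[cands[1], ctx],
                 contextCosine(b$space, topic, cands[1], ctx),
                 tolerance = 1e-12)
  # the topic against itself scores 1 wherever it has usage
  self <- featurize(b$space, topic, topic)
  nz <- vapply(contextIds(b$space), function(ctx) {
    m <- contextMatrix(b$space, ctx)
    ncol(m) > 0 && sum(m[topic, ]) > 0
  }, logical(1))
  expect_true(all(abs(self[1, nz] - 1) < 1e-12))

  expect_warning(fa <- featurize(b$space, topic, c(cands[1], "zzz_absent")),
                 "absent")
  expect_true(all(fa["zzz_absent", ] == 0))
  expect_error(featurize(b$space, topic, "zzz_absent", absent = "error"),
               "absent")
  expect_error(featurize(b$space, "zzz_absent", cands), "unknown topic")
})

test_that("embedding features return raw vectors with zero-row fallback", {
  tab <- randomEmbedding(c("alpha", "beta", "gamma"), dimension = 5, seed = 1)
  fm <- embeddingFeatures(tab, c("beta", "alpha"))
  expect_identical(dim(fm), c(2L, 5L))
  expect_equal(fm["beta", ], tab@vectors["beta", ])
  expect_identical(colnames(fm), paste0("dim_", 0:4))
  expect_warning(fz <- embeddingFeatures(tab, c("alpha", "missing")), "absent")
  expect_true(all(fz["missing", ] == 0))
  empty <- new("EmbeddingTable",
               vectors = matrix(numeric(0), 0, 3,
                                dimnames = list(character(0), c("a","b","c"))))
  expect_error(embeddingFeatures(empty, "x"), "empty")
})

test_that("unsupervised top-k ranking averages context cosines", {
  dep <- rbind(topic = c(A = 1, B = 0), twin = c(A = 1, B = 0),
               other = c(A = 0, B = 1))
  gen <- rbind(topic = c(m = 0.5, f = 0.5), twin = c(m = 0.5, f = 0.5),
               other = c(m = 0.5, f = 0.5))
  space <- make_space(list(department = dep, gender = gen))
  top <- topKSimilar(space, "topic", k = 5)
  expect_identical(top$term[1], "twin")
  # twin matches in both nonzero contexts -> mean over the 10 contexts = 0.2
  expect_equal(top$score[1], 2 / 10)
  # restricting to the department context isolates the planted difference
  top_dep <- topKSimilar(space, "topic", k = 5, contexts = "department")
  expect_equal(top_dep$score, c(1, 0))
  expect_identical(nrow(topKSimilar(space, "topic", k = 0)), 0L)
  # brute-force check of ordering on the bundle
  b <- get_bundle()
  k10 <- topKSimilar(b$space, b$spec$topic_word, k = 10)
  feats <- get_features()
  manual <- sort(rowMeans(feats), decreasing = TRUE)
  expect_equal(unname(k10$score), unname(manual[1:10]), tolerance = 1e-12)
})
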