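test_that("latent profiles are seeded Dirichlet draws with planted copies", {
  spec <- syntheticSpec(seed = 5L, n_notes = 10L, vocab_size = 50L,
                        n_related_terms = 6L)
  p1 <- sampleTermProfiles(spec)
  p2 <- sampleTermProfiles(spec)
  expect_identical(p1, p2)
  p3 <- sampleTermProfiles(syntheticSpec(seed = 6L, n_notes = 10L,
                                         vocab_size = 50L,
                                         n_related_terms = 6L))
  expect_false(identical(p1$profiles, p3$profiles))
  # every profile row is a distribution
  for (ctx in names(p1$profiles))
    expect_equal(unname(rowSums(p1$profiles[[ctx]])),
                 rep(1, spec$vocab_size))
  # related terms copy the topic exactly in related contexts only
  rel <- p1$related_terms[1]
  for (ctx in spec$related_contexts)
    expect_equal(p1$profiles[[ctx]][rel, ],
                 p1$profiles[[ctx]][spec$topic_word, ])
  expect_false(isTRUE(all.equal(p1$profiles$department[rel, ],
                                p1$profiles$department[spec$topic_word, ])))
  # a huge concentration flattens profiles toward uniform
  flat <- sampleTermProfiles(syntheticSpec(seed = 5L, n_notes = 10L,
                                           vocab_size = 50L,
                                           n_related_terms = 6L,
                                           concentration = 1e6))
  expect_lt(max(abs(flat$profiles$department - 1 / 8)), 0.01)
})

test_that("generated notes honor degenerate cardinalities and validate", {
  card <- c(department = 1L, staff = 2L, icd_event = 5L, cpt_event = 5L,
            chief_complaint = 5L, age = 10L, gender = 3L, note_type = 2L,
            note_section = 6L, top_note_section = 5L)
  spec <- syntheticSpec(seed = 3L, n_notes = 15L, vocab_size = 30L,
                        n_related_terms = 2L, context_cardinalities = card)
  notes <- generateNotes(spec, sampleTermProfiles(spec))
  expect_length(notes, 15L)
  expect_true(all(vapply(notes, function(n) n$department, "") == "dept_01"))
  # notes survive a serialization round trip (schema conformance)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeNotes(notes, path)
  back <- readNotes(path)
  expect_length(back, 15L)
  expect_identical(vapply(back, function(n) n$note_id, ""),
                   vapply(notes, function(n) n$note_id, ""))
  # zero notes is a valid degenerate corpus
  spec0 <- syntheticSpec(seed = 3L, n_notes = 0L, vocab_size = 30L,
                         n_related_terms = 2L)
  expect_length(generateNotes(spec0, sampleTermProfiles(spec0)), 0L)
})

test_that("a term's empirical department usage converges to its profile", {
  # moderate concentration: per-note renormalization bias is negligible
  # (very spiky profiles self-saturate within compatible notes and flatten)
  spec <- syntheticSpec(seed = 13L, n_notes = 2000L, vocab_size = 300L,
                        n_related_terms = 10L, concentration = 2)
  prof <- sampleTermProfiles(spec)
  notes <- generateNotes(spec, prof)
  counts <- accumulateContexts(notes, defaultContextRegistry())
  m <- contextMatrix(counts, "department")
  term <- names(which.max(Matrix::rowSums(m)))
  emp <- as.numeric(m[term, ]) / sum(m[term, ])
  truth <- prof$profiles$department[term, colnames(m)]
  tv <- 0.5 * sum(abs(emp - truth))
  expect_lt(tv, 0.1)
})

test_that("planted reviewer drives highlights toward related terms", {
  b <- get_bundle()
  spec <- b$spec
  H <- get_H()
  rel <- b$truth$related_terms
  unrel <- setdiff(b$candidates, rel)
  h_rel <- H[rel]; h_rel[is.na(h_rel)] <- 0
  h_unrel <- H[unrel]; h_unrel[is.na(h_unrel)] <- 0
  expect_gt(mean(h_rel), stats::median(h_unrel))
  # mean similarity to the topic in related contexts separates the groups
  S <- get_features()
  for (ctx in spec$related_contexts)
    expect_gt(mean(S[rel, ctx]), mean(S[unrel, ctx]))
  # an indifferent reviewer produces (almost) no highlights
  spec_off <- b$spec
  spec_off$reviewer_weights[] <- 0
  spec_off$reviewer_intercept <- -20
  h_off <- generateHighlights(spec_off, b$notes, b$space)
  expect_lt(nrow(h_off), 3L)
})

test_that("the bundle is reproducible end-to-end and internally consistent", {
  spec <- syntheticSpec(seed = 8L, n_notes = 60L, vocab_size = 80L,
                        n_related_terms = 8L)
  b1 <- makeBundle(spec)
  b2 <- makeBundle(spec)
  expect_identical(b1$highlights, b2$highlights)
  expect_identical(vocabulary(b1$space), vocabulary(b2$space))
  expect_equal(as.matrix(contextMatrix(b1$space, "chief_complaint")),
               as.matrix(contextMatrix(b2$space, "chief_complaint")))
  expect_true(all(b1$candidates %in% medcontext:::.specVocab(spec)))
  expect_false(spec$topic_word %in% b1$candidates)
  expect_identical(b1$truth$reviewer_weights, spec$reviewer_weights)
  # highlight terms are tokens of the vocabulary actually present in notes
  expect_true(all(b1$highlights$term %in% vocabulary(b1$space)))
})

test_that("the default bundle supports the labeling protocol", {
  sweep <- cutoffSweep(get_bundle()$candidates, get_H())
  expect_gte(length(sweep), 1L)
  expect_gte(nPositives(sweep[[1]]), 10L)
})

test_that("simulateCorpus writes a readable study directory", {
  spec <- syntheticSpec(seed = 14L, n_notes = 25L, vocab_size = 40L,
                        n_related_terms = 4L)
  dir <- withr::local_tempdir()
  simulateCorpus(makeBundle(spec), dir)
  expect_true(all(file.exists(file.path(dir,
    c("notes.jsonl", "highlights.tsv", "candidates.txt", "truth.json")))))
  notes <- readNotes(file.path(dir, "notes.jsonl"))
  expect_length(notes, 25L)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_identical(truth$topic_word, spec$topic_word)
  expect_length(readCandidates(file.path(dir, "candidates.txt")), 39L)
})
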