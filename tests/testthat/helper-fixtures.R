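# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# The default synthetic study bundle (the package's reference conditions).
get_bundle <- function() .memo("bundle", makeBundle(syntheticSpec()))

get_features <- function() .memo("features", {
  b <- get_bundle()
  suppressWarnings(featurize(b$space, b$spec$topic_word, b$candidates))
})

get_H <- function() .memo("H", aggregateHighlightCounts(get_bundle()$highlights))

get_labels1 <- function() .memo("labels1",
  buildLabels(get_bundle()$candidates, get_H(), 1L))

get_embedding_features <- function() .memo("embedding_features", {
  b <- get_bundle()
  embeddingFeatures(randomEmbedding(b$candidates, 100L, seed = 1001L),
                    b$candidates)
})

get_lc_context <- function() .memo("lc_context",
  learningCurve(get_features(), get_labels1(), reps = 100L, seed = 101L,
                feature_space_name = "medical-context"))

get_lc_embedding <- function() .memo("lc_embedding",
  learningCurve(get_embedding_features(), get_labels1(), reps = 100L,
                seed = 101L, standardize = TRUE,
                feature_space_name = "random-embedding"))

# A handmade note with overridable fields.
make_note <- function(note_id = "n1", department = "cardiology",
                      staff_type = "physician", note_type = "progress",
                      timestamp = "2016-06-01T12:00:00",
                      patient_age_years = 40L, patient_gender = "female",
                      events = NULL, text = "chest pain noted",
                      section_name = "assessment", sections = NULL) {
  if (is.null(events))
    events <- data.frame(system = character(0), code = character(0),
                         timestamp = as.POSIXct(character(0), tz = "UTC"))
  if (is.null(sections))
    sections <- data.frame(section_name = section_name, text = text,
                           stringsAsFactors = FALSE)
  noteRecord(note_id = note_id, patient_id = paste0("p_", note_id),
             timestamp = timestamp, department = department,
             staff_type = staff_type, note_type = note_type,
             patient_age_years = patient_age_years,
             patient_gender = patient_gender,
             events = events, sections = sections)
}

# Build a ContextVectorSpace directly from a list of per-context dense
# matrices (term x dimension proportions); contexts not supplied get zero
# columns. Used to construct exact similarity fixtures.
make_space <- function(ctx_mats, vocab = NULL) {
  reg <- defaultContextRegistry()
  if (is.null(vocab)) vocab <- rownames(ctx_mats[[1]])
  vectors <- lapply(contextIds(reg), function(ctx) {
    if (ctx %in% names(ctx_mats)) {
      m <- ctx_mats[[ctx]][vocab, , drop = FALSE]
      rs <- rowSums(m)
      m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
      as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    } else {
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(length(vocab), 0L),
                           dimnames = list(vocab, character(0)))
    }
  })
  names(vectors) <- contextIds(reg)
  new("ContextVectorSpace", vectors = vectors, registry = reg)
}

# Independent brute-force accumulation oracle: a single pass over the
# corpus using nested environments, no sparse matrices, no shared code
# with accumulateContexts beyond tokenize.
brute_force_counts <- function(notes, registry = defaultContextRegistry(),
                               stopwords = defaultStopwords()) {
  out <- list()
  bump <- function(term, ctx, dim, by) {
    key <- paste(term, ctx, dim, sep = "\r")
    out[[key]] <<- (if (is.null(out[[key]])) 0 else out[[key]]) + by
  }
  for (note in notes) {
    attrs <- activeAttributes(note, registry)
    for (s in seq_len(nrow(note$sections))) {
      toks <- tokenize(note$sections$text[s], stopwords)
      sec <- tolower(trimws(note$sections$section_name[s]))
      for (tok in toks) {
        for (ctx in names(attrs))
          for (lab in attrs[[ctx]]) bump(tok, ctx, lab, 1)
        bump(tok, "note_section", sec, 1)
        if (sec %in% keySections(registry))
          bump(tok, "top_note_section", sec, 1)
      }
    }
  }
  out
}
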