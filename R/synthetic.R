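#' Specification of a synthetic EMR corpus with a planted reviewer
#'
#' Defines the generative conditions for a synthetic chart-review study:
#' a vocabulary of clinical terms, each with latent per-context usage
#' profiles (Dirichlet-distributed categorical distributions over each
#' context's dimensions); notes carrying the ten context attributes; and a
#' reviewer whose per-occurrence highlight probability follows a linear
#' logit in the per-context similarities between the topic word and the
#' candidate term. A designated block of "related" terms copies the topic
#' word's profile exactly in the related contexts, so genuinely similar
#' terms exist to be found.
#'
#' Defaults describe a desk-scale study: 800 notes, 1200 terms (candidate
#' pools of this size match practical chart-review tasks), small
#' context cardinalities (8 departments, 6 staff types, 30 ICD codes, 30
#' CPT codes, 20 chief complaints, 10 age bins, 3 genders, 6 note types,
#' 8 sections of which 5 are key sections), concentration 0.4 (spiky,
#' realistic usage profiles), 60 related terms, and distinct planted
#' context weights dominated by chief complaint, note type and note
#' section.
#'
#' @param seed integer master seed; every generation stage derives its RNG
#'   stream from it
#' @param n_notes number of notes
#' @param vocab_size vocabulary size (topic word included)
#' @param topic_word the topic word
#' @param context_cardinalities named integer vector of dimension counts
#'   per context
#' @param concentration Dirichlet concentration of per-term context
#'   profiles (smaller = spikier usage)
#' @param n_related_terms number of terms copying the topic profile in the
#'   related contexts
#' @param related_contexts context ids in which related terms share the
#'   topic's profile
#' @param reviewer_weights named numeric vector: planted per-context logit
#'   weights of the reviewer
#' @param reviewer_intercept planted logit intercept
#' @param tokens_per_section tokens drawn into each section
#' @param sections_per_note sections per note
#' @param events_per_system_max at most this many events per system per
#'   note
#' @param event_offset_hours_max event timestamps are drawn uniformly
#'   within this many hours of the note timestamp (both sides), so a
#'   deliberate mix falls inside and outside the 48 h accumulation window
#' @param event_window_hours window used both for generation weighting and
#'   for space building
#' @param highlight_rate per-occurrence highlight thinning rate
#' @return list of class \code{"SyntheticSpec"}
#' @export
syntheticSpec <- function(seed = 1L,
                          n_notes = 800L,
                          vocab_size = 1200L,
                          topic_word = "diabetes",
                          context_cardinalities = c(
                            department = 8L, staff = 6L, icd_event = 30L,
                            cpt_event = 30L, chief_complaint = 20L,
                            age = 10L, gender = 3L, note_type = 6L,
                            note_section = 8L, top_note_section = 5L),
                          concentration = 0.4,
                          n_related_terms = 60L,
                          related_contexts = c("chief_complaint", "note_type",
                                               "note_section"),
                          reviewer_weights = c(
                            department = 1.5, staff = 0.5, icd_event = 2.5,
                            cpt_event = 1.0, chief_complaint = 6.0,
                            age = 2.0, gender = 0.8, note_type = 4.0,
                            note_section = 3.0, top_note_section = 0.3),
                          reviewer_intercept = -10,
                          tokens_per_section = 40L,
                          sections_per_note = 3L,
                          events_per_system_max = 3L,
                          event_offset_hours_max = 96,
                          event_window_hours = 48,
                          highlight_rate = 0.25) {
  ids <- contextIds(defaultContextRegistry())
  stopifnot(identical(sort(names(context_cardinalities)), sort(ids)),
            identical(sort(names(reviewer_weights)), sort(ids)),
            all(context_cardinalities >= 1L),
            n_related_terms < vocab_size,
            all(related_contexts %in% ids),
            concentration > 0, tokens_per_section >= 1L,
            highlight_rate > 0)
  spec <- list(seed = as.integer(seed), n_notes = as.integer(n_notes),
               vocab_size = as.integer(vocab_size), topic_word = topic_word,
               context_cardinalities = context_cardinalities[ids],
               concentration = concentration,
               n_related_terms = as.integer(n_related_terms),
               related_contexts = related_contexts,
               reviewer_weights = reviewer_weights[ids],
               reviewer_intercept = reviewer_intercept,
               tokens_per_section = as.integer(tokens_per_section),
               sections_per_note = as.integer(sections_per_note),
               events_per_system_max = as.integer(events_per_system_max),
               event_offset_hours_max = event_offset_hours_max,
               event_window_hours = event_window_hours,
               highlight_rate = highlight_rate)
  class(spec) <- "SyntheticSpec"
  spec
}

.specVocab <- function(spec) {
  c(spec$topic_word,
    sprintf("term%04d", seq_len(spec$vocab_size - 1L)))
}

.specRegistry <- function(spec) {
  defaultContextRegistry(event_window_hours = spec$event_window_hours)
}

# Dimension labels per context for a synthetic spec. Section labels are
# real section names (the five key sections plus generic others); age bins
# and genders use the registry labels.
.specDimLabels <- function(spec) {
  reg <- .specRegistry(spec)
  card <- spec$context_cardinalities
  secNames <- c(reg@keySections,
                "history of present illness", "plan", "physical exam",
                "review of systems", "hospital course", "labs")
  list(
    department = sprintf("dept_%02d", seq_len(card[["department"]])),
    staff = sprintf("staff_%02d", seq_len(card[["staff"]])),
    icd_event = sprintf("icd_%03d", seq_len(card[["icd_event"]])),
    cpt_event = sprintf("cpt_%03d", seq_len(card[["cpt_event"]])),
    chief_complaint = sprintf("cc_%03d", seq_len(card[["chief_complaint"]])),
    age = utils::head(ageBinLabels(reg), card[["age"]]),
    gender = utils::head(.GENDERS, card[["gender"]]),
    note_type = sprintf("ntype_%02d", seq_len(card[["note_type"]])),
    note_section = utils::head(secNames, card[["note_section"]]),
    top_note_section = utils::head(reg@keySections, card[["top_note_section"]])
  )
}

#' Sample latent per-term usage profiles
#'
#' For every term and context, draws a Dirichlet categorical distribution
#' over the context's dimensions with concentration
#' \code{spec$concentration}. The designated related terms then copy the
#' topic word's distribution exactly in the related contexts (and keep
#' their independent draws elsewhere). Deterministic given the spec seed.
#'
#' @param spec a \code{"SyntheticSpec"}
#' @return list with elements \code{profiles} (named list context ->
#'   term-by-dimension probability matrix), \code{vocab},
#'   \code{related_terms}, \code{dim_labels}
#' @export
sampleTermProfiles <- function(spec) {
  set.seed(spec$seed + 101L)
  vocab <- .specVocab(spec)
  labs <- .specDimLabels(spec)
  related <- vocab[1L + seq_len(spec$n_related_terms)]
  profiles <- lapply(names(labs), function(ctx) {
    d <- length(labs[[ctx]])
    g <- matrix(stats::rgamma(length(vocab) * d, shape = spec$concentration),
                nrow = length(vocab), ncol = d,
                dimnames = list(vocab, labs[[ctx]]))
    g / rowSums(g)
  })
  names(profiles) <- names(labs)
  for (ctx in spec$related_contexts)
    profiles[[ctx]][related, ] <-
      matrix(profiles[[ctx]][spec$topic_word, ],
             nrow = length(related), ncol = ncol(profiles[[ctx]]),
             byrow = TRUE)
  list(profiles = profiles, vocab = vocab, related_terms = related,
       dim_labels = labs)
}

#' Generate synthetic clinical notes
#'
#' Each note samples its note-level attributes uniformly (department,
#' staff type, note type, gender, age), 0 to
#' \code{spec$events_per_system_max} coded events per system with
#' timestamps spread inside and outside the event window, and a set of
#' named sections. Section text is then filled with
#' \code{spec$tokens_per_section} tokens drawn from the vocabulary with
#' probability proportional to each term's latent compatibility with the
#' note: the product of the term's profile mass on every active attribute
#' (note-level attributes, in-window event codes, and the section being
#' written, including its key-section profile where applicable),
#' renormalized over the vocabulary. Deterministic given the spec seed.
#'
#' @param spec a \code{"SyntheticSpec"}
#' @param profiles result of [sampleTermProfiles()]
#' @return list of note records
#' @export
generateNotes <- function(spec, profiles) {
  set.seed(spec$seed + 202L)
  pr <- profiles$profiles
  labs <- profiles$dim_labels
  vocab <- profiles$vocab
  reg <- .specRegistry(spec)
  base <- as.POSIXct("2016-06-01 00:00:00", tz = "UTC")
  systems <- c(icd_event = "ICD", cpt_event = "CPT",
               chief_complaint = "chief_complaint")
  notes <- vector("list", spec$n_notes)
  logp <- lapply(pr, function(m) log(pmax(m, 1e-300)))
  for (n in seq_len(spec$n_notes)) {
    ts <- base + round(stats::runif(1, 0, 300 * 24 * 3600))
    dept <- sample(labs$department, 1L)
    staff <- sample(labs$staff, 1L)
    ntype <- sample(labs$note_type, 1L)
    gender <- sample(labs$gender, 1L)
    age <- sample(0:99, 1L)
    ageBin <- .ageBin(age, reg)
    ev <- do.call(rbind, lapply(names(systems), function(ctx) {
      k <- sample(0:spec$events_per_system_max, 1L)
      if (k == 0L) return(NULL)
      codes <- sample(labs[[ctx]], k)
      off <- stats::runif(k, -spec$event_offset_hours_max,
                          spec$event_offset_hours_max)
      data.frame(system = systems[[ctx]], code = codes,
                 offset = off, stringsAsFactors = FALSE)
    }))
    lw <- logp$department[, dept] + logp$staff[, staff] +
      logp$note_type[, ntype] + logp$gender[, gender] +
      logp$age[, ageBin]
    if (!is.null(ev)) {
      inw <- abs(ev$offset) <= spec$event_window_hours
      for (i in which(inw)) {
        ctx <- names(systems)[match(ev$system[i], systems)]
        lw <- lw + logp[[ctx]][, ev$code[i]]
      }
    }
    secNames <- sample(labs$note_section, spec$sections_per_note)
    texts <- vapply(secNames, function(s) {
      lws <- lw + logp$note_section[, s]
      if (s %in% reg@keySections)
        lws <- lws + logp$top_note_section[, s]
      w <- exp(lws - max(lws))
      paste(sample(vocab, spec$tokens_per_section, replace = TRUE,
                   prob = w), collapse = " ")
    }, character(1))
    events <- if (is.null(ev)) {
      data.frame(system = character(0), code = character(0),
                 timestamp = as.POSIXct(character(0), tz = "UTC"))
    } else {
      data.frame(system = ev$system, code = ev$code,
                 timestamp = ts + round(ev$offset * 3600),
                 stringsAsFactors = FALSE)
    }
    notes[[n]] <- noteRecord(
      note_id = sprintf("note%05d", n),
      patient_id = sprintf("pt%04d", 1L + (n %% max(1L, spec$n_notes %/% 3L))),
      timestamp = ts, department = dept, staff_type = staff,
      note_type = ntype, patient_age_years = age, patient_gender = gender,
      events = events,
      sections = data.frame(section_name = secNames, text = unname(texts),
                            stringsAsFactors = FALSE))
  }
  notes
}

#' Generate reviewer highlights with a planted linear-logit preference
#'
#' For each candidate term w the reviewer's preference probability is
#' \code{plogis(intercept + sum_c w*_c S_c(topic, w))}, with S the
#' per-context cosine similarities in the supplied vector space. Every
#' occurrence of w in a note is then highlighted independently with
#' probability \code{p(w) * highlight_rate} (clamped to [0, 1]).
#' Deterministic given the spec seed.
#'
#' @param spec a \code{"SyntheticSpec"}
#' @param notes notes the highlights refer to
#' @param space a [ContextVectorSpace-class] built from those notes
#' @return a highlight set (data.frame \code{note_id}, \code{term},
#'   \code{count})
#' @export
generateHighlights <- function(spec, notes, space) {
  if (!spec$topic_word %in% vocabulary(space))
    stop(sprintf("topic word '%s' absent from the vector space",
                 spec$topic_word))
  set.seed(spec$seed + 303L)
  vocab <- .specVocab(spec)
  candidates <- setdiff(vocab, spec$topic_word)
  present <- intersect(candidates, vocabulary(space))
  S <- featurize(space, spec$topic_word, present)
  p <- stats::plogis(spec$reviewer_intercept +
                     as.numeric(S %*% spec$reviewer_weights[colnames(S)]))
  p <- pmin(1, pmax(0, p * spec$highlight_rate))
  names(p) <- present
  rows <- vector("list", length(notes))
  for (i in seq_along(notes)) {
    note <- notes[[i]]
    tab <- table(unlist(lapply(note$sections$text, tokenize)))
    tab <- tab[names(tab) %in% present]
    if (!length(tab)) next
    cnt <- stats::rbinom(length(tab), size = as.integer(tab),
                         prob = p[names(tab)])
    keep <- cnt > 0L
    if (!any(keep)) next
    rows[[i]] <- data.frame(note_id = note$note_id,
                            term = names(tab)[keep],
                            count = as.numeric(cnt[keep]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(note_id = character(0), term = character(0),
                      count = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$note_id, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic study bundle
#'
#' Runs the whole generative pipeline — latent profiles, notes, vector
#' space, reviewer highlights — and records the ground truth (planted
#' reviewer weights, the related-term set and the latent profiles) so that
#' parameter-recovery analyses are well posed. Candidates are the full
#' vocabulary minus the topic word.
#'
#' @param spec a \code{"SyntheticSpec"} (default: [syntheticSpec()])
#' @return list of class \code{"SyntheticBundle"} with elements
#'   \code{notes}, \code{highlights}, \code{candidates}, \code{space},
#'   \code{counts}, \code{truth}, \code{spec}
#' @export
makeBundle <- function(spec = syntheticSpec()) {
  profiles <- sampleTermProfiles(spec)
  notes <- generateNotes(spec, profiles)
  counts <- accumulateContexts(notes, .specRegistry(spec))
  space <- normalizeCounts(counts)
  highlights <- generateHighlights(spec, notes, space)
  structure(list(
    notes = notes, highlights = highlights,
    candidates = setdiff(profiles$vocab, spec$topic_word),
    space = space, counts = counts,
    truth = list(reviewer_weights = spec$reviewer_weights,
                 reviewer_intercept = spec$reviewer_intercept,
                 related_terms = profiles$related_terms,
                 profiles = profiles$profiles),
    spec = spec), class = "SyntheticBundle")
}

#' @export
print.SyntheticBundle <- function(x, ...) {
  cat(sprintf("SyntheticBundle: %d notes, %d candidate terms, %d highlight rows (seed %d)\n",
              length(x$notes), length(x$candidates), nrow(x$highlights),
              x$spec$seed))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Writes \code{notes.jsonl}, \code{highlights.tsv}, \code{candidates.txt}
#' and \code{truth.json} into a directory, in the same formats the readers
#' in this package consume.
#'
#' @param bundle a \code{"SyntheticBundle"} ([makeBundle()])
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
simulateCorpus <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNotes(bundle$notes, file.path(dir, "notes.jsonl"))
  writeHighlights(bundle$highlights, file.path(dir, "highlights.tsv"))
  writeLines(bundle$candidates, file.path(dir, "candidates.txt"))
  jsonlite::write_json(
    list(topic_word = bundle$spec$topic_word,
         reviewer_weights = as.list(bundle$truth$reviewer_weights),
         reviewer_intercept = bundle$truth$reviewer_intercept,
         related_terms = bundle$truth$related_terms,
         seed = bundle$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Random Gaussian embedding baseline
#'
#' A label-independent embedding table with i.i.d. standard-normal entries,
#' used as the uninformative baseline feature space in evaluations.
#'
#' @param terms terms to embed
#' @param dimension embedding dimensionality (default 100)
#' @param seed integer seed
#' @return an [EmbeddingTable-class]
#' @export
randomEmbedding <- function(terms, dimension = 100L, seed = 1L) {
  set.seed(as.integer(seed))
  m <- matrix(stats::rnorm(length(terms) * dimension), nrow = length(terms),
              dimnames = list(terms,
                              paste0("dim_", seq_len(dimension) - 1L)))
  new("EmbeddingTable", vectors = m)
}

#' Planted logistic data for parameter-recovery checks
#'
#' Draws feature vectors with independent Beta(2, 2) entries (bounded in
#' [0, 1] like similarity values) and Bernoulli labels from the linear
#' logit \code{intercept + X w}.
#'
#' @param n number of instances
#' @param weights named numeric vector of true feature weights
#' @param intercept true intercept
#' @param seed integer seed
#' @return list with \code{features} (matrix) and \code{labels} (named 0/1
#'   integer vector)
#' @export
plantedLogisticData <- function(n, weights, intercept, seed = 1L) {
  set.seed(as.integer(seed))
  k <- length(weights)
  X <- matrix(stats::rbeta(n * k, 2, 2), nrow = n,
              dimnames = list(sprintf("inst%04d", seq_len(n)), names(weights)))
  p <- stats::plogis(intercept + as.numeric(X %*% weights))
  y <- stats::setNames(stats::rbinom(n, 1L, p), rownames(X))
  list(features = X, labels = y)
}
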