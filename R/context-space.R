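#' Active context attributes of one note
#'
#' Resolves, for every note-level and event-level context in the registry,
#' the set of dimension labels the note activates: the singleton department,
#' staff type, note type and gender labels; the age bin covering the
#' patient's age; and, for each event system, the codes whose timestamp lies
#' within the registry's event window of the note timestamp (possibly
#' empty). Section-level contexts are resolved per section during
#' accumulation, not here.
#'
#' @param note a note record (see [noteRecord()])
#' @param registry a [ContextRegistry-class]
#' @return named list mapping context id to a character vector of labels
#' @export
activeAttributes <- function(note, registry = defaultContextRegistry()) {
  ev <- note$events
  inWindow <- function(system) {
    if (NROW(ev) == 0L) return(character(0))
    sel <- ev$system == system &
      abs(as.numeric(difftime(ev$timestamp, note$timestamp, units = "hours"))) <=
        registry@eventWindowHours
    unique(ev$code[sel])
  }
  cx <- registry@contexts
  out <- list()
  for (i in seq_len(nrow(cx))) {
    id <- cx$context_id[i]
    if (cx$scope[i] == "section_level") next
    out[[id]] <- switch(id,
      department = note$department,
      staff = note$staff_type,
      note_type = note$note_type,
      gender = note$patient_gender,
      age = .ageBin(note$patient_age_years, registry),
      icd_event = inWindow("ICD"),
      cpt_event = inWindow("CPT"),
      chief_complaint = inWindow("chief_complaint"),
      stop(sprintf("no attribute rule for context '%s'", id)))
  }
  out
}

#' Accumulate per-term per-context usage counts over a corpus
#'
#' For each note, each section's text is tokenized; every token occurrence
#' then increments count cells as dictated by context scope:
#' \itemize{
#'   \item note-level contexts (department, staff, note type, gender, age):
#'     each occurrence anywhere in the note adds 1 to the note's single
#'     active label;
#'   \item event-level contexts (ICD, CPT, chief complaint): each occurrence
#'     adds 1 to \emph{every} code of that system within the event window —
#'     a note with no in-window codes contributes nothing;
#'   \item the note-section context: each occurrence adds 1 to the dimension
#'     of the (case-folded) section it occurs in; the top-note-section
#'     context additionally requires the section to be a key section.
#' }
#'
#' @param notes list of note records
#' @param registry a [ContextRegistry-class]
#' @param stopwords stop words removed during tokenization
#' @return a [TermContextCounts-class]; vocabulary and dimension catalogs
#'   are sorted lexicographically, so the result is independent of note
#'   order
#' @export
accumulateContexts <- function(notes, registry = defaultContextRegistry(),
                               stopwords = defaultStopwords()) {
  ids <- contextIds(registry)
  acc <- lapply(ids, function(.) list(term = list(), dim = list(), x = list()))
  names(acc) <- ids
  emit <- function(ctx, terms, dim, x) {
    if (!length(terms)) return()
    k <- length(acc[[ctx]]$term) + 1L
    acc[[ctx]]$term[[k]] <<- terms
    acc[[ctx]]$dim[[k]] <<- rep_len(dim, length(terms))
    acc[[ctx]]$x[[k]] <<- x
  }
  for (note in notes) {
    secToks <- lapply(note$sections$text, tokenize, stopwords = stopwords)
    allTab <- table(unlist(secToks))
    attrs <- activeAttributes(note, registry)
    if (length(allTab)) {
      terms <- names(allTab)
      x <- as.numeric(allTab)
      for (ctx in names(attrs)) {
        labs <- attrs[[ctx]]
        if (length(labs) == 0L) next
        for (lab in labs) emit(ctx, terms, lab, x)
      }
      secNames <- tolower(trimws(note$sections$section_name))
      for (s in seq_along(secToks)) {
        tab <- table(secToks[[s]])
        if (!length(tab)) next
        emit("note_section", names(tab), secNames[s], as.numeric(tab))
        if (secNames[s] %in% registry@keySections)
          emit("top_note_section", names(tab), secNames[s], as.numeric(tab))
      }
    }
  }
  vocab <- sort(unique(unlist(lapply(acc, function(a) unlist(a$term)))))
  counts <- lapply(ids, function(ctx) {
    a <- acc[[ctx]]
    terms <- unlist(a$term)
    dims <- unlist(a$dim)
    x <- unlist(a$x)
    dimCat <- sort(unique(dims))
    if (length(terms) == 0L)
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(length(vocab), 0L),
                                  dimnames = list(vocab, character(0))))
    Matrix::sparseMatrix(i = match(terms, vocab), j = match(dims, dimCat),
                         x = x, dims = c(length(vocab), length(dimCat)),
                         dimnames = list(vocab, dimCat))
  })
  names(counts) <- ids
  new("TermContextCounts", counts = counts, registry = registry)
}

#' Normalize usage counts into the medical-context vector space
#'
#' Divides each term's per-context count vector by its own sum, turning raw
#' counts into usage proportions in [0, 1]. A term's all-zero context vector
#' stays all-zero (no usage evidence in that context). Dimension catalogs
#' are carried over unchanged so all terms share one index space per
#' context.
#'
#' @param counts a [TermContextCounts-class]
#' @return a [ContextVectorSpace-class]
#' @export
normalizeCounts <- function(counts) {
  stopifnot(is(counts, "TermContextCounts"))
  vectors <- lapply(counts@counts, function(m) {
    if (ncol(m) == 0L || nrow(m) == 0L) return(m)
    rs <- Matrix::rowSums(m)
    inv <- ifelse(rs > 0, 1 / rs, 0)
    out <- as(Matrix::Diagonal(x = inv) %*% m, "CsparseMatrix")
    dimnames(out) <- dimnames(m)
    out
  })
  new("ContextVectorSpace", vectors = vectors, registry = counts@registry)
}

#' Build the medical-context vector space in one step
#'
#' Convenience wrapper: [accumulateContexts()] followed by
#' [normalizeCounts()].
#'
#' @inheritParams accumulateContexts
#' @return a [ContextVectorSpace-class]
#' @export
buildContextSpace <- function(notes, registry = defaultContextRegistry(),
                              stopwords = defaultStopwords()) {
  normalizeCounts(accumulateContexts(notes, registry, stopwords))
}

#' @rdname vocabulary
#' @export
setMethod("vocabulary", "TermContextCounts",
          function(x) rownames(x@counts[[1]]))

#' @rdname vocabulary
#' @export
setMethod("vocabulary", "ContextVectorSpace",
          function(x) rownames(x@vectors[[1]]))

.getCtx <- function(m, context) {
  if (!context %in% names(m))
    stop(sprintf("unknown context '%s'", context))
  m[[context]]
}

#' @rdname contextMatrix
#' @export
setMethod("contextMatrix", "TermContextCounts",
          function(x, context) .getCtx(x@counts, context))

#' @rdname contextMatrix
#' @export
setMethod("contextMatrix", "ContextVectorSpace",
          function(x, context) .getCtx(x@vectors, context))

#' @rdname dimensionSummary
#' @export
setMethod("dimensionSummary", "TermContextCounts",
          function(x) vapply(x@counts, ncol, integer(1)))

#' @rdname dimensionSummary
#' @export
setMethod("dimensionSummary", "ContextVectorSpace",
          function(x) vapply(x@vectors, ncol, integer(1)))

setMethod("show", "TermContextCounts", function(object) {
  cat(sprintf("TermContextCounts: %d terms, %d contexts\n",
              length(vocabulary(object)), length(object@counts)))
  print(dimensionSummary(object))
})

setMethod("show", "ContextVectorSpace", function(object) {
  cat(sprintf("ContextVectorSpace: %d terms, %d contexts\n",
              length(vocabulary(object)), length(object@vectors)))
  print(dimensionSummary(object))
})

#' Largest usage proportions of a term in one context
#'
#' @param space a [ContextVectorSpace-class]
#' @param term a term in the space's vocabulary
#' @param context a context id
#' @param k number of dimensions to return
#' @return data.frame with columns \code{dimension}, \code{proportion},
#'   descending by proportion with ties broken by ascending dimension
#'   label; fewer than \code{k} rows when fewer are nonzero
#' @export
topDimensions <- function(space, term, context, k = 3L) {
  stopifnot(is(space, "ContextVectorSpace"), k >= 0)
  if (!term %in% vocabulary(space))
    stop(sprintf("unknown term '%s'", term))
  m <- contextMatrix(space, context)
  if (ncol(m) == 0L)
    return(data.frame(dimension = character(0), proportion = numeric(0)))
  v <- m[term, ]
  v <- as.numeric(v)
  names(v) <- colnames(m)
  v <- v[v > 0]
  ord <- order(-v, names(v))
  sel <- utils::head(ord, k)
  data.frame(dimension = names(v)[sel], proportion = unname(v[sel]),
             stringsAsFactors = FALSE)
}
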