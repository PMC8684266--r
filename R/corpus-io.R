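#' Default English stop-word list
#'
#' Standard English function words (articles, prepositions, pronouns,
#' auxiliaries), stored case-folded. Users may substitute their own list in
#' [tokenize()], [accumulateContexts()] and [readHighlights()].
#'
#' @return character vector of case-folded stop words
#' @export
defaultStopwords <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "stopwords_en.txt", package = "medcontext")
      cache <<- readLines(path, warn = FALSE)
    }
    cache
  }
})

#' Tokenize clinical text
#'
#' Case-folds, splits on runs of non-alphanumeric characters, then drops
#' single-character tokens and stop words. Numeric tokens are retained.
#' Order and duplicates are preserved.
#'
#' @param text a single character string (empty string gives an empty
#'   token list)
#' @param stopwords case-folded stop words to remove
#' @return character vector of tokens
#' @examples
#' tokenize("a EEG of seizures", stopwords = c("a", "of"))
#' @export
tokenize <- function(text, stopwords = defaultStopwords()) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^[:alnum:]]+")[[1]]
  toks <- toks[nchar(toks) > 1L]
  toks[!toks %in% stopwords]
}

.parseTimestamp <- function(x, where) {
  if (is.null(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("%s: missing timestamp", where), call. = FALSE)
  x2 <- sub("Z$", "", sub("^(\\d{4}-\\d{2}-\\d{2}) ", "\\1T", x))
  t <- as.POSIXct(x2, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(t))
    stop(sprintf("%s: unparseable timestamp '%s' (expected ISO-8601)",
                 where, x), call. = FALSE)
  t
}

.requireField <- function(obj, field, where) {
  if (is.null(obj[[field]]))
    stop(sprintf("%s: missing required field '%s'", where, field),
         call. = FALSE)
  obj[[field]]
}

#' Construct a validated note record
#'
#' A note record holds one clinical note's non-textual context (author
#' department and staff type, note type, timestamp, patient age and gender,
#' concurrent coded events) together with its sectioned text. A note with
#' no explicit sections is represented as a single section named "body".
#'
#' @param note_id unique note identifier
#' @param patient_id patient identifier
#' @param timestamp POSIXct or ISO-8601 string
#' @param department,staff_type,note_type categorical labels
#' @param patient_age_years non-negative integer
#' @param patient_gender one of "male", "female", "unknown"
#' @param events data.frame with columns system ("ICD", "CPT",
#'   "chief_complaint"), code, timestamp (POSIXct)
#' @param sections data.frame with columns section_name, text
#' @return a list of class \code{"NoteRecord"}
#' @export
noteRecord <- function(note_id, patient_id, timestamp, department, staff_type,
                       note_type, patient_age_years, patient_gender,
                       events = data.frame(system = character(0),
                                           code = character(0),
                                           timestamp = as.POSIXct(character(0), tz = "UTC")),
                       sections = NULL) {
  where <- sprintf("note '%s'", note_id)
  if (is.character(timestamp)) timestamp <- .parseTimestamp(timestamp, where)
  if (is.null(sections) || NROW(sections) == 0L)
    sections <- data.frame(section_name = "body", text = "",
                           stringsAsFactors = FALSE)
  rec <- list(note_id = as.character(note_id),
              patient_id = as.character(patient_id),
              timestamp = timestamp,
              department = as.character(department),
              staff_type = as.character(staff_type),
              note_type = as.character(note_type),
              patient_age_years = as.integer(patient_age_years),
              patient_gender = as.character(patient_gender),
              events = events, sections = sections)
  .validateNote(rec, where)
  class(rec) <- "NoteRecord"
  rec
}

.validateNote <- function(rec, where) {
  if (!nzchar(rec$note_id))
    stop(sprintf("%s: note_id must be non-empty", where), call. = FALSE)
  if (is.na(rec$patient_age_years) || rec$patient_age_years < 0L)
    stop(sprintf("%s: field 'patient_age_years' must be a non-negative integer",
                 where), call. = FALSE)
  if (!rec$patient_gender %in% .GENDERS)
    stop(sprintf("%s: field 'patient_gender' value '%s' not in {%s}", where,
                 rec$patient_gender, paste(.GENDERS, collapse = ", ")),
         call. = FALSE)
  ev <- rec$events
  if (NROW(ev)) {
    if (!all(c("system", "code", "timestamp") %in% names(ev)))
      stop(sprintf("%s: events need columns system, code, timestamp", where),
           call. = FALSE)
    if (!all(ev$system %in% .EVENT_SYSTEMS))
      stop(sprintf("%s: field 'events.system' must be in {%s}", where,
                   paste(.EVENT_SYSTEMS, collapse = ", ")), call. = FALSE)
    if (any(!nzchar(ev$code)))
      stop(sprintf("%s: field 'events.code' must be non-empty", where),
           call. = FALSE)
  }
  sx <- rec$sections
  if (NROW(sx) == 0L)
    stop(sprintf("%s: sections must be non-empty", where), call. = FALSE)
  if (any(!nzchar(tolower(trimws(sx$section_name)))))
    stop(sprintf("%s: field 'sections.section_name' must be non-empty", where),
         call. = FALSE)
  invisible(TRUE)
}

#' Read note records from a JSON Lines file
#'
#' One JSON object per line with keys \code{note_id}, \code{patient_id},
#' \code{timestamp}, \code{department}, \code{staff_type}, \code{note_type},
#' \code{patient_age_years}, \code{patient_gender}, \code{events} (array of
#' \code{{system, code, timestamp}}) and \code{sections} (array of
#' \code{{section_name, text}}). Validation failures are hard errors naming
#' the line and field.
#'
#' @param path path to a JSONL file
#' @return list of note records, in file order
#' @seealso [writeNotes()], [noteRecord()]
#' @export
readNotes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  notes <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    where <- sprintf("line %d", i)
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("%s: invalid JSON: %s", where,
                                   conditionMessage(e)), call. = FALSE))
    for (f in c("note_id", "patient_id", "timestamp", "department",
                "staff_type", "note_type", "patient_age_years",
                "patient_gender", "sections"))
      .requireField(obj, f, where)
    if (obj$note_id %in% seen)
      stop(sprintf("%s: duplicate note_id '%s'", where, obj$note_id),
           call. = FALSE)
    seen <- c(seen, obj$note_id)
    ev <- obj$events
    if (is.null(ev) || NROW(ev) == 0L) {
      ev <- data.frame(system = character(0), code = character(0),
                       timestamp = as.POSIXct(character(0), tz = "UTC"))
    } else {
      ev <- as.data.frame(ev, stringsAsFactors = FALSE)
      ev$timestamp <- do.call(c, lapply(as.character(ev$timestamp),
                                        .parseTimestamp, where = where))
      ev$code <- as.character(ev$code)
      ev$system <- as.character(ev$system)
    }
    sx <- as.data.frame(obj$sections, stringsAsFactors = FALSE)
    rec <- tryCatch(
      noteRecord(obj$note_id, obj$patient_id,
                 .parseTimestamp(as.character(obj$timestamp), where),
                 obj$department, obj$staff_type, obj$note_type,
                 obj$patient_age_years, obj$patient_gender, ev, sx),
      error = function(e)
        stop(sprintf("%s: %s", where, conditionMessage(e)), call. = FALSE))
    notes[[i]] <- rec
  }
  notes
}

.fmtTime <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write note records to a JSON Lines file
#'
#' Inverse of [readNotes()]: writing and re-reading yields field-by-field
#' equal records.
#'
#' @param notes list of note records
#' @param path output path
#' @return the path, invisibly
#' @export
writeNotes <- function(notes, path) {
  lines <- vapply(notes, function(n) {
    ev <- n$events
    obj <- list(
      note_id = n$note_id, patient_id = n$patient_id,
      timestamp = .fmtTime(n$timestamp),
      department = n$department, staff_type = n$staff_type,
      note_type = n$note_type,
      patient_age_years = n$patient_age_years,
      patient_gender = n$patient_gender,
      events = if (NROW(ev)) data.frame(system = ev$system, code = ev$code,
                                        timestamp = .fmtTime(ev$timestamp),
                                        stringsAsFactors = FALSE)
               else list(),
      sections = data.frame(section_name = n$sections$section_name,
                            text = n$sections$text, stringsAsFactors = FALSE)
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read reviewer highlight records
#'
#' Reads a TSV with header columns \code{note_id}, \code{term},
#' \code{count}. Terms are canonicalized through [tokenize()]: a multi-token
#' highlight contributes each of its tokens individually with the row's
#' count, and rows mapping to the same (note_id, token) are summed. Tokens
#' removed by tokenization (stop words, single characters) contribute
#' nothing.
#'
#' @param path path to the TSV file
#' @param stopwords stop words used during canonicalization
#' @return a highlight set: data.frame with columns \code{note_id},
#'   \code{term}, \code{count}
#' @export
readHighlights <- function(path, stopwords = defaultStopwords()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(note_id = "character"))
  need <- c("note_id", "term", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("highlight file missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(is.na(df$count)) || any(df$count < 0))
    stop("highlight counts must be non-negative")
  highlightSet(df$note_id, df$term, df$count, stopwords = stopwords)
}

#' Build a canonical highlight set from raw rows
#'
#' @param note_id,term,count parallel vectors of highlight rows
#' @param stopwords stop words used during canonicalization
#' @return data.frame with columns \code{note_id}, \code{term},
#'   \code{count}, one row per (note, canonical token), sorted
#' @export
highlightSet <- function(note_id, term, count,
                         stopwords = defaultStopwords()) {
  stopifnot(length(note_id) == length(term), length(term) == length(count))
  if (any(count < 0)) stop("highlight counts must be non-negative")
  toks <- lapply(as.character(term), tokenize, stopwords = stopwords)
  nrep <- lengths(toks)
  out <- data.frame(note_id = rep(as.character(note_id), nrep),
                    term = unlist(toks),
                    count = rep(as.numeric(count), nrep),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out)
  agg <- stats::aggregate(count ~ note_id + term, data = out, FUN = sum)
  agg <- agg[order(agg$note_id, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("note_id", "term", "count")]
}

#' Write a highlight set as TSV
#' @param highlights data.frame as returned by [readHighlights()]
#' @param path output path
#' @return the path, invisibly
#' @export
writeHighlights <- function(highlights, path) {
  utils::write.table(highlights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate-term list
#'
#' Plain text, one term per line; terms are case-folded, blank lines
#' dropped, duplicates removed (first kept).
#'
#' @param path path to the file
#' @return character vector of candidate terms
#' @export
readCandidates <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- tolower(trimws(readLines(path, warn = FALSE)))
  unique(x[nzchar(x)])
}

#' Read word embeddings in word2vec text format
#'
#' The optional first line may be a header "V D" (vocabulary size and
#' dimension); every other line is a term followed by D numbers, whitespace
#' separated. Terms are case-folded; on a case collision the first
#' occurrence is kept. Inconsistent vector lengths are a format error
#' naming the line.
#'
#' @param path path to the embedding file
#' @return an [EmbeddingTable-class]
#' @export
readEmbeddings <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty embedding file")
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  start <- 1L
  dim <- NA_integer_
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    dim <- as.integer(first[2])
    start <- 2L
  }
  data <- lines[seq.int(start, length(lines))]
  if (!length(data)) stop("embedding file has no vectors")
  terms <- character(length(data))
  rows <- vector("list", length(data))
  for (k in seq_along(data)) {
    parts <- strsplit(trimws(data[k]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric embedding values", k + start - 1L))
    if (is.na(dim)) dim <- length(vals)
    if (length(vals) != dim)
      stop(sprintf("line %d: expected %d values, found %d",
                   k + start - 1L, dim, length(vals)))
    terms[k] <- tolower(parts[1])
    rows[[k]] <- vals
  }
  keep <- !duplicated(terms)
  mat <- do.call(rbind, rows[keep])
  rownames(mat) <- terms[keep]
  colnames(mat) <- paste0("dim_", seq_len(dim) - 1L)
  new("EmbeddingTable", vectors = mat)
}

#' @rdname vocabulary
#' @export
setMethod("vocabulary", "EmbeddingTable", function(x) rownames(x@vectors))

#' @rdname embeddingDim
#' @export
setMethod("embeddingDim", "EmbeddingTable", function(x) ncol(x@vectors))

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d terms x %d dimensions\n",
              nrow(object@vectors), ncol(object@vectors)))
})
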