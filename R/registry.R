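#' Default registry of the ten medical contexts
#'
#' Builds the canonical ten-context registry: author department and staff
#' type (hospital organizational structure); concurrent ICD, CPT and
#' chief-complaint events (medical events); patient age and gender
#' (demographics); note type, note section and top note section (note
#' structure). Event contexts count codes whose timestamp falls within
#' \code{event_window_hours} of the note timestamp; the top-note-section
#' context counts occurrences only inside the designated key sections;
#' patient age is quantized into ten-year bins whose lower edges are
#' \code{age_bin_edges} (final bin open-ended, labeled e.g. \code{"90+"}).
#'
#' @param event_window_hours window (hours) around the note timestamp within
#'   which coded events are considered concurrent; default 48.
#' @param key_sections case-folded names of the sections that feed the
#'   top-note-section context; defaults to the five sections generally most
#'   informative in chart review (assessment, findings, family medical
#'   history, medications, problem list).
#' @param age_bin_edges ascending integer lower edges of the age bins;
#'   default \code{seq(0, 90, 10)} giving bins "0-9" ... "80-89", "90+".
#' @return a [ContextRegistry-class]
#' @examples
#' reg <- defaultContextRegistry()
#' contextIds(reg)
#' @export
defaultContextRegistry <- function(event_window_hours = 48,
                                   key_sections = c("assessment", "findings",
                                     "family medical history", "medications",
                                     "problem list"),
                                   age_bin_edges = seq(0L, 90L, 10L)) {
  contexts <- data.frame(
    context_id = c("department", "staff", "icd_event", "cpt_event",
                   "chief_complaint", "age", "gender", "note_type",
                   "note_section", "top_note_section"),
    context_type = c("organizational", "organizational", "medical_event",
                     "medical_event", "medical_event", "demographics",
                     "demographics", "note_structure", "note_structure",
                     "note_structure"),
    scope = c("note_level", "note_level", "event_level", "event_level",
              "event_level", "note_level", "note_level", "note_level",
              "section_level", "section_level"),
    stringsAsFactors = FALSE
  )
  new("ContextRegistry", contexts = contexts,
      eventWindowHours = event_window_hours,
      keySections = tolower(key_sections),
      ageBinEdges = as.integer(age_bin_edges))
}

#' Age bin labels of a registry
#'
#' @param registry a [ContextRegistry-class]
#' @return character vector of bin labels, e.g. "0-9", ..., "90+"
#' @export
ageBinLabels <- function(registry) {
  e <- registry@ageBinEdges
  n <- length(e)
  c(paste0(e[-n], "-", e[-1] - 1L), paste0(e[n], "+"))
}

# Bin label covering each age; errors on negative age.
.ageBin <- function(age, registry) {
  if (any(age < 0)) stop("patient_age_years must be >= 0")
  labs <- ageBinLabels(registry)
  idx <- findInterval(age, registry@ageBinEdges)
  idx[idx < 1L] <- 1L  # ages below the first edge fall in the first bin
  labs[idx]
}

#' @describeIn defaultContextRegistry event-window accessor
#' @param registry a [ContextRegistry-class]
#' @export
eventWindowHours <- function(registry) registry@eventWindowHours

#' @describeIn defaultContextRegistry key-section accessor
#' @export
keySections <- function(registry) registry@keySections

#' @rdname contextIds
#' @export
setMethod("contextIds", "ContextRegistry",
          function(x) x@contexts$context_id)

#' @rdname contextIds
#' @export
setMethod("contextIds", "TermContextCounts",
          function(x) contextIds(x@registry))

#' @rdname contextIds
#' @export
setMethod("contextIds", "ContextVectorSpace",
          function(x) contextIds(x@registry))

setMethod("show", "ContextRegistry", function(object) {
  cat(sprintf("ContextRegistry with %d contexts\n", nrow(object@contexts)))
  cat("  contexts:", paste(object@contexts$context_id, collapse = ", "), "\n")
  cat(sprintf("  event window: %g h | key sections: %s\n",
              object@eventWindowHours,
              paste(object@keySections, collapse = "; ")))
  cat("  age bins:", paste(ageBinLabels(object), collapse = " "), "\n")
})
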