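#' @import methods
#' @importFrom Matrix sparseMatrix rowSums Diagonal crossprod t colSums
NULL

.CONTEXT_TYPES <- c("organizational", "medical_event", "demographics",
                    "note_structure")
.CONTEXT_SCOPES <- c("note_level", "section_level", "event_level")
.EVENT_SYSTEMS <- c("ICD", "CPT", "chief_complaint")
.GENDERS <- c("male", "female", "unknown")

#' Registry of medical contexts
#'
#' A \code{ContextRegistry} defines the set of medical contexts over which
#' term usage is accumulated: the context identifiers, their broad type
#' (organizational, medical event, demographics, note structure), and the
#' accumulation scope of each (note level, section level, or event level).
#' It also carries the tunable accumulation parameters: the time window
#' around a note's timestamp within which coded events (ICD, CPT, chief
#' complaint) count as concurrent, the set of "key" note sections that feed
#' the top-note-section context, and the age bin edges used to quantize
#' patient age.
#'
#' @slot contexts data.frame with columns \code{context_id},
#'   \code{context_type}, \code{scope}; row order is the canonical context
#'   order used by similarity vectors and classifiers.
#' @slot eventWindowHours positive number; events within this many hours of
#'   the note timestamp (either side) are counted.
#' @slot keySections character vector of case-folded section names feeding
#'   the top-note-section context.
#' @slot ageBinEdges ascending integer vector of lower bin edges; the final
#'   bin is open-ended.
#'
#' @seealso [defaultContextRegistry()]
#' @export
setClass("ContextRegistry",
  representation(
    contexts = "data.frame",
    eventWindowHours = "numeric",
    keySections = "character",
    ageBinEdges = "integer"
  )
)

setValidity("ContextRegistry", function(object) {
  msg <- character(0)
  cx <- object@contexts
  need <- c("context_id", "context_type", "scope")
  if (!all(need %in% names(cx)))
    return(sprintf("contexts must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(cx$context_id))
    msg <- c(msg, "context ids must be unique")
  if (!all(cx$context_type %in% .CONTEXT_TYPES))
    msg <- c(msg, "invalid context_type")
  if (!all(cx$scope %in% .CONTEXT_SCOPES))
    msg <- c(msg, "invalid scope")
  if (length(object@eventWindowHours) != 1L || object@eventWindowHours <= 0)
    msg <- c(msg, "eventWindowHours must be a single positive number")
  if (is.unsorted(object@ageBinEdges, strictly = TRUE))
    msg <- c(msg, "ageBinEdges must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' Raw per-term per-context usage counts
#'
#' Holds, for every term in the corpus vocabulary and every context in the
#' registry, the number of token occurrences attributed to each observed
#' dimension label (department name, ICD code, age bin, section name, ...).
#' One sparse matrix per context: rows are the shared vocabulary, columns
#' the context's observed dimension catalog.
#'
#' @slot counts named list (one entry per registry context, in registry
#'   order) of sparse term-by-dimension count matrices.
#' @slot registry the [ContextRegistry-class] the counts were accumulated
#'   under.
#' @seealso [accumulateContexts()], [normalizeCounts()]
#' @export
setClass("TermContextCounts",
  representation(counts = "list", registry = "ContextRegistry")
)

#' The medical-context vector space
#'
#' The normalized form of [TermContextCounts-class]: each term's per-context
#' count vector divided by its own sum, so every nonzero context vector is a
#' probability vector over that context's dimensions (all-zero vectors stay
#' all-zero). Terms are compared context-by-context with cosine similarity.
#'
#' @slot vectors named list (registry order) of sparse term-by-dimension
#'   matrices of row-normalized proportions in [0, 1].
#' @slot registry the [ContextRegistry-class].
#' @seealso [contextCosine()], [similarityVector()], [featurize()]
#' @export
setClass("ContextVectorSpace",
  representation(vectors = "list", registry = "ContextRegistry")
)

.validateCtxMatrices <- function(object, slotname) {
  m <- slot(object, slotname)
  ids <- object@registry@contexts$context_id
  if (!identical(names(m), ids))
    return("matrix list names must equal registry context ids, in order")
  vocab <- NULL
  for (ctx in names(m)) {
    x <- m[[ctx]]
    if (!is(x, "Matrix") && !is.matrix(x))
      return(sprintf("context '%s': not a matrix", ctx))
    if (is.null(vocab)) vocab <- rownames(x)
    if (!identical(rownames(x), vocab))
      return("all context matrices must share one vocabulary (rownames)")
    if (length(x@x) && min(x@x) < 0)
      return(sprintf("context '%s': negative entries", ctx))
  }
  TRUE
}

setValidity("TermContextCounts", function(object)
  .validateCtxMatrices(object, "counts"))

setValidity("ContextVectorSpace", function(object) {
  v <- .validateCtxMatrices(object, "vectors")
  if (!isTRUE(v)) return(v)
  for (ctx in names(object@vectors)) {
    x <- object@vectors[[ctx]]
    if (ncol(x) == 0L) next
    rs <- Matrix::rowSums(x)
    bad <- rs > 0 & abs(rs - 1) > 1e-9
    if (any(bad))
      return(sprintf("context '%s': %d nonzero rows do not sum to 1",
                     ctx, sum(bad)))
  }
  TRUE
})

#' Word-embedding lookup table
#'
#' A dense term-by-dimension matrix of word embeddings (e.g. word2vec) used
#' as a baseline feature space. Terms are stored case-folded.
#'
#' @slot vectors numeric matrix; rownames are terms.
#' @seealso [readEmbeddings()], [embeddingFeatures()]
#' @export
setClass("EmbeddingTable", representation(vectors = "matrix"))

setValidity("EmbeddingTable", function(object) {
  if (!is.numeric(object@vectors)) return("vectors must be numeric")
  if (nrow(object@vectors) > 0L && is.null(rownames(object@vectors)))
    return("vectors must have term rownames")
  if (anyDuplicated(rownames(object@vectors))) return("duplicate terms")
  TRUE
})

#' Importance labels for candidate terms
#'
#' Binary labels over a candidate set: a term is labeled important (1) when
#' its total highlight count exceeds the importance cutoff, otherwise 0.
#'
#' @slot labels named integer vector of 0/1 labels, one per candidate term.
#' @slot cutoff the importance cutoff I used (labels are \code{H > I}).
#' @slot positives number of 1-labels.
#' @seealso [buildLabels()], [cutoffSweep()]
#' @export
setClass("LabelSet",
  representation(labels = "integer", cutoff = "integer", positives = "integer")
)

setValidity("LabelSet", function(object) {
  if (is.null(names(object@labels))) return("labels must be named by term")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (object@positives != sum(object@labels == 1L))
    return("positives does not match label count")
  if (object@cutoff < 1L) return("cutoff must be >= 1")
  TRUE
})

#' Fitted semantic-preference model
#'
#' A classifier trained on per-context similarity features (or baseline
#' embedding features) to predict which candidate terms a chart reviewer
#' prefers. For logistic regression the per-context weights and intercept
#' are exposed for interpretation; random forest and SVM fits are opaque.
#'
#' @slot modelKind one of \code{"logistic_regression"},
#'   \code{"random_forest"}, \code{"svm"}.
#' @slot featureNames ordered feature labels the model was trained on.
#' @slot fit the underlying fitted object.
#' @slot contextWeights named per-feature coefficients (logistic only).
#' @slot intercept intercept (logistic only).
#' @slot coefTable coefficient table with Wald statistics (logistic only).
#' @slot seed integer seed used for training.
#' @slot standardize whether features were standardized before fitting.
#' @slot center,scale standardization parameters (length 0 when unused).
#' @seealso [trainPreference()], [predictScores()], [interpretModel()]
#' @export
setClass("PreferenceModel",
  representation(
    modelKind = "character",
    featureNames = "character",
    fit = "ANY",
    contextWeights = "numeric",
    intercept = "numeric",
    coefTable = "data.frame",
    seed = "integer",
    standardize = "logical",
    center = "numeric",
    scale = "numeric"
  )
)

setValidity("PreferenceModel", function(object) {
  kinds <- c("logistic_regression", "random_forest", "svm")
  if (!object@modelKind %in% kinds)
    return(sprintf("modelKind must be one of %s", paste(kinds, collapse = ", ")))
  if (object@modelKind == "logistic_regression") {
    if (length(object@contextWeights) != length(object@featureNames))
      return("contextWeights must have one entry per feature")
    if (length(object@intercept) != 1L)
      return("intercept required for logistic_regression")
  } else if (length(object@contextWeights) != 0L) {
    return("contextWeights only allowed for logistic_regression")
  }
  TRUE
})
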