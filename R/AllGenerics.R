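#' Vocabulary of a counts object or vector space
#'
#' @param x a [TermContextCounts-class], [ContextVectorSpace-class] or
#'   [EmbeddingTable-class]
#' @return character vector of terms (lexicographic order for accumulated
#'   objects)
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' Context identifiers, in canonical registry order
#'
#' @param x a [ContextRegistry-class], [TermContextCounts-class] or
#'   [ContextVectorSpace-class]
#' @return character vector of context ids
#' @export
setGeneric("contextIds", function(x) standardGeneric("contextIds"))

#' Extract one context's term-by-dimension matrix
#'
#' @param x a [TermContextCounts-class] or [ContextVectorSpace-class]
#' @param context a context id
#' @return sparse term-by-dimension matrix (counts or proportions)
#' @export
setGeneric("contextMatrix", function(x, context) standardGeneric("contextMatrix"))

#' Number of observed dimensions per context
#'
#' Reports, for each context, the number of distinct dimension labels
#' observed while accumulating the corpus (e.g. how many departments,
#' ICD codes or note sections appeared).
#'
#' @param x a [TermContextCounts-class] or [ContextVectorSpace-class]
#' @return named integer vector, one entry per context
#' @export
setGeneric("dimensionSummary", function(x) standardGeneric("dimensionSummary"))

#' Per-term label vector of a label set
#' @param x a [LabelSet-class]
#' @return named integer vector of 0/1 labels
#' @export
setGeneric("labelVector", function(x) standardGeneric("labelVector"))

#' Importance cutoff of a label set
#' @param x a [LabelSet-class]
#' @return integer cutoff I (labels are H > I)
#' @export
setGeneric("importanceCutoff", function(x) standardGeneric("importanceCutoff"))

#' Number of positive labels
#' @param x a [LabelSet-class]
#' @return integer count of 1-labels
#' @export
setGeneric("nPositives", function(x) standardGeneric("nPositives"))

#' Fitted per-context weights of a preference model
#' @param x a [PreferenceModel-class] (logistic regression)
#' @return named numeric vector of coefficients
#' @export
setGeneric("contextWeights", function(x) standardGeneric("contextWeights"))

#' Embedding dimensionality
#' @param x an [EmbeddingTable-class]
#' @return integer number of embedding dimensions
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
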