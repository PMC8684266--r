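#' Cosine similarity of two terms within one medical context
#'
#' The cosine of the two terms' normalized usage vectors over the context's
#' shared dimension catalog. Because usage vectors are non-negative, the
#' value lies in [0, 1]. If either vector is all-zero (no usage evidence in
#' that context) the similarity is defined as 0.
#'
#' @param space a [ContextVectorSpace-class]
#' @param term_i,term_j terms in the space's vocabulary
#' @param context a context id
#' @return similarity in [0, 1]
#' @export
contextCosine <- function(space, term_i, term_j, context) {
  stopifnot(is(space, "ContextVectorSpace"))
  vocab <- vocabulary(space)
  for (t in c(term_i, term_j))
    if (!t %in% vocab) stop(sprintf("unknown term '%s'", t))
  m <- contextMatrix(space, context)
  if (ncol(m) == 0L) return(0)
  a <- m[term_i, ]
  b <- m[term_j, ]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  as.numeric(sum(a * b) / (na * nb))
}

#' Medical-context similarity vector of two terms
#'
#' Evaluates [contextCosine()] for every context in registry order,
#' yielding the per-context similarity profile of the pair — the feature
#' vector used by preference classifiers.
#'
#' @inheritParams contextCosine
#' @param topic,other terms in the space's vocabulary
#' @return named numeric vector, one similarity in [0, 1] per context
#' @export
similarityVector <- function(space, topic, other) {
  ids <- contextIds(space)
  vapply(ids, function(ctx) contextCosine(space, topic, other, ctx),
         numeric(1))
}

# Cosine of one term (row vector) against many rows of the same context
# matrix, vectorized over rows. Zero rows give 0.
.cosineToTopic <- function(m, topic, terms) {
  if (ncol(m) == 0L) return(stats::setNames(numeric(length(terms)), terms))
  t <- m[topic, , drop = FALSE]
  tn <- sqrt(sum(t@x^2))
  sub <- m[terms, , drop = FALSE]
  num <- as.numeric(sub %*% Matrix::t(t))
  rn <- sqrt(Matrix::rowSums(sub^2))
  den <- rn * tn
  out <- ifelse(den > 0, num / den, 0)
  # guard against tiny negative/overshoot from floating point
  stats::setNames(pmin(pmax(out, 0), 1), terms)
}

#' Similarity-vector feature matrix for a candidate set
#'
#' One row per candidate term: its medical-context similarity vector
#' against the topic word. Candidates absent from the space receive a row
#' of zeros with a warning (or a hard error when \code{absent = "error"}).
#'
#' @param space a [ContextVectorSpace-class]
#' @param topic the topic word (must be in the vocabulary)
#' @param candidates character vector of candidate terms
#' @param absent policy for candidates missing from the vocabulary
#' @return numeric matrix, rows named by candidate, columns by context id
#' @export
featurize <- function(space, topic, candidates,
                      absent = c("zero", "error")) {
  absent <- match.arg(absent)
  stopifnot(is(space, "ContextVectorSpace"))
  vocab <- vocabulary(space)
  if (!topic %in% vocab) stop(sprintf("unknown topic '%s'", topic))
  ids <- contextIds(space)
  known <- candidates %in% vocab
  if (any(!known)) {
    msg <- sprintf("%d candidate(s) absent from the vector space: %s",
                   sum(!known),
                   paste(utils::head(candidates[!known], 5), collapse = ", "))
    if (absent == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  out <- matrix(0, nrow = length(candidates), ncol = length(ids),
                dimnames = list(candidates, ids))
  kc <- candidates[known]
  if (length(kc))
    for (ctx in ids)
      out[kc, ctx] <- .cosineToTopic(contextMatrix(space, ctx), topic, kc)
  out
}

#' Baseline feature matrix from word embeddings
#'
#' One row per candidate: the raw embedding vector. Absent candidates
#' receive a zero row with a warning.
#'
#' @param table an [EmbeddingTable-class]
#' @param candidates character vector of candidate terms
#' @param absent policy for candidates missing from the table
#' @return numeric matrix, rows named by candidate, columns
#'   \code{dim_0 ... dim_{D-1}}
#' @export
embeddingFeatures <- function(table, candidates,
                              absent = c("zero", "error")) {
  absent <- match.arg(absent)
  stopifnot(is(table, "EmbeddingTable"))
  if (nrow(table@vectors) == 0L) stop("empty embedding table")
  known <- candidates %in% rownames(table@vectors)
  if (any(!known)) {
    msg <- sprintf("%d candidate(s) absent from the embedding table: %s",
                   sum(!known),
                   paste(utils::head(candidates[!known], 5), collapse = ", "))
    if (absent == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  out <- matrix(0, nrow = length(candidates), ncol = ncol(table@vectors),
                dimnames = list(candidates, colnames(table@vectors)))
  out[candidates[known], ] <- table@vectors[candidates[known], , drop = FALSE]
  out
}

#' Unsupervised top-k similar terms
#'
#' Ranks the vocabulary (minus the topic itself) by the unweighted mean of
#' per-context cosine similarity to the topic, optionally restricted to a
#' subset of contexts. This is the unsupervised view of the space; the
#' supervised preference model ([trainPreference()]) learns the per-context
#' weighting from reviewer highlights and supersedes it for ranking.
#'
#' @param space a [ContextVectorSpace-class]
#' @param topic the topic word
#' @param k number of terms to return
#' @param contexts optional character vector of context ids to average
#'   over (default: all)
#' @return data.frame with columns \code{term}, \code{score}, descending
#'   by score with lexicographic tie-break
#' @export
topKSimilar <- function(space, topic, k = 10L, contexts = NULL) {
  stopifnot(k >= 0)
  if (is.null(contexts)) contexts <- contextIds(space)
  bad <- setdiff(contexts, contextIds(space))
  if (length(bad)) stop(sprintf("unknown context '%s'", bad[1]))
  others <- setdiff(vocabulary(space), topic)
  if (!topic %in% vocabulary(space)) stop(sprintf("unknown topic '%s'", topic))
  if (length(others) == 0L || k == 0L)
    return(data.frame(term = character(0), score = numeric(0)))
  feats <- featurize(space, topic, others)[, contexts, drop = FALSE]
  score <- rowMeans(feats)
  ord <- order(-score, others)
  sel <- utils::head(ord, k)
  data.frame(term = others[sel], score = unname(score[sel]),
             stringsAsFactors = FALSE)
}
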