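#' Serialize a context vector space to a JSON archive
#'
#' Writes a single JSON file containing the registry and, per context, the
#' dimension catalog and the nonzero proportions in coordinate-triplet form
#' (1-based indices into the vocabulary and catalog). Terms, dimensions and
#' triplets are in stable lexicographic/row-major order, so the archive is
#' bit-reproducible: serializing the same space twice yields identical
#' bytes.
#'
#' @param space a [ContextVectorSpace-class]
#' @param path output path
#' @return the path, invisibly
#' @seealso [loadContextSpace()]
#' @export
saveContextSpace <- function(space, path) {
  stopifnot(is(space, "ContextVectorSpace"))
  reg <- space@registry
  ctxs <- lapply(contextIds(space), function(ctx) {
    m <- as(contextMatrix(space, ctx), "TsparseMatrix")
    ord <- order(m@i, m@j)
    list(dimensions = colnames(m),
         i = m@i[ord] + 1L, j = m@j[ord] + 1L, x = m@x[ord])
  })
  names(ctxs) <- contextIds(space)
  obj <- list(
    format = "medcontext-space-1",
    registry = list(
      contexts = reg@contexts,
      event_window_hours = reg@eventWindowHours,
      key_sections = reg@keySections,
      age_bin_edges = reg@ageBinEdges
    ),
    vocabulary = vocabulary(space),
    contexts = ctxs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Load a context vector space from a JSON archive
#'
#' @param path path written by [saveContextSpace()]
#' @return a [ContextVectorSpace-class] equal to the one serialized
#' @export
loadContextSpace <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "medcontext-space-1"))
    stop("not a medcontext vector-space archive")
  reg <- new("ContextRegistry",
             contexts = as.data.frame(obj$registry$contexts,
                                      stringsAsFactors = FALSE),
             eventWindowHours = obj$registry$event_window_hours,
             keySections = as.character(obj$registry$key_sections),
             ageBinEdges = as.integer(obj$registry$age_bin_edges))
  vocab <- as.character(obj$vocabulary)
  vectors <- lapply(contextIds(reg), function(ctx) {
    c <- obj$contexts[[ctx]]
    dims <- as.character(unlist(c$dimensions))
    Matrix::sparseMatrix(i = as.integer(unlist(c$i)),
                         j = as.integer(unlist(c$j)),
                         x = as.numeric(unlist(c$x)),
                         dims = c(length(vocab), length(dims)),
                         dimnames = list(vocab, if (length(dims)) dims else character(0)))
  })
  names(vectors) <- contextIds(reg)
  new("ContextVectorSpace", vectors = vectors, registry = reg)
}
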