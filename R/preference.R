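#' Total highlight count per term over a document set
#'
#' Sums per-note highlight counts of each term across the given notes,
#' giving the aggregate highlight count H(w) that drives importance labels.
#' Highlights on notes outside \code{doc_ids} are ignored.
#'
#' @param highlights a highlight set (data.frame \code{note_id}, \code{term},
#'   \code{count}; see [readHighlights()])
#' @param doc_ids note ids defining the document set; default: all notes
#'   present in the highlight set
#' @return named numeric vector term -> total count
#' @export
aggregateHighlightCounts <- function(highlights,
                                     doc_ids = unique(highlights$note_id)) {
  sel <- highlights$note_id %in% doc_ids
  if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
  h <- tapply(highlights$count[sel], highlights$term[sel], sum)
  stats::setNames(as.numeric(h), names(h))
}

#' Label candidate terms by highlight count and importance cutoff
#'
#' A candidate is labeled important (1) when its aggregate highlight count
#' strictly exceeds the cutoff I; terms never highlighted count as 0.
#'
#' @param candidates character vector of candidate terms (non-empty)
#' @param H named numeric vector of aggregate highlight counts
#'   ([aggregateHighlightCounts()])
#' @param cutoff positive integer importance cutoff I
#' @return a [LabelSet-class]
#' @export
buildLabels <- function(candidates, H, cutoff = 1L) {
  if (length(candidates) == 0L) stop("empty candidate list")
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L) stop("cutoff must be a positive integer")
  h <- H[candidates]
  h[is.na(h)] <- 0
  labels <- stats::setNames(as.integer(h > cutoff), candidates)
  new("LabelSet", labels = labels, cutoff = cutoff,
      positives = sum(labels == 1L))
}

#' @rdname labelVector
#' @export
setMethod("labelVector", "LabelSet", function(x) x@labels)

#' @rdname importanceCutoff
#' @export
setMethod("importanceCutoff", "LabelSet", function(x) x@cutoff)

#' @rdname nPositives
#' @export
setMethod("nPositives", "LabelSet", function(x) x@positives)

setMethod("show", "LabelSet", function(object) {
  cat(sprintf("LabelSet: %d terms, cutoff I=%d, %d positive\n",
              length(object@labels), object@cutoff, object@positives))
})

.asLabelVector <- function(labels) {
  if (is(labels, "LabelSet")) return(labels@labels)
  if (is.null(names(labels))) stop("labels must be named by term")
  stats::setNames(as.integer(labels), names(labels))
}

.alignFeatures <- function(features, y) {
  miss <- setdiff(names(y), rownames(features))
  if (length(miss))
    stop(sprintf("labeled term(s) missing from feature matrix: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  features[names(y), , drop = FALSE]
}

# Maximum-likelihood binomial logistic fit with Wald statistics. Returns
# coefficients (aliased ones set to 0 for prediction) and one-tailed Wald
# p-values in the direction of each estimate's sign.
.logisticFit <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  beta <- fit$coefficients
  aliased <- is.na(beta)
  beta[aliased] <- 0
  w <- fit$weights
  V <- tryCatch({
    XtWX <- crossprod(Xd[, !aliased, drop = FALSE] * sqrt(w))
    chol2inv(chol(XtWX))
  }, error = function(e) NULL)
  se <- rep(NA_real_, length(beta))
  if (!is.null(V)) se[!aliased] <- sqrt(diag(V))
  z <- beta / se
  ptab <- data.frame(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    z = unname(z),
    p_one_tailed = unname(stats::pnorm(abs(z), lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
  list(beta = beta, coefTable = ptab)
}

#' Train a semantic-preference classifier
#'
#' Fits a classifier that predicts, from a candidate term's per-context
#' similarity vector (or baseline embedding vector), whether a reviewer
#' would deem the term important. Logistic regression exposes the fitted
#' per-context weights and Wald statistics for interpretation; random
#' forest (100 trees) and SVM (RBF kernel with probability calibration)
#' are opaque alternatives. Training is deterministic given \code{seed}.
#'
#' Similarity features are already bounded in [0, 1] and are used as-is by
#' default; for embedding feature spaces set \code{standardize = TRUE} to
#' center and scale each feature (recommended for SVM and logistic fits on
#' raw embeddings).
#'
#' @param features numeric matrix, rows named by term ([featurize()] or
#'   [embeddingFeatures()])
#' @param labels a [LabelSet-class] or named 0/1 vector; must contain both
#'   classes
#' @param model_kind \code{"logistic_regression"} (default),
#'   \code{"random_forest"} or \code{"svm"}
#' @param seed integer seed
#' @param standardize center/scale features before fitting (stored and
#'   re-applied at prediction time)
#' @return a [PreferenceModel-class]
#' @export
trainPreference <- function(features, labels,
                            model_kind = c("logistic_regression",
                                           "random_forest", "svm"),
                            seed = 1L, standardize = FALSE) {
  model_kind <- match.arg(model_kind)
  y <- .asLabelVector(labels)
  X <- .alignFeatures(features, y)
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; lower the importance cutoff to obtain positive and negative terms")
  ctr <- numeric(0); scl <- numeric(0)
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
    X <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  }
  set.seed(as.integer(seed))
  if (model_kind == "logistic_regression") {
    lf <- .logisticFit(X, y)
    beta <- lf$beta
    return(new("PreferenceModel", modelKind = model_kind,
               featureNames = colnames(features),
               fit = lf, contextWeights = beta[-1],
               intercept = unname(beta[1]), coefTable = lf$coefTable,
               seed = as.integer(seed), standardize = standardize,
               center = ctr, scale = scl))
  }
  yf <- factor(y, levels = c(0L, 1L))
  fit <- if (model_kind == "random_forest") {
    randomForest::randomForest(x = X, y = yf, ntree = 100L)
  } else {
    e1071::svm(x = X, y = yf, kernel = "radial", probability = TRUE)
  }
  new("PreferenceModel", modelKind = model_kind,
      featureNames = colnames(features), fit = fit,
      contextWeights = numeric(0), intercept = numeric(0),
      coefTable = data.frame(), seed = as.integer(seed),
      standardize = standardize, center = ctr, scale = scl)
}

#' @rdname contextWeights
#' @export
setMethod("contextWeights", "PreferenceModel", function(x) {
  if (x@modelKind != "logistic_regression")
    stop("context weights are only available for logistic_regression models")
  x@contextWeights
})

setMethod("show", "PreferenceModel", function(object) {
  cat(sprintf("PreferenceModel (%s), %d features, seed %d\n",
              object@modelKind, length(object@featureNames), object@seed))
  if (object@modelKind == "logistic_regression") {
    cat(sprintf("  intercept %.4g\n", object@intercept))
    print(round(object@contextWeights, 4))
  }
})

#' Score candidate terms with a fitted preference model
#'
#' Returns a probability-like preference score in [0, 1] per term. Feature
#' columns must match the model's training features exactly (names and
#' order).
#'
#' @param model a [PreferenceModel-class]
#' @param features numeric matrix, rows named by term
#' @return named numeric vector term -> score in [0, 1]
#' @export
predictScores <- function(model, features) {
  stopifnot(is(model, "PreferenceModel"))
  if (!identical(colnames(features), model@featureNames))
    stop("feature names do not match the model's training features")
  if (nrow(features) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  X <- features
  if (model@standardize)
    X <- sweep(sweep(X, 2, model@center, "-"), 2, model@scale, "/")
  scores <- switch(model@modelKind,
    logistic_regression = {
      beta <- model@fit$beta
      as.numeric(stats::plogis(cbind(1, X) %*% beta))
    },
    random_forest = {
      unname(stats::predict(model@fit, X, type = "prob")[, "1"])
    },
    svm = {
      p <- stats::predict(model@fit, X, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    })
  stats::setNames(scores, rownames(features))
}

#' Rank terms by preference score
#'
#' @param scores named numeric vector ([predictScores()])
#' @return data.frame with columns \code{term}, \code{score}, descending by
#'   score with lexicographic tie-break
#' @export
rankTerms <- function(scores) {
  if (length(scores) == 0L)
    return(data.frame(term = character(0), score = numeric(0)))
  ord <- order(-scores, names(scores))
  data.frame(term = names(scores)[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}

#' Interpretable context-weight table of a logistic preference model
#'
#' Mirrors the standard presentation of a binomial logistic fit on the ten
#' per-context similarities: one row per context (intercept first) with the
#' fitted coefficient and a one-tailed Wald p-value in the direction of the
#' coefficient's sign. A positive, significant coefficient means terms
#' similar to the topic in that context are preferred by the reviewer.
#'
#' @param model a [PreferenceModel-class] of kind logistic_regression
#' @return data.frame with columns \code{context}, \code{coefficient},
#'   \code{std_error}, \code{z}, \code{p_one_tailed}
#' @export
interpretModel <- function(model) {
  stopifnot(is(model, "PreferenceModel"))
  if (model@modelKind != "logistic_regression")
    stop(sprintf("interpretation is only supported for logistic_regression models (got %s)",
                 model@modelKind))
  tab <- model@coefTable
  data.frame(context = c("(Intercept)", model@featureNames),
             coefficient = tab$estimate,
             std_error = tab$std_error,
             z = tab$z,
             p_one_tailed = tab$p_one_tailed,
             stringsAsFactors = FALSE)
}

#' Serialize a preference model
#'
#' Logistic models are written as a portable JSON artifact (model kind,
#' seed, feature names, coefficients, standardization parameters and the
#' coefficient table); random-forest and SVM fits fall back to RDS.
#'
#' @param model a [PreferenceModel-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeModel <- function(model, path) {
  if (model@modelKind == "logistic_regression") {
    obj <- list(format = "medcontext-model-1",
                model_kind = model@modelKind,
                seed = model@seed,
                feature_names = model@featureNames,
                intercept = model@intercept,
                context_weights = as.list(model@contextWeights),
                standardize = model@standardize,
                center = model@center, scale = model@scale,
                coef_table = model@coefTable)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    saveRDS(model, path)
  }
  invisible(path)
}

#' Read a preference model written by [writeModel()]
#' @param path model artifact path
#' @return a [PreferenceModel-class]
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readChar(path, 1L, useBytes = TRUE)
  if (identical(first, "{")) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!identical(obj$format, "medcontext-model-1"))
      stop("not a medcontext model artifact")
    beta <- c(obj$intercept, unlist(obj$context_weights))
    names(beta) <- c("(Intercept)", obj$feature_names)
    new("PreferenceModel", modelKind = obj$model_kind,
        featureNames = as.character(obj$feature_names),
        fit = list(beta = beta, coefTable = as.data.frame(obj$coef_table)),
        contextWeights = beta[-1], intercept = unname(beta[1]),
        coefTable = as.data.frame(obj$coef_table),
        seed = as.integer(obj$seed),
        standardize = isTRUE(obj$standardize),
        center = as.numeric(unlist(obj$center)),
        scale = as.numeric(unlist(obj$scale)))
  } else {
    readRDS(path)
  }
}
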