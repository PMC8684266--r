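#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties credited 1/2 — i.e. the Mann-Whitney U
#' statistic divided by n_pos * n_neg, computed from midranks.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels (both classes required)
#' @return AUROC in [0, 1]
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0L, 1L)))
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUROC requires both positive and negative labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Sweep the importance cutoff
#'
#' Builds label sets for cutoffs I = 1, 2, ... and keeps each while it has
#' at least \code{min_positives} important terms; the sweep stops at the
#' first cutoff falling below that floor (which is excluded). The floor of
#' 10 positives guarantees each fold of a stratified ten-fold
#' cross-validation holds at least one positive label.
#'
#' @param candidates character vector of candidate terms
#' @param H named aggregate highlight counts ([aggregateHighlightCounts()])
#' @param min_positives minimum positives to keep a cutoff (default 10)
#' @return list of [LabelSet-class] objects, one per retained cutoff
#'   (possibly empty)
#' @export
cutoffSweep <- function(candidates, H, min_positives = 10L) {
  out <- list()
  I <- 1L
  repeat {
    ls <- buildLabels(candidates, H, I)
    if (nPositives(ls) < min_positives) break
    out[[length(out) + 1L]] <- ls
    I <- I + 1L
  }
  out
}

# Stratified fold assignment: within each class, members are shuffled and
# dealt round-robin into nfold folds.
.stratifiedFolds <- function(y, nfold) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(nfold), length(idx))
  }
  fold
}

#' Ten-fold cross-validated AUROC of a feature space
#'
#' Stratified, seeded ten-fold cross-validation: each fold's model is
#' trained on the other nine folds and scored by AUROC on the held-out
#' fold. Requires at least 10 positive labels so every test fold holds at
#' least one positive.
#'
#' @param features numeric matrix, rows named by term
#' @param labels a [LabelSet-class] or named 0/1 vector
#' @param model_kind classifier passed to [trainPreference()]
#' @param seed integer seed controlling the fold split (and any stochastic
#'   classifier)
#' @param standardize passed to [trainPreference()]
#' @param feature_space_name label carried into the result
#' @return list of class \code{"CVResult"}: \code{cutoff},
#'   \code{model_kind}, \code{feature_space_name}, \code{fold_aurocs}
#'   (length 10), \code{mean_auroc}
#' @export
crossValidate <- function(features, labels,
                          model_kind = "logistic_regression", seed = 1L,
                          standardize = FALSE,
                          feature_space_name = "features") {
  y <- .asLabelVector(labels)
  X <- .alignFeatures(features, y)
  npos <- sum(y == 1L)
  if (npos < 10L)
    stop(sprintf("cross-validation requires at least 10 positive labels (got %d)", npos))
  if (sum(y == 0L) < 10L)
    stop("cross-validation requires at least 10 negative labels")
  nfold <- 10L
  set.seed(as.integer(seed))
  fold <- .stratifiedFolds(y, nfold)
  aucs <- vapply(seq_len(nfold), function(k) {
    tr <- fold != k
    m <- trainPreference(X[tr, , drop = FALSE], y[tr],
                         model_kind = model_kind,
                         seed = as.integer(seed) + k,
                         standardize = standardize)
    s <- predictScores(m, X[!tr, , drop = FALSE])
    auroc(s, y[!tr])
  }, numeric(1))
  structure(list(cutoff = if (is(labels, "LabelSet")) labels@cutoff else NA_integer_,
                 model_kind = model_kind,
                 feature_space_name = feature_space_name,
                 fold_aurocs = aucs,
                 mean_auroc = mean(aucs)),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult [%s | %s | I=%s]: mean AUROC %.3f over %d folds\n",
              x$feature_space_name, x$model_kind,
              ifelse(is.na(x$cutoff), "?", x$cutoff),
              x$mean_auroc, length(x$fold_aurocs)))
  invisible(x)
}

#' Compare two feature spaces by their fold AUROCs
#'
#' One-sided Mann-Whitney U test on the two sets of cross-validation fold
#' AUROCs, alternative: feature space A outperforms feature space B. The
#' exact distribution is used when both sides have at most 10 folds and no
#' ties; otherwise the tie-corrected normal approximation (the standard
#' \code{\link[stats]{wilcox.test}} behavior).
#'
#' @param cv_a,cv_b \code{"CVResult"} objects with matching cutoff and
#'   model kind
#' @return list of class \code{"ComparisonResult"}: \code{cutoff},
#'   \code{model_kind}, \code{auroc_a}, \code{auroc_b}, \code{p_value}
#' @export
compareFeatureSpaces <- function(cv_a, cv_b) {
  stopifnot(inherits(cv_a, "CVResult"), inherits(cv_b, "CVResult"))
  if (!identical(cv_a$cutoff, cv_b$cutoff))
    stop("cannot compare CV results with different cutoffs")
  if (!identical(cv_a$model_kind, cv_b$model_kind))
    stop("cannot compare CV results with different model kinds")
  wt <- suppressWarnings(
    stats::wilcox.test(cv_a$fold_aurocs, cv_b$fold_aurocs,
                       alternative = "greater"))
  structure(list(cutoff = cv_a$cutoff, model_kind = cv_a$model_kind,
                 feature_space_a = cv_a$feature_space_name,
                 feature_space_b = cv_b$feature_space_name,
                 auroc_a = cv_a$mean_auroc, auroc_b = cv_b$mean_auroc,
                 p_value = wt$p.value),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s (%.3f) vs %s (%.3f), %s, I=%s: one-sided Mann-Whitney p = %.4g\n",
              x$feature_space_a, x$auroc_a, x$feature_space_b, x$auroc_b,
              x$model_kind, ifelse(is.na(x$cutoff), "?", x$cutoff),
              x$p_value))
  invisible(x)
}

#' Learning-curve analysis of a feature space
#'
#' For each training fraction x on the grid, repeatedly (\code{reps} times)
#' draws a stratified training set of size \code{max(2, round(x * n))}
#' (at least one instance of each class, enforced by redraw), trains the
#' classifier on it, and measures AUROC on the complement. All repetition
#' AUROCs are retained; the run is reproducible given \code{seed}.
#'
#' @param features numeric matrix, rows named by term
#' @param labels a [LabelSet-class] or named 0/1 vector with both classes
#' @param model_kind classifier passed to [trainPreference()]
#' @param reps repetitions per fraction (default 100)
#' @param fractions training fractions; default 1\% to 90\% in steps of 1\%
#' @param seed integer seed
#' @param standardize passed to [trainPreference()]
#' @param feature_space_name label carried into the result
#' @return list of class \code{"LearningCurveResult"}: \code{aurocs}
#'   (reps x fractions matrix), \code{fractions}, \code{reps},
#'   \code{mean_auroc} (per fraction), \code{redraws} (count of degenerate
#'   draws that were redrawn), \code{feature_space_name}, \code{cutoff}
#' @export
learningCurve <- function(features, labels,
                          model_kind = "logistic_regression",
                          reps = 100L, fractions = seq(0.01, 0.90, by = 0.01),
                          seed = 1L, standardize = FALSE,
                          feature_space_name = "features") {
  y <- .asLabelVector(labels)
  X <- .alignFeatures(features, y)
  n <- length(y)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (max(2L, round(min(fractions) * n)) >= n)
    stop("dataset too small for the smallest training fraction")
  pos <- which(y == 1L); neg <- which(y == 0L)
  set.seed(as.integer(seed))
  redraws <- 0L
  aucs <- matrix(NA_real_, nrow = reps, ncol = length(fractions),
                 dimnames = list(NULL, sprintf("%g", fractions)))
  for (fi in seq_along(fractions)) {
    x <- fractions[fi]
    size <- max(2L, as.integer(round(x * n)))
    npos_tr <- min(max(1L, as.integer(round(size * length(pos) / n))),
                   length(pos) - 1L)
    nneg_tr <- min(max(1L, size - npos_tr), length(neg) - 1L)
    for (r in seq_len(reps)) {
      repeat {
        tr <- c(sample(pos, npos_tr), sample(neg, nneg_tr))
        te <- setdiff(seq_len(n), tr)
        if (length(unique(y[te])) == 2L) break
        redraws <- redraws + 1L
      }
      m <- trainPreference(X[tr, , drop = FALSE], y[tr],
                           model_kind = model_kind,
                           seed = as.integer(seed) + r,
                           standardize = standardize)
      s <- predictScores(m, X[te, , drop = FALSE])
      aucs[r, fi] <- auroc(s, y[te])
    }
  }
  structure(list(aurocs = aucs, fractions = fractions, reps = reps,
                 mean_auroc = colMeans(aucs), redraws = redraws,
                 model_kind = model_kind,
                 feature_space_name = feature_space_name,
                 cutoff = if (is(labels, "LabelSet")) labels@cutoff else NA_integer_),
            class = "LearningCurveResult")
}

#' @export
print.LearningCurveResult <- function(x, ...) {
  cat(sprintf("LearningCurveResult [%s | %s]: %d fractions x %d reps\n",
              x$feature_space_name, x$model_kind,
              length(x$fractions), x$reps))
  show <- round(seq(1, length(x$fractions), length.out = min(6, length(x$fractions))))
  print(round(x$mean_auroc[show], 3))
  invisible(x)
}

#' Long-format table of a learning-curve result
#' @param lc a \code{"LearningCurveResult"}
#' @return data.frame with columns \code{fraction}, \code{rep}, \code{auroc}
#' @export
learningCurveTable <- function(lc) {
  stopifnot(inherits(lc, "LearningCurveResult"))
  data.frame(fraction = rep(lc$fractions, each = lc$reps),
             rep = rep(seq_len(lc$reps), times = length(lc$fractions)),
             auroc = as.numeric(lc$aurocs))
}
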