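#' Train the extremely randomized tree interaction predictor
#'
#' Fits a probability forest of extremely randomized trees (random
#' split points, no bootstrap resampling, sqrt(d) candidate features per
#' split, fully grown trees) on labelled pair feature vectors. With the
#' seed fixed, training is deterministic.
#'
#' @param x numeric feature matrix, one row per residue pair.
#' @param y labels: factor or character with values `positive` /
#'   `negative`.
#' @param nTrees number of trees (default 1000).
#' @param seed integer seed for tree growing.
#' @param numThreads threads for \pkg{ranger} (default 1 for
#'   reproducibility).
#' @return An [RriPredictor-class] object.
#' @seealso [scorePairs()], [leaveOneComplexOut()]
#' @export
trainPredictor <- function(x, y, nTrees = 1000, seed = 1,
                           numThreads = 1) {
  y <- factor(as.character(y), levels = c("positive", "negative"))
  if (any(is.na(y)))
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  stopifnot(nrow(x) == length(y))
  df <- as.data.frame(x)
  df$.label <- y
  forest <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = nTrees, probability = TRUE,
    splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1, min.node.size = 1,
    seed = seed, num.threads = numThreads, verbose = FALSE)
  new("RriPredictor", forest = forest, featureDim = ncol(x),
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' Score residue-pair feature vectors
#'
#' Returns the ensemble's probability of the positive (contact) class
#' for each feature vector, in input order. Scoring a batch or the same
#' vectors one by one gives identical values.
#'
#' @param predictor an [RriPredictor-class].
#' @param x feature matrix (or single feature vector) with the
#'   dimensionality the predictor was trained on.
#' @param numThreads threads for prediction.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
scorePairs <- function(predictor, x, numThreads = 1) {
  stopifnot(is(predictor, "RriPredictor"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != predictor@featureDim)
    stop("feature dimension ", ncol(x), " does not match the ",
         predictor@featureDim, " the predictor was trained on",
         call. = FALSE)
  pr <- predict(predictor@forest, data = as.data.frame(x),
                num.threads = numThreads, verbose = FALSE)$predictions
  as.numeric(pr[, "positive"])
}

#' Select the top-n scored pairs as positive predictions
#'
#' Exactly `n` pairs are predicted positive: the highest-scoring ones,
#' ties broken by stable input order. All remaining pairs are forced
#' negative — the working practice of inspecting only a handful of top
#' predictions.
#'
#' @param scores numeric score vector.
#' @param n number of positives to keep.
#' @return Logical vector, `TRUE` for predicted positives.
#' @examples
#' rankTopN(c(.9, .8, .1), 2)
#' @export
rankTopN <- function(scores, n) {
  if (n > length(scores))
    stop("n exceeds the number of scored pairs", call. = FALSE)
  keep <- head(order(scores, decreasing = TRUE), n)
  out <- logical(length(scores))
  out[keep] <- TRUE
  out
}

#' Confusion-matrix summary metrics
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), specificity TN/(TN+FP) and
#' F1 = 2PR/(P+R). A zero denominator yields 0 by convention (reported
#' with a message), which keeps the metrics defined when a method makes
#' no true-positive call.
#'
#' @param TP,FP,TN,FN non-negative integer counts, not all zero.
#' @return List with `precision`, `recall`, `specificity`, `f1`.
#' @examples
#' confusionMetrics(4, 1, 8104, 17)
#' @export
confusionMetrics <- function(TP, FP, TN, FN) {
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) stop("all counts are zero", call. = FALSE)
  safe <- function(num, den, what) {
    if (den == 0) {
      message(what, ": zero denominator, reported as 0")
      return(0)
    }
    num / den
  }
  precision <- safe(TP, TP + FP, "precision")
  recall <- safe(TP, TP + FN, "recall")
  specificity <- safe(TN, TN + FP, "specificity")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall,
       specificity = specificity, f1 = f1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie correction: the AUC equals
#' the probability that a randomly chosen positive outranks a randomly
#' chosen negative (ties counting one half). A random scorer has
#' expectation 0.5.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels `positive` / `negative` factor, character or logical
#'   (TRUE = positive).
#' @return AUC in \[0, 1\].
#' @examples
#' rocAUC(c(.9, .7, .3, .1), c("positive", "positive", "negative", "negative"))
#' @export
rocAUC <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else as.character(labels) == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-complex-out cross-validated evaluation
#'
#' For each complex in turn, every other complex supplies the training
#' material: the contact frequency matrix, residual space and
#' principal-component knowledge are rebuilt from the training
#' complexes' positive pairs only (so no statistic of the held-out
#' complex leaks into its own features), feature vectors are encoded for
#' the training pairs, the tree ensemble is fitted, and the held-out
#' complex's candidate pairs are scored and summarized as an AUC.
#'
#' @param complexes list of complexes, each a list with elements `seqA`,
#'   `seqB`, `pairs` (data.frame with columns `i`, `j`, `type_a`,
#'   `type_b`, `label`) and optionally `id`.
#' @param k neighbours per side for feature windows (default 3).
#' @param nComponents principal components (default 6).
#' @param nTrees trees in the ensemble (default 1000).
#' @param seed master seed; per-fold seeds are derived from it.
#' @param negativeRatio optional negatives-per-positive subsampling
#'   ratio applied per training complex (seeded); `NULL` keeps all
#'   negatives.
#' @param numThreads threads for \pkg{ranger}.
#' @return List of class `EvaluationReport`: `perComplex` (data.frame
#'   with `id`, `auc`, `nPos`, `nNeg`), `meanAUC`, `sdAUC`, `seAUC`.
#'   Complexes whose pairs are single-class are skipped with a warning.
#' @seealso [generateComplex()] for synthetic worlds to evaluate on.
#' @export
leaveOneComplexOut <- function(complexes, k = 3, nComponents = 6,
                               nTrees = 1000, seed = 1,
                               negativeRatio = NULL, numThreads = 1) {
  if (length(complexes) < 2L)
    stop("need at least 2 complexes", call. = FALSE)
  ids <- vapply(seq_along(complexes), function(f) {
    id <- complexes[[f]]$id
    if (is.null(id)) paste0("complex", f) else as.character(id)
  }, character(1))
  rows <- list()
  for (f in seq_along(complexes)) {
    test <- complexes[[f]]
    if (length(unique(test$pairs$label)) < 2L) {
      warning("complex ", ids[f], " has a single class; skipped",
              call. = FALSE)
      next
    }
    train <- complexes[-f]
    posTypes <- do.call(rbind, lapply(train, function(cx) {
      p <- cx$pairs[cx$pairs$label == "positive", c("type_a", "type_b")]
      p
    }))
    cfm <- buildContactCounts(posTypes)
    kn <- deepKnowledge(statisticalResiduals(cfm),
                        nComponents = nComponents)
    xs <- list(); ys <- list()
    for (t in seq_along(train)) {
      cx <- train[[t]]
      pr <- cx$pairs
      if (!is.null(negativeRatio)) {
        posI <- which(pr$label == "positive")
        negI <- which(pr$label == "negative")
        nKeep <- min(length(negI),
                     ceiling(negativeRatio * length(posI)))
        set.seed(seed * 1000L + f * 100L + t)
        pr <- pr[sort(c(posI, sample(negI, nKeep))), , drop = FALSE]
      }
      xs[[t]] <- featurizePairs(cx$seqA, cx$seqB, pr, kn, k = k)
      ys[[t]] <- as.character(pr$label)
    }
    model <- trainPredictor(do.call(rbind, xs), unlist(ys),
                            nTrees = nTrees, seed = seed + f,
                            numThreads = numThreads)
    xTest <- featurizePairs(test$seqA, test$seqB, test$pairs, kn, k = k)
    sc <- scorePairs(model, xTest, numThreads = numThreads)
    rows[[length(rows) + 1L]] <- data.frame(
      id = ids[f], auc = rocAUC(sc, test$pairs$label),
      nPos = sum(test$pairs$label == "positive"),
      nNeg = sum(test$pairs$label == "negative"),
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) == 0L)
    stop("no evaluable complexes", call. = FALSE)
  structure(list(perComplex = per, meanAUC = mean(per$auc),
                 sdAUC = sd(per$auc),
                 seAUC = sd(per$auc) / sqrt(nrow(per))),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("Leave-one-complex-out evaluation over", nrow(x$perComplex),
      "complexes\n")
  cat(sprintf(" mean AUC %.4f (sd %.4f, se %.4f)\n",
              x$meanAUC, x$sdAUC, x$seAUC))
  invisible(x)
}
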