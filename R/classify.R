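#' Shallow classifier specification
#'
#' The three classifier families used downstream of feature fusion, with
#' their conventional hyperparameters:
#' \itemize{
#'   \item \code{"lr"} — l2-penalized logistic regression with inverse
#'     regularization C = 1.0 (ridge logistic via glmnet with
#'     \code{lambda = 1/(n C)}, no internal standardization);
#'   \item \code{"svm"} — linear-kernel support vector machine with
#'     C = 0.025 (e1071, no internal scaling);
#'   \item \code{"rf"} — random forest of 100 trees with node count capped
#'     at 8 leaves per tree (the depth-3 regime).
#' }
#'
#' @param family "lr", "svm" or "rf".
#' @param ... overrides: \code{C} (lr, svm), \code{ntree}, \code{maxnodes}
#'   (rf).
#' @return list of class \code{"ClassifierSpec"}.
#' @export
classifierSpec <- function(family = c("lr", "svm", "rf"), ...) {
  family <- match.arg(family)
  hp <- switch(family,
    lr = list(C = 1.0),
    svm = list(C = 0.025),
    rf = list(ntree = 100L, maxnodes = 8L))
  over <- list(...)
  hp[names(over)] <- over
  structure(list(family = family, hyperparams = hp), class = "ClassifierSpec")
}

#' Compute the four evaluation metrics from a confusion matrix
#'
#' Positive class = healthy tissue. Two modes:
#' \itemize{
#'   \item \code{"standard"} (default): precision = tp/(tp+fp),
#'     recall = tp/(tp+fn);
#'   \item \code{"as_printed"}: precision = tp/(tp+fn),
#'     recall = tn/(tn+fp) — the literal nonstandard definitions used by
#'     some of the literature this package mirrors (precision over false
#'     negatives; recall as specificity), kept available for comparability.
#' }
#' In both modes accuracy = (tp+tn)/total and F1 is the harmonic mean of
#' the mode's own precision and recall. Metrics are percentages; a
#' zero-denominator metric is reported as 0 and flagged.
#'
#' @param cm a [ConfusionMatrix-class], or numeric c(tp, tn, fp, fn).
#' @param mode "standard" or "as_printed".
#' @return a [MetricsReport-class].
#' @examples
#' metricsFromConfusion(c(tp = 8, tn = 5, fp = 5, fn = 2), mode = "as_printed")
#' @export
metricsFromConfusion <- function(cm, mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  if (is(cm, "ConfusionMatrix")) {
    tp <- cm@tp; tn <- cm@tn; fp <- cm@fp; fn <- cm@fn
  } else {
    tp <- cm[["tp"]]; tn <- cm[["tn"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]
  }
  total <- tp + tn + fp + fn
  if (total <= 0) stop("confusion matrix is empty")
  flags <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); 0 } else num / den
  }
  accuracy <- (tp + tn) / total
  if (mode == "standard") {
    precision <- ratio(tp, tp + fp, "precision")
    recall <- ratio(tp, tp + fn, "recall")
  } else {
    precision <- ratio(tp, tp + fn, "precision")
    recall <- ratio(tn, tn + fp, "recall")
  }
  f1 <- if (precision + recall == 0) { flags <- c(flags, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  new("MetricsReport", accuracy = 100 * accuracy, precision = 100 * precision,
      recall = 100 * recall, f1 = 100 * f1, mode = mode, flags = flags)
}

# fit one classifier and predict labels on the test matrix
fitPredict <- function(spec, xTrain, yTrain, xTest, seed) {
  set.seed(seed)
  fam <- spec$family
  hp <- spec$hyperparams
  yF <- factor(yTrain)
  if (fam == "lr") {
    if (ncol(xTrain) == 1L) {  # glmnet needs >= 2 columns; pad an inert one
      xTrain <- cbind(xTrain, 0)
      xTest <- cbind(xTest, 0)
    }
    lam <- 1 / (nrow(xTrain) * hp$C)
    fit <- glmnet::glmnet(xTrain, yF, family = "binomial", alpha = 0,
                          lambda = lam, standardize = FALSE)
    pr <- stats::predict(fit, newx = xTest, type = "class")
    factor(as.character(pr), levels = levels(yF))
  } else if (fam == "svm") {
    fit <- e1071::svm(xTrain, yF, kernel = "linear", cost = hp$C,
                      scale = FALSE)
    stats::predict(fit, xTest)
  } else {
    fit <- randomForest::randomForest(xTrain, yF, ntree = hp$ntree,
                                      maxnodes = hp$maxnodes)
    stats::predict(fit, xTest)
  }
}

#' Train a classifier on fused features and evaluate on held-out rows
#'
#' Fits the specified classifier on the training block, predicts the test
#' block, tallies the confusion matrix under the positive = healthy
#' convention, and computes the four metrics. Deterministic given
#' \code{seed}.
#'
#' @param xTrain,xTest numeric feature matrices.
#' @param yTrain,yTest labels (two classes).
#' @param spec a \code{"ClassifierSpec"} (default logistic regression).
#' @param posClass the positive label (default: first factor level).
#' @param mode metric mode, see [metricsFromConfusion()].
#' @param seed integer seed for classifier randomness.
#' @return list with \code{confusion} ([ConfusionMatrix-class]) and
#'   \code{metrics} ([MetricsReport-class]).
#' @export
trainEval <- function(xTrain, yTrain, xTest, yTest, spec = classifierSpec("lr"),
                      posClass = NULL, mode = "standard", seed = 0L) {
  if (!is.matrix(xTrain)) xTrain <- as.matrix(xTrain)
  if (!is.matrix(xTest)) xTest <- as.matrix(xTest)
  if (nrow(xTest) == 0L) stop("test set is empty")
  badCols <- colnames(xTrain)[colSums(!is.finite(xTrain)) > 0]
  if (length(badCols))
    stop("non-finite feature values in columns: ",
         paste(utils::head(badCols, 5L), collapse = ", "))
  yF <- factor(yTrain)
  if (nlevels(yF) != 2L) stop("training labels must contain exactly two classes")
  if (is.null(posClass)) posClass <- levels(yF)[1]
  pred <- fitPredict(spec, xTrain, yTrain, xTest, seed)
  truthPos <- yTest == posClass
  predPos <- pred == posClass
  cm <- new("ConfusionMatrix",
            tp = sum(truthPos & predPos), tn = sum(!truthPos & !predPos),
            fp = sum(!truthPos & predPos), fn = sum(truthPos & !predPos))
  list(confusion = cm, metrics = metricsFromConfusion(cm, mode = mode))
}

#' Sweep a parameter grid of feature extractors and classifiers
#'
#' Evaluates every (setting, classifier) cell of a declared grid
#' \code{n} times with distinct derived seeds and reports mean metrics per
#' cell, flagging the best setting per classifier. Each grid entry is a
#' function mapping a tile to a feature vector; the split and classifier
#' seed are re-drawn per repeat. A failing cell is recorded and the sweep
#' continues.
#'
#' @param tiles named list of tiles.
#' @param labels labels aligned with \code{tiles}.
#' @param grid named list of feature-extractor functions
#'   (\code{function(tile) -> numeric vector}), one per parameter setting.
#' @param classifiers character subset of c("lr", "svm", "rf").
#' @param nRepeats repeats per cell (default 10).
#' @param trainFrac training fraction per repeat (default 0.7).
#' @param posClass positive label (default: first factor level).
#' @param mode metric mode.
#' @param seed master seed; repeat r of cell uses \code{seed + r}.
#' @return data.frame (setting, classifier, accuracy, precision, recall,
#'   f1, nRepeats, best, failed).
#' @export
runSweep <- function(tiles, labels, grid, classifiers = c("lr", "svm", "rf"),
                     nRepeats = 10L, trainFrac = 0.7, posClass = NULL,
                     mode = "standard", seed = 0L) {
  if (length(grid) == 0L) stop("grid must be non-empty")
  labels <- as.character(labels)
  if (is.null(posClass)) posClass <- levels(factor(labels))[1]
  rows <- list()
  for (gName in names(grid)) {
    feats <- try(do.call(rbind, lapply(tiles, grid[[gName]])), silent = TRUE)
    for (clf in classifiers) {
      if (inherits(feats, "try-error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          setting = gName, classifier = clf, accuracy = NA_real_,
          precision = NA_real_, recall = NA_real_, f1 = NA_real_,
          nRepeats = 0L, failed = TRUE)
        next
      }
      acc <- matrix(NA_real_, nRepeats, 4L)
      ok <- TRUE
      for (r in seq_len(nRepeats)) {
        s <- deriveSeed(seed, length(rows) * nRepeats + r)
        set.seed(s)
        tr <- stratifiedIndices(labels, trainFrac)
        res <- try(trainEval(feats[tr, , drop = FALSE], labels[tr],
                             feats[-tr, , drop = FALSE], labels[-tr],
                             spec = classifierSpec(clf), posClass = posClass,
                             mode = mode, seed = s), silent = TRUE)
        if (inherits(res, "try-error")) { ok <- FALSE; break }
        m <- res$metrics
        acc[r, ] <- c(m@accuracy, m@precision, m@recall, m@f1)
      }
      mu <- colMeans(acc)
      rows[[length(rows) + 1L]] <- data.frame(
        setting = gName, classifier = clf,
        accuracy = mu[1], precision = mu[2], recall = mu[3], f1 = mu[4],
        nRepeats = if (ok) nRepeats else 0L, failed = !ok)
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  for (clf in unique(out$classifier)) {
    sel <- which(out$classifier == clf & !out$failed)
    if (length(sel)) out$best[sel[which.max(out$accuracy[sel])]] <- TRUE
  }
  out
}

# per-class stratified sample of training indices
stratifiedIndices <- function(labels, trainFrac) {
  unlist(lapply(split(seq_along(labels), labels), function(ix) {
    sample(ix, round(trainFrac * length(ix)))
  }), use.names = FALSE)
}

# deterministic per-stage seed fan-out from a master seed (kept < 2^31)
deriveSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}
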