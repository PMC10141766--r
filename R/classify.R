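# Cross-validated KNN / SVM / random-forest harness over the CompEn
# feature set, with optional Laplacian-Eigenmap reduction fitted on
# training folds only.

#' Classification metrics for a prediction/truth pair
#'
#' Accuracy (percent correct), macro-averaged precision and recall over the
#' four classes (a class never predicted contributes precision 0 with a
#' warning), and the confusion matrix in fixed class order (left hand,
#' right hand, foot, tongue; rows = true class).
#'
#' @param predictions,truth vectors over the four-class alphabet, equal
#'   length.
#' @return list with `accuracy`, `macroPrecision`, `macroRecall` (percent)
#'   and `confusion` (4x4 matrix).
#' @export
evaluateClassification <- function(predictions, truth) {
  predictions <- as.character(predictions); truth <- as.character(truth)
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  if (!all(c(predictions, truth) %in% MI_CLASSES))
    stop("unknown class label; expected one of: ",
         paste(MI_CLASSES, collapse = ", "))
  p <- factor(predictions, levels = MI_CLASSES)
  t <- factor(truth, levels = MI_CLASSES)
  cm <- table(true = t, predicted = p)
  cm <- matrix(cm, 4, 4, dimnames = dimnames(cm))
  prec <- numeric(4); rec <- numeric(4)
  for (i in 1:4) {
    predTot <- sum(cm[, i]); trueTot <- sum(cm[i, ])
    if (predTot == 0) {
      warning("class '", MI_CLASSES[i], "' never predicted; precision set to 0")
      prec[i] <- 0
    } else prec[i] <- cm[i, i] / predTot
    rec[i] <- if (trueTot == 0) 0 else cm[i, i] / trueTot
  }
  list(accuracy = 100 * sum(diag(cm)) / length(t),
       macroPrecision = 100 * mean(prec),
       macroRecall = 100 * mean(rec),
       confusion = cm)
}

# stratified fold assignment: per class, shuffled indices dealt round-robin
stratifiedFolds <- function(labels, nFolds, seed = NULL) {
  withSeed(seed, {
    folds <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    folds
  })
}

trainAndPredict <- function(classifier, Xtr, ytr, Xte,
                            knnK = 5, svmCost = 10, svmSigma = 0.5,
                            rfTrees = 100, seed = NULL) {
  withSeed(seed, switch(classifier,
    knn = class::knn(Xtr, Xte, ytr, k = min(knnK, nrow(Xtr))),
    svm = {
      fit <- e1071::svm(Xtr, ytr, type = "C-classification",
                        kernel = "radial", cost = svmCost,
                        gamma = 1 / (2 * svmSigma^2), scale = FALSE)
      stats::predict(fit, Xte)
    },
    rf = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = rfTrees)
      stats::predict(fit, Xte)
    },
    stop("unknown classifier: ", classifier)
  ))
}

#' Stratified 10-fold cross-validation of the CompEn feature set
#'
#' For each fold, feature standardization statistics and (optionally) the
#' Laplacian Eigenmap are computed on the training trials only; test trials
#' are standardized with training statistics and embedded by Nystrom
#' extension, so no test-fold information reaches any fitted parameter.
#' Classifiers: KNN (Euclidean, k = 5), SVM (RBF kernel,
#' `k(x,y) = exp(-||x-y||^2 / (2 sigma^2))` with sigma = 0.5, C = 10), and
#' a seeded random forest (100 trees).
#'
#' @param ft a [FeatureTable-class].
#' @param classifiers subset of `c("knn", "svm", "rf")`.
#' @param nFolds number of stratified folds (default 10).
#' @param embed reduce with the Laplacian Eigenmap before classifying.
#' @param r embedding dimension (capped at feature count - 1).
#' @param nNeighbors,scheme graph parameters, see [buildNeighborGraph()].
#' @param knnK,svmCost,svmSigma,rfTrees classifier settings.
#' @param seed master seed; fans out per fold and classifier.
#' @return a [ClassificationReport-class].
#' @export
crossValidate <- function(ft, classifiers = c("knn", "svm", "rf"),
                          nFolds = 10, embed = TRUE, r = 10,
                          nNeighbors = 5, scheme = "binary",
                          knnK = 5, svmCost = 10, svmSigma = 0.5,
                          rfTrees = 100, seed = 1) {
  stopifnot(is(ft, "FeatureTable"))
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  M <- ft@matrix
  y <- factor(ft@labels, levels = MI_CLASSES)
  folds <- stratifiedFolds(y, nFolds, seed = stageSeed(seed, "classify"))

  pred <- matrix(NA_character_, length(y), length(classifiers),
                 dimnames = list(NULL, classifiers))
  for (f in seq_len(nFolds)) {
    te <- folds == f
    Xtr <- standardizeFeatures(M[!te, , drop = FALSE])
    Xte <- standardizeFeatures(M[te, , drop = FALSE],
                               center = attr(Xtr, "center"),
                               scale = attr(Xtr, "scale"))
    if (embed) {
      # cap graph/embedding sizes for very small training folds
      rUse <- min(r, ncol(M) - 1, sum(!te) - 2)
      kUse <- min(nNeighbors, sum(!te) - 1)
      g <- buildNeighborGraph(Xtr, nNeighbors = kUse, scheme = scheme)
      emb <- suppressWarnings(laplacianEmbed(g, r = rUse))
      Ztr <- emb@coordinates
      Zte <- nystromExtend(g, emb, Xte)
    } else {
      Ztr <- Xtr; Zte <- Xte
    }
    for (cl in classifiers) {
      pred[te, cl] <- as.character(
        trainAndPredict(cl, Ztr, y[!te], Zte,
                        knnK = knnK, svmCost = svmCost, svmSigma = svmSigma,
                        rfTrees = rfTrees,
                        seed = stageSeed(seed, "classify") + f))
    }
  }

  metrics <- list(); confusion <- list()
  for (cl in classifiers) {
    ev <- suppressWarnings(evaluateClassification(pred[, cl], as.character(y)))
    metrics[[cl]] <- data.frame(classifier = cl, accuracy = ev$accuracy,
                                macroPrecision = ev$macroPrecision,
                                macroRecall = ev$macroRecall)
    confusion[[cl]] <- ev$confusion
  }
  new("ClassificationReport",
      metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
      confusion = confusion, folds = as.integer(folds),
      seed = as.integer(seed))
}
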