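## KNN / linear SVM classification of selected features under repeated
## stratified k-fold cross-validation; Acc/Sen/Spe and rank-based AUC.
## Positive class = "cad" throughout.

#' Accuracy, sensitivity and specificity from label vectors
#'
#' Sen = TP/(TP+FN), Spe = TN/(TN+FP), Acc = (TP+TN)/total, reported as
#' percentages with the disease class (`positive`) as positive. A metric
#' whose denominator class is absent from `yTrue` is returned as `NA`.
#'
#' @param yTrue,yPred equal-length binary label vectors (factor or character).
#' @param positive positive-class label (default "cad").
#' @return named numeric vector `c(acc, sen, spe)` in percent, plus attribute
#'   `counts` with TP/FP/TN/FN.
#' @examples
#' confusionMetrics(rep(c("cad", "normal"), c(40, 40)),
#'                  rep(c("cad", "normal", "cad"), c(40, 38, 2)))
#' @export
confusionMetrics <- function(yTrue, yPred, positive = "cad") {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch", call. = FALSE)
  tp <- sum(yTrue == positive & yPred == positive)
  fn <- sum(yTrue == positive & yPred != positive)
  tn <- sum(yTrue != positive & yPred != positive)
  fp <- sum(yTrue != positive & yPred == positive)
  sen <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  spe <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  out <- c(acc = 100 * (tp + tn) / length(yTrue), sen = sen, spe = spe)
  attr(out, "counts") <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  out
}

## z-score test data with training-fold statistics only (leak-free)
standardizeBy <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

#' K-nearest-neighbour classification
#'
#' Euclidean-distance majority vote among the `k` nearest training samples.
#' Vote ties are broken deterministically by the class of the single nearest
#' neighbour.
#'
#' @param train numeric matrix of training features.
#' @param trainLabels factor of training labels.
#' @param test numeric matrix of test features (same columns).
#' @param k neighbour count (default 10); must not exceed nrow(train).
#' @return factor of predicted labels for the test rows.
#' @export
knnClassify <- function(train, trainLabels, test, k = 10) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  if (k > nrow(train)) stop("k exceeds training size", call. = FALSE)
  trainLabels <- factor(trainLabels)
  lv <- levels(trainLabels)
  pred <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    d2 <- colSums((t(train) - test[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(trainLabels[nn])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else as.character(trainLabels[nn[1]])
  }
  factor(pred, levels = lv)
}

#' Linear soft-margin SVM classification
#'
#' Linear-kernel SVM (regularisation `cost`, default 1), deterministic given
#' the data. Both classes must be present in the training labels.
#'
#' @inheritParams knnClassify
#' @param cost soft-margin regularisation constant (default 1).
#' @return factor of predicted labels for the test rows.
#' @export
svmClassify <- function(train, trainLabels, test, cost = 1) {
  trainLabels <- factor(trainLabels)
  if (nlevels(droplevels(trainLabels)) < 2)
    stop("training set must contain both classes", call. = FALSE)
  fit <- e1071::svm(as.matrix(train), trainLabels, kernel = "linear",
                    cost = cost, scale = FALSE)
  stats::predict(fit, as.matrix(test))
}

## stratified fold assignment: permute within class, deal out fold ids
stratifiedFolds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat a fresh stratified fold assignment is drawn from the
#' seeded RNG; per fold, the classifier is trained on the remaining folds
#' (features z-scored with training-fold statistics only, switchable) and
#' the confusion counts are pooled over the folds of that repeat. The report
#' gives mean +/- SD of accuracy, sensitivity and specificity across repeats.
#'
#' @param features numeric feature matrix/data.frame, columns ordered as
#'   selected (the first `nFeatures` columns are used).
#' @param labels two-level factor; positive class "cad" when present.
#' @param classifier "knn" or "svm".
#' @param nFeatures prefix length of feature columns to use
#'   (default all columns).
#' @param folds folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param k KNN neighbour count (default 10).
#' @param cost SVM regularisation (default 1).
#' @param standardize z-score features per fold (default TRUE).
#' @param seed RNG seed (default 1).
#' @return list of class `performanceReport`: `perRepeat` data.frame and
#'   `summary` (mean/sd of acc, sen, spe in percent).
#' @export
repeatedKFold <- function(features, labels, classifier = c("knn", "svm"),
                          nFeatures = NULL, folds = 10, repeats = 10,
                          k = 10, cost = 1, standardize = TRUE, seed = 1L) {
  classifier <- match.arg(classifier)
  features <- as.matrix(as.data.frame(features)[,
    seq_len(if (is.null(nFeatures)) ncol(as.data.frame(features)) else nFeatures),
    drop = FALSE])
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must be binary", call. = FALSE)
  if (min(table(labels)) < folds)
    stop("each class needs at least `folds` samples", call. = FALSE)
  positive <- if ("cad" %in% levels(labels)) "cad" else levels(labels)[2]
  set.seed(deriveSeed(seed, "cvfolds"))
  rows <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    fold <- stratifiedFolds(labels, folds)
    yPred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
    for (f in seq_len(folds)) {
      te <- fold == f
      tr <- !te
      trX <- features[tr, , drop = FALSE]; teX <- features[te, , drop = FALSE]
      if (standardize) {
        z <- standardizeBy(trX, teX); trX <- z$train; teX <- z$test
      }
      yPred[te] <- if (classifier == "knn")
        knnClassify(trX, labels[tr], teX, k = k)
      else
        svmClassify(trX, labels[tr], teX, cost = cost)
    }
    m <- confusionMetrics(labels, yPred, positive = positive)
    rows[[rep_i]] <- data.frame(repeatId = rep_i,
                                acc = m[["acc"]], sen = m[["sen"]], spe = m[["spe"]])
  }
  perRepeat <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("acc", "sen", "spe"),
    mean = vapply(perRepeat[c("acc", "sen", "spe")], mean, numeric(1)),
    sd = vapply(perRepeat[c("acc", "sen", "spe")], stats::sd, numeric(1)),
    row.names = NULL)
  structure(list(perRepeat = perRepeat, summary = summ,
                 classifier = classifier, nFeatures = ncol(features),
                 folds = folds, repeats = repeats, positive = positive),
            class = "performanceReport")
}

#' @export
print.performanceReport <- function(x, ...) {
  cat(sprintf("%s, %d features, %dx%d-fold CV (positive class '%s')\n",
              toupper(x$classifier), x$nFeatures, x$repeats, x$folds, x$positive))
  with(x$summary, cat(sprintf("  %s = %.2f +/- %.2f %%\n", metric, mean, sd),
                      sep = ""))
  invisible(x)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from the rank statistic; tied scores
#' receive half credit. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels; `positive` names the positive class.
#' @param positive positive-class label (default "cad").
#' @return AUC in \[0, 1\]; `NA` (flagged `undefined`) when a class is absent.
#' @export
aucScore <- function(scores, labels, positive = "cad") {
  labels <- as.character(labels)
  pos <- labels == positive
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  r <- rank(scores)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}
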