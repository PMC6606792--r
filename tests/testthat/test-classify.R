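blobs <- function(n = 40, gap = 10, sd = 0.1, seed = 1, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p, 0, sd), ncol = p),
             matrix(rnorm(n * p, gap, sd), ncol = p))
  list(x = x, y = factor(rep(c("normal", "cad"), each = n),
                         levels = c("normal", "cad")))
}

test_that("confusion metrics reproduce the canonical CAD geometry", {
  yTrue <- rep(c("cad", "normal"), c(40, 40))
  yPred <- c(rep("cad", 40), rep("normal", 38), rep("cad", 2))
  m <- confusionMetrics(yTrue, yPred)
  expect_equal(as.numeric(m), c(97.5, 100, 95))
  expect_equal(unname(attr(m, "counts")), c(40L, 2L, 38L, 0L))
  expect_equal(as.numeric(confusionMetrics(yTrue, yTrue)), c(100, 100, 100))
  allPos <- confusionMetrics(yTrue, rep("cad", 80))
  expect_equal(as.numeric(allPos), c(50, 100, 0))
  oneClass <- confusionMetrics(rep("cad", 5), rep("normal", 5))
  expect_true(is.na(oneClass["spe"]))
})

test_that("accuracy decomposes over class-conditional rates", {
  set.seed(3)
  for (i in 1:5) {
    yT <- sample(c("cad", "normal"), 60, replace = TRUE, prob = c(0.4, 0.6))
    yP <- sample(c("cad", "normal"), 60, replace = TRUE)
    m <- confusionMetrics(yT, yP)
    P <- sum(yT == "cad"); N <- sum(yT == "normal")
    expect_equal(unname(m["acc"]),
                 unname((m["sen"] * P + m["spe"] * N) / (P + N)))
  }
})

test_that("KNN votes with deterministic tie handling", {
  b <- blobs()
  expect_equal(as.character(knnClassify(b$x, b$y, b$x[1, , drop = FALSE], k = 1)),
               "normal")
  test <- rbind(c(0.05, -0.02), c(9.9, 10.1))
  expect_equal(as.character(knnClassify(b$x, b$y, test, k = 10)),
               c("normal", "cad"))
  # k = full training set on an imbalanced sample: constant majority vote
  idx <- c(1:24, 41:56)   # 24 normal, 16 cad
  pr <- knnClassify(b$x[idx, ], b$y[idx], test, k = 40)
  expect_equal(as.character(pr), c("normal", "normal"))
  expect_error(knnClassify(b$x, b$y, test, k = 100), "exceeds")
})

test_that("linear SVM separates blobs and validates inputs", {
  b <- blobs(seed = 2)
  test <- blobs(seed = 9)
  pr <- svmClassify(b$x, b$y, test$x)
  expect_equal(as.character(pr), as.character(test$y))
  # training-set predictions at least as good as the separability bound
  prTrain <- svmClassify(b$x, b$y, b$x)
  expect_equal(mean(prTrain == b$y), 1)
  expect_error(svmClassify(b$x[1:40, ], b$y[1:40], test$x), "both classes")
})

test_that("repeated stratified k-fold is deterministic and leak-free", {
  b <- blobs(n = 30, seed = 4)
  r1 <- repeatedKFold(b$x, b$y, "knn", folds = 5, repeats = 3, k = 10, seed = 7)
  r2 <- repeatedKFold(b$x, b$y, "knn", folds = 5, repeats = 3, k = 10, seed = 7)
  expect_identical(r1$perRepeat, r2$perRepeat)
  expect_equal(r1$summary$mean, c(100, 100, 100))
  expect_equal(r1$summary$sd, c(0, 0, 0))
  # every sample lands in exactly one test fold per repeat
  set.seed(1)
  fold <- rdisen:::stratifiedFolds(b$y, 5)
  expect_length(fold, 60)
  expect_true(all(table(fold, b$y) == 6))
})

test_that("shuffled labels drive CV accuracy to chance", {
  b <- blobs(n = 30, seed = 5)
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    yP <- sample(b$y)
    repeatedKFold(b$x, yP, "knn", folds = 10, repeats = 2, k = 10,
                  seed = s)$summary$mean[1]
  }, numeric(1))
  expect_true(all(accs >= 30 & accs <= 70))
  svmAcc <- vapply(1:5, function(s) {
    set.seed(s)
    yP <- sample(b$y)
    repeatedKFold(b$x, yP, "svm", folds = 10, repeats = 1,
                  seed = s)$summary$mean[1]
  }, numeric(1))
  expect_true(all(svmAcc >= 50 - 15 - 10 & svmAcc <= 50 + 15 + 10))
})

test_that("rank-based AUC matches hand counts and is monotone-invariant", {
  expect_equal(aucScore(c(1, 2, 3, 4), c("normal", "normal", "cad", "cad")), 1.0)
  expect_equal(aucScore(c(1, 2, 3, 4), c("normal", "cad", "normal", "cad")), 0.75)
  expect_equal(aucScore(rep(2, 10), rep(c("cad", "normal"), 5)), 0.5)
  set.seed(11)
  s <- rnorm(50); y <- rep(c("cad", "normal"), 25)
  a <- aucScore(s, y)
  expect_equal(aucScore(exp(3 * s) - 2, y), a, tolerance = 1e-12)
  expect_true(isUndefined(aucScore(s, rep("cad", 50))))
})
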