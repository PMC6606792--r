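smallGrid <- function() list(N = c(50, 100, 200), B = c(16, 64, 128),
                             r = c(0.2, 0.5), m = 2, q = 0.5)

test_that("a one-cell sweep equals the direct estimator call", {
  set.seed(2)
  x <- rnorm(100)
  g <- list(N = 100, B = 64, r = 0.2, m = 2, q = 0.5)
  sw <- sweepEntropy(list(g1 = list(x)), g, "rdisen")
  expect_equal(nrow(sw), 1)
  expect_equal(sw$mean, rdisEn(x, B = 64, m = 2, q = 0.5))
  swA <- sweepEntropy(list(g1 = list(x)), g, "apen")
  expect_equal(swA$mean, apEn(x, 2, 0.2))
})

test_that("constant signals give an all-zero RdisEn surface", {
  sigs <- list(rep(1, 200), rep(2, 200))
  sw <- suppressWarnings(sweepEntropy(list(flat = sigs), smallGrid(), "rdisen"))
  expect_true(all(sw$mean == 0))
})

test_that("logistic regimes separate across the sweep grid", {
  gA <- logisticMap(3.5, 200, 8, seed = 1)
  gB <- logisticMap(3.8, 200, 8, seed = 2)
  g <- list(N = c(50, 200), B = c(128, 512), r = 0.2, m = 2, q = 0.5)
  sw <- sweepEntropy(list(periodic = gA, chaotic = gB), g, "rdisen")
  for (N in c(50, 200)) for (B in c(128, 512)) {
    mp <- sw$mean[sw$group == "periodic" & sw$N == N & sw$axisValue == B]
    mc <- sw$mean[sw$group == "chaotic" & sw$N == N & sw$axisValue == B]
    expect_gt(abs(mc - mp), 0.05)
  }
})

test_that("undefined sample-entropy cells are masked, not averaged", {
  set.seed(4)
  sigs <- lapply(1:4, function(i) rnorm(60))
  g <- list(N = c(50, 60), B = 16, r = c(0.01, 1.0), m = 2, q = 0.5)
  sw <- sweepEntropy(list(g1 = sigs), g, "sampen")
  tiny <- sw[sw$axisValue == 0.01, ]
  expect_true(any(tiny$nDefined < 4))
  big <- sw[sw$axisValue == 1.0, ]
  expect_true(all(big$nDefined == 4))
  expect_true(all(is.finite(big$mean)))
})

test_that("stability statistic matches an independent two-pass computation", {
  set.seed(9)
  sigs <- lapply(1:3, function(i) 850 + as.numeric(arima.sim(list(ar = 0.7), 200, sd = 30)))
  sw <- sweepEntropy(list(g = sigs), smallGrid(), "rdisen")
  st <- stabilityTable(sw)
  # independent two-pass: reshape and take SDs by hand
  Ns <- sort(unique(sw$N)); Bs <- sort(unique(sw$axisValue))
  surf <- matrix(NA_real_, length(Ns), length(Bs))
  for (i in seq_along(Ns)) for (j in seq_along(Bs))
    surf[i, j] <- sw$mean[sw$N == Ns[i] & sw$axisValue == Bs[j]]
  twoPassSd <- function(v) {
    mu <- sum(v) / length(v)
    sqrt(sum((v - mu)^2) / (length(v) - 1))
  }
  expect_equal(st$sigmaN, mean(apply(surf, 2, twoPassSd)), tolerance = 1e-12)
  expect_equal(st$sigmaAxis, mean(apply(surf, 1, twoPassSd)), tolerance = 1e-12)
})

test_that("stability is zero only along the invariant axis by construction", {
  # hand-built surface varying only along the B axis
  sw <- expand.grid(N = c(50, 100, 200), axisValue = c(8, 64, 512))
  sw$group <- "g"; sw$m <- 2; sw$axis <- "B"
  sw$mean <- log2(sw$axisValue); sw$nDefined <- 1L
  st <- stabilityTable(sw)
  expect_equal(st$sigmaN, 0, tolerance = 1e-12)
  expect_equal(st$sigmaAxis, sd(log2(c(8, 64, 512))), tolerance = 1e-12)
})

test_that("group separation statistics behave under symmetry and identity", {
  set.seed(12)
  sigs <- lapply(1:5, function(i) rnorm(80))
  same <- groupSeparation(sigs, sigs, "rdisen", B = 32)
  expect_equal(same$p, 1)
  gA <- logisticMap(3.5, 1000, 10, seed = 1)
  gB <- logisticMap(3.8, 1000, 10, seed = 2)
  ab <- groupSeparation(gA, gB, "rdisen", B = 512, q = 0.5)
  ba <- groupSeparation(gB, gA, "rdisen", B = 512, q = 0.5)
  expect_lt(ab$p, 0.01)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$t, -ba$t)
})

test_that("Renyi-order optimisation scans the grid and is degenerate-safe", {
  tc <- makeTwoClassBeats(n = 500, recordsPerClass = 12, seed = 3,
                          beatsPerRecord = 1)
  beatsA <- lapply(tc$beats[tc$labels == "normal"], `[[`, "samples")
  beatsB <- lapply(tc$beats[tc$labels == "cad"], `[[`, "samples")
  opt <- optimizeQ(beatsA, beatsB, B = 128)
  expect_equal(nrow(opt$curve), 20)
  expect_equal(opt$curve$q, seq(0.1, 2, by = 0.1))
  expect_equal(opt$qStar, opt$curve$q[which.min(opt$curve$p)])
  flat <- optimizeQ(beatsA, beatsA, B = 128)
  expect_true(all(flat$curve$p == 1))
  expect_equal(flat$qStar, 0.1)   # ties break toward the smallest q
})

test_that("feature assessment flags copies and keeps orthogonal signal", {
  set.seed(15)
  n <- 60
  y <- factor(rep(c("normal", "cad"), each = n), levels = c("normal", "cad"))
  f1 <- c(rnorm(n, 0), rnorm(n, 1.5))
  f2 <- c(rnorm(n, 0), rnorm(n, -1.2))
  tab <- data.frame(f1 = f1, copy = f1, f2 = f2)
  a <- assessFeatures(tab, y)
  cp <- a$correlation[a$correlation$featureA == "f1" &
                        a$correlation$featureB == "copy", ]
  expect_equal(cp$r, 1, tolerance = 1e-12)
  expect_true(cp$redundant)
  expect_false("copy" %in% a$kept)
  expect_true(all(c("f1", "f2") %in% a$kept))
  expect_true(all(a$multivariate$p[a$multivariate$feature %in% c("f1", "f2")] < 0.05))
})

test_that("label-independent features pass the univariate null", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    y <- factor(rep(c("normal", "cad"), each = 30))
    f <- data.frame(noise = rnorm(60))
    a <- assessFeatures(f, y)
    a$univariate$p[1] > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
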