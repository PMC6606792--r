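test_that("embedding produces N - m templates in order", {
  tm <- embedTemplates(1:6, 2)
  expect_equal(dim(tm), c(4, 2))
  expect_equal(tm[1, ], c(1, 2))
  expect_equal(tm[4, ], c(4, 5))
  expect_equal(nrow(embedTemplates(rnorm(500), 5)), 495)
  expect_error(embedTemplates(7, 1), "too short")
  expect_error(embedTemplates(c(1, NA, 3, 4), 1), "non-finite")
})

test_that("Chebyshev distance matrix is exact on hand cases", {
  d <- chebyshevDistances(rbind(c(1, 2), c(3, 4)))
  expect_equal(d[1, 2], 2)
  expect_equal(d[2, 1], 2)
  expect_equal(diag(d), c(0, 0))
  # linear ramp: d(i, j) = |i - j|
  dm <- chebyshevDistances(embedTemplates(1:6, 2))
  expect_equal(dm, abs(outer(1:4, 1:4, "-")))
})

test_that("distance histogram bins, normalises and flags degeneracy", {
  dm <- chebyshevDistances(embedTemplates(1:6, 2))
  h <- distanceHistogram(dm, 2)
  expect_equal(h$p, c(0.5, 0.5))   # {1,1,1,2,2,3} x2: 2 falls in bin [2,3]
  expect_false(attr(h, "degenerate"))
  hz <- distanceHistogram(matrix(3, 4, 4) - diag(3, 4), 8)
  expect_true(attr(hz, "degenerate"))
  expect_equal(sum(hz$p == 1), 1)
  hb <- distanceHistogram(chebyshevDistances(embedTemplates(rnorm(500), 2)), 512)
  expect_length(hb$p, 512)
  expect_equal(sum(hb$p), 1, tolerance = 1e-12)
})

test_that("RdisEn matches the closed-form ramp value for several q", {
  for (q in c(0.4, 0.5, 2)) {
    expect_equal(rdisEn(1:6, B = 2, m = 2, q = q), 1.0, tolerance = 1e-12)
  }
  expect_warning(v <- rdisEn(rep(2, 30), B = 16, m = 2, q = 0.5), "degenerate")
  expect_equal(v, 0)
  expect_error(rdisEn(1:30, q = 0), "positive")
})

test_that("RdisEn equals the brute-force oracle on short random signals", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(15:60, 1)
    m <- sample(2:4, 1)
    B <- sample(c(4, 16, 64), 1)
    q <- sample(c(0.3, 0.5, 1, 1.7), 1)
    x <- rnorm(n)
    expect_equal(rdisEn(x, B = B, m = m, q = q), rdisenOracle(x, B, m, q),
                 tolerance = 1e-12)
  }
})

test_that("RdisEn degenerates to DisEn as q approaches 1", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(60:200, 1))
    d <- disEn(x, B = 64, m = 2)
    expect_lt(abs(rdisEn(x, B = 64, m = 2, q = 1 + 1e-6) - d), 1e-5)
    expect_lt(abs(rdisEn(x, B = 64, m = 2, q = 1 - 1e-6) - d), 1e-5)
  }
})

test_that("RdisEn is affine invariant and bounded in [0, 1]", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(80)
    v <- rdisEn(x, B = 32, m = 2, q = 0.4)
    expect_gte(v, 0); expect_lte(v, 1)
    for (a in c(-2, 0.5, 10)) for (b in c(-5, 3)) {
      expect_equal(rdisEn(a * x + b, B = 32, m = 2, q = 0.4), v,
                   tolerance = 1e-12)
    }
  }
})

test_that("RdisEn is non-increasing in the Renyi order q", {
  set.seed(21)
  qs <- c(0.2, 0.5, 1.5, 2)
  for (i in 1:10) {
    x <- rnorm(100)
    vals <- vapply(qs, function(q) rdisEn(x, B = 32, m = 2, q = q), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("DisEn hand values and limit consistency hold", {
  expect_equal(disEn(1:6, B = 2, m = 2), 1.0)          # p = (0.5, 0.5)
  expect_warning(expect_equal(disEn(rep(1, 30), B = 8, m = 2), 0))
  x <- rnorm(120)
  expect_lt(abs(rdisEn(x, B = 128, m = 2, q = 0.999999) - disEn(x, B = 128, m = 2)),
            1e-5)
})

test_that("amplitude Renyi entropy behaves at its extremes and limit", {
  # uniformly filling all bins: one sample per bin
  expect_equal(renEn(seq(0, 1, length.out = 64), q = 0.9, B = 64), 1.0,
               tolerance = 1e-12)
  expect_warning(expect_equal(renEn(rep(4, 50), q = 0.9, B = 16), 0))
  set.seed(5)
  x <- rnorm(500)
  sh <- -sum((p <- distanceHistogram(x, 32)$p)[p > 0] * log2(p[p > 0])) / log2(32)
  expect_lt(abs(renEn(x, q = 1 + 1e-7, B = 32) - sh), 1e-5)
})

test_that("ApEn matches its counting oracle and known patterns", {
  expect_equal(apEn(rep(3, 40), 2, 0.2), 0)
  alt <- rep(c(1, 2), 50)
  expect_lt(abs(apEn(alt, 2, 0.2)), 1e-3)   # deterministic alternation
  set.seed(31)
  for (i in 1:8) {
    x <- rnorm(sample(20:40, 1))
    expect_equal(apEn(x, 2, 0.5), apenOracle(x, 2, 0.5), tolerance = 1e-12)
  }
  # order sensitivity: a permutation generally changes the value
  x <- as.numeric(arima.sim(list(ar = 0.9), 100))
  set.seed(1)
  expect_false(isTRUE(all.equal(apEn(x, 2, 0.2), apEn(sample(x), 2, 0.2))))
})

test_that("SamEn matches its oracle, handles patterns and undefined state", {
  alt <- rep(c(1, 2), 50)
  expect_equal(sampEn(alt, 2, 0.5), 0)      # every m-match extends
  expect_equal(sampEn(rep(7, 30), 2, 0.2), 0)
  set.seed(17)
  for (i in 1:8) {
    x <- rnorm(sample(20:40, 1))
    o <- sampenOracle(x, 2, 0.5)
    v <- sampEn(x, 2, 0.5)
    if (is.na(o)) expect_true(isUndefined(v))
    else expect_equal(as.numeric(v), o, tolerance = 1e-12)
  }
  u <- sampEn(rnorm(10), 2, 0.01)
  expect_true(isUndefined(u))
  expect_true(is.na(u))
})
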