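rrBeat <- function(seed = 1, n = 500) {
  set.seed(seed)
  850 + as.numeric(arima.sim(list(ar = 0.7), n, sd = 30)) +
    25 * sin(2 * pi * seq_len(n) / 5)
}

test_that("three-level packet tree has 8 nodes of the expected lengths", {
  for (basis in c("haar", "db1", "db2", "db3", "db4", "db5",
                  "coif1", "coif2", "coif3")) {
    sb <- wpdDecompose(rrBeat(), basis)
    expect_length(sb, 8)
    expect_equal(unname(lengths(sb)), rep(63, 8))
  }
  expect_equal(names(wpdDecompose(rrBeat(), "haar")),
               c("AAA", "AAD", "ADA", "ADD", "DAA", "DAD", "DDA", "DDD"))
  expect_error(wpdDecompose(rrBeat(), "sym4"), "unknown wavelet")
})

test_that("packet tree conserves energy on RR-scale beats", {
  for (basis in c("haar", "db2", "db3", "db4", "db5", "coif1", "coif2", "coif3")) {
    for (seed in 1:3) {
      x <- rrBeat(seed)
      ratio <- sum(unlist(wpdDecompose(x, basis))^2) / sum(x^2)
      expect_gte(ratio, 0.99); expect_lte(ratio, 1.01)
    }
  }
})

test_that("constant beat has the Haar closed-form sub-band values", {
  cb <- wpdDecompose(rep(3, 500), "haar")
  expect_equal(cb$AAA, rep(3 * 2^1.5, 63), tolerance = 1e-9)
  expect_lt(max(abs(unlist(cb[2:8]))), 1e-9)
  st <- subbandStats(cb)
  expect_equal(unname(st["M1"]), 3 * 2^1.5, tolerance = 1e-9)
  expect_equal(unname(st["Mi1"]), unname(st["Ma1"]), tolerance = 1e-9)
  expect_lt(abs(st["Ma6"]), 1e-9)
})

test_that("sub-band statistics are the plain mean/min/max per node", {
  sb <- stats::setNames(rep(list(c(1, 2, 3)), 8),
                        c("AAA", "AAD", "ADA", "ADD", "DAA", "DAD", "DDA", "DDD"))
  st <- subbandStats(sb)
  expect_equal(unname(st[c("M1", "Mi1", "Ma1")]), c(2, 1, 3))
  sb[[3]] <- rep(0, 5)
  expect_equal(unname(subbandStats(sb)[c("M3", "Mi3", "Ma3")]), c(0, 0, 0))
  sb[[2]] <- numeric(0)
  expect_error(subbandStats(sb), "empty")
})

test_that("feature vectors are finite, ordered and label-blind deterministic", {
  x <- rrBeat(3)
  fv <- extractFeatures(x)
  expect_length(fv, 25)
  expect_named(fv, c("RdisEn", paste0("M", 1:8), paste0("Mi", 1:8),
                     paste0("Ma", 1:8)))
  expect_true(all(is.finite(fv)))
  for (k in 1:8) {
    expect_lte(fv[paste0("Mi", k)], fv[paste0("M", k)])
    expect_lte(fv[paste0("M", k)], fv[paste0("Ma", k)])
  }
  expect_identical(fv, extractFeatures(x))
})

test_that("group-mean RdisEn separates the two generated classes", {
  tc <- makeTwoClassBeats(n = 500, recordsPerClass = 20, seed = 2,
                          beatsPerRecord = 1)
  tab <- extractFeatureTable(tc$beats, tc$labels)
  ht <- t.test(RdisEn ~ label, data = tab)
  expect_lt(ht$p.value, 0.05)
  expect_gt(mean(tab$RdisEn[tab$label == "cad"]),
            mean(tab$RdisEn[tab$label == "normal"]))
})

test_that("t-test ranking orders by p with documented degeneracies", {
  set.seed(6)
  n <- 40
  tab <- data.frame(
    strong = c(rnorm(n, 0, 0.1), rnorm(n, 10, 0.1)),
    weak = rnorm(2 * n),
    same = rep(1.5, 2 * n)
  )
  labels <- factor(rep(c("a", "b"), each = n))
  rk <- ttestRank(tab, labels)
  expect_equal(rk$feature[1], "strong")
  expect_lt(rk$p[1], 1e-20)
  expect_equal(rk$feature[3], "same")
  expect_equal(rk$p[3], 1)
  expect_equal(rk$t[3], 0)
  expect_false(rk$significant[3])
  expect_setequal(rk$feature, names(tab))  # ranking is a permutation
})

test_that("selection always leads with RdisEn and respects kTop", {
  tc <- makeTwoClassBeats(n = 500, recordsPerClass = 12, seed = 5,
                          beatsPerRecord = 1)
  rk <- ttestRank(extractFeatureTable(tc$beats, tc$labels))
  sel <- selectFeatures(rk, 4)
  expect_length(sel, 5)
  expect_equal(sel[1], "RdisEn")
  expect_false(any(duplicated(sel)))
  expect_equal(selectFeatures(rk, 0), "RdisEn")
  expect_error(selectFeatures(rk, 25), "cannot exceed")
})
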