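## Parameter-sensitivity harness: entropy sweeps over (N, B-or-r, m) grids,
## the mean-of-SD stability statistic, group separation t-tests, Renyi-order
## optimisation, and logistic-regression feature assessment.

#' Default sweep grid
#'
#' The grid used in the sensitivity study: data lengths N, bin counts B (for
#' the distance-histogram entropies), tolerance fractions r (for ApEn/SamEn)
#' and embedding dimensions m; q fixed at 0.5 for RdisEn.
#'
#' @return list with elements `N`, `B`, `r`, `m`, `q`.
#' @export
defaultSweepGrid <- function() {
  list(N = c(50, 200, 350, 500, 650, 800, 1000),
       B = c(100, 250, 350, 500, 650, 1000, 1300, 2000),
       r = seq(0.1, 1.0, by = 0.1),
       m = c(2, 3, 4, 5),
       q = 0.5)
}

## entropy of one signal prefix at one grid cell; distance reuse across B
## happens one level up
.entropyAt <- function(x, estimator, m, B = NULL, r = NULL, q = 0.5) {
  switch(estimator,
         rdisen = suppressWarnings(rdisEn(x, B = B, m = m, q = q)),
         disen = suppressWarnings(disEn(x, B = B, m = m)),
         apen = apEn(x, m = m, rFrac = r),
         sampen = sampEn(x, m = m, rFrac = r),
         stop("unknown estimator ", estimator, call. = FALSE))
}

#' Entropy surface over a parameter grid, per group
#'
#' For every combination of embedding dimension m, data length N and second
#' axis (bin count B for `rdisen`/`disen`, tolerance fraction r for
#' `apen`/`sampen`), the estimator is applied to the leading N samples of
#' every signal and averaged within each group. Undefined sample-entropy
#' cells are masked (excluded from the group mean); a cell where every signal
#' is undefined stays `NA`.
#'
#' For the distance-histogram entropies the Chebyshev distances are computed
#' once per (signal, N, m) and re-binned for each B.
#'
#' @param groups named list of signal groups (each a list of numeric vectors,
#'   all at least max(grid$N) long).
#' @param grid sweep grid as from [defaultSweepGrid()].
#' @param estimator one of "rdisen", "disen", "apen", "sampen".
#' @return long-format data.frame (class `sweepResult`) with columns
#'   `group, m, N, axis, axisValue, mean, nDefined`.
#' @export
sweepEntropy <- function(groups, grid = defaultSweepGrid(),
                         estimator = c("rdisen", "disen", "apen", "sampen")) {
  estimator <- match.arg(estimator)
  distBased <- estimator %in% c("rdisen", "disen")
  axisName <- if (distBased) "B" else "r"
  axisVals <- if (distBased) grid$B else grid$r
  rows <- list()
  for (g in names(groups)) {
    sigs <- groups[[g]]
    for (m in grid$m) {
      for (N in grid$N) {
        vals <- matrix(NA_real_, nrow = length(sigs), ncol = length(axisVals))
        for (si in seq_along(sigs)) {
          x <- sigs[[si]][seq_len(N)]
          if (distBased) {
            d <- chebyshevDistances(embedTemplates(x, m))
            dv <- d[row(d) != col(d)]
            for (bi in seq_along(axisVals)) {
              h <- distanceHistogram(dv, axisVals[bi])
              vals[si, bi] <- if (estimator == "rdisen")
                renyiOfHistogram(h$p, grid$q, axisVals[bi])
              else renyiOfHistogram(h$p, 1, axisVals[bi])
            }
          } else {
            for (bi in seq_along(axisVals)) {
              v <- .entropyAt(x, estimator, m = m, r = axisVals[bi])
              vals[si, bi] <- if (isUndefined(v)) NA_real_ else v
            }
          }
        }
        for (bi in seq_along(axisVals)) {
          col <- vals[, bi]
          rows[[length(rows) + 1]] <- data.frame(
            group = g, m = m, N = N, axis = axisName,
            axisValue = axisVals[bi],
            mean = if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE),
            nDefined = sum(!is.na(col)))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweepResult", "data.frame")
  out
}

#' Mean-of-SD stability statistic of an entropy surface
#'
#' Per group and embedding dimension m: `sigmaN` is the mean over the second
#' axis (B or r) of the SD of the surface along N, and `sigmaAxis` the mean
#' over N of the SD along the second axis. Smaller values mean the estimator
#' is less sensitive to that parameter.
#'
#' @param sweep a `sweepResult` from [sweepEntropy()].
#' @return data.frame with columns `group, m, sigmaN, sigmaAxis`.
#' @export
stabilityTable <- function(sweep) {
  out <- list()
  for (g in unique(sweep$group)) {
    for (m in unique(sweep$m)) {
      sub <- sweep[sweep$group == g & sweep$m == m, ]
      surf <- stats::xtabs(mean ~ N + axisValue, data = sub) # N x axis matrix
      surf <- matrix(as.numeric(surf), nrow = length(unique(sub$N)))
      sdN <- apply(surf, 2, stats::sd, na.rm = TRUE)      # SD along N, per axis
      sdA <- apply(surf, 1, stats::sd, na.rm = TRUE)      # SD along axis, per N
      out[[length(out) + 1]] <- data.frame(
        group = g, m = m,
        sigmaN = mean(sdN, na.rm = TRUE), sigmaAxis = mean(sdA, na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}

#' Two-sample separation test on per-signal entropy values
#'
#' Applies the estimator to every signal of both groups and runs a
#' two-sample t-test on the resulting values (Welch by default; pooled
#' Student's t behind `welch = FALSE`). Degenerate variance yields p = 1.
#'
#' @param groupA,groupB lists of numeric signals.
#' @param estimator one of "rdisen", "disen", "apen", "sampen".
#' @param m,B,r,q estimator parameters (defaults m = 2, B = 512, r = 0.2,
#'   q = 0.5).
#' @param welch use Welch's t (default TRUE).
#' @return list with `t`, `p`, and the per-group value vectors.
#' @export
groupSeparation <- function(groupA, groupB, estimator = "rdisen",
                            m = 2, B = 512, r = 0.2, q = 0.5, welch = TRUE) {
  ev <- function(sigs) {
    v <- vapply(sigs, function(x) {
      e <- .entropyAt(x, estimator, m = m, B = B, r = r, q = q)
      if (isUndefined(e)) NA_real_ else as.numeric(e)
    }, numeric(1))
    v[!is.na(v)]
  }
  a <- ev(groupA); b <- ev(groupB)
  if (length(a) < 2 || length(b) < 2) stop(">= 2 defined values per group required", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    tt <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    return(list(t = tt, p = if (tt == 0) 1 else 0, valuesA = a, valuesB = b))
  }
  if (welch) {
    ht <- stats::t.test(a, b)
    list(t = unname(ht$statistic), p = ht$p.value, valuesA = a, valuesB = b)
  } else {
    st <- studentT(a, b)
    list(t = unname(st["t"]), p = unname(st["p"]), valuesA = a, valuesB = b)
  }
}

#' Renyi-order optimisation by group separation
#'
#' Computes RdisEn of every beat in both groups for each q on the grid
#' (distances and histogram computed once per beat), tests the groups with a
#' pooled Student's t-test per q, and returns the q minimising the p-value
#' (ties broken toward the smallest q).
#'
#' @param groupA,groupB lists of numeric beats.
#' @param B,m RdisEn parameters (defaults 512, 2).
#' @param qGrid Renyi orders to scan (default seq(0.1, 2, by = 0.1)).
#' @return list with `qStar` and data.frame `curve` (`q`, `t`, `p`).
#' @export
optimizeQ <- function(groupA, groupB, B = 512, m = 2,
                      qGrid = seq(0.1, 2, by = 0.1)) {
  histFor <- function(x)
    distanceHistogram(chebyshevDistances(embedTemplates(x, m)), B)$p
  hA <- lapply(groupA, histFor); hB <- lapply(groupB, histFor)
  curve <- t(vapply(qGrid, function(q) {
    a <- vapply(hA, renyiOfHistogram, numeric(1), q = q, B = B)
    b <- vapply(hB, renyiOfHistogram, numeric(1), q = q, B = B)
    studentT(a, b)
  }, numeric(2)))
  curve <- data.frame(q = qGrid, t = curve[, 1], p = curve[, 2])
  list(qStar = curve$q[which.min(curve$p)], curve = curve)
}

#' Logistic-regression assessment of selected features
#'
#' Three-step appraisal of a selected feature set against binary labels:
#' (1) univariate binary logistic regression per feature (Wald p-value);
#' (2) pairwise Pearson correlation tests, flagging a feature pair redundant
#' when p < 0.05 and |r| > 0.5; (3) multivariate logistic regression on the
#' non-redundant set (for each redundant pair the lower-ranked feature is
#' dropped). Perfect separation is caught: non-converged coefficients are
#' reported with `NA` p-values rather than spurious zeros.
#'
#' @param features data.frame of numeric feature columns (in rank order).
#' @param labels two-level factor.
#' @param positive positive-class label (default "cad").
#' @return list with `univariate` (feature, p), `correlation` (pair, r, p,
#'   redundant), `multivariate` (feature, coef, p, converged), `kept`.
#' @export
assessFeatures <- function(features, labels, positive = "cad") {
  features <- as.data.frame(features)
  if ("label" %in% names(features)) {
    labels <- features$label
    features <- features[setdiff(names(features), "label")]
  }
  labels <- factor(labels)
  y <- as.integer(as.character(labels) == positive)
  uni <- do.call(rbind, lapply(names(features), function(f) {
    fit <- suppressWarnings(stats::glm(y ~ features[[f]], family = stats::binomial()))
    conv <- fit$converged && max(abs(stats::coef(fit)), na.rm = TRUE) < 1e3
    p <- if (conv) summary(fit)$coefficients[2, 4] else NA_real_
    data.frame(feature = f, p = p, converged = conv)
  }))
  if (ncol(features) < 2) {
    corr <- data.frame(featureA = character(0), featureB = character(0),
                       r = numeric(0), p = numeric(0), redundant = logical(0))
  } else {
  prs <- utils::combn(names(features), 2)
  corr <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    ct <- stats::cor.test(features[[a]], features[[b]])
    data.frame(featureA = a, featureB = b,
               r = unname(ct$estimate), p = ct$p.value,
               redundant = ct$p.value < 0.05 & abs(ct$estimate) > 0.5)
  }))
  }
  drop <- unique(corr$featureB[corr$redundant])  # keep the higher-ranked of a pair
  kept <- setdiff(names(features), drop)
  dfm <- cbind(data.frame(y = y), features[kept])
  fitm <- suppressWarnings(stats::glm(y ~ ., data = dfm, family = stats::binomial()))
  convm <- fitm$converged && max(abs(stats::coef(fitm)), na.rm = TRUE) < 1e3
  sm <- summary(fitm)$coefficients
  multi <- data.frame(feature = kept,
                      coef = stats::coef(fitm)[-1],
                      p = if (convm) sm[-1, 4] else rep(NA_real_, length(kept)),
                      converged = convm, row.names = NULL)
  list(univariate = uni, correlation = corr, multivariate = multi, kept = kept)
}
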