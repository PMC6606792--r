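## Per-beat feature vector: RdisEn + 24 level-3 wavelet-packet sub-band
## statistics; pooled-variance Student's t ranking and top-k selection.

.FEATURE_NAMES <- c("RdisEn",
                    paste0("M", 1:8), paste0("Mi", 1:8), paste0("Ma", 1:8))

#' Sub-band statistics of a wavelet-packet decomposition
#'
#' For each of the 8 terminal nodes k = 1..8 (natural filter-bank order)
#' computes the arithmetic mean M(k), minimum Mi(k) and maximum Ma(k) of the
#' raw coefficients.
#'
#' @param subbands named list of 8 coefficient vectors from [wpdDecompose()].
#' @param absCoeffs take absolute values of coefficients before the
#'   statistics (default FALSE: raw coefficients).
#' @return named numeric vector `M1..M8, Mi1..Mi8, Ma1..Ma8`.
#' @export
subbandStats <- function(subbands, absCoeffs = FALSE) {
  if (length(subbands) != 8) stop("expected 8 terminal sub-bands", call. = FALSE)
  if (any(lengths(subbands) == 0)) stop("empty sub-band node", call. = FALSE)
  cf <- if (absCoeffs) lapply(subbands, abs) else subbands
  stats::setNames(
    c(vapply(cf, mean, numeric(1)),
      vapply(cf, min, numeric(1)),
      vapply(cf, max, numeric(1))),
    c(paste0("M", 1:8), paste0("Mi", 1:8), paste0("Ma", 1:8)))
}

#' 25-feature vector for one HRV beat
#'
#' Concatenates RdisEn of the beat (defaults B = 512, m = 2, q = 0.4) with
#' the 24 level-3 wavelet-packet sub-band statistics. Extraction never reads
#' the beat's class label.
#'
#' @param beat numeric vector of RR samples (a 500-sample beat in the CAD
#'   scheme) or a `beatSegment`.
#' @param B,m,q RdisEn parameters (defaults 512, 2, 0.4).
#' @param basis wavelet basis for the packet tree (default "db1").
#' @param absCoeffs passed to [subbandStats()].
#' @return named numeric vector of 25 finite features
#'   (`RdisEn, M1..M8, Mi1..Mi8, Ma1..Ma8`).
#' @export
extractFeatures <- function(beat, B = 512, m = 2, q = 0.4, basis = "db1",
                            absCoeffs = FALSE) {
  x <- if (inherits(beat, "beatSegment")) beat$samples else beat
  c(RdisEn = rdisEn(x, B = B, m = m, q = q),
    subbandStats(wpdDecompose(x, basis = basis), absCoeffs = absCoeffs))
}

#' Feature table for a set of beats
#'
#' @param beats list of beats (numeric vectors or `beatSegment`s).
#' @param labels optional factor of class labels (taken from the segments
#'   when absent).
#' @inheritParams extractFeatures
#' @return data.frame with 25 feature columns and a final `label` column.
#' @export
extractFeatureTable <- function(beats, labels = NULL, B = 512, m = 2, q = 0.4,
                                basis = "db1", absCoeffs = FALSE) {
  mat <- t(vapply(beats, extractFeatures, numeric(25),
                  B = B, m = m, q = q, basis = basis, absCoeffs = absCoeffs))
  df <- as.data.frame(mat)
  names(df) <- .FEATURE_NAMES
  if (is.null(labels)) {
    labels <- vapply(beats, function(b)
      if (inherits(b, "beatSegment") && !is.null(b$label)) as.character(b$label)
      else NA_character_, character(1))
  }
  df$label <- factor(labels)
  df
}

## Pooled-variance two-sample Student's t; returns c(t, p).
## Degenerate case (zero variance in both groups, equal means) -> t = 0, p = 1.
studentT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (!is.finite(se) || se == 0) {
    if (mean(a) == mean(b)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- (mean(a) - mean(b)) / se
  c(t = tt, p = 2 * stats::pt(-abs(tt), df = na + nb - 2))
}

#' Rank features by two-sample Student's t-test
#'
#' Pooled-variance Student's t per feature column (Welch's correction behind
#' `welch = TRUE`), ranked by ascending p-value. Ties in p are broken by
#' larger |t|, then by feature name. Features with p < `alpha` are flagged
#' significant.
#'
#' @param features data.frame or matrix of numeric feature columns (a final
#'   `label` column, if present, is used when `labels` is missing).
#' @param labels two-level factor of class labels.
#' @param alpha significance threshold (default 0.05).
#' @param welch use Welch's unequal-variance t instead (default FALSE).
#' @return data.frame (class `featureRanking`) with columns `feature`, `t`,
#'   `p`, `significant`, ordered by rank.
#' @export
ttestRank <- function(features, labels = NULL, alpha = 0.05, welch = FALSE) {
  if (is.null(labels) && "label" %in% colnames(features)) {
    labels <- features$label
    features <- features[, setdiff(colnames(features), "label"), drop = FALSE]
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels", call. = FALSE)
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples", call. = FALSE)
  g1 <- labels == levels(labels)[1]
  res <- t(vapply(colnames(features), function(f) {
    a <- features[[f]][g1]; b <- features[[f]][!g1]
    if (welch) {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) c(0, 1) else c(sign(mean(a) - mean(b)) * Inf, 0)
      } else {
        ht <- stats::t.test(a, b)
        c(unname(ht$statistic), ht$p.value)
      }
    } else studentT(a, b)
  }, numeric(2)))
  out <- data.frame(feature = colnames(features), t = res[, 1], p = res[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$p < alpha
  ord <- order(out$p, -abs(out$t), out$feature)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("featureRanking", "data.frame")
  out
}

#' Select RdisEn plus the top-ranked wavelet-packet statistics
#'
#' RdisEn is always included (first); the `kTop` lowest-p wavelet-packet
#' statistics follow in rank order, matching the protocol of feeding features
#' into the classifier one by one.
#'
#' @param ranking a `featureRanking` from [ttestRank()].
#' @param kTop number of wavelet-packet statistics to add (default 4;
#'   at most 24).
#' @return character vector of selected feature names, RdisEn first.
#' @export
selectFeatures <- function(ranking, kTop = 4) {
  if (kTop > 24) stop("kTop cannot exceed the 24 sub-band statistics", call. = FALSE)
  wpd <- ranking$feature[ranking$feature != "RdisEn"]
  c("RdisEn", utils::head(wpd, kTop))
}
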