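#' @keywords internal
"_PACKAGE"

## ---- validation helpers ----------------------------------------------------

checkSignal <- function(x, minLength = 1L) {
  if (!is.numeric(x)) stop("signal must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("signal contains non-finite samples", call. = FALSE)
  if (length(x) < minLength)
    stop(sprintf("signal too short: length %d, need at least %d",
                 length(x), minLength), call. = FALSE)
  invisible(x)
}

## ---- state-space embedding -------------------------------------------------

#' Embed a signal into m-dimensional template vectors
#'
#' Reconstructs the state space of a scalar time series as the matrix of
#' N - m overlapping templates of length `m`: row i is
#' (x(i), x(i+1), ..., x(i+m-1)).
#'
#' @param x numeric vector, the signal (all samples finite).
#' @param m embedding dimension, integer >= 1; requires length(x) >= m + 2.
#' @return numeric matrix with N - m rows and m columns.
#' @examples
#' embedTemplates(1:6, 2)
#' @export
embedTemplates <- function(x, m) {
  m <- as.integer(m)
  if (m < 1) stop("embedding dimension m must be >= 1", call. = FALSE)
  checkSignal(x, minLength = m + 2L)
  n <- length(x)
  idx <- seq_len(n - m)
  out <- matrix(0, nrow = n - m, ncol = m)
  for (k in seq_len(m)) out[, k] <- x[idx + k - 1L]
  out
}

#' Chebyshev distance matrix between embedded templates
#'
#' Entry (i, j) is the maximum absolute coordinate-wise difference between
#' templates i and j; the matrix is symmetric with a zero diagonal.
#'
#' @param templates numeric matrix of embedded vectors (rows = templates).
#' @return square numeric distance matrix.
#' @export
chebyshevDistances <- function(templates) {
  if (!is.matrix(templates)) templates <- matrix(templates, ncol = 1)
  d <- abs(outer(templates[, 1], templates[, 1], "-"))
  for (k in seq_len(ncol(templates))[-1]) {
    d <- pmax(d, abs(outer(templates[, k], templates[, k], "-")))
  }
  d
}

## ---- distance histogram ----------------------------------------------------

#' Empirical probability histogram of inter-template distances
#'
#' Pools the distances of a template distance matrix and bins them into `B`
#' equal-width bins spanning the observed \[min, max\] range. Bins are
#' left-closed/right-open, the last bin right-closed. The diagonal
#' (structural zeros from self-distances) is excluded by default.
#'
#' When all pooled distances coincide (e.g. a constant signal) the range is
#' degenerate; all mass is placed in one bin and the result is flagged with
#' attribute `degenerate = TRUE` instead of raising an error, so parameter
#' sweeps never abort.
#'
#' @param d square distance matrix (as from [chebyshevDistances()]) or a
#'   numeric vector of pooled distances.
#' @param B number of bins, integer >= 2.
#' @param includeDiagonal include the self-distance zeros on the diagonal
#'   (matrix input only). Default FALSE.
#' @return list with `p` (length-B probabilities summing to one), `breaks`
#'   (B + 1 bin edges) and attribute `degenerate`.
#' @export
distanceHistogram <- function(d, B, includeDiagonal = FALSE) {
  B <- as.integer(B)
  if (B < 2) stop("bin count B must be >= 2", call. = FALSE)
  if (is.matrix(d)) {
    if (nrow(d) < 2) stop("need at least 2 templates", call. = FALSE)
    v <- if (includeDiagonal) as.vector(d) else d[row(d) != col(d)]
  } else {
    v <- as.vector(d)
  }
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0) {
    p <- c(1, rep(0, B - 1))
    breaks <- seq(lo, lo + 1, length.out = B + 1)
    out <- list(p = p, breaks = breaks)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # left-closed/right-open with the top edge folded into the last bin
  bin <- pmin(floor((v - lo) / (hi - lo) * B) + 1L, B)
  p <- tabulate(bin, nbins = B) / length(v)
  out <- list(p = p, breaks = seq(lo, hi, length.out = B + 1))
  attr(out, "degenerate") <- FALSE
  out
}

## ---- Renyi / Shannon functionals on a histogram ----------------------------

renyiOfHistogram <- function(p, q, B = length(p)) {
  p <- p[p > 0]
  if (abs(q - 1) < 1e-8) {
    -sum(p * log2(p)) / log2(B)
  } else {
    log2(sum(p^q)) / ((1 - q) * log2(B))
  }
}

## ---- RdisEn / DisEn --------------------------------------------------------

#' Renyi distribution entropy (RdisEn)
#'
#' Order-q Renyi entropy of the empirical distribution of Chebyshev distances
#' between m-dimensional templates of the signal, normalised by log2(B) so the
#' value lies in \[0, 1\]:
#'
#'   RdisEn(B, m, q) = log2( sum_t p_t^q ) / ( (1 - q) * log2 B )
#'
#' where p_t are the B-bin histogram probabilities of the pooled inter-template
#' distances. For q within 1e-8 of 1 the Shannon limit is used, i.e. the value
#' degenerates to the distribution entropy [disEn()].
#'
#' The estimator is invariant under affine transforms a*x + b (a != 0) of the
#' signal, because Chebyshev distances scale by |a| and the equal-width bins
#' over \[min, max\] rescale identically.
#'
#' @param x numeric signal of length N >= m + 2.
#' @param B number of histogram bins (default 512).
#' @param m embedding dimension (default 2).
#' @param q Renyi order, q > 0 (default 0.4, the operating point used for
#'   CAD-vs-normal HRV discrimination).
#' @param includeDiagonal include structural zero self-distances in the
#'   histogram (default FALSE, the original distribution-entropy convention).
#' @return entropy value in \[0, 1\]. A constant signal yields 0 with a
#'   warning (degenerate single-bin histogram).
#' @examples
#' rdisEn(1:6, B = 2, m = 2, q = 0.5)   # exactly 1
#' @export
rdisEn <- function(x, B = 512, m = 2, q = 0.4, includeDiagonal = FALSE) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0)
    stop("Renyi order q must be a positive number", call. = FALSE)
  h <- distanceHistogram(chebyshevDistances(embedTemplates(x, m)), B,
                         includeDiagonal = includeDiagonal)
  if (isTRUE(attr(h, "degenerate")))
    warning("degenerate distance histogram (constant signal?); entropy is 0")
  renyiOfHistogram(h$p, q, B)
}

#' Distribution entropy (DisEn)
#'
#' Shannon entropy of the inter-template Chebyshev distance histogram,
#' normalised by log2(B); the q -> 1 limit of [rdisEn()].
#'
#' @inheritParams rdisEn
#' @return entropy value in \[0, 1\].
#' @export
disEn <- function(x, B = 512, m = 2, includeDiagonal = FALSE) {
  rdisEn(x, B = B, m = m, q = 1, includeDiagonal = includeDiagonal)
}

## ---- amplitude-histogram Renyi entropy -------------------------------------

#' Renyi entropy of the signal amplitude histogram (RenEn)
#'
#' Order-q Renyi entropy of the B-bin equal-width amplitude histogram of the
#' raw samples (bins spanning \[min, max\]), normalised by log2(B) so results
#' are comparable with [rdisEn()]/[disEn()]. This is the classical
#' (distance-free) Renyi entropy baseline.
#'
#' @param x numeric signal.
#' @param q Renyi order, q > 0 (q = 1 gives the normalised Shannon amplitude
#'   entropy).
#' @param B number of amplitude bins (default 512).
#' @return entropy value in \[0, 1\]; 0 with a warning for a constant signal.
#' @export
renEn <- function(x, q = 0.9, B = 512) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0)
    stop("Renyi order q must be a positive number", call. = FALSE)
  checkSignal(x, minLength = 2L)
  h <- distanceHistogram(as.vector(x), B)
  if (isTRUE(attr(h, "degenerate")))
    warning("degenerate amplitude histogram (constant signal?); entropy is 0")
  renyiOfHistogram(h$p, q, B)
}

## ---- approximate / sample entropy ------------------------------------------

#' Approximate entropy (ApEn)
#'
#' Pincus' approximate entropy with self-matches included:
#' ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r), where Phi_m is the mean natural log
#' of the fraction of templates within Chebyshev tolerance r of each template
#' (N - m + 1 templates of length m).
#'
#' @param x numeric signal of length N >= m + 2.
#' @param m embedding dimension (default 2).
#' @param rFrac tolerance as a fraction of the sample standard deviation of
#'   `x` (default 0.2); r = rFrac * sd(x) is recomputed per analysed window.
#' @return entropy value (0 for a constant signal).
#' @export
apEn <- function(x, m = 2, rFrac = 0.2) {
  m <- as.integer(m)
  if (rFrac <= 0) stop("rFrac must be > 0", call. = FALSE)
  checkSignal(x, minLength = m + 2L)
  r <- rFrac * stats::sd(x)
  phi <- function(mm) {
    n <- length(x)
    t <- matrix(0, n - mm + 1L, mm)
    for (k in seq_len(mm)) t[, k] <- x[seq_len(n - mm + 1L) + k - 1L]
    d <- chebyshevDistances(t)
    # self-matches included: diagonal distance 0 <= r always counts
    ci <- rowMeans(d <= r)
    mean(log(ci))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy (SamEn)
#'
#' Richman-Moorman sample entropy: -ln(A / B) where B counts template pairs
#' (i < j, self-matches excluded) whose length-m templates are within
#' Chebyshev tolerance r, and A counts those whose length-(m+1) extensions
#' also match. N - m templates are used at both lengths.
#'
#' When no pair matches at either length the statistic is undefined; this is
#' reported as `NA` with attribute `undefined = TRUE` rather than an error or
#' a silent number, so sweeps can mask invalid cells.
#'
#' @inheritParams apEn
#' @return entropy value, or `NA` flagged `undefined` when no matches exist.
#' @export
sampEn <- function(x, m = 2, rFrac = 0.2) {
  m <- as.integer(m)
  if (rFrac <= 0) stop("rFrac must be > 0", call. = FALSE)
  checkSignal(x, minLength = m + 2L)
  n <- length(x)
  s <- stats::sd(x)
  r <- rFrac * s
  if (s == 0) return(0)   # constant signal: every pair matches at all lengths
  nt <- n - m             # templates compared at both lengths m and m + 1
  tm <- matrix(0, nt, m + 1L)
  for (k in seq_len(m + 1L)) tm[, k] <- x[seq_len(nt) + k - 1L]
  dm <- chebyshevDistances(tm[, seq_len(m), drop = FALSE])
  dm1 <- pmax(dm, abs(outer(tm[, m + 1L], tm[, m + 1L], "-")))
  ut <- upper.tri(dm)
  bCount <- sum(dm[ut] <= r)
  aCount <- sum(dm1[ut] <= r)
  if (bCount == 0 || aCount == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  -log(aCount / bCount)
}

#' Test whether an entropy value is the undefined marker
#'
#' @param x a value returned by [sampEn()].
#' @return TRUE when the estimator was undefined (no template matches).
#' @export
isUndefined <- function(x) {
  isTRUE(attr(x, "undefined")) || (length(x) == 1 && is.na(x))
}
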