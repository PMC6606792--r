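## Orthogonal wavelet filter bank: DWT/IDWT steps with half-sample symmetric
## boundary extension, full wavelet-packet tree, and universal-threshold
## denoising. Filter coefficients are the standard published Daubechies and
## Coiflet tables.

.WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
          0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
          -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.7511339080210954, 0.49462389039845306, 0.11154074335010947),
  coif1 = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
            0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
  coif2 = c(-0.000720549445520347, -0.0018232088709110323, 0.005611434819368834,
            0.02368017194684777, -0.05943441864643109, -0.07648859907828076,
            0.4170051844232391, 0.8127236354494135, 0.3861100668227629,
            -0.0673725547237256, -0.04146493678687178, 0.01638733646320364),
  coif3 = c(-3.459977319727278e-05, -7.0983302506379e-05, 0.0004662169598204029,
            0.0011175187708306303, -0.0025745176881367972, -0.009007976136730624,
            0.015880544863669452, 0.03455502757329774, -0.08230192710629983,
            -0.07179982161915484, 0.42848347637737, 0.7937772226260872,
            0.40517690240911824, -0.06112339000297255, -0.06577191128146936,
            0.023452696142077168, 0.007782596425672746, -0.003793512864380802)
)

#' Decomposition filters of a named orthogonal wavelet
#'
#' @param name one of `haar`, `db1`..`db6`, `coif1`..`coif3` (`db1` is an
#'   alias for `haar`).
#' @return list with low-pass `lo` and high-pass `hi` decomposition filters.
#' @export
waveletFilter <- function(name) {
  key <- if (identical(name, "db1")) "haar" else name
  h <- .WAVELET_FILTERS[[key]]
  if (is.null(h)) stop(sprintf("unknown wavelet basis '%s'", name), call. = FALSE)
  # quadrature mirror: hi[k] = (-1)^(k+1) * lo[f-1-k]  (0-based k)
  list(lo = h, hi = rev(h) * rep_len(c(-1, 1), length(h)))
}

## One analysis step.
## "periodic": periodized DWT (odd lengths padded by repeating the last
##   sample); output length ceil(n / 2); the transform is orthogonal, so
##   Parseval holds up to the odd-length pad.
## "symmetric": half-sample symmetric extension by f-1 on each side, full
##   convolution; output length floor((n + f - 1) / 2) (slightly redundant
##   for f > 2).
dwtStep <- function(x, filt, boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  f <- length(filt$lo); n <- length(x)
  if (boundary == "periodic") {
    if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1L }
    L <- n %/% 2
    a <- numeric(L); d <- numeric(L)
    for (k in 0:(L - 1)) {
      idx <- ((2 * k + 0:(f - 1)) %% n) + 1L
      seg <- x[idx]
      a[k + 1] <- sum(filt$lo * seg)
      d[k + 1] <- sum(filt$hi * seg)
    }
    return(list(a = a, d = d))
  }
  if (n < f) { x <- c(x, rev(x))[seq_len(f)]; n <- length(x) }  # tiny inputs
  xe <- c(x[(f - 1):1], x, x[n:(n - f + 2)])
  L <- (n + f - 1) %/% 2
  a <- numeric(L); d <- numeric(L)
  lr <- rev(filt$lo); hr <- rev(filt$hi)
  for (k in 0:(L - 1)) {
    seg <- xe[(2 * k + 2):(2 * k + f + 1)]
    a[k + 1] <- sum(lr * seg)
    d[k + 1] <- sum(hr * seg)
  }
  list(a = a, d = d)
}

## One synthesis step; `outLength` trims to the pre-analysis length.
idwtStep <- function(a, d, filt, outLength) {
  f <- length(filt$lo); L <- length(a)
  ua <- rep(0, 2 * L); ua[seq(1, 2 * L, 2)] <- a
  ud <- rep(0, 2 * L); ud[seq(1, 2 * L, 2)] <- d
  y <- stats::convolve(ua, filt$lo, type = "open") +
       stats::convolve(ud, filt$hi, type = "open")
  y <- y[(f - 1):(2 * L)]
  y[seq_len(outLength)]
}

#' Three-level wavelet packet decomposition
#'
#' Expands the full wavelet-packet binary tree to depth 3 (both approximation
#' and detail branches are split at every level) and returns the 8 terminal
#' sub-band coefficient arrays in natural filter-bank order
#' AAA, AAD, ADA, ADD, DAA, DAD, DDA, DDD (k = 1..8). The default boundary
#' mode is the periodized transform (node lengths halve with ceiling, so a
#' length-500 input yields 63 coefficients per node: 500 -> 250 -> 125 -> 63),
#' which keeps the tree orthogonal and energy-preserving to within the
#' odd-length padding; half-sample symmetric extension is available but adds
#' redundant boundary coefficients for filters longer than 2 taps.
#'
#' @param x numeric signal (a 500-sample HRV beat in the CAD workflow, but any
#'   length >= 8 works).
#' @param basis wavelet name accepted by [waveletFilter()] (default "db1").
#' @param levels tree depth (default 3).
#' @param boundary "periodic" (default) or "symmetric".
#' @return named list of `2^levels` coefficient vectors, names "AAA".."DDD".
#' @export
wpdDecompose <- function(x, basis = "db1", levels = 3,
                         boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  checkSignal(x, minLength = 2^levels)
  filt <- waveletFilter(basis)
  nodes <- list(x)
  paths <- ""
  for (lev in seq_len(levels)) {
    nxt <- vector("list", 2 * length(nodes))
    np <- character(2 * length(nodes))
    for (i in seq_along(nodes)) {
      st <- dwtStep(nodes[[i]], filt, boundary = boundary)
      nxt[[2 * i - 1]] <- st$a; np[2 * i - 1] <- paste0(paths[i], "A")
      nxt[[2 * i]] <- st$d;     np[2 * i] <- paste0(paths[i], "D")
    }
    nodes <- nxt
    paths <- np
  }
  names(nodes) <- paths
  attr(nodes, "basis") <- basis
  nodes
}

#' Wavelet denoising with the universal threshold
#'
#' Multi-level DWT (default db6), thresholding of every detail level with the
#' Donoho-Johnstone universal threshold sigma * sqrt(2 log n) — sigma
#' estimated from the finest detail level via MAD / 0.6745 — and
#' reconstruction. Output length equals input length.
#'
#' Hard thresholding is the default: soft shrinkage subtracts the threshold
#' from every retained coefficient, which visibly attenuates the sharp QRS
#' complexes of an ECG and can *lower* the SNR; hard thresholding keeps the
#' retained coefficients intact. The classical soft rule remains available
#' via `rule = "soft"`.
#'
#' @param x numeric signal.
#' @param basis wavelet name (default "db6", the standard ECG choice).
#' @param levels decomposition depth (default 4; capped at the maximum the
#'   record length supports). Deeper trees start thresholding
#'   signal-dominated bands.
#' @param rule "hard" (default) or "soft".
#' @return denoised numeric vector, same length as `x`.
#' @export
waveletDenoise <- function(x, basis = "db6", levels = 4,
                           rule = c("hard", "soft")) {
  rule <- match.arg(rule)
  checkSignal(x, minLength = 2L)
  filt <- waveletFilter(basis)
  maxLev <- max(1L, floor(log2(length(x) / (length(filt$lo) - 1))))
  levels <- min(levels, maxLev)
  if (length(x) < 2^levels) stop("record too short for requested levels", call. = FALSE)
  a <- x
  details <- vector("list", levels)
  lens <- integer(levels)
  for (lev in seq_len(levels)) {
    lens[lev] <- length(a)
    st <- dwtStep(a, filt, boundary = "symmetric")  # paired with idwtStep
    details[[lev]] <- st$d
    a <- st$a
  }
  sigma <- stats::median(abs(details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  shrink <- if (rule == "soft") function(w) sign(w) * pmax(abs(w) - thr, 0)
            else function(w) w * (abs(w) > thr)
  for (lev in rev(seq_len(levels))) {
    a <- idwtStep(a, shrink(details[[lev]]), filt, lens[lev])
  }
  a
}
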