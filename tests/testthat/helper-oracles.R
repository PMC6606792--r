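# Independent brute-force oracles, written with explicit loops and no shared
# code with the package implementation.

# Renyi distribution entropy by direct enumeration.
rdisenOracle <- function(x, B, m, q) {
  n <- length(x)
  nt <- n - m
  # embed
  tmpl <- vector("list", nt)
  for (i in 1:nt) tmpl[[i]] <- x[i:(i + m - 1)]
  # pooled off-diagonal Chebyshev distances (both triangles)
  dists <- numeric(0)
  for (i in 1:nt) for (j in 1:nt) {
    if (i == j) next
    mx <- 0
    for (k in 1:m) {
      dk <- abs(tmpl[[i]][k] - tmpl[[j]][k])
      if (dk > mx) mx <- dk
    }
    dists <- c(dists, mx)
  }
  lo <- min(dists); hi <- max(dists)
  if (hi == lo) return(0)
  counts <- rep(0, B)
  for (d in dists) {
    t <- floor((d - lo) / (hi - lo) * B) + 1
    if (t > B) t <- B
    counts[t] <- counts[t] + 1
  }
  p <- counts / length(dists)
  if (abs(q - 1) < 1e-8) {
    s <- 0
    for (pt in p) if (pt > 0) s <- s - pt * log2(pt)
    s / log2(B)
  } else {
    s <- 0
    for (pt in p) if (pt > 0) s <- s + pt^q
    log2(s) / ((1 - q) * log2(B))
  }
}

# Approximate entropy (self-matches included) by direct counting.
apenOracle <- function(x, m, rFrac) {
  n <- length(x)
  r <- rFrac * sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    acc <- 0
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) {
        mx <- 0
        for (k in 0:(mm - 1)) {
          dk <- abs(x[i + k] - x[j + k])
          if (dk > mx) mx <- dk
        }
        if (mx <= r) cnt <- cnt + 1
      }
      acc <- acc + log(cnt / nt)
    }
    acc / nt
  }
  phi(m) - phi(m + 1)
}

# Sample entropy (self-matches excluded, N - m templates at both lengths).
sampenOracle <- function(x, m, rFrac) {
  n <- length(x)
  r <- rFrac * sd(x)
  nt <- n - m
  a <- 0; b <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    mxB <- 0
    for (k in 0:(m - 1)) {
      dk <- abs(x[i + k] - x[j + k])
      if (dk > mxB) mxB <- dk
    }
    if (mxB <= r) {
      b <- b + 1
      dk <- abs(x[i + m] - x[j + m])
      if (max(mxB, dk) <= r) a <- a + 1
    }
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# Two-class RR beats of the pipeline's default geometry (helper, not oracle).
makeTwoClassBeats <- function(n = 1000, recordsPerClass = 40, seed = 11,
                              beatsPerRecord = 2) {
  g <- twoClassRR(n = n, recordsPerClass = recordsPerClass, seed = seed)
  beats <- unlist(lapply(seq_along(g$signals), function(i)
    segmentBeats(g$signals[[i]], 500, maxBeats = beatsPerRecord,
                 label = as.character(g$labels[i]),
                 recordId = paste0("r", i))), recursive = FALSE)
  labels <- factor(vapply(beats, function(b) b$label, character(1)),
                   levels = c("normal", "cad"))
  list(beats = beats, labels = labels)
}

# Score detected peaks against ground truth within a tolerance (seconds).
peakScore <- function(truth, detected, fs, tolSec = 0.05) {
  tDet <- detected / fs
  recall <- mean(vapply(truth, function(p) any(abs(tDet - p) <= tolSec), logical(1)))
  precision <- if (length(tDet) == 0) 0 else
    mean(vapply(tDet, function(p) any(abs(truth - p) <= tolSec), logical(1)))
  c(recall = recall, precision = precision)
}
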