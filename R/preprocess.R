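## ECG -> labeled 500-sample HRV beat segments: record container, resampling,
## denoising, Pan-Tompkins QRS detection, RR extraction, beat segmentation.

#' ECG record container
#'
#' @param samples numeric vector of ECG samples (mV).
#' @param fs sampling rate in Hz.
#' @param id record identifier.
#' @param label optional class label (e.g. "normal", "cad").
#' @return object of class `ecgRecord`.
#' @export
ecgRecord <- function(samples, fs, id = "record", label = NULL) {
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate must be positive", call. = FALSE)
  checkSignal(samples)
  structure(list(samples = as.numeric(samples), fs = fs, id = id, label = label),
            class = "ecgRecord")
}

#' @export
print.ecgRecord <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d samples at %g Hz (%.1f s)%s\n",
              x$id, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Resample an ECG record to a new rate
#'
#' Fourier-domain resampling: the spectrum is zero-padded (up-sampling) or
#' truncated (down-sampling) so the output is exact for band-limited periodic
#' content; record duration is preserved to within one sample period. Used to
#' bring heterogeneous recordings to a common rate (e.g. 250 Hz records
#' up-sampled to the 257 Hz of the comparison group).
#'
#' @param rec an [ecgRecord()].
#' @param targetRate desired sampling rate in Hz.
#' @return resampled [ecgRecord()].
#' @export
resampleRecord <- function(rec, targetRate) {
  stopifnot(inherits(rec, "ecgRecord"))
  if (targetRate <= 0) stop("targetRate must be positive", call. = FALSE)
  if (targetRate == rec$fs) return(rec)
  x <- rec$samples
  n <- length(x)
  m <- round(n * targetRate / rec$fs)
  X <- stats::fft(x)
  Y <- complex(m)
  keep <- min(n, m)
  half <- (keep - 1) %/% 2
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  # Nyquist bin of an even-length kept band is shared between +/- frequencies
  if (keep %% 2 == 0) {
    nyq <- X[half + 2]
    if (m > n) {
      Y[half + 2] <- nyq / 2
      Y[m - half] <- Conj(nyq) / 2
    } else {
      Y[half + 2] <- nyq
    }
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  ecgRecord(y, targetRate, id = rec$id, label = rec$label)
}

#' Denoise an ECG record (db6 wavelet, universal soft threshold)
#'
#' @param rec an [ecgRecord()].
#' @param basis wavelet basis (default "db6").
#' @param levels decomposition depth (default 4).
#' @param rule threshold rule, "hard" (default) or "soft"
#'   (see [waveletDenoise()]).
#' @return denoised [ecgRecord()].
#' @export
denoiseRecord <- function(rec, basis = "db6", levels = 4,
                          rule = c("hard", "soft")) {
  stopifnot(inherits(rec, "ecgRecord"))
  ecgRecord(waveletDenoise(rec$samples, basis = basis, levels = levels,
                           rule = rule),
            rec$fs, id = rec$id, label = rec$label)
}

#' Pan-Tompkins R-peak detection
#'
#' Classic Pan-Tompkins chain: 5-15 Hz band-pass (zero-phase Butterworth),
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' adaptive dual-threshold peak picking with a 200 ms refractory period and
#' missed-beat searchback at half threshold. Detected peaks are refined to
#' the local maximum of the absolute band-passed ECG within +/- `refineMs`,
#' which makes detection insensitive to QRS polarity.
#'
#' @param rec an [ecgRecord()] with sampling rate >= 100 Hz; records shorter
#'   than 2 s are rejected.
#' @param refractoryMs minimum R-R separation in ms (default 200).
#' @param integrationMs moving-integration window in ms (default 150).
#' @param refineMs half-width of the peak-refinement window in ms (default 75).
#' @param band band-pass corner frequencies in Hz (default c(5, 15)).
#' @return integer vector of strictly increasing R-peak sample indices
#'   (empty, with a warning, when nothing is detected).
#' @export
detectRPeaks <- function(rec, refractoryMs = 200, integrationMs = 150,
                         refineMs = 75, band = c(5, 15)) {
  stopifnot(inherits(rec, "ecgRecord"))
  fs <- rec$fs
  if (fs < 100) stop("sampling rate must be >= 100 Hz", call. = FALSE)
  x <- rec$samples
  n <- length(x)
  if (n < 2 * fs) stop("record shorter than 2 s", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("flat-line record: no peaks detected")
    return(integer(0))
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))
  # centered five-point derivative (zero delay), then squaring
  dv <- as.numeric(stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2))
  dv[is.na(dv)] <- 0
  sq <- dv^2
  w <- max(3L, round(integrationMs / 1000 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  refr <- round(refractoryMs / 1000 * fs)
  # candidate peaks: local maxima of the integrated signal
  isPk <- c(FALSE, diff(mwi) > 0) & c(mwi[-n] > mwi[-1], FALSE)
  cand <- which(isPk & mwi > 0)
  if (length(cand) == 0) {
    warning("no candidate peaks found")
    return(integer(0))
  }
  # adaptive thresholds, initialised from the first 2 seconds
  init <- mwi[seq_len(min(n, 2 * fs))]
  spk <- 0.6 * max(init)
  npk <- 0.5 * mean(init)
  thr1 <- npk + 0.25 * (spk - npk)
  qrs <- integer(0)
  rrAvg <- NA_real_
  lastQrs <- -Inf
  for (i in seq_along(cand)) {
    pk <- cand[i]; v <- mwi[pk]
    if (pk - lastQrs < refr) next
    if (v > thr1) {
      spk <- 0.125 * v + 0.875 * spk
      if (length(qrs) > 0) {
        rr <- pk - lastQrs
        rrAvg <- if (is.na(rrAvg)) rr else 0.125 * rr + 0.875 * rrAvg
      }
      qrs <- c(qrs, pk)
      lastQrs <- pk
    } else {
      npk <- 0.125 * v + 0.875 * npk
      # searchback: a beat is overdue, accept the best sub-threshold peak
      if (!is.na(rrAvg) && (pk - lastQrs) > 1.66 * rrAvg && v > 0.5 * thr1) {
        spk <- 0.25 * v + 0.75 * spk
        qrs <- c(qrs, pk)
        lastQrs <- pk
      }
    }
    thr1 <- npk + 0.25 * (spk - npk)
  }
  if (length(qrs) == 0) {
    warning("no peaks above threshold")
    return(integer(0))
  }
  # refine to the local |band-passed| maximum (polarity-insensitive)
  halfW <- round(refineMs / 1000 * fs)
  ref <- vapply(qrs, function(p) {
    i0 <- max(1L, p - halfW); i1 <- min(n, p + halfW)
    as.integer(i0 + which.max(abs(bp[i0:i1])) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce the refractory period after refinement
  keep <- ref[1]
  for (p in ref[-1]) if (p - keep[length(keep)] >= refr) keep <- c(keep, p)
  as.integer(keep)
}

#' RR intervals from R-peak indices
#'
#' @param peaks strictly increasing R-peak sample indices (>= 2 of them).
#' @param fs sampling rate in Hz.
#' @return numeric vector of RR intervals in milliseconds
#'   (length `length(peaks) - 1`).
#' @export
computeRR <- function(peaks, fs) {
  if (length(peaks) < 2) stop("need at least 2 peaks", call. = FALSE)
  if (any(diff(peaks) <= 0)) stop("peak indices must be strictly increasing", call. = FALSE)
  if (fs <= 0) stop("sampling rate must be positive", call. = FALSE)
  diff(peaks) / fs * 1000
}

#' Segment an RR series into fixed-length HRV beats
#'
#' Cuts non-overlapping consecutive windows of `beatLength` RR samples from
#' the start of the series; the trailing remainder is discarded. A cap limits
#' the number of segments per record (2 for the normal-class balancing
#' protocol, unlimited for the disease class).
#'
#' @param rr numeric RR series (ms).
#' @param beatLength samples per beat (default 500).
#' @param maxBeats cap on segments per record (default Inf).
#' @param label optional class label attached to each segment.
#' @param recordId provenance identifier.
#' @return list of `beatSegment` lists with fields `samples`, `label`,
#'   `record`, `offset`; empty (with a warning) when the series is shorter
#'   than one beat.
#' @export
segmentBeats <- function(rr, beatLength = 500, maxBeats = Inf,
                         label = NULL, recordId = "record") {
  checkSignal(rr)
  nSeg <- length(rr) %/% beatLength
  if (nSeg == 0) {
    warning(sprintf("RR series of length %d yields no %d-sample beats",
                    length(rr), beatLength))
    return(list())
  }
  nSeg <- min(nSeg, maxBeats)
  lapply(seq_len(nSeg), function(k) {
    off <- (k - 1) * beatLength
    structure(list(samples = rr[(off + 1):(off + beatLength)],
                   label = label, record = recordId, offset = off),
              class = "beatSegment")
  })
}
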