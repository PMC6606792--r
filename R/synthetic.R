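## Synthetic signal generators: logistic-map realizations, ECG with known
## R-peak times, and two-class RR-interval series. All generators are pure
## functions of (config, seed).

#' Derive a reproducible child seed for a named stage
#'
#' A single global seed fans out to per-stage child seeds so pipeline stages
#' (generation, splitting, fold assignment, ...) are independently
#' reproducible. The derivation hashes the stage name into an offset; results
#' stay within the 32-bit integer range R requires.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Logistic-map signal realizations
#'
#' Iterates x_{n+1} = w * x_n * (1 - x_n). With w = 3.5 the orbit is periodic
#' (period 4); with w = 3.8 it is chaotic. Each realization starts from its
#' own initial value drawn uniformly from `x0Range` (or from `x0` when given).
#' No transient is discarded.
#'
#' @param w map parameter, 0 < w <= 4.
#' @param n samples per realization.
#' @param realizations number of realizations (default 20).
#' @param x0 optional fixed initial value(s) in (0, 1); recycled across
#'   realizations. When NULL, initial values are drawn from `x0Range`.
#' @param x0Range range for random initial values (default c(0.1, 0.2)).
#' @param seed RNG seed used when `x0` is NULL.
#' @return list of numeric vectors of length `n`.
#' @examples
#' sig <- logisticMap(3.5, n = 100, realizations = 1, x0 = 0.15)[[1]]
#' @export
logisticMap <- function(w, n, realizations = 20, x0 = NULL,
                        x0Range = c(0.1, 0.2), seed = 1L) {
  if (!is.numeric(w) || w <= 0 || w > 4)
    stop("logistic map parameter w must lie in (0, 4]", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(x0)) {
    set.seed(deriveSeed(seed, "logistic"))
    x0 <- stats::runif(realizations, x0Range[1], x0Range[2])
  } else {
    if (any(x0 <= 0 | x0 >= 1)) stop("x0 must lie in (0, 1)", call. = FALSE)
    x0 <- rep_len(x0, realizations)
  }
  lapply(seq_len(realizations), function(i) {
    x <- numeric(n)
    x[1] <- x0[i]
    for (k in seq_len(n - 1)) x[k + 1] <- w * x[k] * (1 - x[k])
    x
  })
}

#' Synthetic ECG with ground-truth R-peak times
#'
#' Builds a lead-II-like ECG as a sum of per-beat templates placed at jittered
#' beat times, plus baseline wander and white noise. The QRS complex is a
#' Ricker (negative second-derivative-of-Gaussian) pulse whose maximum falls
#' exactly on the beat time; small Gaussian P and T waves are added for
#' realism. The exact beat times are returned, so detector recall/precision
#' can be scored against ground truth.
#'
#' @param fs sampling rate in Hz (default 257).
#' @param duration record length in seconds.
#' @param meanHr mean heart rate in bpm (default 60).
#' @param hrSd standard deviation of beat-to-beat interval jitter, in bpm
#'   units of the instantaneous rate (default 3).
#' @param qrsAmplitude QRS peak amplitude in mV (default 1).
#' @param noiseSd additive white noise SD in mV (default 0).
#' @param baselineAmplitude baseline-wander amplitude in mV (default 0.05,
#'   0.25 Hz respiratory drift).
#' @param seed RNG seed.
#' @return list with `record` (an [ecgRecord()]) and `peaks` (true R-peak
#'   times in seconds).
#' @export
syntheticEcg <- function(fs = 257, duration = 60, meanHr = 60, hrSd = 3,
                         qrsAmplitude = 1, noiseSd = 0,
                         baselineAmplitude = 0.05, seed = 1L) {
  if (duration * meanHr / 60 < 2) stop("duration must cover > 2 beats", call. = FALSE)
  set.seed(deriveSeed(seed, "ecg"))
  meanRR <- 60 / meanHr
  # RR jitter: hrSd bpm around meanHr, converted to period jitter
  nBeatsMax <- ceiling(duration / meanRR * 1.5) + 2
  hr <- pmax(20, stats::rnorm(nBeatsMax, meanHr, hrSd))
  rr <- 60 / hr
  beatTimes <- cumsum(c(meanRR / 2, rr))
  beatTimes <- beatTimes[beatTimes < duration - 0.1]
  # snap beat times to the sample grid so the template maximum is a sample
  beatTimes <- round(beatTimes * fs) / fs
  n <- round(duration * fs)
  t <- seq_len(n) / fs
  x <- numeric(n)
  ricker <- function(dt, s) (1 - (dt / s)^2) * exp(-dt^2 / (2 * s^2))
  gauss <- function(dt, s) exp(-dt^2 / (2 * s^2))
  for (bt in beatTimes) {
    i0 <- max(1, floor((bt - 0.35) * fs)); i1 <- min(n, ceiling((bt + 0.45) * fs))
    idx <- i0:i1
    dt <- t[idx] - bt
    x[idx] <- x[idx] + qrsAmplitude * ricker(dt, 0.012) +
      0.12 * qrsAmplitude * gauss(dt + 0.18, 0.025) +   # P wave
      0.25 * qrsAmplitude * gauss(dt - 0.25, 0.045)     # T wave
  }
  x <- x + baselineAmplitude * sin(2 * pi * 0.25 * t)
  if (noiseSd > 0) x <- x + stats::rnorm(n, 0, noiseSd)
  list(record = ecgRecord(x, fs, id = sprintf("synth-ecg-%d", seed)),
       peaks = beatTimes)
}

#' Noise SD achieving a target signal-to-noise ratio
#'
#' @param x clean signal (mV).
#' @param snrDb target SNR in decibels.
#' @return white-noise standard deviation giving the requested SNR.
#' @export
noiseSdForSnr <- function(x, snrDb) {
  sqrt(mean((x - mean(x))^2) / 10^(snrDb / 10))
}

#' Two-class RR-interval series generator
#'
#' Emulates short-term HRV of a normal-like class A and a reduced-variability
#' (CAD-like) class B. Each record is an AR(1) process around the class mean
#' RR with the configured SDNN, plus a sinusoidal respiratory-sinus-arrhythmia
#' modulation (period ~5 beats, random phase). Class A has the larger SDNN
#' and a strong fast modulation with moderate beat-to-beat correlation; class
#' B has reduced SDNN, near-absent modulation and a strongly autocorrelated
#' (smoothed) residual, emulating the vagal-withdrawal pattern of CAD HRV.
#' Under these defaults the distance-histogram entropy comes out higher for
#' the CAD-like class; that direction is engineered by construction, not
#' discovered.
#'
#' @param n samples (RR intervals) per record (default 1000).
#' @param recordsPerClass records per class (default 40).
#' @param meanRR per-class mean RR in ms, length 2 (default c(850, 800)).
#' @param sdnn per-class SDNN in ms, length 2 (default c(50, 18)); class A
#'   must exceed class B.
#' @param arCoef per-class AR(1) coefficient, length 2 (default c(0.7, 0.97)).
#' @param modAmplitude per-class modulation amplitude in ms, length 2
#'   (default c(30, 2)).
#' @param modPeriod modulation period in beats (default 5, the respiratory
#'   rhythm at rest).
#' @param seed RNG seed.
#' @return list with `signals` (list of numeric RR vectors, ms) and `labels`
#'   (factor "normal"/"cad", class A first).
#' @export
twoClassRR <- function(n = 1000, recordsPerClass = 40,
                       meanRR = c(850, 800), sdnn = c(50, 18),
                       arCoef = c(0.7, 0.97), modAmplitude = c(30, 2),
                       modPeriod = 5, seed = 1L) {
  if (any(meanRR <= 0) || any(sdnn < 0)) stop("invalid RR config", call. = FALSE)
  set.seed(deriveSeed(seed, "twoClassRR"))
  gen <- function(mu, sd0, phi, amp) {
    innov <- sd0 * sqrt(1 - phi^2)
    ar <- as.vector(stats::arima.sim(list(ar = phi), n = n, sd = innov))
    phase <- stats::runif(1, 0, 2 * pi)
    mu + ar + amp * sin(2 * pi * seq_len(n) / modPeriod + phase)
  }
  sigs <- c(
    lapply(seq_len(recordsPerClass), function(i)
      gen(meanRR[1], sdnn[1], arCoef[1], modAmplitude[1])),
    lapply(seq_len(recordsPerClass), function(i)
      gen(meanRR[2], sdnn[2], arCoef[2], modAmplitude[2]))
  )
  labels <- factor(rep(c("normal", "cad"), each = recordsPerClass),
                   levels = c("normal", "cad"))
  list(signals = sigs, labels = labels)
}
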