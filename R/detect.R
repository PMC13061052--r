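# R-peak detection at rodent heart rates. The detector is Pan-Tompkins-style
# (derivative -> squaring -> moving-window integration -> adaptive threshold)
# with the refractory period tied to the top of the heart-rate range so the
# same code covers rat (200-500 BPM) and slower species.

# Zero-phase FFT-domain band-pass with raised-cosine transition edges.
# No IIR design package is available in this stack; frequency-domain
# filtering is exactly zero-phase, so peak times are not biased.
fftBandpass <- function(x, fs, low, high) {
  n <- length(x)
  if (n < 8) return(x - mean(x))
  nfft <- stats::nextn(n, c(2, 3, 5))
  mu <- mean(x)
  X <- stats::fft(c(x - mu, rep(0, nfft - n)))
  f <- (seq_len(nfft) - 1) * fs / nfft
  f <- pmin(f, fs - f)                      # fold to [0, fs/2]
  twl <- max(0.2 * low, 0.25)               # transition widths (Hz)
  twh <- max(0.05 * high, 1)
  gain <- rep(0, nfft)
  rise <- f >= low - twl & f < low
  gain[rise] <- 0.5 * (1 - cos(pi * (f[rise] - (low - twl)) / twl))
  gain[f >= low & f <= high] <- 1
  fall <- f > high & f <= high + twh
  gain[fall] <- 0.5 * (1 + cos(pi * (f[fall] - high) / twh))
  Re(stats::fft(X * gain, inverse = TRUE) / nfft)[seq_len(n)]
}

#' Band-pass and standardize every channel of a record
#'
#' Applies a zero-phase band-pass (default 10-200 Hz, where rodent QRS energy
#' concentrates) to each channel, then standardizes the channel to zero mean
#' and unit variance. Constant channels are passed through as zeros rather
#' than dividing by a zero variance. Zero-phase filtering leaves R-peak times
#' unbiased, which is essential for millisecond RR fidelity.
#'
#' @param record an [ECGRecord-class].
#' @param band numeric length-2, band edges in Hz; must be ordered and below
#'   the Nyquist frequency.
#' @return The filtered, standardized [ECGRecord-class], flagged normalized.
#' @export
preprocessRecord <- function(record, band = c(10, 200)) {
  stopifnot(is(record, "ECGRecord"))
  nyq <- sampleRate(record) / 2
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] || band[2] >= nyq)
    stop(sprintf("band edges must satisfy 0 < low < high < Nyquist (%g Hz)", nyq))
  sig <- record@signals
  for (j in seq_len(ncol(sig))) {
    y <- fftBandpass(sig[, j], sampleRate(record), band[1], band[2])
    s <- stats::sd(y)
    sig[, j] <- if (is.na(s) || s == 0) y * 0 else (y - mean(y)) / s
  }
  ECGRecord(sig, sampleRate = sampleRate(record), t0 = record@t0,
            normalized = TRUE)
}

# centered moving average, zero-padded at the edges
movAvg <- function(x, w) {
  if (w <= 1) return(x)
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

#' Detect R-peaks on one channel
#'
#' Derivative-energy transform with a blockwise adaptive threshold: the
#' normalized channel is first narrowed to the QRS energy band (default
#' 15-80 Hz for the ~8 ms rodent complex, which suppresses wideband noise
#' far more than the sharp QRS), then differenced, squared and integrated
#' over a 15 ms moving window. Candidate peaks must clear a per-block
#' adaptive threshold and are spaced by the refractory period
#' \code{60000 / hr_range[2]} ms (120 ms at the default 500 BPM ceiling);
#' each detection is refined to the local extremum of the band-passed signal
#' within +/- 10 ms. The threshold is floored at a fraction of the global
#' QRS energy scale so that dropout stretches containing only noise do not
#' generate spurious beats.
#'
#' @param record an [ECGRecord-class]; preprocessed with [preprocessRecord()]
#'   first if it is not already normalized.
#' @param channel channel label to analyse.
#' @param hr_range plausible heart-rate range in BPM (default \code{c(200,
#'   500)}, the rodent range).
#' @param qrs_band band (Hz) isolating QRS energy for the detection path;
#'   the reported peak times still come from the full preprocessing band.
#' @return A [BeatAnnotation-class]; an empty annotation with a warning when
#'   no peak is found (e.g. a flat channel).
#' @export
#' @examples
#' study <- generateStudy(simConfig(duration_s = 30, n_trials = 1,
#'                                  stim_len_s = 15, washout_len_s = 15))
#' ann <- detectRPeaks(study$record, "chest_I")
#' ann
detectRPeaks <- function(record, channel, hr_range = c(200, 500),
                         qrs_band = c(15, 80)) {
  stopifnot(is(record, "ECGRecord"), length(hr_range) == 2,
            hr_range[1] > 0, hr_range[1] < hr_range[2])
  if (!isNormalized(record)) record <- preprocessRecord(record)
  x <- channelSignal(record, channel)
  fs <- sampleRate(record)
  dt <- 1000 / fs
  empty <- function(msg) {
    warning(msg)
    BeatAnnotation(channel, numeric(0), numeric(0), fs)
  }
  if (length(x) < 3 || stats::sd(x) == 0)
    return(empty(sprintf("channel '%s' is constant; no peaks detected", channel)))

  xd <- fftBandpass(x, fs, qrs_band[1], min(qrs_band[2], fs / 2 * 0.9))
  energy <- movAvg(c(0, diff(xd))^2, max(1L, round(15 / dt)))
  refr <- 60000 / hr_range[2]                  # refractory period (ms)
  refr_n <- max(1L, round(refr / dt))

  # blockwise adaptive threshold with a global floor
  block_n <- max(refr_n * 4L, round(10000 / dt))
  gscale <- stats::quantile(energy, 0.999, names = FALSE)
  nblock <- ceiling(length(energy) / block_n)
  thr <- numeric(length(energy))
  for (b in seq_len(nblock)) {
    idx <- ((b - 1) * block_n + 1):min(b * block_n, length(energy))
    thr[idx] <- max(0.25 * stats::quantile(energy[idx], 0.99, names = FALSE),
                    0.20 * gscale)
  }

  # local maxima of the integrated energy above threshold
  core <- energy[2:(length(energy) - 1)]
  cand <- which(core >= energy[1:(length(energy) - 2)] &
                core > energy[3:length(energy)] &
                core > thr[2:(length(energy) - 1)]) + 1L
  if (!length(cand))
    return(empty(sprintf("no R-peaks found on channel '%s'", channel)))

  # refractory: keep the larger of any two candidates closer than refr
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if ((i - last) >= refr_n) {
      keep <- c(keep, i)
      last <- i
    } else if (energy[i] > energy[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }

  # refine to the local extremum of the band-passed signal within +/- 10 ms
  half <- max(1L, round(10 / dt))
  refined <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(abs(x[lo:hi])) - 1L)
  }, integer(1))
  refined <- refined[!duplicated(refined)]

  # refinement can pull neighbours together; re-impose the refractory gap
  ok <- c(TRUE, diff(refined) >= refr_n)
  while (!all(ok)) {
    refined <- refined[ok]
    ok <- c(TRUE, diff(refined) >= refr_n)
  }

  BeatAnnotation(channel, peakTimes = record@t0 + (refined - 1) * dt,
                 peakIndices = refined - 1L)
}

#' Convert a beat annotation to an RR interval series
#'
#' @param ann a [BeatAnnotation-class] with at least two peaks; with fewer,
#'   an unusable empty series is returned with a warning.
#' @return An [RRSeries-class] with \code{n - 1} intervals, all initially
#'   valid.
#' @export
#' @examples
#' rrIntervals(extractRR(BeatAnnotation("chest_I", c(0, 150, 300))))
extractRR <- function(ann) {
  stopifnot(is(ann, "BeatAnnotation"))
  if (length(beatTimes(ann)) < 2) {
    warning("fewer than 2 peaks; RR series is unusable")
    return(rrSeries(beatTimes(ann)))
  }
  rrSeries(beatTimes(ann))
}

#' Flag artifactual intervals in an RR series
#'
#' Two screening rules, applied sequentially along the series: an interval is
#' flagged invalid when (i) it falls outside the physiological range
#' (default 120-300 ms, i.e. 200-500 BPM), or (ii) it deviates from the
#' running median of the last up-to-9 previously valid intervals by more than
#' \code{jump_frac} of that median (the jump rule engages once at least 3
#' valid intervals precede). Flagged intervals are retained, never deleted,
#' so the beat time axis survives for spectral analysis; the operation is
#' idempotent.
#'
#' @param rr an [RRSeries-class].
#' @param physio_range plausible interval range in ms.
#' @param jump_frac maximal fractional deviation from the running median.
#' @return The [RRSeries-class] with updated validity flags; flagged unusable
#'   (with a warning) if no interval survives.
#' @export
rejectArtifacts <- function(rr, physio_range = c(120, 300), jump_frac = 0.3) {
  stopifnot(is(rr, "RRSeries"), length(physio_range) == 2,
            physio_range[1] < physio_range[2], jump_frac > 0)
  iv <- rrIntervals(rr)
  valid <- rrValid(rr)
  hist <- numeric(0)                       # most recent valid intervals
  for (i in seq_along(iv)) {
    if (!valid[i]) next
    ok <- iv[i] >= physio_range[1] && iv[i] <= physio_range[2]
    if (ok && length(hist) >= 3) {
      med <- stats::median(hist)
      ok <- abs(iv[i] - med) <= jump_frac * med
    }
    valid[i] <- ok
    if (ok) {
      hist <- c(hist, iv[i])
      if (length(hist) > 9) hist <- hist[-1]
    }
  }
  out <- new("RRSeries", beatTimes = beatTimes(rr), rr = iv, valid = valid,
             usable = any(valid))
  if (!out@usable && length(iv))
    warning("all intervals flagged invalid; series is unusable")
  out
}
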