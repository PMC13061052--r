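#' Canonical heart rate variability metric names
#'
#' The sixteen metrics reported per epoch and modality, in report order.
#' Time-domain: mean RR (ms), mean HR (BPM, mean of per-beat instantaneous
#' heart rate), SDNN (ms), RMSSD (ms), PNN5 (%). Frequency-domain: LF, HF and
#' total spectral power (ms^2) and the LF/HF ratio. Non-linear: Poincare SD1,
#' SD2 (ms) and their ratio, sample entropy, and DFA alpha1, alpha2 and their
#' ratio.
#'
#' @return Character vector of the internal metric keys.
#' @export
#' @examples
#' hrvMetricNames()
hrvMetricNames <- function() {
  c("mean_rr", "mean_hr", "sdnn", "rmssd", "pnn5",
    "lf", "hf", "total_power", "lf_hf",
    "sd1", "sd2", "sd1_sd2",
    "sampen", "dfa_a1", "dfa_a2", "dfa_ratio")
}

#' Human-readable labels for the HRV metrics
#'
#' Maps the internal metric keys to the row labels used in report tables
#' ("Mean RR" ... "DFA Alpha Ratio").
#'
#' @return Named character vector keyed by [hrvMetricNames()].
#' @export
hrvMetricLabels <- function() {
  c(mean_rr = "Mean RR", mean_hr = "Mean HR", sdnn = "SDNN", rmssd = "RMSSD",
    pnn5 = "PNN5", lf = "LF", hf = "HF", total_power = "Total Power",
    lf_hf = "LF/HF", sd1 = "SD1", sd2 = "SD2", sd1_sd2 = "SD1/SD2",
    sampen = "Sample Entropy", dfa_a1 = "DFA Alpha 1", dfa_a2 = "DFA Alpha 2",
    dfa_ratio = "DFA Alpha Ratio")
}

.EPOCH_LABELS <- c("stimulation", "washout", "baseline")

#' ECGRecord: a multi-channel sampled voltage record
#'
#' Holds uniformly sampled ECG voltage series for one or more channels
#' (typically the in-ear leads \code{ear_left}, \code{ear_right} and the
#' chest lead \code{chest_I}), together with the sampling rate and the time
#' of the first sample.
#'
#' @slot signals numeric matrix, samples x channels; column names are the
#'   unique channel labels.
#' @slot sampleRate sampling rate in Hz (> 0).
#' @slot t0 time of the first sample in ms.
#' @slot normalized logical; TRUE after [preprocessRecord()] has band-passed
#'   and standardized the channels.
#' @name ECGRecord-class
#' @rdname ECGRecord-class
#' @exportClass ECGRecord
setClass("ECGRecord",
  representation(signals = "matrix", sampleRate = "numeric",
                 t0 = "numeric", normalized = "logical"),
  prototype(signals = matrix(numeric(0), 0, 0), sampleRate = 1000,
            t0 = 0, normalized = FALSE),
  validity = function(object) {
    msg <- character(0)
    if (length(object@sampleRate) != 1 || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    labs <- colnames(object@signals)
    if (ncol(object@signals) > 0 && (is.null(labs) || anyDuplicated(labs)))
      msg <- c(msg, "channel labels must be present and unique")
    if (!is.numeric(object@signals))
      msg <- c(msg, "signals must be numeric")
    if (length(msg)) msg else TRUE
  })

#' Construct an ECGRecord
#'
#' @param signals numeric matrix (samples x channels) with channel labels as
#'   column names, or a named list of equal-length numeric vectors.
#' @param sampleRate sampling rate in Hz.
#' @param t0 time of the first sample in ms (default 0).
#' @param normalized whether the record has already been preprocessed.
#' @return An [ECGRecord-class] object.
#' @export
#' @examples
#' rec <- ECGRecord(list(chest_I = sin(seq(0, 10, by = 0.001))), 1000)
#' rec
ECGRecord <- function(signals, sampleRate, t0 = 0, normalized = FALSE) {
  if (is.list(signals)) {
    n <- unique(lengths(signals))
    if (length(n) > 1)
      stop("all channels must have the same length")
    signals <- do.call(cbind, signals)
  }
  new("ECGRecord", signals = signals, sampleRate = as.numeric(sampleRate),
      t0 = as.numeric(t0), normalized = normalized)
}

#' EpochSchedule: labelled stimulation/washout intervals
#'
#' A set of half-open, non-overlapping time intervals \code{[start_ms,
#' end_ms)}, each labelled \code{stimulation}, \code{washout} or
#' \code{baseline} and assigned to a trial index. The half-open convention
#' prevents boundary beats from being counted in two epochs.
#'
#' @slot epochs data.frame with columns \code{label}, \code{start_ms},
#'   \code{end_ms}, \code{trial}, sorted by start.
#' @name EpochSchedule-class
#' @rdname EpochSchedule-class
#' @exportClass EpochSchedule
setClass("EpochSchedule",
  representation(epochs = "data.frame"),
  prototype(epochs = data.frame(label = character(0), start_ms = numeric(0),
                                end_ms = numeric(0), trial = integer(0))),
  validity = function(object) {
    e <- object@epochs
    need <- c("label", "start_ms", "end_ms", "trial")
    if (!all(need %in% names(e)))
      return(sprintf("epochs must have columns %s", paste(need, collapse = ", ")))
    if (nrow(e) == 0) return(TRUE)
    if (!all(e$label %in% .EPOCH_LABELS))
      return(sprintf("unknown epoch label(s) %s; allowed: %s",
                     paste(unique(setdiff(e$label, .EPOCH_LABELS)), collapse = ", "),
                     paste(.EPOCH_LABELS, collapse = ", ")))
    if (any(e$start_ms >= e$end_ms))
      return("every epoch must satisfy start_ms < end_ms")
    if (any(e$trial < 1))
      return("trial indices must be >= 1")
    o <- order(e$start_ms)
    s <- e$start_ms[o]; en <- e$end_ms[o]
    bad <- which(s[-1] < en[-length(en)])
    if (length(bad))
      return(sprintf("epochs overlap: [%g, %g) and [%g, %g)",
                     s[bad[1]], en[bad[1]], s[bad[1] + 1], en[bad[1] + 1]))
    TRUE
  })

#' Construct an EpochSchedule
#'
#' @param label character vector of epoch labels (\code{stimulation},
#'   \code{washout} or \code{baseline}).
#' @param start_ms,end_ms epoch bounds in ms; intervals are half-open
#'   \code{[start_ms, end_ms)}.
#' @param trial integer trial index (>= 1) pairing each stimulation epoch
#'   with its washout.
#' @return An [EpochSchedule-class], sorted by start time.
#' @export
#' @examples
#' EpochSchedule(c("stimulation", "washout"), c(0, 60e3), c(60e3, 120e3), c(1, 1))
EpochSchedule <- function(label, start_ms, end_ms, trial) {
  e <- data.frame(label = as.character(label), start_ms = as.numeric(start_ms),
                  end_ms = as.numeric(end_ms), trial = as.integer(trial))
  e <- e[order(e$start_ms), , drop = FALSE]
  rownames(e) <- NULL
  new("EpochSchedule", epochs = e)
}

#' BeatAnnotation: detected R-peaks for one channel
#'
#' Strictly increasing R-peak sample indices and times for a single channel.
#' Successive peaks must be separated by at least the detector's refractory
#' period (not enforced here beyond strict monotonicity).
#'
#' @slot channel channel label.
#' @slot peakIndices 0-based sample indices of the refined R apices.
#' @slot peakTimes peak times in ms.
#' @name BeatAnnotation-class
#' @rdname BeatAnnotation-class
#' @exportClass BeatAnnotation
setClass("BeatAnnotation",
  representation(channel = "character", peakIndices = "numeric",
                 peakTimes = "numeric"),
  prototype(channel = NA_character_, peakIndices = numeric(0),
            peakTimes = numeric(0)),
  validity = function(object) {
    if (length(object@peakIndices) != length(object@peakTimes))
      return("peakIndices and peakTimes must have equal length")
    if (length(object@peakTimes) > 1 && any(diff(object@peakTimes) <= 0))
      return("peak times must be strictly increasing")
    TRUE
  })

#' Construct a BeatAnnotation
#'
#' @param channel channel label.
#' @param peakTimes strictly increasing peak times in ms.
#' @param peakIndices 0-based sample indices; derived from \code{peakTimes}
#'   and \code{sampleRate} when omitted.
#' @param sampleRate sampling rate in Hz used to derive indices.
#' @return A [BeatAnnotation-class] object.
#' @export
BeatAnnotation <- function(channel, peakTimes, peakIndices = NULL,
                           sampleRate = 1000) {
  if (is.null(peakIndices))
    peakIndices <- round(peakTimes * sampleRate / 1000)
  new("BeatAnnotation", channel = as.character(channel),
      peakIndices = as.numeric(peakIndices), peakTimes = as.numeric(peakTimes))
}

#' RRSeries: beat times with NN intervals and validity flags
#'
#' Beat-to-beat (RR) intervals derived from a beat train. Intervals that fail
#' artifact screening are flagged invalid but retained, preserving the time
#' axis for spectral analysis; downstream statistics skip invalid intervals
#' (and successive-difference statistics skip pairs that span one).
#'
#' @slot beatTimes strictly increasing beat times in ms (length n).
#' @slot rr intervals in ms (length n - 1), \code{rr[i] = beatTimes[i+1] -
#'   beatTimes[i]}.
#' @slot valid logical flags per interval.
#' @slot usable FALSE when the series cannot support analysis (< 2 beats or
#'   all intervals invalid).
#' @name RRSeries-class
#' @rdname RRSeries-class
#' @exportClass RRSeries
setClass("RRSeries",
  representation(beatTimes = "numeric", rr = "numeric", valid = "logical",
                 usable = "logical"),
  prototype(beatTimes = numeric(0), rr = numeric(0), valid = logical(0),
            usable = FALSE),
  validity = function(object) {
    n <- length(object@beatTimes)
    if (length(object@rr) != max(0L, n - 1L))
      return("rr must have length(beatTimes) - 1 intervals")
    if (length(object@valid) != length(object@rr))
      return("valid must have one flag per interval")
    if (n > 1) {
      if (any(diff(object@beatTimes) <= 0))
        return("beat times must be strictly increasing")
      if (max(abs(object@rr - diff(object@beatTimes))) > 1e-6)
        return("rr must equal diff(beatTimes)")
    }
    TRUE
  })

#' Construct an RRSeries from beat times
#'
#' @param beatTimes strictly increasing beat times in ms.
#' @param valid optional logical flags per interval (default all TRUE).
#' @return An [RRSeries-class]; flagged unusable when it holds fewer than two
#'   beats or no valid interval.
#' @export
#' @examples
#' rrSeries(c(0, 150, 300, 450))
rrSeries <- function(beatTimes, valid = NULL) {
  beatTimes <- as.numeric(beatTimes)
  rr <- if (length(beatTimes) > 1) diff(beatTimes) else numeric(0)
  if (is.null(valid)) valid <- rep(TRUE, length(rr))
  usable <- length(rr) >= 1 && any(valid)
  new("RRSeries", beatTimes = beatTimes, rr = rr, valid = as.logical(valid),
      usable = usable)
}

#' GroundTruth: simulated beat times with known epoch structure
#'
#' The simulator's exact beat point process, the intervals between beats and
#' the epoch label active at each beat, used to score detection and fusion.
#'
#' @slot beatTimes strictly increasing true beat times in ms.
#' @slot rr true intervals in ms (length n - 1).
#' @slot epoch epoch label per beat (\code{stimulation}, \code{washout} or
#'   \code{baseline}).
#' @name GroundTruth-class
#' @rdname GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(beatTimes = "numeric", rr = "numeric", epoch = "character"),
  validity = function(object) {
    n <- length(object@beatTimes)
    if (n > 1 && any(diff(object@beatTimes) <= 0))
      return("true beat times must be strictly increasing")
    if (length(object@rr) != max(0L, n - 1L))
      return("rr must have length(beatTimes) - 1")
    if (length(object@epoch) != n)
      return("one epoch label per beat required")
    TRUE
  })

#' ChannelQuality: windowed usability of a detected channel
#'
#' Per-window beat coverage of one channel relative to the minimum plausible
#' beat count at the low end of the heart-rate range. Windows whose coverage
#' falls below the threshold are flagged unusable, triggering single-channel
#' fallback in [aggregateBeats()].
#'
#' @slot channel channel label.
#' @slot windows data.frame with columns \code{start_ms}, \code{end_ms},
#'   \code{nBeats}, \code{coverage} (in \code{[0, 1]}), \code{usable}.
#' @name ChannelQuality-class
#' @rdname ChannelQuality-class
#' @exportClass ChannelQuality
setClass("ChannelQuality",
  representation(channel = "character", windows = "data.frame"),
  validity = function(object) {
    w <- object@windows
    need <- c("start_ms", "end_ms", "nBeats", "coverage", "usable")
    if (!all(need %in% names(w)))
      return(sprintf("windows must have columns %s", paste(need, collapse = ", ")))
    if (nrow(w) && (any(w$coverage < 0) || any(w$coverage > 1)))
      return("coverage must lie in [0, 1]")
    TRUE
  })

#' HRVSummary: the full metric battery for one epoch and modality
#'
#' All sixteen HRV metrics (see [hrvMetricNames()]) computed from one NN
#' interval series, plus the beat count and the epoch/modality/trial labels.
#' Metrics that are undefined for a series (too few beats, zero spread, too
#' short an epoch for spectral analysis) are carried as \code{NA}, never
#' imputed as zero.
#'
#' @slot metrics named numeric vector over [hrvMetricNames()].
#' @slot nBeats number of beats in the series.
#' @slot epochLabel,modality,trial provenance labels.
#' @name HRVSummary-class
#' @rdname HRVSummary-class
#' @exportClass HRVSummary
setClass("HRVSummary",
  representation(metrics = "numeric", nBeats = "integer",
                 epochLabel = "character", modality = "character",
                 trial = "integer"),
  prototype(metrics = structure(rep(NA_real_, 16), names = c(
      "mean_rr", "mean_hr", "sdnn", "rmssd", "pnn5", "lf", "hf",
      "total_power", "lf_hf", "sd1", "sd2", "sd1_sd2", "sampen",
      "dfa_a1", "dfa_a2", "dfa_ratio")),
    nBeats = 0L, epochLabel = NA_character_, modality = NA_character_,
    trial = NA_integer_),
  validity = function(object) {
    if (!identical(names(object@metrics), hrvMetricNames()))
      return("metrics must be named exactly by hrvMetricNames()")
    ms <- object@metrics[c("mean_rr", "sdnn", "rmssd", "lf", "hf",
                           "total_power", "sd1", "sd2")]
    if (any(!is.na(ms) & ms < 0))
      return("ms-valued and power metrics must be non-negative")
    TRUE
  })
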