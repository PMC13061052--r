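#' Accessors for earHRV classes
#'
#' Small accessor functions for the S4 containers; user code should use these
#' rather than reaching into slots.
#'
#' \describe{
#'   \item{sampleRate, channelLabels, channelSignal, sampleTimes,
#'     recordDuration, isNormalized}{[ECGRecord-class]: sampling rate (Hz),
#'     channel labels, one channel's samples, sample times (ms), record
#'     duration (ms), and whether the record was preprocessed.}
#'   \item{channelLabel, peakIndices, beatTimes}{[BeatAnnotation-class]:
#'     source channel, 0-based R-peak sample indices, peak times (ms).}
#'   \item{beatTimes, rrIntervals, rrValid, isUsable}{[RRSeries-class] and
#'     [GroundTruth-class]: beat times (ms), intervals (ms), per-interval
#'     validity, overall usability.}
#'   \item{epochs}{[EpochSchedule-class]: the epoch table.}
#'   \item{epochLabels}{[GroundTruth-class]: epoch label per beat.}
#'   \item{metrics}{[HRVSummary-class]: the named metric vector.}
#'   \item{qualityWindows}{[ChannelQuality-class]: the per-window coverage
#'     table.}
#' }
#'
#' @param x an earHRV object.
#' @param channel a channel label.
#' @name accessors
#' @aliases sampleRate channelLabels channelSignal sampleTimes recordDuration
#'   isNormalized beatTimes peakIndices channelLabel rrIntervals rrValid
#'   isUsable epochs epochLabels metrics qualityWindows
NULL

#' @rdname accessors
#' @export
setMethod("sampleRate", "ECGRecord", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("channelLabels", "ECGRecord", function(x) colnames(x@signals))

#' @rdname accessors
#' @export
setMethod("channelSignal", "ECGRecord", function(x, channel) {
  if (!channel %in% colnames(x@signals))
    stop(sprintf("channel '%s' not present; available: %s", channel,
                 paste(colnames(x@signals), collapse = ", ")))
  x@signals[, channel]
})

#' @rdname accessors
#' @export
setMethod("sampleTimes", "ECGRecord", function(x)
  x@t0 + (seq_len(nrow(x@signals)) - 1) * 1000 / x@sampleRate)

#' @rdname accessors
#' @export
setMethod("recordDuration", "ECGRecord", function(x)
  nrow(x@signals) * 1000 / x@sampleRate)

#' @rdname accessors
#' @export
setMethod("isNormalized", "ECGRecord", function(x) x@normalized)

#' @rdname accessors
#' @export
setMethod("channelLabel", "BeatAnnotation", function(x) x@channel)

#' @rdname accessors
#' @export
setMethod("peakIndices", "BeatAnnotation", function(x) x@peakIndices)

#' @rdname accessors
#' @export
setMethod("beatTimes", "BeatAnnotation", function(x) x@peakTimes)

#' @rdname accessors
#' @export
setMethod("beatTimes", "RRSeries", function(x) x@beatTimes)

#' @rdname accessors
#' @export
setMethod("beatTimes", "GroundTruth", function(x) x@beatTimes)

#' @rdname accessors
#' @export
setMethod("rrIntervals", "RRSeries", function(x) x@rr)

#' @rdname accessors
#' @export
setMethod("rrIntervals", "GroundTruth", function(x) x@rr)

#' @rdname accessors
#' @export
setMethod("rrValid", "RRSeries", function(x) x@valid)

#' @rdname accessors
#' @export
setMethod("isUsable", "RRSeries", function(x) x@usable)

#' @rdname accessors
#' @export
setMethod("epochs", "EpochSchedule", function(x) x@epochs)

#' @rdname accessors
#' @export
setMethod("epochLabels", "GroundTruth", function(x) x@epoch)

#' @rdname accessors
#' @export
setMethod("metrics", "HRVSummary", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("qualityWindows", "ChannelQuality", function(x) x@windows)

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord: %d channel(s) x %d samples @ %g Hz (%.1f s)%s\n",
              ncol(object@signals), nrow(object@signals), object@sampleRate,
              nrow(object@signals) / object@sampleRate,
              if (object@normalized) ", normalized" else ""))
  if (ncol(object@signals))
    cat("  channels:", paste(colnames(object@signals), collapse = ", "), "\n")
})

setMethod("show", "EpochSchedule", function(object) {
  e <- object@epochs
  cat(sprintf("EpochSchedule: %d epoch(s), %d trial(s)\n", nrow(e),
              length(unique(e$trial))))
  if (nrow(e)) {
    tab <- table(e$label)
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "BeatAnnotation", function(object) {
  n <- length(object@peakTimes)
  cat(sprintf("BeatAnnotation: %d peak(s) on channel '%s'\n", n, object@channel))
  if (n > 1)
    cat(sprintf("  span %.1f s, median RR %.1f ms\n",
                diff(range(object@peakTimes)) / 1000,
                stats::median(diff(object@peakTimes))))
})

setMethod("show", "RRSeries", function(object) {
  cat(sprintf("RRSeries: %d beats, %d interval(s) (%d valid)%s\n",
              length(object@beatTimes), length(object@rr), sum(object@valid),
              if (!object@usable) " [unusable]" else ""))
  if (any(object@valid))
    cat(sprintf("  valid NN: mean %.1f ms, range [%.1f, %.1f]\n",
                mean(object@rr[object@valid]), min(object@rr[object@valid]),
                max(object@rr[object@valid])))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d beats over %.1f s\n", length(object@beatTimes),
              if (length(object@beatTimes)) diff(range(object@beatTimes)) / 1000 else 0))
  if (length(object@epoch)) {
    tab <- table(object@epoch)
    cat(" ", paste(sprintf("%s: %d beats", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "ChannelQuality", function(object) {
  w <- object@windows
  cat(sprintf("ChannelQuality '%s': %d window(s), %d usable\n",
              object@channel, nrow(w), sum(w$usable)))
})

setMethod("show", "HRVSummary", function(object) {
  cat(sprintf("HRVSummary [%s / %s, trial %s]: %d beats\n",
              object@epochLabel, object@modality,
              ifelse(is.na(object@trial), "-", object@trial), object@nBeats))
  m <- object@metrics
  lab <- hrvMetricLabels()
  for (k in names(m))
    cat(sprintf("  %-16s %s\n", lab[[k]],
                ifelse(is.na(m[[k]]), "undefined", format(m[[k]], digits = 4))))
})

#' Flatten HRV summaries into a data.frame
#'
#' One row per summary with the metric columns plus \code{epoch},
#' \code{modality}, \code{trial} and \code{n_beats}; the long-format input to
#' [sequentialAnalysis()] and [modalityAgreement()].
#'
#' @param summaries a list of [HRVSummary-class] objects.
#' @return data.frame with one row per summary.
#' @export
summariesTable <- function(summaries) {
  if (inherits(summaries, "HRVSummary")) summaries <- list(summaries)
  stopifnot(all(vapply(summaries, is, logical(1), "HRVSummary")))
  rows <- lapply(summaries, function(s) {
    data.frame(epoch = s@epochLabel, modality = s@modality, trial = s@trial,
               n_beats = s@nBeats, t(s@metrics), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
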