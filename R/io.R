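# On-disk formats: comma-separated, "." decimal, UTF-8, mandatory header.
# Times are milliseconds everywhere on disk; sample indices are 0-based.

fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.12g", v)
  }, character(1))
  out
}

#' Write a multi-channel ECG record to CSV
#'
#' Columns are \code{time_ms} followed by one column per channel label.
#'
#' @param record an [ECGRecord-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecord <- function(record, path) {
  stopifnot(is(record, "ECGRecord"))
  df <- data.frame(time_ms = sampleTimes(record), record@signals,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-channel ECG record from CSV
#'
#' Expects a header \code{time_ms,<label1>,<label2>,...} and a strictly
#' monotone, uniformly sampled time column (maximum deviation from the median
#' sample period below half a period). Malformed input is rejected, never
#' silently coerced.
#'
#' @param path CSV file path.
#' @param expected_rate optional sampling rate in Hz; inferred from the
#'   median time step when omitted.
#' @return An [ECGRecord-class].
#' @export
readRecord <- function(path, expected_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_ms" %in% names(df) || ncol(df) < 2)
    stop(sprintf("%s: header must be time_ms,<label1>,... ", path))
  t <- df$time_ms
  if (anyNA(t) || anyNA(as.matrix(df)))
    stop(sprintf("%s: missing values at line %d", path,
                 which(!stats::complete.cases(df))[1] + 1L))
  if (length(t) < 2)
    stop(sprintf("%s: need at least 2 samples", path))
  dt <- diff(t)
  if (any(dt <= 0))
    stop(sprintf("%s: time column not strictly increasing at line %d",
                 path, which(dt <= 0)[1] + 2L))
  period <- if (is.null(expected_rate)) stats::median(dt) else 1000 / expected_rate
  if (max(abs(dt - period)) >= period / 2)
    stop(sprintf("%s: non-uniform sampling (time step deviates from %g ms at line %d)",
                 path, period, which.max(abs(dt - period)) + 2L))
  sig <- as.matrix(df[, setdiff(names(df), "time_ms"), drop = FALSE])
  ECGRecord(sig, sampleRate = 1000 / period, t0 = t[1])
}

#' Write an epoch schedule to CSV
#'
#' @param schedule an [EpochSchedule-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "EpochSchedule"))
  utils::write.csv(epochs(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epoch schedule from CSV
#'
#' Expects columns \code{label,start_ms,end_ms,trial}. Overlapping epochs and
#' unknown labels are rejected (the allowed labels are \code{stimulation},
#' \code{washout}, \code{baseline}); the result is sorted by start time.
#'
#' @param path CSV file path.
#' @return An [EpochSchedule-class].
#' @export
readSchedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("label", "start_ms", "end_ms", "trial")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: schedule must have columns %s", path,
                 paste(need, collapse = ",")))
  EpochSchedule(df$label, df$start_ms, df$end_ms, df$trial)
}

#' Write R-peak annotations to CSV
#'
#' Columns \code{channel,sample_index,time_ms}; one or several channels per
#' file. An empty annotation yields a header-only file.
#'
#' @param ann a [BeatAnnotation-class] or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(ann, path) {
  if (is(ann, "BeatAnnotation")) ann <- list(ann)
  stopifnot(all(vapply(ann, is, logical(1), "BeatAnnotation")))
  rows <- lapply(ann, function(a)
    data.frame(channel = rep(channelLabel(a), length(beatTimes(a))),
               sample_index = peakIndices(a), time_ms = beatTimes(a)))
  df <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("channel,sample_index,time_ms", con)
  if (!is.null(df) && nrow(df))
    writeLines(paste(df$channel, fmtNum(df$sample_index), fmtNum(df$time_ms),
                     sep = ","), con)
  invisible(path)
}

#' Read R-peak annotations from CSV
#'
#' @param path CSV with columns \code{channel,sample_index,time_ms}.
#' @return A named list of [BeatAnnotation-class], one per channel.
#' @export
readAnnotations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("channel", "sample_index", "time_ms")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: annotations must have columns %s", path,
                 paste(need, collapse = ",")))
  chans <- unique(df$channel)
  out <- lapply(chans, function(ch) {
    d <- df[df$channel == ch, , drop = FALSE]
    BeatAnnotation(ch, peakTimes = d$time_ms, peakIndices = d$sample_index)
  })
  names(out) <- chans
  out
}

#' Write an RR interval series to CSV
#'
#' One row per beat with columns \code{beat_time_ms,rr_ms,valid}; the
#' interval columns refer to the interval ending at that beat, so the first
#' row's interval fields are empty.
#'
#' @param rr an [RRSeries-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRRSeries <- function(rr, path) {
  stopifnot(is(rr, "RRSeries"))
  n <- length(beatTimes(rr))
  df <- data.frame(beat_time_ms = fmtNum(beatTimes(rr)),
                   rr_ms = c("", fmtNum(rrIntervals(rr))),
                   valid = c("", as.character(as.integer(rrValid(rr)))))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("beat_time_ms,rr_ms,valid", con)
  if (n) writeLines(paste(df$beat_time_ms, df$rr_ms, df$valid, sep = ","), con)
  invisible(path)
}

#' Read an RR interval series from CSV
#'
#' @param path CSV produced by [writeRRSeries()].
#' @return An [RRSeries-class].
#' @export
readRRSeries <- function(path) {
  df <- utils::read.csv(path)
  need <- c("beat_time_ms", "rr_ms", "valid")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: RR series must have columns %s", path,
                 paste(need, collapse = ",")))
  if (!nrow(df)) return(rrSeries(numeric(0)))
  rrSeries(df$beat_time_ms, valid = as.logical(df$valid[-1]))
}

#' Write simulator ground truth to CSV
#'
#' Columns \code{beat_time_ms,rr_ms,epoch_label}; the interval column refers
#' to the interval ending at that beat.
#'
#' @param truth a [GroundTruth-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("beat_time_ms,rr_ms,epoch_label", con)
  n <- length(beatTimes(truth))
  if (n) writeLines(paste(fmtNum(beatTimes(truth)),
                          c("", fmtNum(rrIntervals(truth))),
                          epochLabels(truth), sep = ","), con)
  invisible(path)
}

#' Read simulator ground truth from CSV
#'
#' @param path CSV produced by [writeGroundTruth()].
#' @return A [GroundTruth-class].
#' @export
readGroundTruth <- function(path) {
  df <- utils::read.csv(path)
  need <- c("beat_time_ms", "rr_ms", "epoch_label")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: ground truth must have columns %s", path,
                 paste(need, collapse = ",")))
  t <- df$beat_time_ms
  new("GroundTruth", beatTimes = t,
      rr = if (length(t) > 1) diff(t) else numeric(0),
      epoch = as.character(df$epoch_label))
}

#' Write per-epoch HRV summaries to CSV
#'
#' One row per (epoch, trial, modality) with one column per metric, labelled
#' by the report names of [hrvMetricLabels()] ("Mean RR" ... "DFA Alpha
#' Ratio"). Undefined metrics are written as empty cells, never zeros.
#'
#' @param summaries a list of [HRVSummary-class] or the data.frame from
#'   [summariesTable()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSummaries <- function(summaries, path) {
  df <- if (is.data.frame(summaries)) summaries else summariesTable(summaries)
  lab <- hrvMetricLabels()
  out <- df[, c("epoch", "modality", "trial", "n_beats")]
  for (k in hrvMetricNames()) out[[lab[[k]]]] <- df[[k]]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  for (i in seq_len(nrow(out)))
    writeLines(paste(c(out$epoch[i], out$modality[i], out$trial[i],
                       out$n_beats[i],
                       fmtNum(unlist(out[i, -(1:4)]))), collapse = ","), con)
  invisible(path)
}

#' Read per-epoch HRV summaries from CSV
#'
#' @param path CSV produced by [writeSummaries()].
#' @return data.frame in the layout of [summariesTable()] (internal metric
#'   keys as columns).
#' @export
readSummaries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lab <- hrvMetricLabels()
  if (!all(c("epoch", "modality", "trial", "n_beats", lab) %in% names(df)))
    stop(sprintf("%s: not a summaries table (missing metric columns)", path))
  out <- df[, c("epoch", "modality", "trial", "n_beats")]
  for (k in hrvMetricNames()) out[[k]] <- as.numeric(df[[lab[[k]]]])
  out
}
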