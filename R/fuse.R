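# Multi-lead integration: beat trains detected independently on each channel
# are compared and averaged into one aggregate RR series; windowed quality
# gating falls back to a single channel when a sensor drops out mid-session.

#' Windowed quality assessment of a detected channel
#'
#' Splits the record into fixed windows (default 30 s) and computes, per
#' window, the detected beat count relative to the minimum plausible count at
#' the low end of the heart-rate range (\code{window * hr_range[1] / 60000}
#' beats). Coverage is capped at 1; a window is usable when its coverage
#' reaches \code{threshold}. Windowing keeps a mid-recording sensor loss
#' local: only the affected windows trigger single-channel fallback.
#'
#' @param ann a [BeatAnnotation-class].
#' @param record_duration_ms record length in ms.
#' @param hr_range plausible heart-rate range in BPM.
#' @param window_ms window length in ms; a window longer than the record
#'   yields a single window.
#' @param threshold minimum coverage for a window to count as usable.
#' @return A [ChannelQuality-class].
#' @export
channelQuality <- function(ann, record_duration_ms, hr_range = c(200, 500),
                           window_ms = 30000, threshold = 0.5) {
  stopifnot(is(ann, "BeatAnnotation"), record_duration_ms > 0, window_ms > 0)
  if (window_ms > record_duration_ms) window_ms <- record_duration_ms
  starts <- seq(0, record_duration_ms, by = window_ms)
  starts <- starts[record_duration_ms - starts > 1e-6]
  ends <- pmin(starts + window_ms, record_duration_ms)
  bt <- beatTimes(ann)
  nb <- vapply(seq_along(starts), function(i)
    sum(bt >= starts[i] & bt < ends[i]), numeric(1))
  expected <- (ends - starts) * hr_range[1] / 60000
  cov <- pmin(nb / expected, 1)
  new("ChannelQuality", channel = channelLabel(ann),
      windows = data.frame(start_ms = starts, end_ms = ends, nBeats = nb,
                           coverage = cov, usable = cov >= threshold))
}

#' Match two beat trains
#'
#' Greedy chronological one-to-one matching: walking both trains in time
#' order, the nearest pair within tolerance is matched (with a one-step
#' lookahead so a peak is not paired when its partner lies closer to the next
#' peak); each peak is used at most once. The default tolerance of 30 ms is
#' below half the minimum rodent RR interval, so distinct beats cannot be
#' confused. The procedure is symmetric in its two arguments.
#'
#' @param ann_a,ann_b [BeatAnnotation-class] objects (empty inputs allowed).
#' @param tol_ms matching tolerance in ms.
#' @return A list with \code{pairs} (data.frame \code{time_a}, \code{time_b},
#'   \code{offset}), and vectors \code{unmatched_a}, \code{unmatched_b} of
#'   unmatched peak times.
#' @export
#' @examples
#' a <- BeatAnnotation("ear_left", c(100, 250, 400))
#' b <- BeatAnnotation("ear_right", c(110, 260, 410))
#' matchBeats(a, b)$pairs
matchBeats <- function(ann_a, ann_b, tol_ms = 30) {
  stopifnot(is(ann_a, "BeatAnnotation"), is(ann_b, "BeatAnnotation"),
            tol_ms > 0)
  a <- beatTimes(ann_a); b <- beatTimes(ann_b)
  na <- length(a); nb <- length(b)
  ia <- integer(0); ib <- integer(0)
  i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    d <- b[j] - a[i]
    if (abs(d) <= tol_ms) {
      if (d > 0 && i < na && abs(b[j] - a[i + 1]) < d) {
        i <- i + 1L                       # b_j belongs to the next a peak
      } else if (d < 0 && j < nb && abs(a[i] - b[j + 1]) < -d) {
        j <- j + 1L                       # a_i belongs to the next b peak
      } else {
        ia <- c(ia, i); ib <- c(ib, j)
        i <- i + 1L; j <- j + 1L
      }
    } else if (b[j] < a[i]) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(pairs = data.frame(time_a = a[ia], time_b = b[ib],
                          offset = b[ib] - a[ia]),
       unmatched_a = a[setdiff(seq_len(na), ia)],
       unmatched_b = b[setdiff(seq_len(nb), ib)])
}

#' Fuse per-channel beat trains into one aggregate RR series
#'
#' Within windows where both channels are usable, the fused beat time is the
#' arithmetic mean of each matched pair's times (averaging times rather than
#' intervals keeps the fused series a genuine point process); beats seen by
#' only one of two usable channels are dropped as likely artifacts. Within
#' windows where a single channel is usable — the sensor-loss fallback — that
#' channel's beats pass through unchanged. Windows with no usable channel are
#' excluded with a message. The fused beat train is then converted to RR
#' intervals and artifact-screened with [rejectArtifacts()].
#'
#' @param anns list of one or two [BeatAnnotation-class] objects.
#' @param quality list of [ChannelQuality-class], parallel to \code{anns} and
#'   built on a common window grid; computed with [channelQuality()] defaults
#'   when omitted.
#' @param record_duration_ms record length in ms (needed when \code{quality}
#'   is omitted).
#' @param tol_ms beat-matching tolerance in ms.
#' @param physio_range,jump_frac artifact-screening parameters, passed to
#'   [rejectArtifacts()].
#' @return The fused, screened [RRSeries-class].
#' @export
aggregateBeats <- function(anns, quality = NULL, record_duration_ms = NULL,
                           tol_ms = 30, physio_range = c(120, 300),
                           jump_frac = 0.3) {
  if (is(anns, "BeatAnnotation")) anns <- list(anns)
  stopifnot(length(anns) %in% 1:2,
            all(vapply(anns, is, logical(1), "BeatAnnotation")))
  if (is.null(quality)) {
    if (is.null(record_duration_ms))
      record_duration_ms <- max(unlist(lapply(anns, beatTimes)), 0) + 1
    quality <- lapply(anns, channelQuality,
                      record_duration_ms = record_duration_ms)
  }
  stopifnot(length(quality) == length(anns),
            all(vapply(quality, is, logical(1), "ChannelQuality")))

  if (length(anns) == 1) {
    fused <- beatTimes(anns[[1]])
    w <- qualityWindows(quality[[1]])
    keep <- rep(FALSE, length(fused))
    for (i in which(w$usable))
      keep <- keep | (fused >= w$start_ms[i] & fused < w$end_ms[i])
    fused <- fused[keep]
  } else {
    wa <- qualityWindows(quality[[1]])
    wb <- qualityWindows(quality[[2]])
    if (!isTRUE(all.equal(wa$start_ms, wb$start_ms)))
      stop("quality objects must share a common window grid")
    m <- matchBeats(anns[[1]], anns[[2]], tol_ms)
    pair_t <- (m$pairs$time_a + m$pairs$time_b) / 2
    ta <- beatTimes(anns[[1]]); tb <- beatTimes(anns[[2]])
    fused <- numeric(0)
    dropped <- 0L
    for (i in seq_len(nrow(wa))) {
      ws <- wa$start_ms[i]; we <- wa$end_ms[i]
      au <- wa$usable[i]; bu <- wb$usable[i]
      if (au && bu) {
        fused <- c(fused, pair_t[pair_t >= ws & pair_t < we])
        dropped <- dropped +
          sum(m$unmatched_a >= ws & m$unmatched_a < we) +
          sum(m$unmatched_b >= ws & m$unmatched_b < we)
      } else if (au) {
        fused <- c(fused, ta[ta >= ws & ta < we])
      } else if (bu) {
        fused <- c(fused, tb[tb >= ws & tb < we])
      } else {
        message(sprintf("window [%g, %g) ms has no usable channel; excluded",
                        ws, we))
      }
    }
    if (dropped)
      message(sprintf("%d beat(s) unmatched across usable channels dropped",
                      dropped))
  }

  fused <- sort(fused)
  # collapse duplicates of the same physical beat at window transitions
  if (length(fused) > 1)
    fused <- fused[c(TRUE, diff(fused) > tol_ms)]
  rejectArtifacts(rrSeries(fused), physio_range = physio_range,
                  jump_frac = jump_frac)
}
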