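# Epoch segmentation and the two statistical comparisons: paired
# stimulation-vs-washout sequential effects (S - W diffs, paired t, Cohen's
# d_z) and independent (Welch) modality-agreement tests. Two-sided tests
# throughout; no multiple-testing correction by default, matching per-metric
# reporting (a Holm correction can be switched on).

#' Split an RR series by epoch schedule
#'
#' An interval belongs to an epoch exactly when both of its bounding beats
#' lie inside the half-open window \code{[start_ms, end_ms)}; intervals that
#' span an epoch boundary belong to no epoch. Validity flags are carried
#' over.
#'
#' @param rr an [RRSeries-class].
#' @param schedule an [EpochSchedule-class].
#' @return A list with one element per epoch, each a list with \code{epoch}
#'   (label), \code{trial} and \code{rr} (the per-epoch [RRSeries-class];
#'   empty and unusable when fewer than 2 beats fall inside).
#' @export
segmentEpochs <- function(rr, schedule) {
  stopifnot(is(rr, "RRSeries"), is(schedule, "EpochSchedule"))
  e <- epochs(schedule)
  bt <- beatTimes(rr)
  v <- rrValid(rr)
  out <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    inside <- which(bt >= e$start_ms[i] & bt < e$end_ms[i])
    if (length(inside) < 2) {
      message(sprintf("epoch %s (trial %d) holds < 2 beats; empty series",
                      e$label[i], e$trial[i]))
      sub <- rrSeries(bt[inside])
    } else {
      sub <- rrSeries(bt[inside], valid = v[inside[-length(inside)]])
    }
    out[[i]] <- list(epoch = e$label[i], trial = e$trial[i], rr = sub)
  }
  names(out) <- paste(e$label, e$trial, sep = "_")
  out
}

#' Per-epoch HRV summaries for one modality
#'
#' Segments the series with [segmentEpochs()] and computes a
#' [computeSummary()] for every epoch.
#'
#' @param rr an [RRSeries-class] covering the whole session.
#' @param schedule an [EpochSchedule-class].
#' @param modality modality label stored in the summaries (e.g. \code{chest},
#'   \code{ear}).
#' @param ... further arguments passed to [computeSummary()].
#' @return A list of [HRVSummary-class], one per epoch.
#' @export
epochSummaries <- function(rr, schedule, modality = NA_character_, ...) {
  segs <- segmentEpochs(rr, schedule)
  lapply(segs, function(s)
    computeSummary(s$rr, epoch_label = s$epoch, modality = modality,
                   trial = s$trial, ...))
}

powerLabel <- function(d) {
  ifelse(is.na(d), NA_character_,
         ifelse(abs(d) > 0.8, "large",
                ifelse(abs(d) > 0.5, "medium", "small")))
}

asSummariesDF <- function(summaries) {
  if (is.data.frame(summaries)) summaries else summariesTable(summaries)
}

#' Paired stimulation-vs-washout sequential analysis
#'
#' For every metric, each stimulation epoch is paired with the subsequent
#' washout epoch of the same trial and the differences \code{d_i = S_i -
#' W_i} are tested with a two-sided paired t-test. The effect size is the
#' paired-data Cohen's \code{d_z = |mean(d)| / sd(d)} (sample SD), labelled
#' \code{large} when \code{|d| > 0.8} and \code{medium} when \code{|d| >
#' 0.5}. Zero spread of the differences leaves both \code{d} and \code{p}
#' undefined.
#'
#' @param summaries per-epoch summaries of one modality: a list of
#'   [HRVSummary-class] or a [summariesTable()] data.frame.
#' @param p_adjust multiple-testing correction method passed to
#'   [stats::p.adjust()]; \code{"none"} (default) matches per-metric
#'   reporting.
#' @return data.frame with one row per metric: \code{metric}, \code{kind},
#'   \code{mean_delta} (S - W, in the metric's units), \code{cohens_d},
#'   \code{p_value}, \code{n_pairs}, \code{power_label}.
#' @export
sequentialAnalysis <- function(summaries, p_adjust = "none") {
  df <- asSummariesDF(summaries)
  s <- df[df$epoch == "stimulation", , drop = FALSE]
  w <- df[df$epoch == "washout", , drop = FALSE]
  trials <- intersect(s$trial, w$trial)
  if (length(trials) < 2)
    stop("need >= 2 stimulation/washout pairs for the sequential analysis")
  rows <- lapply(intersect(hrvMetricNames(), names(df)), function(k) {
    d <- vapply(trials, function(tr)
      s[[k]][match(tr, s$trial)] - w[[k]][match(tr, w$trial)], numeric(1))
    d <- d[!is.na(d)]
    if (length(d) < 2)
      return(data.frame(metric = k, kind = "sequential", mean_delta = NA_real_,
                        cohens_d = NA_real_, p_value = NA_real_,
                        n_pairs = length(d), power_label = NA_character_))
    sdd <- stats::sd(d)
    if (sdd == 0) {
      cd <- NA_real_; p <- NA_real_
    } else {
      cd <- abs(mean(d)) / sdd
      p <- stats::t.test(d)$p.value
    }
    data.frame(metric = k, kind = "sequential", mean_delta = mean(d),
               cohens_d = cd, p_value = p, n_pairs = length(d),
               power_label = powerLabel(cd))
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Independent-sample modality agreement tests
#'
#' For every metric, the per-epoch values of the two modalities are compared
#' with a two-sided independent t-test in the Welch (unequal-variance) form,
#' pooling epochs across trials. A non-significant p indicates
#' cross-platform fidelity between the chest and in-ear recordings. The test
#' is symmetric in its two arguments.
#'
#' @param summaries_a,summaries_b per-epoch summaries of the two modalities
#'   (lists of [HRVSummary-class] or [summariesTable()] data.frames), each
#'   with at least 2 defined values per metric; metrics with fewer are
#'   skipped with a message.
#' @param p_adjust multiple-testing correction method (default
#'   \code{"none"}).
#' @return data.frame with one row per metric: \code{metric}, \code{kind},
#'   \code{mean_delta} (mean A - mean B), \code{cohens_d} (pooled-SD form),
#'   \code{p_value}, \code{n_pairs} (min group size), \code{power_label}.
#' @export
modalityAgreement <- function(summaries_a, summaries_b, p_adjust = "none") {
  a <- asSummariesDF(summaries_a)
  b <- asSummariesDF(summaries_b)
  shared <- intersect(intersect(hrvMetricNames(), names(a)), names(b))
  rows <- lapply(shared, function(k) {
    x <- a[[k]][!is.na(a[[k]])]
    y <- b[[k]][!is.na(b[[k]])]
    if (length(x) < 2 || length(y) < 2) {
      message(sprintf("metric %s: < 2 defined values in a modality; skipped", k))
      return(data.frame(metric = k, kind = "modality_agreement",
                        mean_delta = NA_real_, cohens_d = NA_real_,
                        p_value = NA_real_, n_pairs = min(length(x), length(y)),
                        power_label = NA_character_))
    }
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
    cd <- if (sp > 0) abs(mean(x) - mean(y)) / sp else NA_real_
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else NA_real_
    } else {
      stats::t.test(x, y, var.equal = FALSE)$p.value
    }
    data.frame(metric = k, kind = "modality_agreement",
               mean_delta = mean(x) - mean(y), cohens_d = cd, p_value = p,
               n_pairs = min(length(x), length(y)),
               power_label = powerLabel(cd))
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  rownames(out) <- NULL
  out
}
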