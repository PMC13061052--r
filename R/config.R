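# YAML configuration and the end-to-end pipeline:
# simulate -> preprocess -> detect -> fuse -> hrv -> stats -> report.

#' Default analysis parameters
#'
#' All tunables of the detection/fusion/HRV chain with their defaults: the
#' 10-200 Hz preprocessing band, the rodent 200-500 BPM heart-rate range and
#' its 120-300 ms interval counterpart, the 0.3 jump fraction of artifact
#' screening, the 30 ms beat-matching tolerance, the 30 s quality window with
#' 0.5 coverage threshold, the 5 ms PNNx threshold, rat LF (0.2-0.75 Hz) and
#' HF (0.75-3 Hz) bands with 20 Hz tachogram resampling, sample-entropy
#' parameters (m = 2, r = 0.2 SD) and DFA box ranges (4-16, 16-64 beats).
#'
#' @return Named list of parameters.
#' @export
analysisDefaults <- function() {
  list(band = c(10, 200), hr_range = c(200, 500),
       physio_range = c(120, 300), jump_frac = 0.3,
       tol_ms = 30, window_ms = 30000, quality_threshold = 0.5,
       pnn_threshold_ms = 5, lf_band = c(0.2, 0.75), hf_band = c(0.75, 3),
       resample_hz = 20, m = 2, r_frac = 0.2,
       a1_scales = c(4, 16), a2_scales = c(16, 64))
}

#' Read a study configuration from YAML
#'
#' The file may hold a \code{simulate} section (arguments of [simConfig()];
#' \code{channel_noise} as a mapping of channel label to noise SD,
#' \code{dropout_windows} as a list of \code{channel/start_ms/end_ms}
#' mappings) and an \code{analysis} section overriding any entry of
#' [analysisDefaults()].
#'
#' @param path YAML file path.
#' @return List with elements \code{simulate} (a \code{SimConfig} or
#'   \code{NULL}) and \code{analysis} (full parameter list).
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    args <- cfg$simulate
    if (!is.null(args$channel_noise))
      args$channel_noise <- unlist(args$channel_noise)
    sim <- do.call(simConfig, args)
  }
  ana <- analysisDefaults()
  for (k in names(cfg$analysis)) {
    if (!k %in% names(ana))
      stop(sprintf("unknown analysis parameter '%s'", k))
    ana[[k]] <- unlist(cfg$analysis[[k]])
  }
  list(simulate = sim, analysis = ana)
}

#' Run the full analysis pipeline on a record
#'
#' Preprocesses the record, detects R-peaks independently on every channel,
#' assesses windowed channel quality, fuses the in-ear channels (labels
#' starting with \code{ear}) into the \code{ear} modality and screens the
#' chest channel (label starting with \code{chest}) as the \code{chest}
#' modality, computes per-epoch HRV summaries for both, and runs the paired
#' sequential analysis per modality plus the chest-vs-ear modality agreement
#' tests.
#'
#' @param record an [ECGRecord-class].
#' @param schedule an [EpochSchedule-class].
#' @param analysis parameter list as from [analysisDefaults()].
#' @param out_dir optional report directory; when given, [buildReport()]
#'   writes tables and figures there.
#' @return List with \code{annotations} (per channel), \code{quality} (per
#'   channel), \code{rr} (fused [RRSeries-class] per modality),
#'   \code{summaries} (per-epoch [HRVSummary-class] list), \code{sequential}
#'   (per-modality comparison tables), \code{agreement} (chest-vs-ear table)
#'   and \code{report} (paths written, or \code{NULL}).
#' @export
#' @examples
#' study <- generateStudy(simConfig(duration_s = 240, n_trials = 2))
#' res <- analyzeStudy(study$record, study$schedule)
#' res$sequential$chest[res$sequential$chest$metric == "mean_rr", ]
analyzeStudy <- function(record, schedule, analysis = analysisDefaults(),
                         out_dir = NULL) {
  stopifnot(is(record, "ECGRecord"), is(schedule, "EpochSchedule"))
  pre <- preprocessRecord(record, analysis$band)
  dur <- recordDuration(pre)
  chans <- channelLabels(pre)
  ear_ch <- chans[startsWith(chans, "ear")]
  chest_ch <- chans[startsWith(chans, "chest")]
  if (!length(chest_ch) && !length(ear_ch))
    stop("record holds no 'ear*' or 'chest*' channels")

  anns <- lapply(chans, function(ch)
    detectRPeaks(pre, ch, hr_range = analysis$hr_range))
  names(anns) <- chans
  qual <- lapply(anns, channelQuality, record_duration_ms = dur,
                 hr_range = analysis$hr_range, window_ms = analysis$window_ms,
                 threshold = analysis$quality_threshold)

  rr <- list()
  if (length(chest_ch))
    rr$chest <- aggregateBeats(anns[chest_ch[1]], qual[chest_ch[1]],
                               tol_ms = analysis$tol_ms,
                               physio_range = analysis$physio_range,
                               jump_frac = analysis$jump_frac)
  if (length(ear_ch))
    rr$ear <- aggregateBeats(anns[ear_ch], qual[ear_ch],
                             tol_ms = analysis$tol_ms,
                             physio_range = analysis$physio_range,
                             jump_frac = analysis$jump_frac)

  summaries <- list()
  for (md in names(rr))
    summaries <- c(summaries,
                   epochSummaries(rr[[md]], schedule, modality = md,
                                  pnn_threshold_ms = analysis$pnn_threshold_ms,
                                  lf_band = analysis$lf_band,
                                  hf_band = analysis$hf_band,
                                  resample_hz = analysis$resample_hz,
                                  m = analysis$m, r_frac = analysis$r_frac,
                                  a1_scales = analysis$a1_scales,
                                  a2_scales = analysis$a2_scales))
  df <- summariesTable(summaries)
  sequential <- lapply(stats::setNames(names(rr), names(rr)), function(md)
    tryCatch(sequentialAnalysis(df[df$modality == md, , drop = FALSE]),
             error = function(e) {
               message("sequential analysis skipped: ", conditionMessage(e))
               NULL
             }))
  agreement <- if (all(c("chest", "ear") %in% names(rr)))
    modalityAgreement(df[df$modality == "chest", , drop = FALSE],
                      df[df$modality == "ear", , drop = FALSE]) else NULL

  report <- if (!is.null(out_dir))
    buildReport(summaries, rr = rr, record = pre, schedule = schedule,
                out_dir = out_dir, lf_band = analysis$lf_band,
                hf_band = analysis$hf_band) else NULL

  list(annotations = anns, quality = qual, rr = rr, summaries = summaries,
       sequential = sequential, agreement = agreement, report = report)
}
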