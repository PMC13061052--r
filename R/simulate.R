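# Synthetic two-channel rodent ECG with known autonomic structure.
# RR synthesis modulates intervals directly (not via integral pulse frequency
# modulation): ground truth stays exact and the difference is immaterial at
# the modulation depths used here.

#' Simulation configuration for synthetic rodent ECG studies
#'
#' Describes a stimulation/washout study: a rodent RR tachogram with
#' low-frequency (baroreflex-range) and high-frequency (parasympathetic-range)
#' sinusoidal interval modulation, white interval jitter, an additive mean-RR
#' shift during stimulation epochs, and a multi-channel ECG rendering with
#' per-channel waveform noise, baseline wander and optional dropout windows
#' (sensor-out-of-canal faults, rendered as noise only).
#'
#' Defaults describe a 400 BPM rat (mean RR 150 ms, within the physiological
#' 120-300 ms band for 200-500 BPM), 3 ms LF modulation at 0.4 Hz, 3 ms HF
#' modulation at 1.5 Hz, 2 ms white jitter, and waveform noise of 0.1 in
#' R-amplitude units on every channel (peak SNR 20 dB relative to the unit
#' R apex).
#'
#' @param duration_s record duration in seconds.
#' @param mean_rr_ms mean RR interval in ms; 120-300 ms corresponds to the
#'   rodent 200-500 BPM range.
#' @param lf_amp_ms,hf_amp_ms amplitudes (ms) of the LF and HF sinusoidal
#'   interval modulations.
#' @param lf_freq_hz,hf_freq_hz modulation frequencies (Hz); defaults sit in
#'   the conventional rat LF (0.2-0.75 Hz) and HF (0.75-3 Hz) bands.
#' @param noise_sd_ms SD (ms) of white interval jitter.
#' @param stim_delta_rr_ms additive mean-RR shift (ms) during stimulation
#'   epochs.
#' @param n_trials number of stimulation/washout trial pairs.
#' @param stim_len_s,washout_len_s epoch lengths in seconds.
#' @param channel_noise named numeric vector of per-channel waveform noise SD
#'   (in R-amplitude units); names define the channels rendered.
#' @param dropout_windows list of \code{list(channel=, start_ms=, end_ms=)}
#'   describing sensor-loss windows; samples inside are replaced by noise.
#' @param sample_rate_hz ECG sampling rate in Hz (default 1000; must be >=
#'   200 to support millisecond peak localization).
#' @param seed integer seed; identical seeds give identical studies.
#' @return A validated configuration of class \code{SimConfig}.
#' @export
#' @examples
#' cfg <- simConfig(duration_s = 120, n_trials = 1)
#' cfg
simConfig <- function(duration_s = 720, mean_rr_ms = 150,
                      lf_amp_ms = 3, hf_amp_ms = 3,
                      lf_freq_hz = 0.4, hf_freq_hz = 1.5,
                      noise_sd_ms = 2, stim_delta_rr_ms = 0,
                      n_trials = 3, stim_len_s = 60, washout_len_s = 60,
                      channel_noise = c(ear_left = 0.1, ear_right = 0.1,
                                        chest_I = 0.1),
                      dropout_windows = list(),
                      sample_rate_hz = 1000, seed = 1L) {
  cfg <- list(duration_s = duration_s, mean_rr_ms = mean_rr_ms,
              lf_amp_ms = lf_amp_ms, hf_amp_ms = hf_amp_ms,
              lf_freq_hz = lf_freq_hz, hf_freq_hz = hf_freq_hz,
              noise_sd_ms = noise_sd_ms, stim_delta_rr_ms = stim_delta_rr_ms,
              n_trials = as.integer(n_trials), stim_len_s = stim_len_s,
              washout_len_s = washout_len_s, channel_noise = channel_noise,
              dropout_windows = dropout_windows,
              sample_rate_hz = sample_rate_hz, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %.0f s @ %g Hz, mean RR %g ms (%.0f BPM), seed %d\n",
              x$duration_s, x$sample_rate_hz, x$mean_rr_ms,
              60000 / x$mean_rr_ms, x$seed))
  cat(sprintf("  LF %g ms @ %g Hz, HF %g ms @ %g Hz, jitter %g ms\n",
              x$lf_amp_ms, x$lf_freq_hz, x$hf_amp_ms, x$hf_freq_hz,
              x$noise_sd_ms))
  cat(sprintf("  %d trial(s) of %g s stim + %g s washout, stim delta %+g ms\n",
              x$n_trials, x$stim_len_s, x$washout_len_s, x$stim_delta_rr_ms))
  cat(sprintf("  channels: %s; %d dropout window(s)\n",
              paste(sprintf("%s (noise %g)", names(x$channel_noise),
                            x$channel_noise), collapse = ", "),
              length(x$dropout_windows)))
  invisible(x)
}

validateSimConfig <- function(cfg) {
  stopifnot(cfg$duration_s > 0, cfg$mean_rr_ms > 0, cfg$sample_rate_hz > 0,
            cfg$stim_len_s > 0, cfg$washout_len_s > 0, cfg$n_trials >= 1,
            cfg$noise_sd_ms >= 0, cfg$lf_amp_ms >= 0, cfg$hf_amp_ms >= 0)
  if (is.null(names(cfg$channel_noise)) || anyDuplicated(names(cfg$channel_noise)))
    stop("channel_noise must be a named vector with unique channel labels")
  dur_ms <- cfg$duration_s * 1000
  for (w in cfg$dropout_windows) {
    if (!all(c("channel", "start_ms", "end_ms") %in% names(w)))
      stop("each dropout window needs channel, start_ms, end_ms")
    if (!w$channel %in% names(cfg$channel_noise))
      stop(sprintf("dropout window names unknown channel '%s'", w$channel))
    if (w$start_ms < 0 || w$end_ms > dur_ms || w$start_ms >= w$end_ms)
      stop("dropout windows must lie inside the record")
  }
  invisible(TRUE)
}

# Run code under a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build the alternating stimulation/washout schedule of a simulated study
#'
#' @param config a [simConfig()] object.
#' @return An [EpochSchedule-class] with \code{2 * n_trials} alternating
#'   epochs starting at time 0.
#' @export
studySchedule <- function(config) {
  trial_ms <- (config$stim_len_s + config$washout_len_s) * 1000
  if (config$n_trials * trial_ms > config$duration_s * 1000 + 1e-9)
    stop(sprintf("schedule (%g s) exceeds record duration (%g s)",
                 config$n_trials * trial_ms / 1000, config$duration_s))
  starts <- (seq_len(config$n_trials) - 1) * trial_ms
  EpochSchedule(
    label = rep(c("stimulation", "washout"), config$n_trials),
    start_ms = as.vector(rbind(starts, starts + config$stim_len_s * 1000)),
    end_ms = as.vector(rbind(starts + config$stim_len_s * 1000, starts + trial_ms)),
    trial = rep(seq_len(config$n_trials), each = 2))
}

epochLabelAt <- function(times_ms, schedule) {
  lab <- rep("baseline", length(times_ms))
  if (is.null(schedule)) return(lab)
  e <- epochs(schedule)
  for (i in seq_len(nrow(e))) {
    inside <- times_ms >= e$start_ms[i] & times_ms < e$end_ms[i]
    lab[inside] <- e$label[i]
  }
  lab
}

#' Generate the ground-truth RR tachogram of a simulated study
#'
#' Beats are placed sequentially from time 0: each interval is the configured
#' mean RR, plus the stimulation shift when the beat falls inside a
#' stimulation epoch, plus LF and HF sinusoids (random phases drawn from the
#' seeded generator) and white jitter:
#' \deqn{RR_i = \bar{RR} + \Delta \cdot 1[stim](t_i)
#'       + A_{LF}\sin(2\pi f_{LF} t_i + \phi_{LF})
#'       + A_{HF}\sin(2\pi f_{HF} t_i + \phi_{HF})
#'       + \sigma \epsilon_i.}
#'
#' @param config a [simConfig()] object.
#' @param schedule optional [EpochSchedule-class]; defaults to
#'   [studySchedule()] when the configured stimulation shift is non-zero,
#'   otherwise no schedule (all beats labelled \code{baseline}).
#' @return A [GroundTruth-class] with exact beat times, intervals and
#'   per-beat epoch labels.
#' @export
#' @examples
#' truth <- generateTachogram(simConfig(duration_s = 60, n_trials = 1,
#'                                      stim_len_s = 30, washout_len_s = 30))
#' truth
generateTachogram <- function(config, schedule = NULL) {
  validateSimConfig(config)
  if (is.null(schedule) && config$stim_delta_rr_ms != 0)
    schedule <- studySchedule(config)
  dur_ms <- config$duration_s * 1000
  stim <- if (is.null(schedule)) NULL else {
    e <- epochs(schedule)
    e[e$label == "stimulation", c("start_ms", "end_ms"), drop = FALSE]
  }
  withSeed(config$seed, {
    phi_lf <- stats::runif(1, 0, 2 * pi)
    phi_hf <- stats::runif(1, 0, 2 * pi)
    # upper bound on beat count to pre-draw jitter deterministically
    min_rr <- config$mean_rr_ms - abs(config$stim_delta_rr_ms) -
      config$lf_amp_ms - config$hf_amp_ms
    n_max <- ceiling(dur_ms / max(min_rr, 1)) + 10
    eps <- stats::rnorm(n_max)
    t <- numeric(n_max)
    t[1] <- 0
    n <- 1
    repeat {
      ti <- t[n]
      in_stim <- !is.null(stim) &&
        any(ti >= stim$start_ms & ti < stim$end_ms)
      rr <- config$mean_rr_ms +
        config$stim_delta_rr_ms * in_stim +
        config$lf_amp_ms * sin(2 * pi * config$lf_freq_hz * ti / 1000 + phi_lf) +
        config$hf_amp_ms * sin(2 * pi * config$hf_freq_hz * ti / 1000 + phi_hf) +
        config$noise_sd_ms * eps[n]
      if (rr <= 0)
        stop("configuration produced a non-positive RR interval; ",
             "reduce modulation amplitudes or jitter relative to mean RR")
      if (ti + rr > dur_ms) break
      t[n + 1] <- ti + rr
      n <- n + 1
    }
    t <- t[seq_len(n)]
    new("GroundTruth", beatTimes = t,
        rr = if (n > 1) diff(t) else numeric(0),
        epoch = epochLabelAt(t, schedule))
  })
}

# Rodent QRST template: Q, R and T Gaussians; the R apex (unit amplitude,
# ~8 ms wide) is the global extremum of every complex.
qrstTemplate <- function(tau_ms) {
  -0.15 * exp(-0.5 * ((tau_ms + 12) / 3)^2) +
    1.00 * exp(-0.5 * (tau_ms / 3.4)^2) +
    0.25 * exp(-0.5 * ((tau_ms - 25) / 8)^2)
}

#' Render a multi-channel ECG record from a ground-truth beat train
#'
#' Each channel renders a rodent QRST template (three Gaussians; the R apex
#' is the global extremum of each complex) at every true beat time, then adds
#' slow sinusoidal baseline wander (0.3 Hz, amplitude 0.25 of the R apex) and
#' white waveform noise with the configured per-channel SD. Samples inside a
#' channel's dropout windows are replaced by noise alone, emulating a sensor
#' out of the ear canal.
#'
#' @param truth a [GroundTruth-class] from [generateTachogram()].
#' @param config the [simConfig()] used to generate it.
#' @return An [ECGRecord-class] of \code{duration_s * sample_rate_hz} samples
#'   per channel.
#' @export
synthesizeECG <- function(truth, config) {
  validateSimConfig(config)
  if (config$sample_rate_hz < 200)
    stop("sample rate below 200 Hz cannot support millisecond R-peak localization")
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  bt <- beatTimes(truth)
  if (length(bt) && (min(bt) < 0 || max(bt) > config$duration_s * 1000))
    stop("beat times must lie within the configured duration")
  dt <- 1000 / fs
  half <- ceiling(60 / dt)                       # template support +/- 60 ms
  clean <- numeric(n)
  for (b in bt) {
    i0 <- max(1L, floor(b / dt) - half)
    i1 <- min(n, floor(b / dt) + half)
    idx <- i0:i1
    clean[idx] <- clean[idx] + qrstTemplate((idx - 1) * dt - b)
  }
  tsec <- (seq_len(n) - 1) / fs
  withSeed(config$seed + 1L, {
    sigs <- lapply(names(config$channel_noise), function(ch) {
      sd_ch <- config$channel_noise[[ch]]
      wander <- 0.25 * sin(2 * pi * 0.3 * tsec + stats::runif(1, 0, 2 * pi))
      noise <- if (sd_ch > 0) stats::rnorm(n, 0, sd_ch) else numeric(n)
      x <- clean + wander + noise
      for (w in config$dropout_windows) {
        if (w$channel != ch) next
        idx <- which((seq_len(n) - 1) * dt >= w$start_ms &
                     (seq_len(n) - 1) * dt < w$end_ms)
        x[idx] <- noise[idx]                     # signal gone, noise remains
      }
      x
    })
    names(sigs) <- names(config$channel_noise)
    ECGRecord(sigs, sampleRate = fs)
  })
}

#' Generate a complete simulated stimulation/washout study
#'
#' Builds the alternating epoch schedule, the ground-truth tachogram under
#' that schedule, and the rendered multi-channel ECG record.
#'
#' @param config a [simConfig()] object.
#' @return A list with elements \code{record} ([ECGRecord-class]),
#'   \code{schedule} ([EpochSchedule-class]) and \code{truth}
#'   ([GroundTruth-class]).
#' @export
#' @examples
#' study <- generateStudy(simConfig(duration_s = 120, n_trials = 1))
#' study$schedule
generateStudy <- function(config) {
  validateSimConfig(config)
  schedule <- studySchedule(config)
  truth <- generateTachogram(config, schedule)
  record <- synthesizeECG(truth, config)
  list(record = record, schedule = schedule, truth = truth)
}
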