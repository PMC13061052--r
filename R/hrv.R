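# The HRV metric battery: time-domain, spectral and non-linear measures of an
# NN interval series. Conventions that matter:
#  * successive-difference statistics (RMSSD, PNN5, SD1) use only pairs of
#    adjacent intervals that are both valid, so flagged artifacts never leak
#    into them;
#  * the Poincare axes use the uncentered second moment of the successive
#    differences, making sd1 = rmssd/sqrt(2) an exact identity, and the
#    population variance of the intervals, making sd1^2 + sd2^2 = 2*sdnn_pop^2
#    exact (SDNN is reported with the sample convention in summaries);
#  * spectral power integrates a Welch averaged periodogram of the cubic-
#    interpolated, linearly detrended tachogram, in ms^2;
#  * total power is defined as LF + HF.

validNN <- function(rr) rrIntervals(rr)[rrValid(rr)]

# successive differences over pairs of adjacent *valid* intervals
validSuccDiffs <- function(rr) {
  iv <- rrIntervals(rr); v <- rrValid(rr)
  if (length(iv) < 2) return(numeric(0))
  both <- v[-length(v)] & v[-1]
  diff(iv)[both]
}

#' Time-domain HRV metrics
#'
#' Mean RR (ms), mean HR (BPM; the mean of the per-beat instantaneous rate
#' \code{60000/NN}, not \code{60000/mean(NN)}), SDNN (sample SD, ms), RMSSD
#' (ms) and PNNx (%, the share of adjacent valid pairs whose absolute
#' difference strictly exceeds the threshold; the 5 ms default is the rodent
#' analogue of human pNN50, scaled for 200-500 BPM hearts).
#'
#' @param rr an [RRSeries-class].
#' @param pnn_threshold_ms PNNx threshold in ms (default 5).
#' @return Named numeric vector \code{mean_rr}, \code{mean_hr}, \code{sdnn},
#'   \code{rmssd}, \code{pnn5}; metrics whose preconditions fail (fewer than
#'   2 valid intervals for SDNN, fewer than 2 valid successive pairs for
#'   RMSSD/PNNx) are \code{NA}, never 0.
#' @export
#' @examples
#' timeDomain(rrSeries(cumsum(c(0, rep(c(140, 160), 50)))))
timeDomain <- function(rr, pnn_threshold_ms = 5) {
  stopifnot(is(rr, "RRSeries"))
  nn <- validNN(rr)
  d <- validSuccDiffs(rr)
  c(mean_rr = if (length(nn) >= 1) mean(nn) else NA_real_,
    mean_hr = if (length(nn) >= 1) mean(60000 / nn) else NA_real_,
    sdnn = if (length(nn) >= 2) stats::sd(nn) else NA_real_,
    rmssd = if (length(d) >= 2) sqrt(mean(d^2)) else NA_real_,
    pnn5 = if (length(d) >= 2) 100 * mean(abs(d) > pnn_threshold_ms)
           else NA_real_)
}

#' Poincare plot axes SD1 and SD2
#'
#' SD1 (dispersion perpendicular to the identity line of the
#' \code{NN[i+1]} vs \code{NN[i]} scatter) indexes short-term, vagally
#' mediated variability; SD2 (dispersion along it) long-term regulation.
#' Computed as \code{sd1^2 = mean(d^2)/2} over valid successive differences
#' \code{d} (the uncentered convention, so \code{sd1 = rmssd/sqrt(2)}
#' exactly) and \code{sd2^2 = 2*var_pop(NN) - sd1^2}, floored at zero.
#'
#' @param rr an [RRSeries-class] with at least 3 valid intervals.
#' @return Named numeric vector \code{sd1}, \code{sd2}, \code{sd1_sd2}; the
#'   ratio is \code{NA} when \code{sd2 = 0} (e.g. perfect alternans).
#' @export
poincare <- function(rr) {
  stopifnot(is(rr, "RRSeries"))
  nn <- validNN(rr)
  d <- validSuccDiffs(rr)
  if (length(nn) < 3 || length(d) < 2)
    return(c(sd1 = NA_real_, sd2 = NA_real_, sd1_sd2 = NA_real_))
  sd1 <- sqrt(mean(d^2) / 2)
  var_pop <- mean((nn - mean(nn))^2)
  sd2 <- sqrt(max(2 * var_pop - sd1^2, 0))
  c(sd1 = sd1, sd2 = sd2,
    sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

# Welch averaged periodogram (Hann window, 50% overlap), one-sided, scaled so
# that sum(power) * df equals the variance of the input. Returns freq in Hz
# and power density in input-units^2 per Hz.
welchPSD <- function(x, fs, n_segments = 4, min_seg_s = 0) {
  n <- length(x)
  L <- floor(2 * n / (n_segments + 1))
  if (L < 16 || L < min_seg_s * fs) return(NULL)
  step <- floor(L / 2)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  U <- sum(w^2)
  starts <- seq(1, n - L + 1, by = step)
  acc <- numeric(floor(L / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    P <- Mod(X[seq_along(acc)])^2 / (fs * U)
    P[-1] <- 2 * P[-1]
    if (L %% 2 == 0) P[length(P)] <- P[length(P)] / 2
    acc <- acc + P
  }
  data.frame(freq = (seq_along(acc) - 1) * fs / L,
             power = acc / length(starts))
}

#' Spectral HRV metrics (LF, HF, total power, LF/HF)
#'
#' The valid-interval tachogram is cubic-spline interpolated onto a uniform
#' grid (invalid intervals are bridged by the interpolation), linearly
#' detrended, and its power spectral density estimated by a Welch averaged
#' periodogram over at least 4 half-overlapping Hann-windowed segments. LF
#' and HF are the integrated band powers in ms^2; total power is their sum by
#' definition, and LF/HF their ratio. Default bands follow the rodent
#' convention (LF 0.2-0.75 Hz, baroreflex range; HF 0.75-3 Hz,
#' respiratory/parasympathetic range); band edges are half-open
#' \code{[low, high)}.
#'
#' @param rr an [RRSeries-class]; the epoch must span at least ~30 s of valid
#'   beats for the default segmentation.
#' @param lf_band,hf_band band edges in Hz.
#' @param resample_hz tachogram resampling rate in Hz (default 20, an order
#'   of magnitude above the HF band top).
#' @return A list with \code{lf}, \code{hf}, \code{total_power},
#'   \code{lf_hf} and the \code{psd} data.frame (\code{freq}, \code{power});
#'   all-\code{NA} metrics when the epoch is too short for 4 segments.
#' @export
spectralPower <- function(rr, lf_band = c(0.2, 0.75), hf_band = c(0.75, 3),
                          resample_hz = 20) {
  stopifnot(is(rr, "RRSeries"), lf_band[1] < lf_band[2],
            hf_band[1] < hf_band[2], resample_hz > 2 * hf_band[2])
  undefined <- list(lf = NA_real_, hf = NA_real_, total_power = NA_real_,
                    lf_hf = NA_real_, psd = NULL)
  v <- rrValid(rr)
  if (sum(v) < 4) return(undefined)
  tv <- beatTimes(rr)[-1][v] / 1000          # interval end times, s
  rv <- rrIntervals(rr)[v]
  span <- tv[length(tv)] - tv[1]
  if (span <= 0) return(undefined)
  grid <- seq(tv[1], tv[length(tv)], by = 1 / resample_hz)
  y <- stats::splinefun(tv, rv, method = "natural")(grid)
  y <- stats::lm.fit(cbind(1, grid), y)$residuals
  # each segment must also be long enough to resolve the lowest band edge
  psd <- welchPSD(y, resample_hz, n_segments = 4, min_seg_s = 1 / lf_band[1])
  if (is.null(psd)) return(undefined)
  df <- psd$freq[2] - psd$freq[1]
  bandPower <- function(band)
    sum(psd$power[psd$freq >= band[1] & psd$freq < band[2]]) * df
  lf <- bandPower(lf_band)
  hf <- bandPower(hf_band)
  list(lf = lf, hf = hf, total_power = lf + hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_, psd = psd)
}

#' Sample entropy of an NN interval series
#'
#' \code{SampEn(m, r) = -ln(A/B)} where \code{B} counts pairs of length-m
#' templates within Chebyshev distance \code{r} (self-matches excluded) and
#' \code{A} the same for length m+1; both counts run over the \code{N - m}
#' templates of the valid-interval sequence, following the standard
#' definition. Higher values mean a less predictable, more complex rhythm.
#'
#' @param rr an [RRSeries-class]; defined for any series long enough to hold
#'   length-(m+1) templates, though estimates from fewer than ~30 intervals
#'   are statistically unreliable.
#' @param m embedding (template) length, default 2.
#' @param r_frac tolerance as a fraction of the population SD of the valid
#'   intervals, default 0.2.
#' @return The entropy value, or \code{NA} when undefined (too short, or no
#'   template matches at either length).
#' @export
sampleEntropy <- function(rr, m = 2, r_frac = 0.2) {
  stopifnot(is(rr, "RRSeries"), m >= 1, r_frac > 0)
  nn <- validNN(rr)
  N <- length(nn)
  if (N < m + 2) return(NA_real_)
  r <- r_frac * sqrt(mean((nn - mean(nn))^2))
  Nm <- N - m
  idx <- seq_len(Nm)
  Dm <- matrix(0, Nm, Nm)
  for (k in 0:(m - 1))
    Dm <- pmax(Dm, abs(outer(nn[idx + k], nn[idx + k], "-")))
  Dm1 <- pmax(Dm, abs(outer(nn[idx + m], nn[idx + m], "-")))
  B <- (sum(Dm <= r) - Nm) / 2
  A <- (sum(Dm1 <= r) - Nm) / 2
  if (A <= 0 || B <= 0) return(NA_real_)
  -log(A / B)
}

# Fluctuation function F(n) of first-order DFA at one box size: integrate the
# mean-centered series, split into floor(N/n) non-overlapping boxes, detrend
# each box linearly, and take the RMS of all residuals.
dfaFluctuation <- function(nn, n) {
  N <- length(nn)
  nbox <- floor(N / n)
  if (nbox < 2) return(NA_real_)
  y <- cumsum(nn - mean(nn))
  Y <- matrix(y[seq_len(nbox * n)], nrow = n)
  x <- seq_len(n)
  xc <- x - mean(x)
  Yc <- Y - matrix(colMeans(Y), n, nbox, byrow = TRUE)
  beta <- colSums(Yc * xc) / sum(xc^2)
  res <- Yc - outer(xc, beta)
  sqrt(mean(res^2))
}

#' Detrended fluctuation analysis scaling exponents
#'
#' First-order DFA of the valid NN intervals: the mean-centered series is
#' integrated, divided into non-overlapping boxes of size n, each box is
#' linearly detrended, and the fluctuation \code{F(n)} is the RMS residual.
#' The scaling exponents are least-squares slopes of \code{log F(n)} vs
#' \code{log n} over log-spaced box sizes within the short-range (alpha1,
#' default 4-16 beats) and long-range (alpha2, default 16-64 beats) windows.
#' Uncorrelated intervals give alpha ~ 0.5, Brownian (integrated-noise)
#' profiles alpha ~ 1.5.
#'
#' At very small boxes first-order DFA is biased upward: for uncorrelated
#' data the exact expectation is \code{E[F^2(n)] = sigma^2 (n^2 - 4)/(15 n)},
#' not \code{sigma^2 n / 15}, which inflates the 4-16-beat slope to ~0.59.
#' By default the fit therefore uses the finite-size-corrected fluctuations
#' \code{F^2(n) / (1 - 4/n^2)}, which restores the theoretical 0.5 scaling
#' for uncorrelated series; the reported \code{fluctuations} table keeps the
#' raw \code{F(n)}.
#'
#' @param rr an [RRSeries-class]; alpha2 additionally requires at least 200
#'   valid intervals.
#' @param a1_scales,a2_scales length-2 integer ranges of box sizes (beats).
#' @param n_scales number of log-spaced box sizes per range.
#' @param finite_size_correction divide the squared fluctuations by
#'   \code{1 - 4/n^2} before fitting (default TRUE).
#' @return A list with \code{dfa_a1}, \code{dfa_a2}, \code{dfa_ratio}
#'   (\code{alpha1/alpha2}) and a \code{fluctuations} data.frame
#'   (\code{range}, \code{n}, \code{F}); an alpha is \code{NA} when the
#'   series is too short for its scale range.
#' @export
dfa <- function(rr, a1_scales = c(4, 16), a2_scales = c(16, 64),
                n_scales = 8, finite_size_correction = TRUE) {
  stopifnot(is(rr, "RRSeries"), a1_scales[1] >= 2, a1_scales[1] < a1_scales[2],
            a2_scales[1] < a2_scales[2])
  nn <- validNN(rr)
  N <- length(nn)
  fitAlpha <- function(scales, min_n) {
    ns <- unique(round(exp(seq(log(scales[1]), log(scales[2]),
                               length.out = n_scales))))
    if (N < min_n) return(list(alpha = NA_real_, tab = NULL))
    Fv <- vapply(ns, function(n) dfaFluctuation(nn, n), numeric(1))
    ok <- is.finite(Fv) & Fv > 0
    if (sum(ok) < 3) return(list(alpha = NA_real_, tab = NULL))
    Ffit <- if (finite_size_correction)
      Fv[ok] / sqrt(1 - 4 / ns[ok]^2) else Fv[ok]
    fit <- stats::lm.fit(cbind(1, log(ns[ok])), log(Ffit))
    list(alpha = fit$coefficients[2], tab = data.frame(n = ns, F = Fv))
  }
  f1 <- fitAlpha(a1_scales, min_n = 2 * a1_scales[2])
  f2 <- fitAlpha(a2_scales, min_n = max(200, 2 * a2_scales[2]))
  tabs <- rbind(
    if (!is.null(f1$tab)) cbind(range = "alpha1", f1$tab),
    if (!is.null(f2$tab)) cbind(range = "alpha2", f2$tab))
  list(dfa_a1 = unname(f1$alpha), dfa_a2 = unname(f2$alpha),
       dfa_ratio = if (!is.na(f1$alpha) && !is.na(f2$alpha) && f2$alpha != 0)
         unname(f1$alpha / f2$alpha) else NA_real_,
       fluctuations = tabs)
}

#' Assemble the full HRV summary for one epoch and modality
#'
#' Runs [timeDomain()], [poincare()], [spectralPower()], [sampleEntropy()]
#' and [dfa()] on one NN series and assembles the sixteen-metric battery.
#' Metrics that are undefined for the series are carried as \code{NA}, never
#' imputed.
#'
#' @param rr an [RRSeries-class].
#' @param epoch_label,modality,trial provenance labels stored in the summary.
#' @param pnn_threshold_ms PNNx threshold (ms).
#' @param lf_band,hf_band,resample_hz spectral parameters, see
#'   [spectralPower()].
#' @param m,r_frac sample-entropy parameters, see [sampleEntropy()].
#' @param a1_scales,a2_scales DFA box-size ranges, see [dfa()].
#' @return An [HRVSummary-class].
#' @export
#' @examples
#' rr <- rrSeries(cumsum(c(0, 150 + 5 * sin(1:400))))
#' computeSummary(rr, "baseline", "chest")
computeSummary <- function(rr, epoch_label = NA_character_,
                           modality = NA_character_, trial = NA_integer_,
                           pnn_threshold_ms = 5,
                           lf_band = c(0.2, 0.75), hf_band = c(0.75, 3),
                           resample_hz = 20, m = 2, r_frac = 0.2,
                           a1_scales = c(4, 16), a2_scales = c(16, 64)) {
  stopifnot(is(rr, "RRSeries"))
  vals <- structure(rep(NA_real_, 16), names = hrvMetricNames())
  if (isUsable(rr)) {
    td <- timeDomain(rr, pnn_threshold_ms)
    vals[names(td)] <- td
    pc <- poincare(rr)
    vals[names(pc)] <- pc
    sp <- spectralPower(rr, lf_band, hf_band, resample_hz)
    vals[c("lf", "hf", "total_power", "lf_hf")] <-
      c(sp$lf, sp$hf, sp$total_power, sp$lf_hf)
    vals["sampen"] <- sampleEntropy(rr, m, r_frac)
    dd <- dfa(rr, a1_scales, a2_scales)
    vals[c("dfa_a1", "dfa_a2", "dfa_ratio")] <-
      c(dd$dfa_a1, dd$dfa_a2, dd$dfa_ratio)
  }
  new("HRVSummary", metrics = vals, nBeats = length(beatTimes(rr)),
      epochLabel = as.character(epoch_label), modality = as.character(modality),
      trial = as.integer(trial))
}
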