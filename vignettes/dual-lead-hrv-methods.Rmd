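---
title: "Methods: dual-lead rodent HRV from in-ear and chest ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-lead rodent HRV from in-ear and chest ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earHRV)
```

# The problem

Heart rate variability (HRV) — the beat-to-beat fluctuation of RR intervals —
indexes autonomic (sympathetic/parasympathetic) tone and is the natural
readout for closed-loop neuromodulation experiments. In anesthetized rodent
preparations the ECG is typically recorded on a gold-standard chest lead and,
increasingly, on wearable in-ear electrodes, during alternating stimulation
and washout epochs. Two questions then arise: do the two modalities agree
(cross-platform fidelity), and does the stimulus shift autonomic tone between
a stimulation epoch and the washout that follows it?

`earHRV` implements the full chain needed to answer both on simulated or
recorded data: multi-channel preprocessing, R-peak detection at rodent rates,
quality-gated fusion of independently detected beat trains into one aggregate
RR series, a sixteen-metric HRV battery per epoch and modality, and the two
statistical comparisons. Because real dual-modality rodent recordings are not
freely available, the package also contains a first-class simulator whose
ground truth makes every downstream stage testable.

# The simulator: a stated world

`simConfig()` describes a study; `generateStudy()` realises it. The defaults
are the conditions the pipeline is designed for and are not tuned per
experiment:

* **Rhythm.** Mean RR 150 ms (400 BPM), inside the 120–300 ms band implied by
  the rodent 200–500 BPM range. Intervals are modulated directly:

  $$RR_i = \bar{RR} + \Delta\,[t_i \in \text{stim}]
        + A_{LF}\sin(2\pi f_{LF} t_i + \phi_{LF})
        + A_{HF}\sin(2\pi f_{HF} t_i + \phi_{HF})
        + \sigma\,\varepsilon_i$$

  with defaults $A_{LF} = A_{HF} = 3$ ms at 0.4 and 1.5 Hz, $\sigma = 2$ ms,
  and beats placed sequentially ($t_{i+1} = t_i + RR_i$). Direct interval
  modulation (rather than integral pulse frequency modulation) keeps the
  ground truth exact; at these modulation depths the difference between the
  two constructions is far below every tolerance used in the tests.
* **Epochs.** `n_trials` alternating stimulation/washout pairs (default 60 s
  each) starting at time zero; the stimulation shift $\Delta$ (default 0;
  +10 ms in the recovery tests) applies to beats falling in stimulation
  epochs.
* **Waveform.** Each channel renders a three-Gaussian QRST template (R width
  ~8 ms, unit apex, the global extremum of each complex), plus 0.3 Hz
  baseline wander at 25 % of the R amplitude — enough to exercise the
  high-pass stage without burying the QRS — plus white noise. The default
  noise SD of 0.1 per channel defines the 20 dB *peak* SNR scenario
  ($20\log_{10}(A_R/\sigma_{noise})$); SNR is stated relative to the R apex
  because the low QRS duty cycle makes average-power SNR uninformative for
  detection.
* **Dropout.** A sensor out of the ear canal is modelled as replacement of
  the cardiac signal by the channel noise alone inside the configured window
  — the signal is gone, the amplifier noise is not. This matches the
  mid-session single-sensor loss scenario the fusion stage must survive.

What the generator does **not** emulate: respiratory sinus coupling to an
actual respiration signal, motion artifacts, electrode impedance drift,
ectopy, or acquisition-chain filtering. A green test therefore establishes
correctness of the algorithms under known autonomic structure and realistic
noise/dropout — not robustness to every artifact class of a live recording.

# Detection

`preprocessRecord()` applies a zero-phase band-pass (default 10–200 Hz, where
rodent QRS energy sits, higher than in humans) and standardizes each channel
to zero mean, unit variance. No IIR filter-design package exists in this
stack, so the filter is FFT-domain with raised-cosine transition edges —
exactly zero phase, which matters because any phase distortion would bias
peak times and hence every millisecond-scale RR statistic.

`detectRPeaks()` is Pan–Tompkins-style: the normalized channel is narrowed
to the QRS energy band (default 15–80 Hz), differenced, squared and
integrated over a 15 ms window. The extra band-limiting step is load-bearing
at rodent SNRs: squaring the derivative amplifies wideband noise roughly in
proportion to the cube of its bandwidth, and restricting to 15–80 Hz
improves the QRS-to-noise energy ratio by an order of magnitude. Candidates
must clear a per-10 s adaptive threshold (25 % of the block's 99th energy
percentile) **floored** at 20 % of the global 99.9th percentile; the floor is
what keeps a noise-only dropout stretch from emitting spurious beats while
the block term tracks slow amplitude drift. The refractory period is tied to
the top of the heart-rate range (60000/hr\_max ms, 120 ms at 500 BPM) so the
same code covers rat and slower species, and every detection is refined to
the local extremum of the band-passed signal within ±10 ms.

`rejectArtifacts()` flags rather than deletes: intervals outside 120–300 ms,
or deviating from the running median of the last up-to-9 valid intervals by
more than 30 %, are marked invalid but kept, preserving the time axis for
spectral interpolation. The jump rule engages only once three valid intervals
precede, which makes the operation idempotent. Successive-difference
statistics downstream skip any pair that spans an invalid interval.

# Fusion

Beat trains detected independently per channel are compared and averaged.
`matchBeats()` performs greedy chronological one-to-one matching within a
30 ms tolerance (below half the minimum rodent RR, so distinct beats cannot
be confused), with a one-step lookahead as tie-break so a peak is never
paired when its partner sits closer to the next peak; on jittered trains this
reproduces the exhaustive optimal assignment. "Averaged" is read as
averaging matched peak *times*, not the two RR series: time-averaging keeps
the fused series a genuine point process on which all downstream metrics
remain well defined.

Quality gating is windowed (default 30 s, coverage = detected beats over the
minimum plausible count at 200 BPM, usable at ≥ 50 %): where both channels
are usable, fused beats are the means of matched pairs and beats seen by only
one lead are dropped as likely artifacts; where a single channel is usable —
the sensor-loss fallback — its beats pass through unchanged; windows with no
usable channel are excluded. A known limitation follows from the window
granularity: a dropout that only partially covers a window can cost beats in
that boundary window (both channels still look "usable" there while one of
them is blind for part of it). The acceptance tests therefore guarantee
fidelity outside the dropout span ± one window, and the artifact screen
flags the bridging interval so no corrupted interval reaches the metrics.

# The metric battery

Conventions that required a decision, and why:

* **Mean HR** is the mean of per-beat instantaneous rates $60000/NN_i$, not
  $60000/\overline{NN}$. Published per-animal tables in this field are
  internally inconsistent with the reciprocal convention (a 149 ms mean RR
  printed next to a 451 BPM mean HR), and consistent with per-beat
  averaging, so that convention is adopted and documented.
* **PNN5** uses a strict `>` on the 5 ms threshold — the rodent analogue of
  pNN50, scaled for 200–500 BPM hearts.
* **Poincaré SD1/SD2** use the uncentered second moment of the successive
  differences, $SD1^2 = \tfrac{1}{2}\,\overline{d^2}$, making
  $SD1 = RMSSD/\sqrt{2}$ an *exact* identity, and the population variance of
  the intervals, making $SD1^2 + SD2^2 = 2\,SDNN_{pop}^2$ exact
  ($SD2^2$ floored at zero; perfect alternans gives $SD2 = 0$ and an
  undefined ratio). SDNN itself is reported with the sample convention in
  summaries; the identity tests use matched estimators.
* **Spectral power** interpolates the valid-interval tachogram with a
  natural cubic spline onto a 20 Hz grid (invalid intervals are bridged),
  detrends linearly, and averages ≥ 4 half-overlapping Hann periodograms,
  scaled so the integrated density equals the signal variance in ms².
  Rodent LF (0.2–0.75 Hz) and HF (0.75–3 Hz) band edges are conventions, not
  measured constants, and are config-exposed; band intervals are half-open,
  total power is LF + HF by definition. Segments must additionally span
  $1/f_{LF,low}$ (5 s at the default edge) or the spectral metrics are
  reported undefined rather than from an unresolvable band.
* **Sample entropy** follows the standard template-counting definition
  ($m = 2$, $r = 0.2\,SD_{pop}$, Chebyshev distance, self-matches excluded,
  $N-m$ templates at both lengths). It is defined whenever length-$(m+1)$
  templates exist; estimates from fewer than ~30 intervals are unreliable
  and flagged as such in the documentation rather than refused.
* **DFA** integrates the mean-centered intervals, detrends non-overlapping
  boxes linearly, and fits $\log F(n)$ over log-spaced boxes, 4–16 beats for
  $\alpha_1$ and 16–64 for $\alpha_2$ (the latter requiring ≥ 200
  intervals). First-order DFA is provably biased at very small boxes: for
  uncorrelated data $E[F^2(n)] = \sigma^2 (n^2 - 4)/(15n)$, which inflates
  the 4–16-beat slope to ≈ 0.59 instead of the theoretical 0.5. The fit
  therefore divides $F^2(n)$ by $(1 - 4/n^2)$ by default — the analytic
  white-noise form of the standard finite-size correction — restoring
  $\alpha \approx 0.5$ for uncorrelated series while leaving Brownian
  profiles within their expected range ($\approx 1.4$ measured, theory 1.5).
  The reported per-box $F(n)$ table stays uncorrected so it can be checked
  against brute-force recomputation.

Undefined metrics (too few beats, zero spread, too-short epochs) are carried
as `NA` end to end and rendered as blank cells — never imputed as zero,
which would silently bias every group statistic.

# Statistics

The sequential analysis pairs each stimulation epoch with the subsequent
washout of the same trial and tests the differences $d_i = S_i - W_i$ with a
two-sided paired t-test; the effect size is the paired-data Cohen's
$d_z = |\bar d|/s_d$, labelled large above 0.8 and medium above 0.5.
Modality agreement uses the two-sided Welch (unequal-variance) independent
t-test on per-epoch values pooled across trials; Welch is chosen because
nothing guarantees equal variances across sensor sites, and the test is
symmetric in its arguments. No multiple-testing correction is applied by
default, matching per-metric reporting; a `p_adjust` argument exposes one.
"Normalized HR" in the report figures is each beat's instantaneous HR
divided by the session mean of its modality.

# Numerical and degenerate-input policy

* Identical seeds give bit-identical studies; the simulator restores the
  caller's RNG state.
* Constant channels preprocess to zeros (no division by a zero SD) and
  detect to an empty annotation with a warning, not an error.
* Fewer than two peaks yield an unusable RR series that every metric
  refuses with `NA`.
* Zero-spread paired differences leave Cohen's d and the paired p undefined;
  two identical constant samples compare with p = 1 by convention (their
  means are equal) since the t statistic degenerates.
* Epoch membership is half-open `[start, end)` everywhere, so boundary
  beats are never double-counted; an interval belongs to an epoch only when
  both bounding beats do.

# Known limitations

Single-subject sessions are the unit of analysis: there is no mixed-effects
pooling across animals. Fusion consensus is limited to two channels. The
simulator's stationary sinusoidal modulation is a deliberately simple
autonomic model — sufficient to calibrate band power, scaling exponents and
effect recovery, but not a substitute for physiological validation on real
recordings.
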