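Package: earHRV
Title: In-Ear and Chest ECG Fusion and Heart Rate Variability Analysis for
    Rodent Neuromodulation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing autonomic tone from dual-modality rodent
    electrocardiograms recorded during stimulation/washout neuromodulation
    protocols. Simulates two-channel ECG with known autonomic structure
    (low- and high-frequency RR modulation, stimulation shifts, channel
    dropout), detects R-peaks at rodent heart rates (200-500 BPM) with a
    derivative-energy detector, fuses independently detected beat trains
    into a single aggregate RR series with windowed single-channel
    fallback, computes a full battery of time-domain, spectral and
    non-linear heart rate variability metrics (SDNN, RMSSD, PNN5, LF/HF
    power, Poincare SD1/SD2, sample entropy, DFA alpha1/alpha2), and runs
    paired stimulation-versus-washout and independent modality-agreement
    statistics with Cohen's d effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'earHRV-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'simulate.R'
    'io.R'
    'detect.R'
    'fuse.R'
    'hrv.R'
    'stats.R'
    'report.R'
    'config.R'
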