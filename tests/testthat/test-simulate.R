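test_that("tachogram generation honours the configured interval structure", {
  # all modulation off: every interval equals the mean RR
  cfg <- simConfig(duration_s = 30, mean_rr_ms = 150, lf_amp_ms = 0,
                   hf_amp_ms = 0, noise_sd_ms = 0, n_trials = 1,
                   stim_len_s = 15, washout_len_s = 15, seed = 1)
  tr <- generateTachogram(cfg, schedule = NULL)
  expect_true(all(abs(rrIntervals(tr) - 150) < 1e-9))
  expect_equal(rrIntervals(tr), diff(beatTimes(tr)))

  # determinism: same config, same seed, twice
  tr2 <- generateTachogram(cfg, schedule = NULL)
  expect_identical(beatTimes(tr), beatTimes(tr2))

  # closed form: SD of a densely sampled sinusoid of amplitude A is A/sqrt(2)
  cfg_hf <- simConfig(duration_s = 300, mean_rr_ms = 150, lf_amp_ms = 0,
                      hf_amp_ms = 5, noise_sd_ms = 0, n_trials = 1,
                      stim_len_s = 150, washout_len_s = 150, seed = 2)
  tr_hf <- generateTachogram(cfg_hf, schedule = NULL)
  expect_lt(abs(sd(rrIntervals(tr_hf)) - 5 / sqrt(2)) / (5 / sqrt(2)), 0.05)

  # extreme parameters that would produce non-positive intervals are rejected
  bad <- simConfig(duration_s = 10, mean_rr_ms = 150, hf_amp_ms = 200,
                   noise_sd_ms = 0, n_trials = 1, stim_len_s = 5,
                   washout_len_s = 5, seed = 3)
  expect_error(generateTachogram(bad, schedule = NULL), "non-positive")
})

test_that("ECG synthesis places QRS complexes at the true beat times", {
  cfg <- simConfig(duration_s = 20, noise_sd_ms = 0, n_trials = 1,
                   stim_len_s = 10, washout_len_s = 10,
                   channel_noise = c(ear_left = 0, chest_I = 0), seed = 4)
  tr <- generateTachogram(cfg, schedule = NULL)
  rec <- synthesizeECG(tr, cfg)

  # length contract
  expect_equal(nrow(rec@signals), 20 * 1000)
  expect_equal(channelLabels(rec), c("ear_left", "chest_I"))

  # noiseless render: argmax near each true beat within one sample, after
  # removing the slow wander with the standard preprocessing
  x <- channelSignal(preprocessRecord(rec), "chest_I")
  for (b in beatTimes(tr)[5:10]) {
    idx <- round(b) + (-10:10) + 1
    expect_lte(abs(which.max(x[idx]) - 11), 1)
  }

  # sub-200 Hz sampling cannot support millisecond peak localization
  cfg_low <- simConfig(duration_s = 20, sample_rate_hz = 100, n_trials = 1,
                       stim_len_s = 10, washout_len_s = 10, seed = 4)
  expect_error(synthesizeECG(tr, cfg_low), "200 Hz")
})

test_that("dropout windows remove the cardiac signal but keep channel noise", {
  cfg <- simConfig(duration_s = 30, n_trials = 1, stim_len_s = 15,
                   washout_len_s = 15, seed = 5,
                   dropout_windows = list(list(channel = "ear_left",
                                               start_ms = 10e3, end_ms = 20e3)))
  tr <- generateTachogram(cfg, schedule = NULL)
  rec <- synthesizeECG(tr, cfg)
  cfg_clean <- cfg; cfg_clean$dropout_windows <- list()
  ref <- synthesizeECG(tr, cfg_clean)
  inside <- 10001:20000
  outside <- 1:10000
  x <- channelSignal(rec, "ear_left"); y <- channelSignal(ref, "ear_left")
  # inside the dropout nothing of the cardiac render survives: against the
  # noiseless render (cardiac signal + wander only) the correlation is ~0
  cfg_nl <- cfg
  cfg_nl$channel_noise <- c(ear_left = 0)
  cfg_nl$dropout_windows <- list()
  ynl <- channelSignal(synthesizeECG(tr, cfg_nl), "ear_left")
  expect_lt(abs(cor(x[inside], ynl[inside])), 0.1)
  expect_gt(cor(x[outside], ynl[outside]), 0.9)
  # outside the dropout the channel is bit-identical to the clean render
  expect_identical(x[outside], y[outside])
  # the other channel is untouched
  expect_identical(channelSignal(rec, "chest_I"), channelSignal(ref, "chest_I"))
})

test_that("study generation builds a consistent schedule and injects the stim effect", {
  cfg <- simConfig(duration_s = 360, n_trials = 3, stim_len_s = 60,
                   washout_len_s = 60, stim_delta_rr_ms = 10, seed = 6)
  study <- generateStudy(cfg)
  e <- epochs(study$schedule)
  expect_equal(nrow(e), 6)
  expect_equal(e$label, rep(c("stimulation", "washout"), 3))
  expect_true(all(e$start_ms[-1] >= e$end_ms[-nrow(e)]))  # non-overlapping

  # injected +10 ms shift recovered from ground truth within 3 SEM
  lab <- epochLabels(study$truth)[-length(epochLabels(study$truth))]
  rr <- rrIntervals(study$truth)
  d <- mean(rr[lab == "stimulation"]) - mean(rr[lab == "washout"])
  sem <- sqrt(var(rr[lab == "stimulation"]) / sum(lab == "stimulation") +
              var(rr[lab == "washout"]) / sum(lab == "washout"))
  expect_lt(abs(d - 10), 3 * sem)

  # a schedule longer than the record is rejected
  expect_error(generateStudy(simConfig(duration_s = 100, n_trials = 3,
                                       stim_len_s = 60, washout_len_s = 60)),
               "exceeds")
})

test_that("pure HF modulation concentrates tachogram spectral power at its frequency", {
  cfg <- simConfig(duration_s = 120, lf_amp_ms = 0, hf_amp_ms = 5,
                   hf_freq_hz = 1.5, noise_sd_ms = 0, n_trials = 1,
                   stim_len_s = 60, washout_len_s = 60, seed = 7)
  tr <- generateTachogram(cfg, schedule = NULL)
  sp <- spectralPower(rrSeries(beatTimes(tr)))
  peak <- sp$psd$freq[which.max(sp$psd$power)]
  bin <- diff(sp$psd$freq[1:2])
  expect_lte(abs(peak - 1.5), bin)
})
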