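test_that("windowed channel quality caps coverage and spots dead windows", {
  # 210 beats in one 60 s window against a 200-beat minimum at 200 BPM
  ann <- BeatAnnotation("ear_left", seq(0, 59999, length.out = 210))
  q <- channelQuality(ann, record_duration_ms = 60000, window_ms = 60000)
  w <- qualityWindows(q)
  expect_equal(nrow(w), 1)
  expect_equal(w$coverage, 1)           # capped
  expect_true(w$usable)

  # an empty 30 s window has zero coverage and is unusable
  ann2 <- BeatAnnotation("ear_left", seq(0, 29999, by = 150))
  q2 <- channelQuality(ann2, record_duration_ms = 60000, window_ms = 30000)
  expect_equal(qualityWindows(q2)$coverage[2], 0)
  expect_false(qualityWindows(q2)$usable[2])

  # a window longer than the record collapses to a single window
  q3 <- channelQuality(ann2, record_duration_ms = 30000, window_ms = 90000)
  expect_equal(nrow(qualityWindows(q3)), 1)
})

test_that("simulated sensor loss is flagged unusable exactly in the dropout span", {
  cfg <- simConfig(duration_s = 240, n_trials = 2, seed = 21,
                   dropout_windows = list(list(channel = "ear_left",
                                               start_ms = 120e3,
                                               end_ms = 210e3)))
  study <- generateStudy(cfg)
  ann <- detectRPeaks(study$record, "ear_left")
  q <- channelQuality(ann, recordDuration(study$record))
  w <- qualityWindows(q)
  in_drop <- w$start_ms >= 120e3 & w$end_ms <= 210e3
  expect_true(all(!w$usable[in_drop]))
  expect_true(all(w$usable[w$end_ms <= 120e3 | w$start_ms >= 210e3]))
})

test_that("beat matching is exact on constructed cases and optimal on jittered trains", {
  a <- BeatAnnotation("a", seq(0, 1500, by = 150))
  m <- matchBeats(a, a)
  expect_equal(nrow(m$pairs), 11)
  expect_length(m$unmatched_a, 0)
  expect_true(all(m$pairs$offset == 0))

  b <- BeatAnnotation("b", beatTimes(a) + 10)
  m2 <- matchBeats(a, b, tol_ms = 30)
  expect_equal(nrow(m2$pairs), 11)
  expect_true(all(m2$pairs$offset == 10))

  # symmetry: swapping arguments mirrors the matching
  m2r <- matchBeats(b, a, tol_ms = 30)
  expect_equal(m2r$pairs$time_a, m2$pairs$time_b)
  expect_equal(m2r$pairs$time_b, m2$pairs$time_a)

  # random-jitter trains of <= 12 beats against the exhaustive DP oracle
  set.seed(55)
  for (rep in 1:25) {
    tt <- cumsum(runif(12, 130, 180))
    ta <- sort(tt[sample(12, 10)] + rnorm(10, 0, 5))
    tb <- sort(tt[sample(12, 10)] + rnorm(10, 0, 5))
    got <- matchBeats(BeatAnnotation("a", ta), BeatAnnotation("b", tb),
                      tol_ms = 30)$pairs
    want <- oracleMatch(ta, tb, tol = 30)
    expect_equal(got$time_a, want$time_a)
    expect_equal(got$time_b, want$time_b)
  }
})

test_that("aggregation averages matched beat times and falls back per the quality gate", {
  a <- BeatAnnotation("ear_left", c(100, 250, 400))
  b <- BeatAnnotation("ear_right", c(110, 260, 410))
  fused <- aggregateBeats(list(a, b), record_duration_ms = 500)
  expect_equal(beatTimes(fused), c(105, 255, 405))
  expect_equal(rrIntervals(fused), c(150, 150))
  expect_true(all(rrValid(fused)))

  # one empty, unusable channel: the other channel passes through
  empty <- BeatAnnotation("ear_left", numeric(0))
  fused2 <- aggregateBeats(list(empty, b), record_duration_ms = 500)
  expect_equal(beatTimes(fused2), beatTimes(b))

  # fusing a channel with itself is the identity
  self <- aggregateBeats(list(a, a), record_duration_ms = 500)
  expect_equal(beatTimes(self), beatTimes(a))

  # symmetry in channel order
  fused_rev <- aggregateBeats(list(b, a), record_duration_ms = 500)
  expect_equal(beatTimes(fused_rev), beatTimes(fused))
})

test_that("fusing two noisy channels beats either one alone against ground truth", {
  cfg <- simConfig(duration_s = 60, n_trials = 1, stim_len_s = 30,
                   washout_len_s = 30, seed = 23,
                   channel_noise = c(ear_left = 0.15, ear_right = 0.15))
  study <- generateStudy(cfg)
  pre <- preprocessRecord(study$record)
  anns <- lapply(c("ear_left", "ear_right"), function(ch)
    detectRPeaks(pre, ch))
  fused <- aggregateBeats(anns, record_duration_ms = recordDuration(pre))
  r_fused <- rrRMSE(study$truth, beatTimes(fused))
  r_a <- rrRMSE(study$truth, beatTimes(anns[[1]]))
  r_b <- rrRMSE(study$truth, beatTimes(anns[[2]]))
  expect_lt(r_fused, min(r_a, r_b))
  expect_true(all(diff(beatTimes(fused)) > 0))
})
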