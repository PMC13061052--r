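# builds a summaries data.frame with given per-trial values of one metric
mkSummariesDF <- function(metric, stim, wash, modality = "chest") {
  n <- length(stim)
  df <- data.frame(epoch = rep(c("stimulation", "washout"), each = n),
                   modality = modality, trial = rep(seq_len(n), 2),
                   n_beats = 100L)
  df[[metric]] <- c(stim, wash)
  df
}

test_that("epoch segmentation applies the half-open both-beats rule", {
  rr <- rrSeries(seq(0, 1200, by = 150))
  sched <- EpochSchedule("stimulation", 300, 900, 1)
  segs <- segmentEpochs(rr, sched)
  expect_equal(beatTimes(segs[[1]]$rr), c(300, 450, 600, 750))
  expect_equal(rrIntervals(segs[[1]]$rr), rep(150, 3))

  # an epoch covering the whole record reproduces the series
  all_in <- segmentEpochs(rr, EpochSchedule("baseline", 0, 1201, 1))
  expect_equal(beatTimes(all_in[[1]]$rr), beatTimes(rr))

  # disjoint epochs partition the intervals except boundary-spanning ones
  sched2 <- EpochSchedule(c("stimulation", "washout"), c(0, 600), c(600, 1201),
                          c(1, 1))
  segs2 <- segmentEpochs(rr, sched2)
  n_in <- sum(vapply(segs2, function(s) length(rrIntervals(s$rr)), numeric(1)))
  expect_equal(n_in, length(rrIntervals(rr)) - 1)  # one interval spans 600

  # epochs with < 2 beats give empty unusable series
  expect_message(tiny <- segmentEpochs(rr, EpochSchedule("washout", 70, 140, 1)),
                 "< 2 beats")
  expect_false(isUsable(tiny[[1]]$rr))
})

test_that("sequential analysis reproduces closed-form t, p and Cohen's d", {
  df <- mkSummariesDF("mean_rr", stim = c(101, 102, 103), wash = c(100, 100, 100))
  out <- sequentialAnalysis(df)
  row <- out[out$metric == "mean_rr", ]
  expect_equal(row$mean_delta, 2)
  expect_equal(row$cohens_d, 2)
  expect_equal(row$p_value, 2 * pt(-2 / (1 / sqrt(3)), df = 2),
               tolerance = 1e-12)
  expect_equal(row$p_value, 0.0742, tolerance = 1e-3)
  expect_equal(row$n_pairs, 3)
  expect_equal(row$power_label, "large")

  # degenerate zero-spread differences: effect undefined, never zero
  df0 <- mkSummariesDF("mean_rr", stim = c(100, 100, 100), wash = c(100, 100, 100))
  row0 <- sequentialAnalysis(df0)[1, ]
  expect_equal(row0$mean_delta, 0)
  expect_true(is.na(row0$cohens_d))
  expect_true(is.na(row0$p_value))

  expect_error(sequentialAnalysis(mkSummariesDF("mean_rr", 1, 2)), ">= 2")
})

test_that("power labels follow the effect-size thresholds", {
  d <- c(0.2, 0.5, 0.51, 0.8, 0.81, 1.5, NA)
  expect_equal(earHRV:::powerLabel(d),
               c("small", "small", "medium", "medium", "large", "large", NA))
})

test_that("modality agreement is a symmetric Welch test with sane edge cases", {
  a <- mkSummariesDF("sdnn", c(5.1, 5.3, 5.6), c(5.0, 5.2, 5.4), "chest")
  b <- mkSummariesDF("sdnn", c(5.2, 5.4, 5.5), c(5.1, 5.0, 5.3), "ear")
  out <- modalityAgreement(a, b)
  row <- out[out$metric == "sdnn", ]
  expect_equal(row$p_value,
               t.test(a$sdnn, b$sdnn, var.equal = FALSE)$p.value)

  # symmetric in its arguments
  out_rev <- modalityAgreement(b, a)
  expect_equal(out_rev$p_value, out$p_value)

  # identical samples (and shuffles of them) give p = 1
  same <- mkSummariesDF("sdnn", c(1, 2), c(3, NA), "chest")
  shuf <- mkSummariesDF("sdnn", c(3, 2), c(1, NA), "ear")
  expect_equal(modalityAgreement(same, same)[1, "p_value"], 1)
  expect_equal(modalityAgreement(same, shuf)[1, "p_value"], 1)
})

test_that("agreement between two noisy views of one rhythm is null-calibrated", {
  # per-epoch mean RR measured from two independently jittered beat trains of
  # the same truth; the Welch test should reject at ~ the nominal 5% rate
  set.seed(77)
  rejections <- 0L
  for (run in 1:100) {
    truth <- cumsum(c(0, 150 + rnorm(800, 0, 4)))
    sched <- EpochSchedule(rep(c("stimulation", "washout"), 5),
                           seq(0, by = 12000, length.out = 10),
                           seq(12000, by = 12000, length.out = 10),
                           rep(1:5, each = 2))
    mk <- function() {
      obs <- rrSeries(truth + rnorm(length(truth), 0, 1))
      segs <- segmentEpochs(obs, sched)
      do.call(rbind, lapply(segs, function(s)
        data.frame(epoch = s$epoch, trial = s$trial, modality = "m",
                   n_beats = 10L, mean_rr = mean(rrIntervals(s$rr)))))
    }
    p <- modalityAgreement(mk(), mk())[1, "p_value"]
    if (p <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 10)
})

test_that("an injected stimulation RR shift is recovered with the right sign", {
  cfg <- simConfig(duration_s = 720, n_trials = 6, stim_delta_rr_ms = 10,
                   seed = 31)
  truth <- generateTachogram(cfg)
  rr <- rrSeries(beatTimes(truth))
  segs <- segmentEpochs(rr, studySchedule(cfg))
  df <- do.call(rbind, lapply(segs, function(s)
    data.frame(epoch = s$epoch, trial = s$trial, modality = "truth",
               n_beats = length(beatTimes(s$rr)),
               mean_rr = mean(rrIntervals(s$rr)))))
  row <- sequentialAnalysis(df)[1, ]
  expect_gt(row$mean_delta, 0)                  # S - W positive by injection
  sem <- sd(df$mean_rr) / sqrt(3)
  expect_lt(abs(row$mean_delta - 10), 3 * max(sem, 0.5))
  expect_lt(row$p_value, 0.05)
})
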