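test_that("time-domain metrics match hand calculations and the formula oracle", {
  # degenerate constant series
  const <- rrSeries(cumsum(c(0, rep(150, 100))))
  td <- timeDomain(const)
  expect_equal(unname(td), c(150, 400, 0, 0, 0))

  # two-value alternation
  alt <- rrSeries(cumsum(c(0, rep(c(140, 160), 50))))
  td2 <- timeDomain(alt)
  expect_equal(td2[["mean_rr"]], 150)
  expect_equal(td2[["mean_hr"]], (60000 / 140 + 60000 / 160) / 2)
  expect_equal(td2[["sdnn"]], sd(rep(c(140, 160), 50)))
  expect_equal(td2[["rmssd"]], 20)
  expect_equal(td2[["pnn5"]], 100)

  # random series against a direct-formula recomputation
  set.seed(7)
  iv <- rnorm(50, 160, 12)
  rr <- rrSeries(cumsum(c(0, iv)))
  td3 <- timeDomain(rr)
  d <- diff(iv)
  expect_equal(td3[["mean_rr"]], mean(iv))
  expect_equal(td3[["mean_hr"]], mean(60000 / iv))
  expect_equal(td3[["sdnn"]], sd(iv))
  expect_equal(td3[["rmssd"]], sqrt(mean(d^2)))
  expect_equal(td3[["pnn5"]], 100 * mean(abs(d) > 5))

  # PNNx is monotone non-increasing in its threshold
  pnn <- vapply(c(0, 2, 5, 10, 25), function(th)
    timeDomain(rr, pnn_threshold_ms = th)[["pnn5"]], numeric(1))
  expect_true(all(diff(pnn) <= 0))

  # undefined, never zero, on a too-short series
  expect_true(all(is.na(timeDomain(rrSeries(c(0, 150)))[c("sdnn", "rmssd")])))
})

test_that("successive-difference metrics skip pairs spanning invalid intervals", {
  iv <- c(150, 150, 600, 150, 150)
  rr <- rejectArtifacts(rrSeries(cumsum(c(0, iv))))
  expect_identical(rrValid(rr), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # valid successive pairs are (1,2) and (4,5) only; all diffs zero
  expect_equal(timeDomain(rr)[["rmssd"]], 0)
  expect_equal(timeDomain(rr)[["mean_rr"]], 150)
})

test_that("Poincare axes satisfy their analytic identities", {
  alt <- rrSeries(cumsum(c(0, rep(c(140, 160), 50))))
  pc <- poincare(alt)
  expect_equal(pc[["sd1"]], 20 / sqrt(2), tolerance = 1e-12)
  expect_equal(pc[["sd2"]], 0)
  expect_true(is.na(pc[["sd1_sd2"]]))

  set.seed(8)
  for (rep in 1:10) {
    iv <- rnorm(200, 150, 10)
    rr <- rrSeries(cumsum(c(0, iv)))
    pc <- poincare(rr)
    td <- timeDomain(rr)
    # sd1 = rmssd / sqrt(2)
    expect_equal(pc[["sd1"]], td[["rmssd"]] / sqrt(2), tolerance = 1e-12)
    # sd1^2 + sd2^2 = 2 * sdnn^2 with the population estimator
    sdnn_pop <- sqrt(mean((iv - mean(iv))^2))
    expect_equal(pc[["sd1"]]^2 + pc[["sd2"]]^2, 2 * sdnn_pop^2,
                 tolerance = 1e-9)
  }
})

test_that("spectral power lands in the band of the injected modulation", {
  mkTach <- function(freq) {
    cfg <- simConfig(duration_s = 120, lf_amp_ms = 5 * (freq < 0.75),
                     hf_amp_ms = 5 * (freq >= 0.75),
                     lf_freq_hz = freq, hf_freq_hz = freq,
                     noise_sd_ms = 0, n_trials = 1, stim_len_s = 60,
                     washout_len_s = 60, seed = 9)
    rrSeries(beatTimes(generateTachogram(cfg, schedule = NULL)))
  }
  hi <- spectralPower(mkTach(1.5))
  expect_gte(hi$hf / (hi$lf + hi$hf), 0.95)
  lo <- spectralPower(mkTach(0.4))
  expect_gte(lo$lf / (lo$lf + lo$hf), 0.95)
  expect_equal(hi$total_power, hi$lf + hi$hf)

  # constant series carries (numerically) no power
  flat <- spectralPower(rrSeries(cumsum(c(0, rep(150, 400)))))
  expect_lt(flat$total_power, 1e-6)

  # a short epoch cannot support 4 segments: undefined, not an error
  short <- spectralPower(rrSeries(cumsum(c(0, rep(150, 20)))))
  expect_true(is.na(short$lf))
})

test_that("sample entropy equals the exhaustive enumeration oracle exactly", {
  # 8-interval alternating series, fully regular
  alt8 <- rrSeries(cumsum(c(0, rep(c(140, 160), 4))))
  r_alt <- 0.2 * sqrt(mean((rep(c(140, 160), 4) - 150)^2))
  expect_equal(sampleEntropy(alt8), oracleSampEn(rep(c(140, 160), 4), 2, r_alt))
  expect_equal(sampleEntropy(alt8), 0)

  # constant series: every template matches
  expect_equal(sampleEntropy(rrSeries(cumsum(c(0, rep(150, 50))))), 0)

  set.seed(10)
  for (N in c(20, 50, 100)) {
    iv <- rnorm(N, 150, 8)
    rr <- rrSeries(cumsum(c(0, iv)))
    r <- 0.2 * sqrt(mean((iv - mean(iv))^2))
    expect_identical(sampleEntropy(rr), oracleSampEn(iv, 2, r))
  }

  # irregular beats are more entropic than a sinusoidal rhythm of equal SD
  set.seed(11)
  iid <- 150 + rnorm(500, 0, 5)
  sine <- 150 + 5 * sqrt(2) * sin(2 * pi * seq_len(500) / 40)
  expect_gt(sampleEntropy(rrSeries(cumsum(c(0, iid)))),
            sampleEntropy(rrSeries(cumsum(c(0, sine)))))
})

test_that("DFA fluctuations match the per-box oracle and alphas calibrate", {
  set.seed(12)
  iv <- rnorm(64, 150, 10)
  rr <- rrSeries(cumsum(c(0, iv)))
  out <- dfa(rr)
  tab <- out$fluctuations[out$fluctuations$range == "alpha1", ]
  for (k in seq_len(nrow(tab)))
    expect_equal(tab$F[k], oracleDFAFluct(iv, tab$n[k]), tolerance = 1e-10)

  # uncorrelated intervals scale like alpha ~ 0.5
  set.seed(13)
  wn <- dfa(rrSeries(cumsum(c(0, rnorm(1000, 150, 5)))))
  expect_gte(wn$dfa_a1, 0.4); expect_lte(wn$dfa_a1, 0.6)

  # an integrated-noise (Brownian) profile scales like alpha ~ 1.5
  set.seed(14)
  prof <- 150 + 2 * cumsum(rnorm(1000)); prof <- prof - mean(prof) + 150
  bn <- dfa(rrSeries(cumsum(c(0, prof))))
  expect_gte(bn$dfa_a1, 1.3); expect_lte(bn$dfa_a1, 1.7)

  # too short for the long-range window: alpha2 undefined
  expect_true(is.na(dfa(rrSeries(cumsum(c(0, rnorm(100, 150, 5)))))$dfa_a2))
})

test_that("the assembled summary is consistent, shift-invariant and complete", {
  set.seed(15)
  iv <- 150 + 5 * sin(2 * pi * seq_len(600) * 0.15 / 6.6) + rnorm(600, 0, 3)
  rr <- rrSeries(cumsum(c(0, iv)))
  s <- computeSummary(rr, "stimulation", "chest", 1L)
  m <- metrics(s)
  expect_equal(m[["mean_rr"]], timeDomain(rr)[["mean_rr"]])
  expect_equal(m[["sd1"]], poincare(rr)[["sd1"]])
  expect_equal(m[["sampen"]], sampleEntropy(rr))
  expect_equal(m[["total_power"]], m[["lf"]] + m[["hf"]])
  expect_equal(m[["dfa_ratio"]], m[["dfa_a1"]] / m[["dfa_a2"]])
  expect_false(anyNA(m))

  # every metric is invariant under a global shift of the time axis
  s_shift <- computeSummary(rrSeries(beatTimes(rr) + 1e5), "stimulation",
                            "chest", 1L)
  expect_equal(metrics(s_shift), m, tolerance = 1e-9)

  # concatenating two identical epochs leaves interval-wise statistics alone
  s2 <- computeSummary(rrSeries(cumsum(c(0, iv, iv))))
  expect_equal(metrics(s2)[["mean_rr"]], m[["mean_rr"]])
  expect_equal(metrics(s2)[["mean_hr"]], m[["mean_hr"]])
  expect_equal(metrics(s2)[["sdnn"]], m[["sdnn"]], tolerance = 2e-3)
})
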