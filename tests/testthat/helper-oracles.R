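# Independent brute-force oracles, deliberately written with plain loops and
# none of the package's internals, so they can certify the fast paths.

# O(N^2) pair enumeration for sample entropy (Chebyshev distance, self-matches
# excluded; N - m templates at both lengths).
oracleSampEn <- function(x, m = 2, r) {
  N <- length(x)
  Nm <- N - m
  A <- 0; B <- 0
  for (i in seq_len(Nm - 1)) {
    for (j in (i + 1):Nm) {
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# per-box DFA fluctuation with an explicit lm() per box
oracleDFAFluct <- function(x, n) {
  y <- cumsum(x - mean(x))
  nbox <- floor(length(x) / n)
  res2 <- c()
  for (b in seq_len(nbox)) {
    seg <- y[((b - 1) * n + 1):(b * n)]
    fit <- stats::lm(seg ~ seq_len(n))
    res2 <- c(res2, stats::residuals(fit)^2)
  }
  sqrt(mean(res2))
}

# exhaustive re-application of the two artifact-screening rules
oracleArtifactFlags <- function(iv, valid0, physio = c(120, 300), jump = 0.3) {
  valid <- valid0
  hist <- c()
  for (i in seq_along(iv)) {
    if (!valid[i]) next
    ok <- iv[i] >= physio[1] && iv[i] <= physio[2]
    if (ok && length(hist) >= 3) {
      med <- stats::median(utils::tail(hist, 9))
      ok <- abs(iv[i] - med) <= jump * med
    }
    valid[i] <- ok
    if (ok) hist <- c(hist, iv[i])
  }
  valid
}

# optimal one-to-one assignment of two beat trains (max matches, then min
# total |offset|), by dynamic programming over suffixes; feasible for <= 12
oracleMatch <- function(a, b, tol) {
  na <- length(a); nb <- length(b)
  # value = matches * 1e9 - total cost; memo over (i, j)
  memo <- array(NA_real_, dim = c(na + 1, nb + 1))
  choice <- array(0L, dim = c(na + 1, nb + 1))
  for (i in (na + 1):1) {
    for (j in (nb + 1):1) {
      if (i > na || j > nb) { memo[i, j] <- 0; next }
      best <- memo[i + 1, j]; ch <- 1L
      if (memo[i, j + 1] > best) { best <- memo[i, j + 1]; ch <- 2L }
      d <- abs(a[i] - b[j])
      if (d <= tol) {
        v <- 1e9 - d + memo[i + 1, j + 1]
        if (v > best) { best <- v; ch <- 3L }
      }
      memo[i, j] <- best; choice[i, j] <- ch
    }
  }
  ia <- c(); ib <- c(); i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    ch <- choice[i, j]
    if (ch == 3L) { ia <- c(ia, i); ib <- c(ib, j); i <- i + 1L; j <- j + 1L }
    else if (ch == 1L) i <- i + 1L else j <- j + 1L
  }
  data.frame(time_a = a[ia], time_b = b[ib])
}

# detection scoring against ground truth with +/- tol matching
scoreDetection <- function(true_times, det_times, tol = 5) {
  m <- matchBeats(BeatAnnotation("truth", true_times),
                  BeatAnnotation("det", det_times), tol_ms = tol)
  list(sensitivity = nrow(m$pairs) / length(true_times),
       precision = nrow(m$pairs) / length(det_times),
       rmse = sqrt(mean(m$pairs$offset^2)))
}

# RMSE of detected RR intervals against true RR, over beats matched +/- 5 ms
rrRMSE <- function(truth, est_times, tol = 5) {
  m <- matchBeats(BeatAnnotation("truth", beatTimes(truth)),
                  BeatAnnotation("est", est_times), tol_ms = tol)
  ta <- m$pairs$time_a; tb <- m$pairs$time_b
  keep <- which(diff(match(ta, beatTimes(truth))) == 1)
  sqrt(mean((diff(tb)[keep] - diff(ta)[keep])^2))
}
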