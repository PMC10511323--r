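shiftRows <- function(m, k) {
  ## delay each row by k bins (zero-fill), so the source leads the copy
  out <- matrix(0, nrow(m), ncol(m))
  if (k >= 0) out[, (k + 1):ncol(m)] <- m[, 1:(ncol(m) - k)]
  else out[, 1:(ncol(m) + k)] <- m[, (1 - k):ncol(m)]
  out
}

test_that("a delayed copy peaks at a positive lag under the A-leads-B convention", {
  set.seed(31)
  a <- matrix(rnorm(100 * 40), 100, 40)
  b <- shiftRows(a, 2)
  ta <- makeTensor(a, window = c(1.08, 1.08))
  tb <- makeTensor(b, window = c(1.08, 1.08))
  cc <- crosscovLagged(ta, tb, max_lag = 0.54, mode = "raw")
  ## brute force over all lags
  expect_equal(cc$lag_bins[which.max(cc$value)], 2)
  expect_equal(attr(cc, "max_lag_s"), 2 * 0.054)
  ## brute-force value check at the peak
  ac <- a - mean(a); bc <- b - mean(b)
  manual <- mean(ac[, 1:38] * bc[, 3:40])
  expect_equal(max(cc$value), manual, tolerance = 1e-12)
})

test_that("K(t1,t2) equals the naive double loop exactly", {
  set.seed(32)
  a <- matrix(rnorm(20 * 30), 20, 30)
  b <- matrix(rnorm(20 * 30), 20, 30)
  ta <- makeTensor(a, window = c(0.54, 1.08))
  tb <- makeTensor(b, window = c(0.54, 1.08))
  K <- covMatrix2D(ta, tb, mode = "raw")
  ac <- a - mean(a); bc <- b - mean(b)
  Kn <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) Kn[i, j] <- mean(ac[, i] * bc[, j])
  expect_equal(K@K, Kn, tolerance = 1e-12)
})

test_that("lag-0 cross-covariance equals the K diagonal average", {
  tens <- fixTensors()
  cc <- crosscovLagged(tens$da, tens$ach, max_lag = 0.3, mode = "noise",
                       conditions = tens$outcome)
  K <- covMatrix2D(tens$da, tens$ach, mode = "noise",
                   conditions = tens$outcome)
  expect_equal(cc$value[cc$lag_bins == 0], mean(diag(K@K)),
               tolerance = 1e-12)
})

test_that("condition-mean residuals centre every condition at every bin", {
  tens <- fixTensors()
  res <- conditionMeanResiduals(tens$da, tens$outcome)
  for (cnd in unique(tens$outcome)) {
    m <- colMeans(tensorData(res)[tens$outcome == cnd, ])
    expect_lt(max(abs(m)), 1e-12)
  }
  ## identical trials give all-zero residuals
  d <- matrix(rep(sin(1:30), each = 6), 6, 30)
  r <- conditionMeanResiduals(makeTensor(d, window = c(0.54, 1.08)),
                              rep("x", 6))
  expect_true(all(abs(tensorData(r)) < 1e-12))
  expect_error(conditionMeanResiduals(makeTensor(d, window = c(0.54, 1.08)),
                                      c("x", rep("y", 5))), "singleton")
})

test_that("noise mode ignores condition-locked deterministic waveforms", {
  set.seed(33)
  a <- matrix(rnorm(80 * 40), 80, 40)
  b <- matrix(rnorm(80 * 40), 80, 40)
  cond <- rep(c("p", "q"), each = 40)
  wave <- sin(seq(0, 3, length.out = 40)) * 5
  a2 <- a; a2[cond == "p", ] <- sweep(a2[cond == "p", ], 2, wave, "+")
  b2 <- b; b2[cond == "q", ] <- sweep(b2[cond == "q", ], 2, -wave, "+")
  mk <- function(m) makeTensor(m, window = c(1.08, 1.08))
  c1 <- crosscovLagged(mk(a), mk(b), 0.3, "noise", conditions = cond)
  c2 <- crosscovLagged(mk(a2), mk(b2), 0.3, "noise", conditions = cond)
  expect_equal(c1$value, c2$value, tolerance = 1e-10)
})

test_that("off-diagonal extraction on an identity-like matrix", {
  n <- 20
  K <- new("CovMatrix", K = diag(n), t1 = (0:(n - 1)) * 0.054,
           t2 = (0:(n - 1)) * 0.054, nTrials = 50L,
           channels = c("A", "B"), mode = "raw")
  od0 <- offDiagonal(K, offset = 0, band_halfwidth = 0)
  expect_true(all(od0$value == 1))
  od2 <- offDiagonal(K, offset = 2 * 0.054, band_halfwidth = 0)
  expect_true(all(od2$value[!od2$truncated] == 0))
  expect_error(offDiagonal(K, offset = 10), "outside")
})

test_that("independent tensors stay inside the simultaneous null band", {
  set.seed(34)
  a <- matrix(rnorm(500 * 40), 500, 40)
  b <- matrix(rnorm(500 * 40), 500, 40)
  ta <- makeTensor(a, window = c(1.08, 1.08))
  tb <- makeTensor(b, window = c(1.08, 1.08))
  cc <- crosscovLagged(ta, tb, 0.54, "raw")
  nc <- nullControls(ta, tb, 0.54, "circular_shift", "raw", n_perm = 300,
                     seed = 9)
  ## truly null data: the observed extrema behave like one more draw from
  ## the permutation extremum distribution
  expect_gte(min(cc$value), stats::quantile(nc$null_min, 0.005))
  expect_lte(max(cc$value), stats::quantile(nc$null_max, 0.995))
})

test_that("coupled generator data fall outside the null band, uncoupled inside", {
  s <- fixSession()
  coupled <- fixDefaultSynth()
  ## noise correlations conditioned on the full trial type (history label):
  ## shared deterministic amplitude modulation is absorbed into the
  ## condition means, leaving the coupling as the only cross-channel source
  mk <- function(out) {
    da <- alignTrials(zscoreSession(out$da), s$trials, window = c(1, 2))
    ach <- alignTrials(zscoreSession(out$ach), s$trials, window = c(1, 2))
    lab <- s$trials$history_label[trialIndex(da)]
    keep <- which(!is.na(lab) & lab %in% names(which(table(lab) >= 2)))
    sub <- function(x) methods::initialize(
      x, data = tensorData(x)[keep, ], trialIndex = trialIndex(x)[keep])
    list(da = sub(da), ach = sub(ach), lab = lab[keep])
  }
  tc <- mk(coupled)
  cc <- crosscovLagged(tc$da, tc$ach, 0.5, "noise", conditions = tc$lab)
  nc <- nullControls(tc$da, tc$ach, 0.5, "circular_shift", "noise",
                     conditions = tc$lab, n_perm = 200, seed = 10)
  expect_lt(min(cc$value), nc$simultaneous["lo"])
  expect_equal(cc$lag_bins[which.min(cc$value)], 2)  # 108 ms at 54 ms bins

  un <- mk(synthesizeTraces(s$trials,
                            generatorSpec(coupling = list(gain = 0)),
                            seed = 32))
  cc0 <- crosscovLagged(un$da, un$ach, 0.5, "noise", conditions = un$lab)
  nc0 <- nullControls(un$da, un$ach, 0.5, "circular_shift", "noise",
                      conditions = un$lab, n_perm = 200, seed = 10)
  expect_gte(min(cc0$value), stats::quantile(nc0$null_min, 0.005))
})

test_that("session-swap nulls require and use a second session", {
  tens <- fixTensors()
  expect_error(nullControls(tens$da, tens$ach, 0.3, "session_swap"),
               "B_alt")
  s2 <- simulateSession(taskConfig(n_trials = 300), agentParams(), seed = 99)
  out2 <- synthesizeTraces(s2$trials, generatorSpec(), seed = 98)
  ach2 <- alignTrials(zscoreSession(out2$ach), s2$trials, window = c(1, 2))
  nc <- nullControls(tens$da, tens$ach, 0.3, "session_swap",
                     B_alt = ach2, n_perm = 120, seed = 3)
  expect_equal(nrow(nc$band), 2 * round(0.3 / 0.054) + 1)
  expect_true(all(nc$band$lo <= nc$band$hi))
})

test_that("null band narrows as permutations accumulate", {
  set.seed(35)
  a <- matrix(rnorm(120 * 30), 120, 30)
  b <- matrix(rnorm(120 * 30), 120, 30)
  ta <- makeTensor(a, window = c(0.54, 1.08))
  tb <- makeTensor(b, window = c(0.54, 1.08))
  n1 <- nullControls(ta, tb, 0.3, "circular_shift", "raw", n_perm = 100,
                     seed = 1)
  n2 <- nullControls(ta, tb, 0.3, "circular_shift", "raw", n_perm = 1000,
                     seed = 1)
  ## more permutations give a more stable (not wider) simultaneous band
  w1 <- diff(n1$simultaneous)
  w2 <- diff(n2$simultaneous)
  expect_lt(abs(w2 - w1) / w1, 0.5)
  expect_identical(
    nullControls(ta, tb, 0.3, "circular_shift", "raw", n_perm = 100,
                 seed = 1)$band,
    n1$band)
})
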