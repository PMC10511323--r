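test_that("lock-in demodulation recovers a constant envelope with unit gain", {
  fs <- 2000; t <- seq(0, 5, by = 1 / fs)
  A <- 1.7
  raw <- photometryTrace(A * sin(2 * pi * 167 * t), fs, "x", units = "raw")
  env <- traceValues(demodulate(raw, 167))
  mid <- round(length(t) / 2) + (-200:200)
  expect_equal(mean(env[mid]), A, tolerance = 1e-3)

  zero <- photometryTrace(rep(0, length(t)), fs, "x", units = "raw")
  expect_true(all(abs(traceValues(demodulate(zero, 167))) < 1e-12))
})

test_that("demodulation rejects invalid carrier/cutoff combinations", {
  raw <- photometryTrace(rnorm(1000), fs = 300, "x", units = "raw")
  expect_error(demodulate(raw, carrier = 167), "Nyquist")
  raw2 <- photometryTrace(rnorm(1000), fs = 2000, "x", units = "raw")
  expect_error(demodulate(raw2, carrier = 167, lowpass_cutoff = 200),
               "below the carrier")
})

test_that("two multiplexed channels demodulate with negligible crosstalk", {
  fs <- 2000; dur <- 30
  t <- seq(0, dur, by = 1 / fs)
  set.seed(11)
  bf <- signal::butter(4, 10 / (fs / 2), "low")
  mkenv <- function() {
    e <- signal::filtfilt(bf, rnorm(length(t)))
    e / stats::sd(e) * 0.5
  }
  ea <- mkenv(); eb <- mkenv()
  raw <- modulateCarriers(photometryTrace(ea, fs, "A"),
                          photometryTrace(eb, fs, "B"),
                          carriers = c(167, 223), fs = fs)
  trim <- (2 * fs):(length(t) - 2 * fs)
  da <- traceValues(demodulate(raw, 167))[trim]
  db <- traceValues(demodulate(raw, 223))[trim]
  expect_gt(stats::cor(da, ea[trim]), 0.99)
  expect_gt(stats::cor(db, eb[trim]), 0.99)
  ## crosstalk: flat channel A, varying channel B
  raw0 <- modulateCarriers(photometryTrace(rep(0, length(t)), fs, "A"),
                           photometryTrace(eb, fs, "B"),
                           carriers = c(167, 223), fs = fs)
  leak <- traceValues(demodulate(raw0, 167))[trim]
  expect_lt(stats::sd(leak) / stats::sd(eb[trim]), 0.01)
})

test_that("dF/F0 base cases", {
  tr <- photometryTrace(rep(3, 1000), fs = 100, "x")
  out <- dff(tr, "constant", list(F0 = 3))
  expect_true(all(out@values == 0))
  expect_equal(signalUnits(out), "dF/F")

  v <- rep(1, 500); v[250] <- 1.1
  out2 <- dff(photometryTrace(v, 100, "x"), "constant", list(F0 = 1))
  expect_equal(traceValues(out2)[250], 0.1)
  expect_equal(traceValues(out2)[1], 0)

  expect_error(dff(photometryTrace(c(-1, -1, 2), 10, "x"), "constant",
                   list(F0 = -1)), "non-positive")
})

test_that("running-percentile dF/F0 undoes slow multiplicative drift", {
  fs <- 50; t <- seq(0, 400, by = 1 / fs)
  baseline <- 2 + 0.25 * sin(2 * pi * 0.002 * t)
  set.seed(2)
  events <- sort(sample(t[t > 20 & t < 380], 60))
  s <- rep(0, length(t))
  for (e in events) {
    idx <- which(t >= e & t < e + 1)
    s[idx] <- s[idx] + 0.5 * exp(-(t[idx] - e) / 0.3)
  }
  F <- baseline * (1 + s)
  out <- dff(photometryTrace(F, fs, "x"), "running_percentile",
             list(window = 20, prob = 0.1))
  v <- traceValues(out)
  ## event amplitudes restored within 5% of the drift-free truth
  peak_true <- 0.5
  peaks <- vapply(events, function(e) max(v[t >= e & t < e + 0.5]), 1)
  expect_lt(abs(stats::median(peaks) - peak_true) / peak_true, 0.05)
})

test_that("session z-scoring is exact, affine-invariant and idempotent", {
  set.seed(4)
  x <- photometryTrace(rnorm(2000, 3, 2), 100, "x")
  z <- zscoreSession(x)
  expect_equal(mean(traceValues(z)), 0, tolerance = 1e-12)
  expect_equal(stats::sd(traceValues(z)), 1, tolerance = 1e-12)
  y <- photometryTrace(5 * traceValues(x) - 2, 100, "x")
  expect_equal(traceValues(zscoreSession(y)), traceValues(z),
               tolerance = 1e-12)
  expect_equal(traceValues(zscoreSession(z)), traceValues(z),
               tolerance = 1e-12)
  expect_error(zscoreSession(photometryTrace(rep(1, 10), 10, "x")),
               "variance")
})

test_that("unit transitions refuse invalid orderings", {
  z <- zscoreSession(photometryTrace(rnorm(100) + 10, 10, "x"))
  expect_error(dff(z), "undefined")
})

test_that("trial alignment bin count and t=0 placement follow the contract", {
  tr <- fixSession()$trials
  fs <- 1 / 0.054
  n <- ceiling((max(tr$t_side_exit) + 3) * fs)
  ## impulses at the first sample at/after each side entry: that sample
  ## falls in the bin whose left edge is t = 0
  v <- rep(0, n)
  v[ceiling(tr$t_side_entry * fs - 1e-9) + 1] <- 1
  tens <- alignTrials(photometryTrace(v, fs, "imp"), tr, window = c(1, 2))
  expect_equal(ncol(tensorData(tens)), 56)  # round(3 / 0.054)
  bt <- binTimes(tens)
  zero_bin <- which(bt > 0 & bt < 0.054)
  hits <- apply(tensorData(tens), 1, which.max)
  expect_true(all(hits == zero_bin))
  expect_true(all(rowSums(tensorData(tens)) >= 1 - 1e-9))
})

test_that("alignment drops edge trials instead of padding", {
  tr <- fixSession()$trials[1:10, ]
  fs <- 1 / 0.054
  short_n <- ceiling((tr$t_side_entry[10] + 0.5) * fs)  # ends mid-window
  v <- rnorm(short_n)
  expect_message(
    tens <- alignTrials(photometryTrace(v, fs, "x"), tr, window = c(1, 2)),
    "dropped")
  expect_lt(nrow(tensorData(tens)), 10)
  expect_equal(nrow(tensorData(tens)), length(trialIndex(tens)))
})

test_that("trial-averaged aligned tensor reproduces the side-entry kernel", {
  tr <- fixSession()$trials
  ks <- defaultKernels("da")
  co <- kernelCoef(ks); co[setdiff(rownames(co), "side_entry"), ] <- 0
  spec <- generatorSpec(kernels = list(da = kernelSet(co, kernelLags(ks)),
                                       ach = defaultKernels("ach")),
                        coupling = list(gain = 0), noise_sd = 0,
                        drift = list(amplitude = 0, freqs = 0.002),
                        amplitude_cv = 0, history_effects = FALSE)
  out <- synthesizeTraces(tr, spec, seed = 3)
  tens <- alignTrials(out$da, tr, window = c(1, 2))
  avg <- colMeans(tensorData(tens))
  bt <- binTimes(tens)
  truth <- approx(kernelLags(ks), co["side_entry", ], xout = bt, rule = 2)$y
  ## small contamination from adjacent-trial kernels at window edges
  expect_lt(sqrt(mean((avg - truth)^2)), 0.02 * max(truth))
})

test_that("sweep baseline subtraction centres the pre-stimulus window", {
  d <- matrix(5, 20, 56)
  tens <- makeTensor(d)
  out <- sweepBaselineSubtract(tens, c(-1, 0))
  expect_true(all(tensorData(out) == 0))
  set.seed(9)
  d2 <- matrix(rnorm(20 * 56), 20, 56)
  t1 <- sweepBaselineSubtract(makeTensor(d2), c(-1, 0))
  t2 <- sweepBaselineSubtract(makeTensor(d2 + 7), c(-1, 0))
  expect_equal(tensorData(t1), tensorData(t2), tolerance = 1e-12)
  expect_error(sweepBaselineSubtract(makeTensor(d2), c(5, 6)), "no bins")
})
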