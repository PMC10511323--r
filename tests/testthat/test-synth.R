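zeroKernels <- function() {
  z <- function(ks) {
    k <- kernelCoef(ks); k[] <- 0
    kernelSet(k, kernelLags(ks))
  }
  list(da = z(defaultKernels("da")), ach = z(defaultKernels("ach")))
}

quietSpec <- function(...) generatorSpec(noise_sd = 0,
                                         drift = list(amplitude = 0,
                                                      freqs = 0.002),
                                         amplitude_cv = 0, ...)

test_that("silent generator produces identically zero traces", {
  tr <- singleTrial()
  spec <- quietSpec(kernels = zeroKernels(), coupling = list(gain = 0))
  out <- synthesizeTraces(tr, spec, seed = 1)
  expect_true(all(traceValues(out$da) == 0))
  expect_true(all(traceValues(out$ach) == 0))
})

test_that("a single event reproduces its kernel at the event sample", {
  tr <- singleTrial(reward = 0)
  tr$lick_times <- ""
  ks <- zeroKernels()
  lags <- kernelLags(ks$da)
  kvec <- dnorm(lags, 0.3, 0.1) / dnorm(0.3, 0.3, 0.1) * (lags >= 0)
  co <- kernelCoef(ks$da); co["side_entry", ] <- kvec
  ks$da <- kernelSet(co, lags)
  ## one sample per kernel bin: the trace must equal the kernel exactly
  spec <- quietSpec(fs = 1 / 0.054, kernels = ks,
                    coupling = list(gain = 0), history_effects = FALSE)
  out <- synthesizeTraces(tr, spec, seed = 1)
  ## side entry at 2.16 s = sample 41 on the 54 ms grid
  v <- traceValues(out$da)
  fs <- samplingRate(out$da)
  i0 <- round(tr$t_side_entry * fs) + 1
  on_support <- round(lags * fs) + i0
  expect_equal(v[on_support], kvec, tolerance = 1e-9)
  expect_true(all(v[-on_support] == 0))
})

test_that("synthesis is linear in the kernels", {
  tr <- fixSession()$trials[1:40, ]
  k1 <- list(da = defaultKernels("da"), ach = defaultKernels("ach"))
  half <- function(ks) kernelSet(kernelCoef(ks) / 2, kernelLags(ks))
  k2 <- list(da = half(k1$da), ach = half(k1$ach))
  ksum <- list(da = kernelSet(kernelCoef(k1$da) + kernelCoef(k2$da),
                              kernelLags(k1$da)),
               ach = kernelSet(kernelCoef(k1$ach) + kernelCoef(k2$ach),
                               kernelLags(k1$ach)))
  outs <- lapply(list(k1, k2, ksum), function(k)
    synthesizeTraces(tr, quietSpec(kernels = k, coupling = list(gain = 0.4),
                                   history_effects = FALSE), seed = 7))
  expect_equal(traceValues(outs[[1]]$da) + traceValues(outs[[2]]$da),
               traceValues(outs[[3]]$da), tolerance = 1e-12)
  expect_equal(traceValues(outs[[1]]$ach) + traceValues(outs[[2]]$ach),
               traceValues(outs[[3]]$ach), tolerance = 1e-12)
})

test_that("synthesis is deterministic given the master seed", {
  tr <- fixSession()$trials[1:30, ]
  a <- synthesizeTraces(tr, generatorSpec(), seed = 5)
  b <- synthesizeTraces(tr, generatorSpec(), seed = 5)
  expect_identical(traceValues(a$da), traceValues(b$da))
  expect_identical(traceValues(a$ach), traceValues(b$ach))
  c <- synthesizeTraces(tr, generatorSpec(), seed = 6)
  expect_false(identical(traceValues(a$da), traceValues(c$da)))
})

test_that("a coupling lag off the sample grid is snapped with a warning", {
  tr <- fixSession()$trials[1:20, ]
  expect_warning(
    out <- synthesizeTraces(tr, quietSpec(coupling = list(gain = 0.5,
                                                          lag = 0.1)),
                            seed = 1),
    "snapped")
  fs <- 4 / 0.054
  expect_equal(out$truth$coupling$lag_snapped, round(0.1 * fs) / fs,
               tolerance = 1e-9)
})

test_that("the coupling subtracts lagged clean DA from Ach", {
  tr <- singleTrial(reward = 0)
  tr$lick_times <- ""
  ks <- zeroKernels()
  lags <- kernelLags(ks$da)
  co <- kernelCoef(ks$da)
  co["side_entry", ] <- exp(-abs(lags - 0.2)) * (lags >= 0)
  ks$da <- kernelSet(co, lags)
  g <- 0.5; del <- 0.108
  out <- synthesizeTraces(tr, quietSpec(kernels = ks,
                                        coupling = list(gain = g, lag = del)),
                          seed = 1)
  fs <- samplingRate(out$da)
  d <- round(del * fs)
  da <- traceValues(out$da); ach <- traceValues(out$ach)
  n <- length(da)
  expect_equal(ach[(d + 1):n], -g * da[1:(n - d)], tolerance = 1e-12)
})

test_that("carrier modulation yields a two-tone spectrum for flat envelopes", {
  fs <- 2000; dur <- 4
  n <- fs * dur
  flat <- photometryTrace(rep(0, n), fs, "x")
  raw <- modulateCarriers(flat, flat, carriers = c(167, 223), fs = fs,
                          offsets = c(2, 1))
  v <- traceValues(raw)[1:n]
  sp <- Mod(stats::fft(v))[1:(n / 2)]
  freq <- (seq_len(n / 2) - 1) / dur
  peaks <- freq[sp > 0.05 * max(sp)]
  expect_true(all(apply(abs(outer(peaks, c(167, 223), "-")), 1, min) < 1))
  ## amplitudes proportional to the offsets
  expect_equal(sp[which.min(abs(freq - 167))] /
                 sp[which.min(abs(freq - 223))], 2, tolerance = 0.05)
})

test_that("negative envelope excursions are rejected", {
  fs <- 500
  tr <- photometryTrace(rep(-2, fs), fs, "x")
  flat <- photometryTrace(rep(0, fs), fs, "y")
  expect_error(modulateCarriers(tr, flat, fs = fs, offsets = c(1, 1)),
               "below -B")
})

test_that("kernel sets survive a JSON round trip", {
  ks <- defaultKernels("da")
  f <- withr::local_tempfile(fileext = ".json")
  writeKernelSet(ks, f)
  back <- readKernelSet(f)
  expect_equal(kernelCoef(back), kernelCoef(ks), tolerance = 1e-12)
  expect_equal(kernelLags(back), kernelLags(ks), tolerance = 1e-12)
})
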