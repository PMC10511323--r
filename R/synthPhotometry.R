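## Synthetic DA / Ach generator: linear event-kernel model with
## history-dependent amplitudes, lagged negative DA->Ach coupling, slow
## drift, white noise, and optional frequency-multiplexed carriers.

## Difference-of-Gaussians kernel evaluated on a lag axis, truncated to
## non-negative lags (event-locked transients are causal; the negative half
## of the lag axis stays in the model so fitted kernels can be checked
## against zero there).
dogKernel <- function(lags, mu1, sd1, a1, mu2 = NA, sd2 = NA, a2 = 0) {
  k <- a1 * exp(-(lags - mu1)^2 / (2 * sd1^2))
  if (a2 != 0) k <- k - a2 * exp(-(lags - mu2)^2 / (2 * sd2^2))
  k * (lags >= 0)
}

#' Default generator kernels
#'
#' Difference-of-Gaussians event kernels per channel on a lag axis spanning
#' [-0.5, 2] s (bin 54 ms), causal (zero at negative lags), with amplitudes
#' placing the z-scored traces roughly in [-3, 4]: a large positive reward
#' transient and moderate port-entry transients for DA, a multiphasic
#' side-entry transient with a negative reward lobe and small lick and
#' side-exit responses for Ach. The two channels are event-selective (Ach
#' carries no centre-port kernels, DA no lick/side-exit kernels), so the
#' only cross-channel covariance the default generator produces is the
#' explicit DA-to-Ach coupling — which keeps that coupling identifiable in
#' the noise-correlation analyses. The DA centre-exit kernel is identically
#' zero, giving leave-out analyses a known-null feature.
#'
#' @param channel "da" or "ach".
#' @param bin lag bin width in seconds (default 0.054).
#' @param span lag axis span in seconds (default c(-0.5, 2)).
#' @return a [KernelSet-class] with the six task event features.
#' @export
defaultKernels <- function(channel = c("da", "ach"), bin = 0.054,
                           span = c(-0.5, 2)) {
  channel <- match.arg(channel)
  ## lag axis snapped to integer multiples of the bin so kernels sit exactly
  ## on the default sample grid (no interpolation smoothing at synthesis)
  lags <- seq(round(span[1] / bin), round(span[2] / bin)) * bin
  k <- if (channel == "da") rbind(
    centre_entry = dogKernel(lags, 0.15, 0.08, 0.4),
    centre_exit  = 0 * lags,
    side_entry   = dogKernel(lags, 0.20, 0.10, 0.6, 0.60, 0.18, 0.25),
    side_exit    = 0 * lags,
    lick         = 0 * lags,
    reward       = dogKernel(lags, 0.30, 0.12, 1.0, 0.75, 0.15, 0.3))
  else rbind(
    centre_entry = 0 * lags,
    centre_exit  = 0 * lags,
    side_entry   = dogKernel(lags, 0.15, 0.08, 0.8, 0.5, 0.20, 0.4),
    side_exit    = dogKernel(lags, 0.20, 0.10, 0.2),
    lick         = dogKernel(lags, 0.10, 0.06, 0.15),
    reward       = -dogKernel(lags, 0.40, 0.18, 0.5))
  kernelSet(k, lags, binWidth = bin)
}

#' Default amplitude rules
#'
#' Gains applied to the side-entry-locked transient (the side-entry kernel,
#' and the reward kernel on rewarded trials) as a function of reward outcome
#' and of the eight stay/switch x previous x current outcome history labels.
#' The history ordering follows an unexpected-reward pattern: a win after a
#' loss ("lose-win") drives a larger transient than a win after a win, and
#' the modulation is present on stay trials but absent on switch trials.
#'
#' @param channel "da" or "ach".
#' @param history_effects logical; FALSE sets all history gains to 1.
#' @return list with `side_entry_outcome` (win/lose gains),
#'   `side_entry_history` (8 named gains) and `reward_gain`.
#' @export
defaultAmplitudeRules <- function(channel = c("da", "ach"),
                                  history_effects = TRUE) {
  channel <- match.arg(channel)
  labels <- as.vector(outer(c("stay", "switch"),
                            as.vector(outer(c("win", "lose"), c("win", "lose"),
                                            paste, sep = "_")),
                            paste, sep = "_"))
  hist <- stats::setNames(rep(1, 8), labels)
  if (history_effects) {
    ## reward-prediction-error-like ordering on stay trials (an unexpected
    ## win after a loss drives the largest transient; an unexpected loss
    ## after a win the largest deviation in the other direction); history
    ## effects are absent when the animal switches ports
    if (channel == "da") {
      hist["stay_lose_win"] <- 1.6
      hist["stay_win_lose"] <- 0.5
      hist["stay_lose_lose"] <- 0.8
    } else {
      hist["stay_lose_win"] <- 1.5
      hist["stay_win_lose"] <- 1.4
      hist["stay_lose_lose"] <- 0.7
    }
  }
  outcome <- if (channel == "ach") c(win = 1, lose = 1.4) else c(win = 1, lose = 1)
  list(side_entry_outcome = outcome, side_entry_history = hist,
       reward_gain = 1)
}

#' Generator specification
#'
#' Full description of the synthetic photometry model:
#' \deqn{DA(t) = \sum_{events} a_e k_{DA}(t - t_e) + drift + noise}
#' \deqn{Ach(t) = \sum_{events} a_e k_{Ach}(t - t_e)
#'   - g(t) DA_{clean}(t - \delta) + drift + noise}
#' where the coupling acts on the noiseless DA signal with gain `g >= 0`,
#' lag `delta` (~100 ms by default, snapped to the sample grid) and negative
#' sign, and event amplitudes `a_e` carry outcome/history gains plus
#' independent per-trial lognormal jitter (`amplitude_cv`).
#'
#' @param fs sampling rate of the generated (demodulated-scale) traces;
#'   default `4/0.054` (~74 Hz), four samples per 54 ms analysis bin, so
#'   that bin-mean aggregation averages out sub-bin alignment phase.
#' @param kernels list with `da` and `ach` [KernelSet-class] ground truth.
#' @param amplitude_rules list with `da` and `ach` rule lists
#'   ([defaultAmplitudeRules()]).
#' @param coupling list: `gain` (g >= 0), `lag` (seconds, >= 0), optional
#'   `gate` = c(start, end) seconds relative to side entry inside which the
#'   gain is zero (the within-trial epoch where the interaction shuts off).
#' @param noise_sd additive white-noise standard deviation (trace units).
#' @param drift list: `amplitude` and `freqs` (< 0.01 Hz sinusoids).
#' @param amplitude_cv per-trial lognormal amplitude jitter of the
#'   side-entry/reward transients, independent across channels.
#' @param history_effects convenience switch forwarded to
#'   [defaultAmplitudeRules()] when `amplitude_rules` is not supplied.
#' @param carriers optional c(f_DA, f_Ach) in Hz for [modulateCarriers()].
#' @return classed generator specification list.
#' @examples
#' spec <- generatorSpec(coupling = list(gain = 0.5, lag = 0.108))
#' @export
generatorSpec <- function(fs = 4 / 0.054, kernels = NULL,
                          amplitude_rules = NULL,
                          coupling = list(gain = 0.5, lag = 0.108),
                          noise_sd = 0.1,
                          drift = list(amplitude = 0.05,
                                       freqs = c(0.002, 0.005)),
                          amplitude_cv = 0.25, history_effects = TRUE,
                          carriers = NULL) {
  if (is.null(kernels))
    kernels <- list(da = defaultKernels("da"), ach = defaultKernels("ach"))
  if (is.null(amplitude_rules))
    amplitude_rules <- list(
      da = defaultAmplitudeRules("da", history_effects),
      ach = defaultAmplitudeRules("ach", history_effects))
  coupling <- utils::modifyList(list(gain = 0.5, lag = 0.108, gate = NULL),
                                coupling)
  stopIf(coupling$gain < 0, "coupling gain must be >= 0")
  stopIf(coupling$lag < 0, "coupling lag must be >= 0")
  if (!is.null(carriers))
    stopIf(fs <= 2 * max(carriers),
           "fs must exceed twice the carrier frequency")
  structure(list(fs = fs, kernels = kernels,
                 amplitude_rules = amplitude_rules, coupling = coupling,
                 noise_sd = noise_sd, drift = drift,
                 amplitude_cv = amplitude_cv, carriers = carriers),
            class = "generatorSpec")
}

#' @export
print.generatorSpec <- function(x, ...) {
  cat(sprintf(
    "Generator spec: fs = %.4g Hz, coupling g = %.2g @ %.0f ms, noise sd = %.2g, amplitude cv = %.2g\n",
    x$fs, x$coupling$gain, 1000 * x$coupling$lag, x$noise_sd,
    x$amplitude_cv))
  invisible(x)
}

## Add amplitude-scaled kernels at event times onto a sample grid (linear
## interpolation of the stored kernel onto the sample lags; exact when
## events sit on the grid and fs matches the kernel bin rate). Samples
## outside the kernel's nonzero support stay exactly zero, so a causal
## kernel with a step at lag 0 never bleeds across it by interpolation.
addKernel <- function(trace, t_grid, times, amps, lags, coefs) {
  if (!length(times) || !any(coefs != 0)) return(trace)
  fs <- 1 / (t_grid[2] - t_grid[1])
  nz <- range(lags[coefs != 0])
  for (j in seq_along(times)) {
    i0 <- floor((times[j] + lags[1]) * fs) + 1
    i1 <- ceiling((times[j] + lags[length(lags)]) * fs) + 1
    idx <- max(1, i0):min(length(trace), i1)
    xout <- t_grid[idx] - times[j]
    kv <- stats::approx(lags, coefs, xout = xout, rule = 1)$y
    kv[is.na(kv) | xout < nz[1] - 1e-12 | xout > nz[2] + 1e-12] <- 0
    trace[idx] <- trace[idx] + amps[j] * kv
  }
  trace
}

#' Synthesize DA and Ach traces from a behavioural session
#'
#' Builds both channels as sums of per-event kernels with outcome- and
#' history-dependent amplitudes, applies the lagged negative DA-to-Ach
#' coupling to the noiseless DA signal, then adds slow sinusoidal drift and
#' white noise. Deterministic given `seed`; all per-channel randomness uses
#' substreams derived from it.
#'
#' @param trials trial table from [simulateSession()].
#' @param spec a [generatorSpec()].
#' @param seed master seed.
#' @param events optional event stream (accepted for interface symmetry;
#'   event times are taken from the trial table, which carries the labels
#'   the amplitude rules need).
#' @return list: `da`, `ach` ([PhotometryTrace-class]), and `truth` with the
#'   ground-truth kernels, the coupling (lag snapped to the sample grid as
#'   `lag_snapped`) and the per-trial amplitude gains actually applied.
#' @examples
#' sess <- simulateSession(taskConfig(n_trials = 30), agentParams(), seed = 1)
#' out <- synthesizeTraces(sess$trials, generatorSpec(), seed = 1)
#' out$da
#' @export
synthesizeTraces <- function(trials, spec = generatorSpec(), seed = 1L,
                             events = NULL) {
  stopifnot(inherits(spec, "generatorSpec"))
  fs <- spec$fs
  max_lag <- max(kernelLags(spec$kernels$da))
  t_end <- max(trials$t_side_exit) + max_lag + 0.5
  n <- ceiling(t_end * fs) + 1
  t_grid <- (seq_len(n) - 1) / fs
  ntr <- nrow(trials)
  lab <- trials$history_label
  outc <- ifelse(trials$reward == 1, "win", "lose")
  lk <- lickTimes(trials$lick_times)

  sdlog <- sqrt(log(1 + spec$amplitude_cv^2))
  clean <- list()
  gains <- list()
  for (ch in c("da", "ach")) {
    jit <- withSeed(subSeed(seed, paste0("amp_", ch)),
                    stats::rlnorm(ntr, -sdlog^2 / 2, sdlog))
    rules <- spec$amplitude_rules[[ch]]
    ## history gains scale the whole side-entry-locked transient complex
    ## (side-entry and reward kernels), matching metrics that read out the
    ## post-side-entry window
    hgain <- ifelse(is.na(lab), 1, rules$side_entry_history[lab])
    se_amp <- rules$side_entry_outcome[outc] * hgain * jit
    rw_amp <- rules$reward_gain * hgain * jit
    ks <- spec$kernels[[ch]]
    lags <- kernelLags(ks)
    co <- kernelCoef(ks)
    tr <- numeric(n)
    tr <- addKernel(tr, t_grid, trials$t_centre_entry, rep(1, ntr), lags,
                    co["centre_entry", ])
    tr <- addKernel(tr, t_grid, trials$t_centre_exit, rep(1, ntr), lags,
                    co["centre_exit", ])
    tr <- addKernel(tr, t_grid, trials$t_side_entry, se_amp, lags,
                    co["side_entry", ])
    tr <- addKernel(tr, t_grid, trials$t_side_exit, rep(1, ntr), lags,
                    co["side_exit", ])
    tr <- addKernel(tr, t_grid, unlist(lk), rep(1, length(unlist(lk))), lags,
                    co["lick", ])
    rewarded <- which(trials$reward == 1)
    tr <- addKernel(tr, t_grid, trials$t_side_entry[rewarded],
                    rw_amp[rewarded], lags, co["reward", ])
    clean[[ch]] <- tr
    gains[[ch]] <- data.frame(trial = trials$trial, side_entry = se_amp,
                              reward = rw_amp * (trials$reward == 1))
  }

  ## lagged negative coupling on the noiseless DA signal
  delay <- round(spec$coupling$lag * fs)
  lag_snapped <- delay / fs
  if (abs(lag_snapped - spec$coupling$lag) > 1e-9)
    warning(sprintf(
      "coupling lag %.4g s is not a multiple of the sample period; snapped to %.4g s",
      spec$coupling$lag, lag_snapped))
  gvec <- rep(spec$coupling$gain, n)
  if (!is.null(spec$coupling$gate)) {
    gate <- spec$coupling$gate
    for (i in seq_len(ntr)) {
      idx <- which(t_grid - trials$t_side_entry[i] >= gate[1] &
                     t_grid - trials$t_side_entry[i] <= gate[2])
      gvec[idx] <- 0
    }
  }
  da_delayed <- c(numeric(delay), clean$da)[seq_len(n)]
  clean$ach <- clean$ach - gvec * da_delayed

  out <- list()
  for (ch in c("da", "ach")) {
    dr <- numeric(n)
    if (spec$drift$amplitude > 0) {
      ph <- withSeed(subSeed(seed, paste0("drift_", ch)),
                     stats::runif(length(spec$drift$freqs), 0, 2 * pi))
      for (j in seq_along(spec$drift$freqs))
        dr <- dr + spec$drift$amplitude *
          sin(2 * pi * spec$drift$freqs[j] * t_grid + ph[j])
    }
    noise <- if (spec$noise_sd > 0)
      withSeed(subSeed(seed, paste0("noise_", ch)),
               stats::rnorm(n, 0, spec$noise_sd)) else numeric(n)
    out[[ch]] <- photometryTrace(clean[[ch]] + dr + noise, fs = fs,
                                 channel = toupper(ch), units = "F")
  }
  list(da = out$da, ach = out$ach,
       truth = list(kernels = spec$kernels,
                    coupling = c(spec$coupling,
                                 list(lag_snapped = lag_snapped)),
                    gains = gains, clean = clean))
}

#' Amplitude-modulate two envelope traces onto carriers
#'
#' Produces the raw frequency-multiplexed stream
#' \deqn{raw(t) = (B_A + A(t))\sin(2\pi f_A t) + (B_B + B(t))\sin(2\pi f_B t)}
#' at the acquisition rate, with positive offsets keeping both envelopes
#' non-negative; [demodulate()] inverts it channel by channel.
#'
#' @param traceA,traceB envelope [PhotometryTrace-class] objects.
#' @param carriers c(f_A, f_B) in Hz (default c(167, 223)).
#' @param fs output sampling rate (default 2000 Hz).
#' @param offsets c(B_A, B_B) carrier baseline offsets (default c(3, 3)).
#' @return a [PhotometryTrace-class] with units "raw".
#' @export
modulateCarriers <- function(traceA, traceB, carriers = c(167, 223),
                             fs = 2000, offsets = c(3, 3)) {
  stopIf(fs <= 2 * max(carriers), "fs violates Nyquist for the carriers")
  t_end <- min(max(traceTimes(traceA)), max(traceTimes(traceB)))
  t <- seq(0, t_end, by = 1 / fs)
  a <- stats::approx(traceTimes(traceA), traceValues(traceA), xout = t,
                     rule = 2)$y
  b <- stats::approx(traceTimes(traceB), traceValues(traceB), xout = t,
                     rule = 2)$y
  stopIf(any(offsets[1] + a < 0) || any(offsets[2] + b < 0),
         "envelope excursions below -B; increase the carrier offsets")
  raw <- (offsets[1] + a) * sin(2 * pi * carriers[1] * t) +
    (offsets[2] + b) * sin(2 * pi * carriers[2] * t)
  photometryTrace(raw, fs = fs, channel = "multiplexed", units = "raw")
}

#' Serialize a KernelSet to JSON
#' @param ks a [KernelSet-class].
#' @param path output path.
#' @return the path invisibly.
#' @export
writeKernelSet <- function(ks, path) {
  jsonlite::write_json(list(
    features = kernelFeatures(ks), lags = kernelLags(ks),
    coef = as.data.frame(t(kernelCoef(ks))),
    sd = as.data.frame(t(ks@sd)), bin_width = ks@binWidth),
    path, digits = NA)
  invisible(path)
}

#' @rdname writeKernelSet
#' @export
readKernelSet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- t(as.matrix(x$coef))
  sd <- t(as.matrix(x$sd))
  dimnames(co) <- dimnames(sd) <- list(x$features, NULL)
  kernelSet(co, x$lags, sd = sd, binWidth = x$bin_width)
}
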