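## Preprocessing: lock-in demodulation, dF/F0, session z-scoring, trial
## alignment, pre-stimulus baseline subtraction.

#' Quadrature lock-in demodulation
#'
#' Recovers the slowly varying envelope of one amplitude-modulated carrier
#' from a frequency-multiplexed stream: the raw signal is multiplied by sine
#' and cosine references at the carrier frequency, each product is low-pass
#' filtered (4th-order Butterworth, forward-backward for zero phase), and
#' the output is `2 * sqrt(I^2 + Q^2)`, calibrated so a constant envelope A
#' returns A. Optionally decimated.
#'
#' @param raw a [PhotometryTrace-class] with units "raw".
#' @param carrier carrier frequency in Hz.
#' @param lowpass_cutoff low-pass corner in Hz (default 15; must be well
#'   below the carrier separation).
#' @param fs_out optional output rate; the envelope is bin-averaged down to
#'   it after demodulation.
#' @return a [PhotometryTrace-class] with units "F".
#' @export
demodulate <- function(raw, carrier, lowpass_cutoff = 15, fs_out = NULL) {
  fs <- samplingRate(raw)
  stopIf(fs <= 2 * carrier, "Nyquist violation: fs must exceed 2 * carrier")
  stopIf(lowpass_cutoff >= carrier, "low-pass cutoff must be below the carrier")
  t <- traceTimes(raw)
  x <- traceValues(raw)
  bf <- signal::butter(4, lowpass_cutoff / (fs / 2), type = "low")
  i_arm <- signal::filtfilt(bf, x * sin(2 * pi * carrier * t))
  q_arm <- signal::filtfilt(bf, x * cos(2 * pi * carrier * t))
  env <- 2 * sqrt(i_arm^2 + q_arm^2)
  out <- photometryTrace(env, fs = fs, channel = channelName(raw),
                         units = "F", t0 = raw@t0)
  if (!is.null(fs_out) && fs_out < fs) {
    dec <- floor(fs / fs_out)
    nb <- floor(length(env) / dec)
    env2 <- colMeans(matrix(env[seq_len(nb * dec)], nrow = dec))
    out <- photometryTrace(env2, fs = fs / dec, channel = channelName(raw),
                           units = "F", t0 = raw@t0 + (dec - 1) / (2 * fs))
  }
  out
}

## Running percentile baseline on a coarse anchor grid (one anchor per
## `step` seconds), linearly interpolated back to the full grid. The window
## is much longer than a trial so transients do not drag the baseline.
runningPercentile <- function(x, fs, window = 30, prob = 0.1, step = 1) {
  n <- length(x)
  half <- round(window * fs / 2)
  anchors <- unique(pmin(pmax(round(seq(1, n, by = max(1, round(step * fs))))
                              , 1), n))
  vals <- vapply(anchors, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::quantile(x[lo:hi], prob, names = FALSE)
  }, numeric(1))
  stats::approx(anchors, vals, xout = seq_len(n), rule = 2)$y
}

#' Fractional fluorescence change dF/F0
#'
#' `(F - F0) / F0` with the baseline `F0` estimated per `baseline_mode`:
#' `"running_percentile"` (default: 10th percentile in a running 30-s
#' window, robust to transients), `"pre_event_window"` (mean of a window
#' before each supplied event, interpolated between events), or
#' `"constant"`.
#'
#' @param trace a [PhotometryTrace-class] with units "F".
#' @param baseline_mode baseline estimator.
#' @param params list of estimator parameters: `window`, `prob`, `step`
#'   (running percentile); `event_times`, `window` (pre-event); `F0`
#'   (constant).
#' @return a [PhotometryTrace-class] with units "dF/F".
#' @export
dff <- function(trace, baseline_mode = c("running_percentile",
                                         "pre_event_window", "constant"),
                params = list()) {
  baseline_mode <- match.arg(baseline_mode)
  stopIf(signalUnits(trace) == "zscore",
         "dF/F of a z-scored trace is undefined; apply dff before zscoreSession")
  x <- traceValues(trace)
  fs <- samplingRate(trace)
  f0 <- switch(baseline_mode,
    running_percentile = {
      p <- utils::modifyList(list(window = 30, prob = 0.1, step = 1), params)
      runningPercentile(x, fs, p$window, p$prob, p$step)
    },
    pre_event_window = {
      stopIf(is.null(params$event_times), "pre_event_window needs event_times")
      w <- if (is.null(params$window)) 1 else params$window
      tt <- traceTimes(trace)
      means <- vapply(params$event_times, function(e)
        mean(x[tt >= e - w & tt < e]), numeric(1))
      stats::approx(params$event_times, means, xout = tt, rule = 2)$y
    },
    constant = {
      if (is.null(params$F0)) stats::quantile(x, 0.1, names = FALSE)
      else params$F0
    })
  bad <- which(f0 <= 0)
  stopIf(length(bad) > 0,
         "non-positive baseline F0 at %d samples (first at index %d); add an offset or choose another baseline mode",
         length(bad), bad[1])
  photometryTrace((x - f0) / f0, fs = fs, channel = channelName(trace),
                  units = "dF/F", t0 = trace@t0)
}

#' Session z-score
#'
#' `(x - mean) / sd` over the whole session.
#'
#' @param trace a [PhotometryTrace-class].
#' @return a [PhotometryTrace-class] with units "zscore".
#' @export
zscoreSession <- function(trace) {
  x <- traceValues(trace)
  s <- stats::sd(x)
  stopIf(!is.finite(s) || s == 0, "trace variance must be positive")
  photometryTrace((x - mean(x)) / s, fs = samplingRate(trace),
                  channel = channelName(trace), units = "zscore",
                  t0 = trace@t0)
}

#' Align a trace into a trials x time-bins tensor
#'
#' Cuts a window around the per-trial alignment timestamp and aggregates
#' samples into uniform bins by bin means (preserving the noise statistics
#' that the covariance analyses use; no interpolation). The alignment
#' timestamp falls in the bin whose left edge is t = 0. Trials whose window
#' exceeds the trace span are dropped with a message, never zero-padded.
#'
#' @param trace a [PhotometryTrace-class].
#' @param trials trial table.
#' @param align_event name of the timestamp column to align to (default
#'   `"t_side_entry"`).
#' @param window c(pre, post) seconds around the event (both positive).
#' @param bin_width bin width in seconds (default 0.054; must be >= one
#'   sample period).
#' @return a [TrialTensor-class].
#' @examples
#' sess <- simulateSession(taskConfig(n_trials = 40), agentParams(), seed = 3)
#' out <- synthesizeTraces(sess$trials, generatorSpec(), seed = 3)
#' tens <- alignTrials(out$da, sess$trials, window = c(1, 2))
#' dim(tens)
#' @export
alignTrials <- function(trace, trials, align_event = "t_side_entry",
                        window = c(1, 2), bin_width = 0.054) {
  fs <- samplingRate(trace)
  stopIf(bin_width < 1 / fs, "bin_width must be at least one sample period")
  stopIf(!align_event %in% names(trials), "unknown alignment event column")
  nb <- round(sum(window) / bin_width)
  npre <- round(window[1] / bin_width)
  edges_rel <- (seq_len(nb + 1) - npre - 1) * bin_width
  tt0 <- trace@t0
  nsamp <- length(trace)
  x <- traceValues(trace)
  keep <- integer(0)
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    t0 <- trials[[align_event]][i]
    edges <- t0 + edges_rel
    i_lo <- ceiling((edges[1] - tt0) * fs - 1e-9) + 1
    i_hi <- floor((edges[nb + 1] - tt0) * fs + 1e-9) + 1
    if (i_lo < 1 || i_hi > nsamp) next
    idx <- i_lo:i_hi
    bin_of <- findInterval((idx - 1) / fs + tt0, edges,
                           rightmost.closed = FALSE)
    ok <- bin_of >= 1 & bin_of <= nb
    m <- vapply(seq_len(nb), function(b) mean(x[idx[ok][bin_of[ok] == b]]),
                numeric(1))
    rows[[length(rows) + 1L]] <- m
    keep <- c(keep, i)
  }
  if (length(keep) < nrow(trials))
    message(sprintf("alignTrials: dropped %d edge trial(s) whose window exceeds the trace span",
                    nrow(trials) - length(keep)))
  stopIf(length(keep) == 0, "no trials fall inside the trace span")
  new("TrialTensor", data = do.call(rbind, rows), alignEvent = align_event,
      window = as.numeric(window), binWidth = bin_width,
      trialIndex = as.integer(keep), channel = channelName(trace))
}

#' Subtract a pre-stimulus baseline from a sweep tensor
#'
#' Subtracts the scalar mean of the baseline window, computed across all
#' sweeps, from every bin of every sweep (the pre-stimulus averaging used
#' for stimulation sweeps).
#'
#' @param tensor a [TrialTensor-class].
#' @param baseline_window c(start, end) seconds relative to alignment; must
#'   lie inside the tensor window.
#' @return a baseline-subtracted [TrialTensor-class].
#' @export
sweepBaselineSubtract <- function(tensor, baseline_window = c(-1.5, 0)) {
  bt <- binTimes(tensor)
  sel <- bt >= baseline_window[1] & bt <= baseline_window[2]
  stopIf(!any(sel), "baseline window contains no bins")
  base <- mean(tensorData(tensor)[, sel])
  new("TrialTensor", data = tensorData(tensor) - base,
      alignEvent = tensor@alignEvent, window = tensor@window,
      binWidth = tensor@binWidth, trialIndex = tensor@trialIndex,
      channel = tensor@channel)
}
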