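## DA-Ach relationship: lagged cross-covariance of trial-segregated
## signals, noise correlations about condition means, the two-dimensional
## covariance function K(t1, t2) with off-diagonal extraction, and
## permutation null controls.

checkPair <- function(A, B) {
  stopIf(!identical(dim(A@data), dim(B@data)),
         "tensors must share the trial x bin grid")
  stopIf(!identical(A@trialIndex, B@trialIndex),
         "tensors must cover the same trials")
  stopIf(abs(A@binWidth - B@binWidth) > 1e-12,
         "tensors must share the bin width")
}

centreTensor <- function(T_, mode, conditions) {
  d <- tensorData(T_)
  if (mode == "raw") return(d - mean(d))
  stopIf(is.null(conditions), "noise mode requires condition labels")
  stopIf(length(conditions) != nrow(d),
         "condition labels must match tensor rows")
  tb <- table(conditions)
  stopIf(any(tb < 2), "singleton condition: %s",
         paste(names(tb)[tb < 2], collapse = ", "))
  for (cnd in names(tb)) {
    i <- which(conditions == cnd)
    d[i, ] <- sweep(d[i, , drop = FALSE], 2,
                    colMeans(d[i, , drop = FALSE]))
  }
  d
}

#' Residuals about condition-specific trial-averaged waveforms
#'
#' Subtracts each condition's mean waveform from its member trials — the
#' centering behind "noise correlations". Residual means are zero at every
#' bin within each condition.
#'
#' @param tensor a [TrialTensor-class].
#' @param conditions per-trial condition labels (e.g. rewarded/unrewarded).
#' @return a [TrialTensor-class] of residuals.
#' @export
conditionMeanResiduals <- function(tensor, conditions) {
  d <- centreTensor(tensor, "noise", conditions)
  methods::initialize(tensor, data = d)
}

## Core lagged covariance on centred matrices; positive lag = A leads B
## (A at time t is paired with B at time t + lag). Overlapping-segment
## estimate: per-lag means over the valid bins, never zero-padded.
lagCov <- function(a, b, max_lag_bins) {
  nb <- ncol(a)
  lags <- seq(-max_lag_bins, max_lag_bins)
  vals <- vapply(lags, function(l) {
    if (l >= 0) mean(a[, seq_len(nb - l), drop = FALSE] *
                       b[, seq_len(nb - l) + l, drop = FALSE])
    else mean(a[, seq_len(nb + l) - l, drop = FALSE] *
                b[, seq_len(nb + l), drop = FALSE])
  }, numeric(1))
  data.frame(lag_bins = lags, value = vals)
}

#' Lagged cross-covariance of two trial tensors
#'
#' Covariance between channel A at time t and channel B at time t + lag,
#' averaged over trials and valid bins. In `"raw"` mode each tensor is
#' centred by its session mean; in `"noise"` mode per-trial residuals about
#' the condition-specific trial-averaged waveforms are used, isolating
#' trial-to-trial co-fluctuation from event-locked structure. Sign
#' convention: a positive-lag extremum means channel A leads channel B.
#'
#' @param A,B [TrialTensor-class] objects on the same grid and trials.
#' @param max_lag maximum |lag| in seconds.
#' @param mode "raw" or "noise".
#' @param conditions per-trial labels, required for noise mode.
#' @param normalize "covariance" (default, matching the analyses) or
#'   "correlation".
#' @return classed `lagCurve` data.frame: `lag_s`, `lag_bins`, `value`,
#'   with the extremum lag in attributes.
#' @export
crosscovLagged <- function(A, B, max_lag = 1, mode = c("raw", "noise"),
                           conditions = NULL,
                           normalize = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  checkPair(A, B)
  L <- round(max_lag / A@binWidth)
  stopIf(L >= ncol(A@data), "max_lag exceeds the tensor window")
  a <- centreTensor(A, mode, conditions)
  b <- centreTensor(B, mode, conditions)
  out <- lagCov(a, b, L)
  if (normalize == "correlation")
    out$value <- out$value / (stats::sd(a) * stats::sd(b))
  out$lag_s <- out$lag_bins * A@binWidth
  structure(out[, c("lag_s", "lag_bins", "value")],
            class = c("lagCurve", "data.frame"),
            mode = mode, channels = c(A@channel, B@channel),
            convention = "positive lag = A leads B",
            min_lag_s = out$lag_s[which.min(out$value)],
            max_lag_s = out$lag_s[which.max(out$value)])
}

#' Two-dimensional covariance function K(t1, t2)
#'
#' `K[i, j]` is the mean over trials of the centred channel-A signal at
#' time `t1[i]` times the centred channel-B signal at `t2[j]` — how
#' fluctuation about the mean in one channel at one time relates to
#' fluctuation in the other channel at another time. Centering follows
#' `mode` as in [crosscovLagged()].
#'
#' @inheritParams crosscovLagged
#' @return a [CovMatrix-class].
#' @export
covMatrix2D <- function(A, B, mode = c("raw", "noise"), conditions = NULL) {
  mode <- match.arg(mode)
  checkPair(A, B)
  n <- nrow(A@data)
  stopIf(n < 3, "need at least 3 trials")
  if (n < 10) warning("fewer than 10 trials; K(t1,t2) will be noisy")
  a <- centreTensor(A, mode, conditions)
  b <- centreTensor(B, mode, conditions)
  K <- crossprod(a, b) / n
  bt <- binTimes(A)
  new("CovMatrix", K = K, t1 = bt, t2 = binTimes(B), nTrials = as.integer(n),
      channels = c(A@channel, B@channel), mode = mode)
}

#' Off-diagonal band of a covariance matrix
#'
#' For each t1, the mean of `K(t1, t2)` over `t2` in
#' `[t1 + offset - band_halfwidth, t1 + offset + band_halfwidth]` — the
#' covariance at a fixed time offset, as a function of within-trial time.
#' Edge bins whose band falls partly outside the matrix are averaged over
#' the available part and flagged.
#'
#' @param K a [CovMatrix-class].
#' @param offset band offset in seconds (positive: channel A leads).
#' @param band_halfwidth half-width of the averaged band in seconds
#'   (default one bin).
#' @return data.frame: `t1`, `value`, `n_bins`, `truncated`.
#' @export
offDiagonal <- function(K, offset = 0.1, band_halfwidth = NULL) {
  bw <- if (length(K@t1) > 1) K@t1[2] - K@t1[1] else 1
  if (is.null(band_halfwidth)) band_halfwidth <- bw / 2
  stopIf(abs(offset) > diff(range(K@t2)),
         "offset lies outside the matrix span")
  rows <- lapply(seq_along(K@t1), function(i) {
    target <- K@t1[i] + offset
    sel <- which(K@t2 >= target - band_halfwidth - 1e-9 &
                   K@t2 <= target + band_halfwidth + 1e-9)
    full <- target - band_halfwidth >= min(K@t2) - bw / 2 &
      target + band_halfwidth <= max(K@t2) + bw / 2
    data.frame(t1 = K@t1[i],
               value = if (length(sel)) mean(K@K[i, sel]) else NA_real_,
               n_bins = length(sel), truncated = !full)
  })
  do.call(rbind, rows)
}

#' Permutation null controls for the lagged cross-covariance
#'
#' Destroys the within-trial temporal pairing between channels while
#' keeping each channel's own statistics: `"circular_shift"` applies an
#' independent random circular time shift to each trial of channel B per
#' permutation; `"session_swap"` pairs channel A trials with channel B
#' trials from a different session (`B_alt`), permuting the pairing each
#' time. Returns pointwise 2.5/97.5 percentile bands per lag plus a
#' simultaneous band built from each permutation's extrema (min/max across
#' lags), which is the right reference when asking whether *any* lag shows
#' coupling. Deterministic given `seed`.
#'
#' @inheritParams crosscovLagged
#' @param null_mode "circular_shift" or "session_swap".
#' @param B_alt channel-B tensor from another session (session_swap).
#' @param n_perm number of permutations (default 500; < 100 warns).
#' @param seed RNG seed.
#' @return list: `band` (data.frame lag_s, lo, hi), `simultaneous`
#'   (c(lo, hi) from per-permutation extrema), `null_min`, `null_max`.
#' @export
nullControls <- function(A, B, max_lag = 1,
                         null_mode = c("circular_shift", "session_swap"),
                         mode = c("raw", "noise"), conditions = NULL,
                         B_alt = NULL, n_perm = 500L, seed = 1L) {
  null_mode <- match.arg(null_mode)
  mode <- match.arg(mode)
  checkPair(A, B)
  if (n_perm < 100) warning("fewer than 100 permutations; bands will be coarse")
  L <- round(max_lag / A@binWidth)
  a <- centreTensor(A, mode, conditions)
  if (null_mode == "session_swap") {
    stopIf(is.null(B_alt),
           "session_swap requires B_alt, a channel-B tensor from another session")
    b_src <- centreTensor(B_alt, mode,
                          if (!is.null(conditions)) conditions else NULL)
    stopIf(ncol(b_src) != ncol(a), "B_alt must share the bin grid")
  } else {
    b_src <- centreTensor(B, mode, conditions)
  }
  nb <- ncol(a)
  nt <- nrow(a)
  perms <- withSeed(subSeed(seed, "null"),
    lapply(seq_len(n_perm), function(p) {
      bp <- if (null_mode == "circular_shift") {
        sh <- sample(nb - 1L, nt, replace = TRUE)
        t(vapply(seq_len(nt), function(i)
          b_src[i, ((seq_len(nb) - 1 + sh[i]) %% nb) + 1], numeric(nb)))
      } else {
        b_src[sample(min(nt, nrow(b_src)), nt, replace = nt > nrow(b_src)), ,
              drop = FALSE]
      }
      lagCov(a, bp, L)$value
    }))
  M <- do.call(rbind, perms)
  lags <- seq(-L, L) * A@binWidth
  band <- data.frame(lag_s = lags,
                     lo = apply(M, 2, stats::quantile, 0.025),
                     hi = apply(M, 2, stats::quantile, 0.975))
  mins <- apply(M, 1, min)
  maxs <- apply(M, 1, max)
  list(band = band,
       simultaneous = c(lo = stats::quantile(mins, 0.025, names = FALSE),
                        hi = stats::quantile(maxs, 0.975, names = FALSE)),
       null_min = mins, null_max = maxs, n_perm = n_perm,
       null_mode = null_mode)
}

#' Null control for the off-diagonal covariance summary
#'
#' Circular-shift permutation null for the mean off-diagonal value of
#' K(t1, t2) at a fixed offset.
#'
#' @inheritParams nullControls
#' @param offset off-diagonal offset in seconds.
#' @return list: `observed` mean off-diagonal value, `band` (2.5/97.5
#'   percentiles of the null means), `null_values`.
#' @export
offDiagonalNull <- function(A, B, offset = 0.1, mode = c("raw", "noise"),
                            conditions = NULL, n_perm = 500L, seed = 1L) {
  mode <- match.arg(mode)
  checkPair(A, B)
  a <- centreTensor(A, mode, conditions)
  b <- centreTensor(B, mode, conditions)
  nb <- ncol(a); nt <- nrow(a)
  off_bins <- round(offset / A@binWidth)
  meanOff <- function(bm) {
    K <- crossprod(a, bm) / nt
    i <- seq_len(nb - abs(off_bins))
    if (off_bins >= 0) mean(K[cbind(i, i + off_bins)])
    else mean(K[cbind(i - off_bins, i)])
  }
  obs <- meanOff(b)
  nulls <- withSeed(subSeed(seed, "offdiag"),
    vapply(seq_len(n_perm), function(p) {
      sh <- sample(nb - 1L, nt, replace = TRUE)
      bp <- t(vapply(seq_len(nt), function(i)
        b[i, ((seq_len(nb) - 1 + sh[i]) %% nb) + 1], numeric(nb)))
      meanOff(bp)
    }, numeric(1)))
  list(observed = obs,
       band = stats::quantile(nulls, c(0.025, 0.975), names = FALSE),
       null_values = nulls)
}

#' @export
print.lagCurve <- function(x, ...) {
  cat(sprintf(
    "Lag curve (%s mode, %s vs %s): %d lags in [%.3g, %.3g] s; min at %+.0f ms, max at %+.0f ms\n",
    attr(x, "mode"), attr(x, "channels")[1], attr(x, "channels")[2],
    nrow(x), min(x$lag_s), max(x$lag_s), 1000 * attr(x, "min_lag_s"),
    1000 * attr(x, "max_lag_s")))
  cat("  convention:", attr(x, "convention"), "\n")
  invisible(x)
}
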