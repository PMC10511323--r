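#' @import methods
NULL

## ---------------------------------------------------------------------------
## Central S4 data containers. Trial tables and event streams are plain
## data.frames (documented column contracts, CSV round-trippable); fits and
## configs are classed lists. The containers below carry metadata that the
## analyses must not lose (sampling rate, units, alignment, lag axes).
## ---------------------------------------------------------------------------

#' PhotometryTrace: a uniformly sampled continuous signal
#'
#' Container for one channel of photometry (raw carrier-multiplexed,
#' demodulated fluorescence, dF/F0 or z-scored), with sampling metadata.
#' Unit transitions (raw -> dF/F -> zscore) happen only through
#' [dff()] and [zscoreSession()], which record the transition.
#'
#' @slot values numeric vector of samples.
#' @slot fs sampling rate, samples per second.
#' @slot channel channel label (e.g. "DA", "Ach", "multiplexed").
#' @slot units one of "raw", "F", "dF/F", "zscore".
#' @slot t0 time of the first sample, seconds.
#' @exportClass PhotometryTrace
setClass("PhotometryTrace",
  representation(values = "numeric", fs = "numeric", channel = "character",
                 units = "character", t0 = "numeric"),
  prototype(values = numeric(0), fs = 1, channel = "trace", units = "F",
            t0 = 0))

setValidity("PhotometryTrace", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (!object@units %in% c("raw", "F", "dF/F", "zscore"))
    msg <- c(msg, "units must be one of raw, F, dF/F, zscore")
  if (length(msg)) msg else TRUE
})

#' Construct a PhotometryTrace
#'
#' @param values numeric samples.
#' @param fs sampling rate (Hz).
#' @param channel channel label.
#' @param units signal units; see [PhotometryTrace-class].
#' @param t0 time of first sample (s).
#' @return A [PhotometryTrace-class] object.
#' @examples
#' tr <- photometryTrace(sin(seq(0, 10, by = 0.01)), fs = 100, channel = "DA")
#' samplingRate(tr)
#' @export
photometryTrace <- function(values, fs, channel = "trace", units = "F",
                            t0 = 0) {
  new("PhotometryTrace", values = as.numeric(values), fs = as.numeric(fs),
      channel = channel, units = units, t0 = as.numeric(t0))
}

#' TrialTensor: trials x time-bins matrix aligned to a behavioural event
#'
#' Rows are retained trials (in `trialIndex` order), columns are uniform time
#' bins covering `[-window[1], +window[2]]` seconds around the alignment
#' event; the alignment timestamp falls in the bin whose left edge is t = 0.
#'
#' @slot data trials x bins numeric matrix.
#' @slot alignEvent name of the alignment event column in the trial table.
#' @slot window length-2 numeric, seconds before/after the event (both >= 0).
#' @slot binWidth bin width in seconds.
#' @slot trialIndex integer indices of retained trials in the source table.
#' @slot channel channel label inherited from the source trace.
#' @exportClass TrialTensor
setClass("TrialTensor",
  representation(data = "matrix", alignEvent = "character",
                 window = "numeric", binWidth = "numeric",
                 trialIndex = "integer", channel = "character"))

setValidity("TrialTensor", function(object) {
  msg <- character(0)
  nb <- round(sum(object@window) / object@binWidth)
  if (ncol(object@data) != nb)
    msg <- c(msg, sprintf("bin count %d != round((pre+post)/bin_width) = %d",
                          ncol(object@data), nb))
  if (nrow(object@data) != length(object@trialIndex))
    msg <- c(msg, "rows must correspond 1:1 to retained trials")
  if (length(object@window) != 2L || any(object@window < 0))
    msg <- c(msg, "window must be c(pre, post), both >= 0")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' KernelSet: per-feature time-lag coefficient vectors
#'
#' Shared lag axis for all features; used both for generator ground truth and
#' for GLM kernels (where `sd` holds the across-run standard deviation).
#' Positive lag means the predictor influences the signal later in time.
#'
#' @slot lags numeric lag axis, seconds, uniform bins.
#' @slot coef features x lags coefficient matrix (rownames = features).
#' @slot sd features x lags standard-deviation matrix (0 when not applicable).
#' @slot binWidth lag bin width, seconds.
#' @exportClass KernelSet
setClass("KernelSet",
  representation(lags = "numeric", coef = "matrix", sd = "matrix",
                 binWidth = "numeric"))

setValidity("KernelSet", function(object) {
  msg <- character(0)
  if (ncol(object@coef) != length(object@lags))
    msg <- c(msg, "coef columns must match the lag axis")
  if (!identical(dim(object@sd), dim(object@coef)))
    msg <- c(msg, "sd must have the same dimensions as coef")
  if (is.null(rownames(object@coef)))
    msg <- c(msg, "coef must carry feature rownames")
  if (anyNA(object@coef) || any(!is.finite(object@coef)))
    msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a KernelSet
#'
#' @param coef features x lags matrix with feature rownames.
#' @param lags lag axis in seconds.
#' @param sd optional matrix of across-run standard deviations.
#' @param binWidth lag bin width (s); default inferred from `lags`.
#' @return A [KernelSet-class] object.
#' @export
kernelSet <- function(coef, lags, sd = NULL, binWidth = NULL) {
  coef <- as.matrix(coef)
  if (is.null(sd)) sd <- matrix(0, nrow(coef), ncol(coef),
                                dimnames = dimnames(coef))
  if (is.null(binWidth))
    binWidth <- if (length(lags) > 1L) stats::median(diff(lags)) else 1
  new("KernelSet", lags = as.numeric(lags), coef = coef, sd = as.matrix(sd),
      binWidth = binWidth)
}

#' CovMatrix: two-dimensional covariance function K(t1, t2)
#'
#' `K[i, j]` is the across-trial covariance between channel A at time
#' `t1[i]` and channel B at time `t2[j]`, both relative to the alignment
#' event. `mode` records the centering: "raw" (session-mean centred) or
#' "noise" (condition-mean-waveform residuals).
#'
#' @slot K numeric matrix, length(t1) x length(t2).
#' @slot t1 time axis for channel A (s).
#' @slot t2 time axis for channel B (s).
#' @slot nTrials number of trials averaged.
#' @slot channels length-2 character, names of channels A and B.
#' @slot mode "raw" or "noise".
#' @exportClass CovMatrix
setClass("CovMatrix",
  representation(K = "matrix", t1 = "numeric", t2 = "numeric",
                 nTrials = "integer", channels = "character",
                 mode = "character"))

setValidity("CovMatrix", function(object) {
  msg <- character(0)
  if (!identical(dim(object@K), c(length(object@t1), length(object@t2))))
    msg <- c(msg, "K dimensions must match the two time axes")
  if (!object@mode %in% c("raw", "noise"))
    msg <- c(msg, "mode must be 'raw' or 'noise'")
  if (length(msg)) msg else TRUE
})

#' DesignMatrix: time-shifted event design for the encoding GLM
#'
#' Rows are retained time bins (trial spans plus margins; bins whose shift
#' window crosses a trial boundary appear once per adjacent trial and are
#' flagged duplicated). Columns are (feature, lag) pairs: `F * (2T + 1)` in
#' total. `rowInfo` carries the row-to-trial map used as the grouping key in
#' cross-validation so duplicated rows never leak across folds.
#'
#' @slot X numeric design matrix.
#' @slot y response vector aligned to rows.
#' @slot colInfo data.frame with columns feature, lag_bins, lag_s.
#' @slot rowInfo data.frame with columns bin, trial, time, duplicated.
#' @slot features character vector of feature names (pre-expansion).
#' @slot binWidth bin width, seconds.
#' @slot nShifts the T of the 2T+1 shift expansion.
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(X = "matrix", y = "numeric", colInfo = "data.frame",
                 rowInfo = "data.frame", features = "character",
                 binWidth = "numeric", nShifts = "integer"))

setValidity("DesignMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@X) !=
      length(object@features) * (2L * object@nShifts + 1L))
    msg <- c(msg, "column count must equal F * (2T + 1)")
  if (nrow(object@X) != length(object@y) ||
      nrow(object@X) != nrow(object@rowInfo))
    msg <- c(msg, "X rows, y and rowInfo must align")
  if (nrow(object@colInfo) != ncol(object@X))
    msg <- c(msg, "colInfo must describe every column")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Generics
## ---------------------------------------------------------------------------

#' @rdname PhotometryTrace-class
#' @param object,x a package object.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname PhotometryTrace-class
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname PhotometryTrace-class
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))
#' @rdname PhotometryTrace-class
#' @export
setGeneric("signalUnits", function(object) standardGeneric("signalUnits"))
#' @rdname PhotometryTrace-class
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname TrialTensor-class
#' @export
setGeneric("tensorData", function(object) standardGeneric("tensorData"))
#' @rdname TrialTensor-class
#' @export
setGeneric("binTimes", function(object) standardGeneric("binTimes"))
#' @rdname TrialTensor-class
#' @export
setGeneric("trialIndex", function(object) standardGeneric("trialIndex"))
#' @rdname KernelSet-class
#' @export
setGeneric("kernelLags", function(object) standardGeneric("kernelLags"))
#' @rdname KernelSet-class
#' @export
setGeneric("kernelCoef", function(object) standardGeneric("kernelCoef"))
#' @rdname KernelSet-class
#' @export
setGeneric("kernelFeatures", function(object) standardGeneric("kernelFeatures"))

setMethod("samplingRate", "PhotometryTrace", function(object) object@fs)
setMethod("traceValues", "PhotometryTrace", function(object) object@values)
setMethod("channelName", "PhotometryTrace", function(object) object@channel)
setMethod("signalUnits", "PhotometryTrace", function(object) object@units)
setMethod("traceTimes", "PhotometryTrace", function(object)
  object@t0 + (seq_along(object@values) - 1) / object@fs)

setMethod("tensorData", "TrialTensor", function(object) object@data)
setMethod("trialIndex", "TrialTensor", function(object) object@trialIndex)
#' @rdname TrialTensor-class
#' @section Bin times:
#' `binTimes()` returns bin centres; the alignment timestamp lies in the bin
#' whose left edge is 0.
setMethod("binTimes", "TrialTensor", function(object) {
  nb <- ncol(object@data)
  npre <- round(object@window[1] / object@binWidth)
  (seq_len(nb) - npre - 1) * object@binWidth + object@binWidth / 2
})

setMethod("kernelLags", "KernelSet", function(object) object@lags)
setMethod("kernelCoef", "KernelSet", function(object) object@coef)
setMethod("kernelFeatures", "KernelSet", function(object)
  rownames(object@coef))

#' @describeIn PhotometryTrace-class length = number of samples
#' @export
setMethod("length", "PhotometryTrace", function(x) length(x@values))

#' @describeIn TrialTensor-class dim of the trials x bins matrix
#' @export
setMethod("dim", "TrialTensor", function(x) dim(x@data))

setMethod("show", "PhotometryTrace", function(object) {
  cat(sprintf(
    "PhotometryTrace '%s': %d samples @ %.6g Hz (%.1f s), units '%s'\n",
    object@channel, length(object@values), object@fs,
    length(object@values) / object@fs, object@units))
})

setMethod("show", "TrialTensor", function(object) {
  cat(sprintf(
    "TrialTensor '%s': %d trials x %d bins, aligned to %s, window [-%g, +%g] s, bin %g s\n",
    object@channel, nrow(object@data), ncol(object@data), object@alignEvent,
    object@window[1], object@window[2], object@binWidth))
})

setMethod("show", "KernelSet", function(object) {
  cat(sprintf("KernelSet: %d features x %d lags (%.3g .. %.3g s, bin %g s)\n",
              nrow(object@coef), length(object@lags), min(object@lags),
              max(object@lags), object@binWidth))
  cat("  features:", paste(rownames(object@coef), collapse = ", "), "\n")
})

setMethod("show", "CovMatrix", function(object) {
  cat(sprintf(
    "CovMatrix (%s mode): %s x %s, %d x %d bins, %d trials\n",
    object@mode, object@channels[1], object@channels[2],
    length(object@t1), length(object@t2), object@nTrials))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf(
    "DesignMatrix: %d rows x %d columns (%d features x %d lags), bin %g s\n",
    nrow(object@X), ncol(object@X), length(object@features),
    2L * object@nShifts + 1L, object@binWidth))
  cat(sprintf("  duplicated boundary rows: %d (%.1f%%)\n",
              sum(object@rowInfo$duplicated),
              100 * mean(object@rowInfo$duplicated)))
})
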