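## Base-graphics views of the main result objects.

#' Plot a kernel set
#'
#' One panel per feature: mean kernel against lag, with a +/- 1 sd ribbon
#' when across-run variability is present.
#'
#' @param ks a [KernelSet-class].
#' @param features subset of features to draw (default all).
#' @export
plotKernels <- function(ks, features = kernelFeatures(ks)) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(features)),
                       mar = c(3.5, 3.5, 2, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(old))
  for (f in features) {
    m <- kernelCoef(ks)[f, ]
    s <- ks@sd[f, ]
    ylim <- range(m - s, m + s, 0)
    plot(kernelLags(ks), m, type = "l", lwd = 2, ylim = ylim,
         xlab = "lag (s)", ylab = "coefficient", main = f)
    if (any(s > 0))
      graphics::polygon(c(kernelLags(ks), rev(kernelLags(ks))),
                        c(m - s, rev(m + s)), border = NA,
                        col = grDevices::adjustcolor("grey40", 0.3))
    graphics::abline(h = 0, v = 0, lty = 3)
  }
  invisible(NULL)
}

#' Plot a lagged cross-covariance curve
#'
#' @param x a `lagCurve` from [crosscovLagged()].
#' @param null optional output of [nullControls()]; draws the pointwise band.
#' @param ... passed to [plot()].
#' @export
plotLagCurve <- function(x, null = NULL, ...) {
  plot(x$lag_s, x$value, type = "l", lwd = 2, xlab = "lag (s)",
       ylab = attr(x, "mode"), ...)
  if (!is.null(null))
    graphics::polygon(c(null$band$lag_s, rev(null$band$lag_s)),
                      c(null$band$lo, rev(null$band$hi)), border = NA,
                      col = grDevices::adjustcolor("orange", 0.3))
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::abline(v = attr(x, "min_lag_s"), col = "red", lty = 2)
  invisible(NULL)
}

#' Image view of a two-dimensional covariance matrix
#'
#' @param K a [CovMatrix-class].
#' @param ... passed to [graphics::image()].
#' @export
plotCovMatrix <- function(K, ...) {
  graphics::image(K@t1, K@t2, K@K,
                  xlab = sprintf("%s time t1 (s)", K@channels[1]),
                  ylab = sprintf("%s time t2 (s)", K@channels[2]),
                  main = sprintf("K(t1, t2), %s mode", K@mode), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(NULL)
}
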