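## Per-trial scalar metrics, paired group comparisons across mice, and
## regularized linear discriminant classification of trial type.

windowBins <- function(tensor, window) {
  bt <- binTimes(tensor)
  sel <- which(bt >= window[1] & bt <= window[2])
  stopIf(length(sel) == 0, "window [%g, %g] contains no bins",
         window[1], window[2])
  sel
}

#' Per-trial mean signal in a window
#'
#' Arithmetic mean of the z-scored (or other) signal over the bins inside
#' `window`, one value per trial — the "mean DA" style metric.
#'
#' @param tensor a [TrialTensor-class].
#' @param window c(start, end) seconds relative to the alignment event.
#' @return numeric vector, one value per retained trial.
#' @export
meanSignal <- function(tensor, window = c(0, 1)) {
  sel <- windowBins(tensor, window)
  rowMeans(tensorData(tensor)[, sel, drop = FALSE])
}

#' Per-trial max-minus-min in a window
#'
#' The peak-to-trough excursion (max - min over bins in the window), one
#' value per trial — the "delta-Ach" style metric for multiphasic
#' transients. Always non-negative.
#'
#' @inheritParams meanSignal
#' @return numeric vector, one value per retained trial.
#' @export
deltaSignal <- function(tensor, window = c(0, 1)) {
  sel <- windowBins(tensor, window)
  d <- tensorData(tensor)[, sel, drop = FALSE]
  apply(d, 1, max) - apply(d, 1, min)
}

#' Paired group comparison across mice
#'
#' Collapses per-trial values to per-mouse condition means first (so mice
#' with different trial counts weigh equally), then runs a paired two-sided
#' t-test across mice between the two conditions. Mice lacking either
#' condition are excluded with a message.
#'
#' @param values per-trial metric values.
#' @param conditions per-trial condition labels (exactly 2 levels).
#' @param mouse_ids per-trial mouse identifiers.
#' @param metric_name optional metric label carried into the result.
#' @return classed list: per-mouse condition means, `statistic`, `p_value`,
#'   `significant` at 0.05, test name, and the condition level ordering
#'   (the t statistic is mean(level1) - mean(level2)).
#' @export
groupCompare <- function(values, conditions, mouse_ids,
                         metric_name = "metric") {
  conditions <- as.character(conditions)
  lev <- sort(unique(conditions))
  stopIf(length(lev) != 2, "exactly two conditions are required")
  tab <- stats::aggregate(values,
                          by = list(mouse = mouse_ids, cond = conditions),
                          FUN = mean)
  wide <- stats::reshape(tab, idvar = "mouse", timevar = "cond",
                         direction = "wide")
  names(wide) <- sub("^x\\.", "", names(wide))
  ok <- stats::complete.cases(wide)
  if (any(!ok))
    message(sprintf("groupCompare: excluded %d mouse/mice lacking a condition",
                    sum(!ok)))
  wide <- wide[ok, ]
  stopIf(nrow(wide) < 2, "need at least 2 mice with both conditions")
  d <- wide[[lev[1]]] - wide[[lev[2]]]
  if (stats::sd(d) == 0) {
    ## degenerate paired differences: identical means give t = 0 by
    ## definition; a constant nonzero difference is infinitely significant
    tt <- if (mean(d) == 0) list(statistic = 0, p.value = 1)
    else list(statistic = sign(mean(d)) * Inf, p.value = 0)
  } else {
    tt <- stats::t.test(wide[[lev[1]]], wide[[lev[2]]], paired = TRUE)
  }
  structure(list(metric = metric_name, levels = lev, per_mouse = wide,
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 significant = tt$p.value < 0.05,
                 test = "paired two-sided t-test", n_mice = nrow(wide)),
            class = "metricResult")
}

#' @export
print.metricResult <- function(x, ...) {
  cat(sprintf("%s: %s vs %s across %d mice, t = %.3f, p = %.4g%s\n",
              x$metric, x$levels[1], x$levels[2], x$n_mice, x$statistic,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

## Shrinkage LDA for collinear waveform features: pooled within-class
## covariance shrunk toward a scaled identity, gamma chosen by the
## bins-vs-trials regime.
ldaTrain <- function(x, y, gamma = NULL) {
  cl <- sort(unique(y))
  x0 <- x[y == cl[1], , drop = FALSE]
  x1 <- x[y == cl[2], , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1); p <- ncol(x)
  if (is.null(gamma)) gamma <- if (p > (n0 + n1) / 5) 0.2 else 1e-8
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  S <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) / (n0 + n1 - 2)
  Sstar <- (1 - gamma) * S + gamma * mean(diag(S)) * diag(p)
  w <- solve(Sstar, m1 - m0)
  b <- -sum(w * (m0 + m1)) / 2 + log(n1 / n0)
  list(w = w, b = b, classes = cl)
}

ldaPredict <- function(model, x) {
  score <- as.vector(x %*% model$w) + model$b
  ifelse(score > 0, model$classes[2], model$classes[1])
}

#' LDA classification of trial type from waveforms
#'
#' Uses the time bins inside `window` as features and classifies the binary
#' trial labels with shrinkage LDA under stratified k-fold cross-validation.
#' Reports per-fold and mean held-out accuracy; deterministic given `seed`.
#'
#' @param tensor a [TrialTensor-class].
#' @param labels per-trial binary labels (length = rows of the tensor).
#' @param window feature window in seconds relative to alignment.
#' @param cv_folds number of stratified folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param gamma covariance shrinkage intensity; default picks 0.2 when bins
#'   exceed trials/5 and (numerically) 0 otherwise.
#' @return classed list: `accuracy` per fold, `mean_accuracy`, `n_per_class`,
#'   `window`, `seed`.
#' @export
ldaClassify <- function(tensor, labels, window = c(0, 1), cv_folds = 5L,
                        seed = 1L, gamma = NULL) {
  sel <- windowBins(tensor, window)
  x <- tensorData(tensor)[, sel, drop = FALSE]
  stopIf(length(labels) != nrow(x), "labels must match tensor rows")
  labels <- as.character(labels)
  cl <- sort(unique(labels))
  stopIf(length(cl) != 2, "labels must be binary")
  counts <- table(labels)
  stopIf(min(counts) < cv_folds,
         "each class needs at least as many trials as folds")
  stopIf(min(counts) < 20, "need at least 20 trials per class")
  fold <- integer(length(labels))
  withSeed(seed, for (c_i in cl) {
    idx <- sample(which(labels == c_i))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  })
  acc <- vapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    model <- ldaTrain(x[tr, , drop = FALSE], labels[tr], gamma = gamma)
    mean(ldaPredict(model, x[!tr, , drop = FALSE]) == labels[!tr])
  }, numeric(1))
  structure(list(accuracy = acc, mean_accuracy = mean(acc),
                 n_per_class = as.vector(counts), classes = cl,
                 window = window, cv_folds = cv_folds, seed = seed),
            class = "ldaResult")
}

#' @export
print.ldaResult <- function(x, ...) {
  cat(sprintf(
    "LDA (%d-fold CV, window [%g, %g] s): mean accuracy %.3f (folds %s)\n",
    x$cv_folds, x$window[1], x$window[2], x$mean_accuracy,
    paste(sprintf("%.2f", x$accuracy), collapse = ", ")))
  invisible(x)
}

#' Permutation null for LDA accuracy
#'
#' Re-runs [ldaClassify()] with label assignments shuffled `n_perm` times
#' and returns the null accuracies plus their 95th percentile; an observed
#' accuracy above that bound indicates decodable structure.
#'
#' @inheritParams ldaClassify
#' @param n_perm number of label permutations (default 200).
#' @return list with `null_accuracies` and `q95`.
#' @export
ldaPermutationNull <- function(tensor, labels, window = c(0, 1),
                               cv_folds = 5L, n_perm = 200L, seed = 1L,
                               gamma = NULL) {
  null_acc <- withSeed(subSeed(seed, "lda_perm"),
    vapply(seq_len(n_perm), function(p) {
      lab_p <- sample(labels)
      ldaClassify(tensor, lab_p, window = window, cv_folds = cv_folds,
                  seed = subSeed(seed, p), gamma = gamma)$mean_accuracy
    }, numeric(1)))
  list(null_accuracies = null_acc,
       q95 = stats::quantile(null_acc, 0.95, names = FALSE),
       q05 = stats::quantile(null_acc, 0.05, names = FALSE))
}
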