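## Event-kernel encoding GLM: time-shifted design matrices, the four cost
## functions (OLS / ridge / lasso / elastic net), grouped cross-validation
## with boundary-row duplication, leave-one-feature-out analysis, kernel
## extraction and reconstruction.

#' Encoding-GLM configuration
#'
#' @param n_shifts number of time shifts in each direction (the T of the
#'   2T+1 expansion; default 20).
#' @param bin_width time bin in seconds (default 0.054).
#' @param features ordered base event features.
#' @param method one of "ols", "ridge", "lasso", "elastic_net".
#' @param alpha regularization strength (the cost-function alpha; for
#'   ridge this multiplies `||beta||_2^2` added to the residual sum of
#'   squares, for lasso/elastic net it is the glmnet-scale penalty of the
#'   `1/(2N)` objective — see [ridgeAlphaFromEnet()] for the conversion).
#' @param l1_ratio elastic-net L1 ratio lambda in [0, 1] (1 = lasso).
#' @param runs number of full model runs Y (fresh train/test splits).
#' @param gss_folds folds of the group shuffle split on the training half
#'   (default 10).
#' @param val_fraction fraction of training trials held out for validation
#'   within each fold (default 0.2).
#' @param train_fraction fraction of trials in the training half (default
#'   0.5).
#' @param trial_margin seconds modelled before centre entry and after side
#'   exit (default 1).
#' @return classed config list.
#' @export
glmConfig <- function(n_shifts = 20L, bin_width = 0.054,
                      features = c("centre_entry", "centre_exit",
                                   "side_entry", "side_exit", "lick",
                                   "reward"),
                      method = c("ols", "ridge", "lasso", "elastic_net"),
                      alpha = 0, l1_ratio = 1, runs = 3L, gss_folds = 10L,
                      val_fraction = 0.2, train_fraction = 0.5,
                      trial_margin = 1) {
  method <- match.arg(method)
  stopIf(n_shifts < 0, "n_shifts must be >= 0")
  stopIf(alpha < 0, "alpha must be >= 0")
  stopIf(l1_ratio < 0 || l1_ratio > 1, "l1_ratio must be in [0, 1]")
  stopIf(val_fraction <= 0 || val_fraction >= 1 ||
           train_fraction <= 0 || train_fraction >= 1,
         "fractions must be in (0, 1)")
  structure(list(n_shifts = as.integer(n_shifts), bin_width = bin_width,
                 features = features, method = method, alpha = alpha,
                 l1_ratio = l1_ratio, runs = as.integer(runs),
                 gss_folds = as.integer(gss_folds),
                 val_fraction = val_fraction,
                 train_fraction = train_fraction,
                 trial_margin = trial_margin),
            class = "glmConfig")
}

#' Convert between the two ridge regularization scales
#'
#' The unscaled ridge objective `RSS + alpha_r ||beta||^2` and the
#' elastic-net objective at `l1_ratio = 0`,
#' `RSS/(2N) + (alpha_e/2) ||beta||^2`, coincide when
#' `alpha_r = N * alpha_e` — the two alpha scales differ by the number of
#' modelled time bins.
#'
#' @param alpha penalty on the elastic-net (ridge: `alpha_r`) scale.
#' @param n number of rows N.
#' @return the equivalent penalty on the other scale.
#' @export
ridgeAlphaFromEnet <- function(alpha, n) alpha * n

#' @rdname ridgeAlphaFromEnet
#' @export
enetAlphaFromRidge <- function(alpha, n) alpha / n

## The epsilon keeps grid-aligned sample times (exact multiples of the bin
## width) from straddling a bin edge through floating-point error.
binIndex <- function(t, bw) floor(t / bw + 1e-6) + 1L

## Bin a trace onto the design grid by bin means.
binTrace <- function(trace, bw, n_bins) {
  idx <- binIndex(traceTimes(trace), bw)
  ok <- idx >= 1 & idx <= n_bins
  sums <- rowsum(traceValues(trace)[ok], idx[ok])
  cnts <- rowsum(rep(1, sum(ok)), idx[ok])
  y <- rep(NA_real_, n_bins)
  y[as.integer(rownames(sums))] <- sums / cnts
  y
}

#' Build a time-shifted design matrix from behavioural events
#'
#' Bins the session onto a uniform grid, marks each behavioural event with a
#' 0/1 indicator per bin (the reward indicator sits at the side-entry bin of
#' rewarded trials), expands every feature into 2T+1 time-shifted copies,
#' and restricts rows to each trial's span (centre entry to side exit) plus
#' the configured margins — bins of the long ITI carry no task events and
#' are excluded. When adjacent trials' extended spans overlap, the
#' overlapping bins are included once per trial and flagged duplicated; the
#' row-to-trial map keeps both copies in the same cross-validation group.
#'
#' Variants: `"history"` replaces the single side-entry column with eight
#' columns segregated by the stay/switch x previous x current outcome label
#' (trials without a label, i.e. the first trial, are dropped);
#' `"photometry"` appends a continuous predictor column from `extra_trace`,
#' also shift-expanded.
#'
#' @param trials trial table.
#' @param trace response [PhotometryTrace-class] (typically z-scored); bin
#'   means form the response vector y.
#' @param cfg a [glmConfig()].
#' @param variant "base", "history" or "photometry".
#' @param extra_trace continuous predictor trace for the photometry variant.
#' @return a [DesignMatrix-class].
#' @export
buildDesign <- function(trials, trace, cfg = glmConfig(),
                        variant = c("base", "history", "photometry"),
                        extra_trace = NULL) {
  variant <- match.arg(variant)
  bw <- cfg$bin_width
  Tn <- cfg$n_shifts
  n_bins <- binIndex(max(trials$t_side_exit) + cfg$trial_margin, bw) + Tn
  lk <- lickTimes(trials$lick_times)

  use_trials <- trials
  if (variant == "history") {
    drop <- is.na(trials$history_label)
    if (any(drop))
      message(sprintf("buildDesign: dropped %d trial(s) without history label",
                      sum(drop)))
    use_trials <- trials[!drop, , drop = FALSE]
  }

  ev_times <- list(
    centre_entry = use_trials$t_centre_entry,
    centre_exit = use_trials$t_centre_exit,
    side_entry = use_trials$t_side_entry,
    side_exit = use_trials$t_side_exit,
    lick = unlist(lk[match(use_trials$trial, trials$trial)]),
    reward = use_trials$t_side_entry[use_trials$reward == 1])
  base_feats <- cfg$features
  stopIf(!all(base_feats %in% names(ev_times)),
         "unknown feature(s): %s",
         paste(setdiff(base_feats, names(ev_times)), collapse = ", "))
  ev_times <- ev_times[base_feats]

  if (variant == "history") {
    labs <- sort(unique(stats::na.omit(trials$history_label)))
    hist_ev <- lapply(labs, function(l)
      use_trials$t_side_entry[use_trials$history_label == l])
    names(hist_ev) <- paste0("side_entry_", labs)
    pos <- match("side_entry", names(ev_times))
    stopIf(is.na(pos), "history variant requires the side_entry feature")
    ev_times <- append(ev_times[-pos], hist_ev, after = pos - 1L)
  }

  E <- matrix(0, n_bins, length(ev_times),
              dimnames = list(NULL, names(ev_times)))
  for (f in names(ev_times)) {
    ## indicator marks the bin containing the event; with bin-mean
    ## responses (representative time at the bin centre) this keeps the
    ## estimated kernels unbiased in time
    b <- binIndex(ev_times[[f]], bw)
    b <- b[b >= 1 & b <= n_bins]
    E[unique(b), f] <- 1
  }
  feats <- names(ev_times)
  if (variant == "photometry") {
    stopIf(is.null(extra_trace), "photometry variant requires extra_trace")
    pb <- binTrace(extra_trace, bw, n_bins)
    pb[is.na(pb)] <- 0
    E <- cbind(E, photometry = pb)
    feats <- c(feats, "photometry")
  }

  ## per-trial row spans (margins included); overlapping bins duplicated
  span <- lapply(seq_len(nrow(use_trials)), function(i) {
    lo <- max(1L, binIndex(use_trials$t_centre_entry[i] - cfg$trial_margin, bw))
    hi <- min(n_bins, binIndex(use_trials$t_side_exit[i] + cfg$trial_margin, bw))
    lo:hi
  })
  bins <- unlist(span)
  trial_of <- rep(use_trials$trial, lengths(span))
  dup <- bins %in% bins[duplicated(bins)]
  ## partner trial of each duplicated row (margins overlap only between
  ## adjacent trials, so at most one partner): used as the shared group key
  ## in the fold splits so both copies stay on the same side
  partner <- rep(NA_real_, length(bins))
  if (any(dup)) {
    ord <- order(bins, trial_of)
    b_o <- bins[ord]; t_o <- trial_of[ord]
    same_next <- c(b_o[-1] == b_o[-length(b_o)], FALSE)
    same_prev <- c(FALSE, same_next[-length(same_next)])
    p_o <- rep(NA_real_, length(b_o))
    p_o[same_next] <- t_o[c(FALSE, same_next[-length(same_next)])]
    p_o[same_prev] <- t_o[c(same_prev[-1], FALSE)]
    partner[ord] <- p_o
  }

  y_all <- binTrace(trace, bw, n_bins)
  ok <- !is.na(y_all[bins])
  if (any(!ok))
    message(sprintf("buildDesign: dropped %d row(s) outside the trace span",
                    sum(!ok)))
  bins <- bins[ok]; trial_of <- trial_of[ok]; dup <- dup[ok]
  partner <- partner[ok]

  nlag <- 2L * Tn + 1L
  lags <- seq(-Tn, Tn)
  X <- matrix(0, length(bins), length(feats) * nlag)
  colInfo <- data.frame(feature = rep(feats, each = nlag),
                        lag_bins = rep(lags, length(feats)))
  colInfo$lag_s <- colInfo$lag_bins * bw
  for (j in seq_len(nrow(colInfo))) {
    src <- bins - colInfo$lag_bins[j]
    valid <- src >= 1 & src <= n_bins
    X[valid, j] <- E[src[valid], colInfo$feature[j]]
  }
  colnames(X) <- paste0(colInfo$feature, "_lag", colInfo$lag_bins)

  new("DesignMatrix", X = X, y = y_all[bins], colInfo = colInfo,
      rowInfo = data.frame(bin = bins, trial = trial_of,
                           time = (bins - 0.5) * bw, duplicated = dup,
                           partner = partner,
                           group = ifelse(is.na(partner), trial_of,
                                          pmin(trial_of, partner))),
      features = feats, binWidth = bw, nShifts = Tn)
}

## ---------------------------------------------------------------------------
## Solvers. OLS and ridge go through per-trial Gram accumulation so that the
## many grouped-CV refits (and the leave-out column subsets) reuse one pass
## over the data; lasso / elastic net go through glmnet, whose objective is
## exactly the printed elastic-net cost with lambda = alpha, alpha = l1_ratio.
## ---------------------------------------------------------------------------

trialGrams <- function(design, cols) {
  rows_by <- split(seq_along(design@y), design@rowInfo$group)
  G <- vector("list", length(rows_by)); b <- vector("list", length(rows_by))
  names(G) <- names(b) <- names(rows_by)
  for (k in seq_along(rows_by)) {
    Xi <- cbind(1, design@X[rows_by[[k]], cols, drop = FALSE])
    G[[k]] <- crossprod(Xi)
    b[[k]] <- crossprod(Xi, design@y[rows_by[[k]]])
  }
  list(ids = as.numeric(names(rows_by)), G = G, b = b, rows_by = rows_by)
}

sumGrams <- function(tg, ids) {
  key <- as.character(ids)
  G <- tg$G[[key[1]]]; b <- tg$b[[key[1]]]
  for (k in key[-1]) { G <- G + tg$G[[k]]; b <- b + tg$b[[k]] }
  list(G = G, b = b)
}

solveGram <- function(G, b, method, alpha) {
  p <- nrow(G) - 1L
  pen <- if (method == "ridge") alpha else 0
  A <- G + diag(c(0, rep(pen, p)))
  beta <- tryCatch(solve(A, b), error = function(e) {
    ## rank-deficient system (e.g. all-zero event columns): minimal-jitter
    ## pseudo-solution, flagged by attribute
    structure(solve(A + diag(1e-8 * max(diag(A)), p + 1L), b),
              degenerate = TRUE)
  })
  as.numeric(beta)
}

glmnetBeta <- function(X, y, cfg) {
  l1 <- if (cfg$method == "lasso") 1 else cfg$l1_ratio
  ## glmnet standardizes y internally (1/n sd), which leaves its effective
  ## L1 penalty on the requested scale but divides the L2 penalty by sd(y);
  ## remap (lambda, alpha) so the *requested* objective
  ##   RSS/(2N) + alpha (l1_ratio ||b||_1 + (1 - l1_ratio)/2 ||b||_2^2)
  ## is the one minimized
  s <- sqrt(mean((y - mean(y))^2))
  A <- cfg$alpha * l1
  B <- cfg$alpha * (1 - l1)
  lam <- A + B * s
  a <- if (lam > 0) A / lam else 1
  ## a short decreasing path ending at the target improves coordinate
  ## descent accuracy at a single user lambda
  fit <- glmnet::glmnet(X, y, alpha = a, lambda = lam * c(16, 8, 4, 2, 1),
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12, maxit = 200000)
  as.numeric(stats::coef(fit, s = lam))  # intercept first
}

fitBeta <- function(design, cfg, rows = NULL, cols = NULL, tg = NULL,
                    trial_ids = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(design@X))
  if (cfg$method %in% c("ols", "ridge")) {
    if (!is.null(tg) && !is.null(trial_ids)) {
      gb <- sumGrams(tg, trial_ids)
      return(solveGram(gb$G, gb$b, cfg$method, cfg$alpha))
    }
    if (is.null(rows)) rows <- seq_along(design@y)
    Xi <- cbind(1, design@X[rows, cols, drop = FALSE])
    return(solveGram(crossprod(Xi), crossprod(Xi, design@y[rows]),
                     cfg$method, cfg$alpha))
  }
  if (is.null(rows)) rows <- seq_along(design@y)
  glmnetBeta(design@X[rows, cols, drop = FALSE], design@y[rows], cfg)
}

predictRows <- function(design, beta, rows, cols) {
  as.numeric(design@X[rows, cols, drop = FALSE] %*% beta[-1] + beta[1])
}

#' Fit an encoding GLM on (a subset of) the design rows
#'
#' Minimizes the configured cost function: OLS `||y - Xb||^2`; ridge
#' `||y - Xb||^2 + alpha ||b||^2`; elastic net
#' `||y - Xb||^2 / (2N) + alpha (l1_ratio ||b||_1 +
#' (1 - l1_ratio)/2 ||b||_2^2)` with `l1_ratio = 1` giving the lasso. The
#' intercept is never penalized.
#'
#' @param design a [DesignMatrix-class].
#' @param cfg a [glmConfig()].
#' @param rows optional row subset to fit on (default all).
#' @return list with `beta` (coefficients, no intercept), `intercept`,
#'   `fitted` (on the fit rows), `mse`, `r2`, `method`.
#' @export
fitGLM <- function(design, cfg = glmConfig(), rows = NULL) {
  if (is.null(rows)) rows <- seq_along(design@y)
  if (cfg$method == "ols")
    stopIf(length(rows) <= ncol(design@X),
           "OLS needs more rows than columns; use regularization")
  beta <- fitBeta(design, cfg, rows = rows)
  yhat <- predictRows(design, beta, rows, seq_len(ncol(design@X)))
  y <- design@y[rows]
  list(beta = beta[-1], intercept = beta[1], fitted = yhat,
       mse = mean((y - yhat)^2),
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       method = cfg$method)
}

runOnce <- function(design, cfg, seed_run, cols, tg) {
  ids <- unique(design@rowInfo$group)
  all_cols <- cols
  rows_of <- function(trs) which(design@rowInfo$group %in% trs)
  withSeed(seed_run, {
    n_train <- round(cfg$train_fraction * length(ids))
    train_ids <- sort(sample(ids, n_train))
    test_ids <- setdiff(ids, train_ids)
    ## grouped shuffle-split folds on the training half
    sq_res <- numeric(0)
    fold_mse <- numeric(cfg$gss_folds)
    for (k in seq_len(cfg$gss_folds)) {
      val_ids <- sort(sample(train_ids,
                             max(1, round(cfg$val_fraction * n_train))))
      fit_ids <- setdiff(train_ids, val_ids)
      beta <- fitBeta(design, cfg, rows = rows_of(fit_ids), cols = all_cols,
                      tg = tg, trial_ids = if (!is.null(tg)) fit_ids)
      vr <- rows_of(val_ids)
      res <- design@y[vr] - predictRows(design, beta, vr, all_cols)
      fold_mse[k] <- mean(res^2)
      sq_res <- c(sq_res, res^2)
    }
    ## refit on the full training half, evaluate on the held-out test half
    beta <- fitBeta(design, cfg, rows = rows_of(train_ids), cols = all_cols,
                    tg = tg, trial_ids = if (!is.null(tg)) train_ids)
    tr_rows <- rows_of(train_ids); te_rows <- rows_of(test_ids)
    ytr <- design@y[tr_rows]; yte <- design@y[te_rows]
    ftr <- predictRows(design, beta, tr_rows, all_cols)
    fte <- predictRows(design, beta, te_rows, all_cols)
    ## leakage audit: with shared group keys for duplicated boundary rows
    ## no bin should appear on both sides of the split
    dup_frac <- mean(design@rowInfo$duplicated[te_rows])
    leak_frac <- mean(design@rowInfo$bin[te_rows] %in%
                        design@rowInfo$bin[tr_rows])
    list(beta = beta, train_ids = train_ids, leak_fraction = leak_frac,
         mse_train = mean((ytr - ftr)^2), mse_val = mean(sq_res),
         fold_mse = fold_mse, mse_test = mean((yte - fte)^2),
         r2_train = 1 - sum((ytr - ftr)^2) / sum((ytr - mean(ytr))^2),
         r2_test = 1 - sum((yte - fte)^2) / sum((yte - mean(yte))^2),
         dup_fraction = dup_frac)
  })
}

#' Run the full training/validation/test protocol
#'
#' Per run: trials are split 50/50 into training and test halves; a 10-fold
#' group shuffle split by trial on the training half (80-20 within folds)
#' yields the validation MSE as the mean of the concatenated squared
#' residuals across folds; the model is then refit on the entire training
#' half and evaluated on the held-out test half. Repeated `cfg$runs` times
#' with fresh splits. Both copies of a duplicated boundary row carry one
#' shared group key (the earlier trial's), and all splits act on group
#' keys, so duplicated rows are never separated across the two sides of any
#' split; the per-run share of duplicated rows in the test half and a
#' leakage audit (fraction of test bins also present in training, expected
#' 0) are reported.
#'
#' @param design a [DesignMatrix-class].
#' @param cfg a [glmConfig()].
#' @param seed master seed for the splits.
#' @param cols optional design-column subset (used by the leave-out
#'   analysis).
#' @return classed `glmFit`: per-run records, coefficient matrix
#'   (columns = runs), and an `mse` data.frame with train/validation/test
#'   MSE and R-squared per run.
#' @export
runProtocol <- function(design, cfg = glmConfig(), seed = 1L, cols = NULL) {
  ids <- unique(design@rowInfo$trial)
  stopIf(length(ids) < 20, "need at least 20 trials")
  stopIf(length(ids) < cfg$gss_folds, "fewer trials than folds")
  if (is.null(cols)) cols <- seq_len(ncol(design@X))
  tg <- if (cfg$method %in% c("ols", "ridge")) trialGrams(design, cols)
  runs <- lapply(seq_len(cfg$runs), function(r)
    runOnce(design, cfg, subSeed(seed, paste0("run", r)), cols, tg))
  mse <- data.frame(
    run = seq_len(cfg$runs),
    mse_train = vapply(runs, `[[`, 1, "mse_train"),
    mse_val = vapply(runs, `[[`, 1, "mse_val"),
    mse_test = vapply(runs, `[[`, 1, "mse_test"),
    r2_train = vapply(runs, `[[`, 1, "r2_train"),
    r2_test = vapply(runs, `[[`, 1, "r2_test"),
    dup_fraction = vapply(runs, `[[`, 1, "dup_fraction"),
    leak_fraction = vapply(runs, `[[`, 1, "leak_fraction"))
  structure(list(runs = runs,
                 beta = vapply(runs, function(r) r$beta[-1],
                               numeric(length(cols))),
                 intercept = vapply(runs, function(r) r$beta[1], 1),
                 mse = mse, cols = cols,
                 colInfo = design@colInfo[cols, , drop = FALSE],
                 features = unique(design@colInfo$feature[cols]),
                 nShifts = design@nShifts, binWidth = design@binWidth,
                 config = cfg, seed = seed),
            class = "glmFit")
}

#' @export
print.glmFit <- function(x, ...) {
  cat(sprintf("Encoding GLM (%s), %d run(s):\n", x$config$method,
              nrow(x$mse)))
  cat(sprintf(
    "  MSE train %.4f, validation %.4f, test %.4f; test R2 %.3f; boundary duplication %.1f%%\n",
    mean(x$mse$mse_train), mean(x$mse$mse_val), mean(x$mse$mse_test),
    mean(x$mse$r2_test), 100 * mean(x$mse$dup_fraction)))
  invisible(x)
}

#' Leave-one-feature-out analysis
#'
#' Iteratively drops each feature's 2T+1 columns, reruns [runProtocol()]
#' with identical splits (same seed), and reports the change in validation
#' and test MSE relative to the full model, together with the full model's
#' cross-validation noise band (2 standard deviations of its per-fold
#' validation MSEs) against which a null feature's delta should be judged.
#'
#' @inheritParams runProtocol
#' @param features features to leave out (default: all in the design).
#' @return list: `table` (feature, dmse_val, dmse_test), `full` (the full
#'   [runProtocol()] fit), `noise_band`.
#' @export
leaveOutAnalysis <- function(design, cfg = glmConfig(), seed = 1L,
                             features = NULL) {
  stopIf(length(design@features) < 2, "need at least 2 features")
  if (is.null(features)) features <- design@features
  full <- runProtocol(design, cfg, seed)
  fold_mses <- unlist(lapply(full$runs, `[[`, "fold_mse"))
  noise_band <- 2 * stats::sd(fold_mses)
  rows <- lapply(features, function(f) {
    keep <- which(design@colInfo$feature != f)
    fit <- runProtocol(design, cfg, seed, cols = keep)
    data.frame(feature = f,
               dmse_val = mean(fit$mse$mse_val) - mean(full$mse$mse_val),
               dmse_test = mean(fit$mse$mse_test) - mean(full$mse$mse_test))
  })
  list(table = do.call(rbind, rows), full = full, noise_band = noise_band)
}

#' Extract kernels from a fitted encoding GLM
#'
#' Reshapes the fitted coefficients into per-feature lag vectors and
#' aggregates the mean and standard deviation across the Y model runs.
#'
#' @param fit a `glmFit` from [runProtocol()], or the output of [fitGLM()]
#'   together with `design`.
#' @return a [KernelSet-class]; `sd` is zero when there is a single run.
#' @export
extractKernels <- function(fit) {
  stopifnot(inherits(fit, "glmFit"))
  nlag <- 2L * fit$nShifts + 1L
  feats <- fit$features
  beta <- fit$beta
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1)
  mean_k <- matrix(NA_real_, length(feats), nlag,
                   dimnames = list(feats, NULL))
  sd_k <- mean_k
  for (f in feats) {
    idx <- which(fit$colInfo$feature == f)
    stopIf(length(idx) != nlag, "feature %s has %d columns, expected %d",
           f, length(idx), nlag)
    mean_k[f, ] <- rowMeans(beta[idx, , drop = FALSE])
    sd_k[f, ] <- apply(beta[idx, , drop = FALSE], 1,
                       function(v) if (length(v) > 1) stats::sd(v) else 0)
  }
  sd_k[is.na(sd_k)] <- 0
  kernelSet(mean_k, lags = seq(-fit$nShifts, fit$nShifts) * fit$binWidth,
            sd = sd_k, binWidth = fit$binWidth)
}

#' Reconstruct the signal from a fitted encoding GLM
#'
#' Predicts `y_hat = X beta` (run-averaged coefficients) on the design rows,
#' reports the overall R-squared, and returns a trial-averaged observed vs
#' predicted waveform (rows aligned by time from trial start) with a
#' bootstrap-over-trials 95% confidence interval.
#'
#' @param design the [DesignMatrix-class] the fit was made on.
#' @param fit a `glmFit`.
#' @param n_boot bootstrap draws over trials (default 200).
#' @param seed bootstrap seed.
#' @return list: `yhat`, `r2`, `average` (data.frame time, observed,
#'   predicted, lo, hi), `n_trials`.
#' @export
reconstructSignal <- function(design, fit, n_boot = 200L, seed = 1L) {
  beta <- if (is.null(dim(fit$beta))) fit$beta else rowMeans(fit$beta)
  icpt <- mean(fit$intercept)
  stopIf(length(beta) != length(fit$cols), "row/beta dimension mismatch")
  yhat <- as.numeric(design@X[, fit$cols, drop = FALSE] %*% beta + icpt)
  y <- design@y
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  ## align trials on time-from-trial-start for the averaged overlay
  byt <- split(seq_along(y), design@rowInfo$trial)
  len <- stats::quantile(lengths(byt), 0.1, names = FALSE)
  keep <- byt[lengths(byt) >= len]
  obs <- t(vapply(keep, function(i) y[i[seq_len(len)]], numeric(len)))
  prd <- t(vapply(keep, function(i) yhat[i[seq_len(len)]], numeric(len)))
  bmeans <- withSeed(subSeed(seed, "boot"),
    vapply(seq_len(n_boot), function(b) {
      i <- sample(nrow(prd), replace = TRUE)
      colMeans(prd[i, , drop = FALSE])
    }, numeric(len)))
  list(yhat = yhat, r2 = r2,
       average = data.frame(
         time = (seq_len(len) - 0.5) * design@binWidth,
         observed = colMeans(obs), predicted = colMeans(prd),
         lo = apply(bmeans, 1, stats::quantile, 0.025),
         hi = apply(bmeans, 1, stats::quantile, 0.975)),
       n_trials = nrow(prd))
}

#' Serialize a GLM fit summary to JSON
#' @param fit a `glmFit`.
#' @param path output path.
#' @return the path invisibly.
#' @export
writeGLMFit <- function(fit, path) {
  jsonlite::write_json(list(
    method = fit$config$method, alpha = fit$config$alpha,
    l1_ratio = fit$config$l1_ratio, runs = nrow(fit$mse),
    mse = fit$mse, features = fit$features), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}
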