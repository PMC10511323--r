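## Small cached design built from the clean linear generator.
fixDesign <- function() fixture("design", {
  buildDesign(fixSession()$trials, fixCleanSynth()$da,
              glmConfig(method = "ols", runs = 2))
})

test_that("design dimensions and column layout follow F(2T+1)", {
  des <- fixDesign()
  expect_equal(ncol(des@X), 6 * 41)
  expect_equal(nrow(des@colInfo), 246)
  expect_equal(unique(table(des@colInfo$feature)), 41L)
  expect_equal(range(des@colInfo$lag_bins), c(-20, 20))
  ## binary event columns
  expect_true(all(des@X %in% c(0, 1)))
})

test_that("a single event produces ones exactly at shifted rows", {
  tr <- singleTrial(reward = 0)
  tr$lick_times <- ""
  cfg <- glmConfig(n_shifts = 3L, trial_margin = 0.6)
  fs <- 1 / 0.054
  n <- ceiling((tr$t_side_exit + 2) * fs)
  trace <- photometryTrace(rnorm(n), fs, "x")
  des <- buildDesign(tr, trace, cfg)
  b_event <- floor(tr$t_side_entry / 0.054 + 1e-6) + 1
  for (l in -3:3) {
    col <- which(des@colInfo$feature == "side_entry" &
                   des@colInfo$lag_bins == l)
    hit_rows <- which(des@X[, col] == 1)
    expect_equal(des@rowInfo$bin[hit_rows], b_event + l)
  }
})

test_that("history variant partitions side entries across eight columns", {
  des <- suppressMessages(
    buildDesign(fixSession()$trials, fixCleanSynth()$da,
                glmConfig(method = "ols"), variant = "history"))
  hist_feats <- grep("^side_entry_", des@features, value = TRUE)
  expect_lte(length(hist_feats), 8)
  expect_gte(length(hist_feats), 4)
  lag0 <- vapply(hist_feats, function(f)
    which(des@colInfo$feature == f & des@colInfo$lag_bins == 0), 1L)
  sums <- rowSums(des@X[, lag0, drop = FALSE])
  se_rows <- sums > 0
  expect_true(all(sums[se_rows] == 1))
  ## every labelled trial contributes exactly one side-entry marker
  n_lab <- sum(!is.na(fixSession()$trials$history_label))
  expect_equal(sum(colSums(des@X[, lag0, drop = FALSE])),
               sum(des@rowInfo$duplicated[se_rows]) + n_lab)
})

test_that("photometry variant appends a shifted continuous predictor", {
  s <- fixSession()
  out <- fixCleanSynth()
  des <- buildDesign(s$trials, out$ach, glmConfig(method = "ols"),
                     variant = "photometry", extra_trace = out$da)
  expect_true("photometry" %in% des@features)
  expect_equal(ncol(des@X), 7 * 41)
  pcols <- des@colInfo$feature == "photometry"
  expect_false(all(des@X[, pcols] %in% c(0, 1)))
})

test_that("OLS recovers exactly a noiseless linear response", {
  des <- fixDesign()
  set.seed(8)
  beta_star <- rnorm(ncol(des@X), sd = 0.3)
  y_star <- as.numeric(des@X %*% beta_star + 0.7)
  des2 <- methods::initialize(des, y = y_star)
  fit <- fitGLM(des2, glmConfig(method = "ols"))
  expect_lt(max(abs(fit$beta - beta_star)), 1e-6)
  expect_lt(abs(fit$intercept - 0.7), 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("ridge shrinks monotonically with alpha", {
  des <- fixDesign()
  norms <- vapply(c(0, 10, 100, 1000, 10000), function(a) {
    f <- fitGLM(des, glmConfig(method = "ridge", alpha = a))
    sqrt(sum(f$beta^2))
  }, 1)
  expect_true(all(diff(norms) < 0))
})

test_that("large-alpha lasso collapses to the training mean", {
  des <- fixDesign()
  fit <- fitGLM(des, glmConfig(method = "lasso", alpha = 10))
  expect_lt(max(abs(fit$beta)), 1e-8)
  expect_equal(fit$intercept, mean(des@y), tolerance = 1e-6)
})

test_that("elastic net at l1_ratio 0 matches ridge through the scale conversion", {
  des <- fixDesign()
  n <- length(des@y)
  a_enet <- 0.005
  f_en <- fitGLM(des, glmConfig(method = "elastic_net", alpha = a_enet,
                                l1_ratio = 0))
  f_rg <- fitGLM(des, glmConfig(method = "ridge",
                                alpha = ridgeAlphaFromEnet(a_enet, n)))
  expect_lt(max(abs(f_en$beta - f_rg$beta)), 0.02 * max(abs(f_rg$beta)))
  expect_equal(enetAlphaFromRidge(ridgeAlphaFromEnet(a_enet, n), n), a_enet)
})

test_that("the protocol yields near-zero errors on noiseless data and no skill on noise", {
  des <- fixDesign()
  set.seed(12)
  beta_star <- rnorm(ncol(des@X), sd = 0.3)
  des_clean <- methods::initialize(des,
                                   y = as.numeric(des@X %*% beta_star))
  cfg <- glmConfig(method = "ols", runs = 2)
  fit_clean <- runProtocol(des_clean, cfg, seed = 3)
  expect_lt(mean(fit_clean$mse$mse_val), 1e-12)
  expect_lt(mean(fit_clean$mse$mse_test), 1e-12)

  des_noise <- methods::initialize(des, y = rnorm(length(des@y)))
  fit_noise <- runProtocol(des_noise, cfg, seed = 3)
  expect_lt(mean(fit_noise$mse$r2_test), 0.02)
})

test_that("duplicated boundary rows never leak across split sides", {
  des <- fixDesign()
  fit <- runProtocol(des, glmConfig(method = "ols", runs = 3), seed = 4)
  expect_true(all(fit$mse$leak_fraction == 0))
  expect_gt(mean(des@rowInfo$duplicated), 0)
  ## both copies of a duplicated bin carry the same group key
  dup_bins <- des@rowInfo$bin[des@rowInfo$duplicated]
  for (b in unique(dup_bins)[1:20]) {
    g <- des@rowInfo$group[des@rowInfo$bin == b]
    expect_equal(length(unique(g)), 1)
  }
})

test_that("kernel extraction reshapes runs into mean and sd", {
  des <- fixDesign()
  cfg1 <- glmConfig(method = "ols", runs = 1)
  ks1 <- extractKernels(runProtocol(des, cfg1, seed = 5))
  expect_true(all(ks1@sd == 0))
  expect_equal(length(kernelLags(ks1)), 41)
  expect_equal(sort(kernelFeatures(ks1)), sort(des@features))

  cfg3 <- glmConfig(method = "ols", runs = 3)
  ks3 <- extractKernels(runProtocol(des, cfg3, seed = 5))
  expect_true(any(ks3@sd > 0))
})

test_that("dropping either of two redundant duplicate features is harmless", {
  des <- fixDesign()
  ## duplicate the side_entry block wholesale: two perfectly collinear
  ## features
  se_cols <- which(des@colInfo$feature == "side_entry")
  X2 <- cbind(des@X, des@X[, se_cols])
  ci2 <- rbind(des@colInfo,
               transform(des@colInfo[se_cols, ], feature = "side_entry_dup"))
  des2 <- methods::new("DesignMatrix", X = X2, y = des@y, colInfo = ci2,
                       rowInfo = des@rowInfo,
                       features = c(des@features, "side_entry_dup"),
                       binWidth = des@binWidth, nShifts = des@nShifts)
  cfg <- glmConfig(method = "ridge", alpha = 1, runs = 2)
  lo <- leaveOutAnalysis(des2, cfg, seed = 6,
                         features = c("side_entry", "side_entry_dup",
                                      "reward"))
  tab <- lo$table
  expect_lt(abs(tab$dmse_val[tab$feature == "side_entry"]), lo$noise_band)
  expect_lt(abs(tab$dmse_val[tab$feature == "side_entry_dup"]),
            lo$noise_band)
  expect_gt(tab$dmse_val[tab$feature == "reward"], lo$noise_band)
})

test_that("reconstruction is exact for a perfect fit and definitional for beta = 0", {
  des <- fixDesign()
  set.seed(13)
  beta_star <- rnorm(ncol(des@X), sd = 0.2)
  des_clean <- methods::initialize(des, y = as.numeric(des@X %*% beta_star))
  fit <- runProtocol(des_clean, glmConfig(method = "ols", runs = 1),
                     seed = 7)
  rec <- reconstructSignal(des_clean, fit, n_boot = 20)
  expect_equal(rec$r2, 1, tolerance = 1e-9)

  fit0 <- fit
  fit0$beta <- matrix(0, nrow(fit$beta), 1)
  fit0$intercept <- 0
  rec0 <- reconstructSignal(des_clean, fit0, n_boot = 20)
  y <- des_clean@y
  expect_equal(rec0$r2, 1 - sum(y^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_true(all(rec0$yhat == 0))
})
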