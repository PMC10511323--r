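#' RFLR agent parameters
#'
#' Parameters of the recursively formulated logistic regression (RFLR)
#' choice model: the log-odds of choosing right on trial t are
#' \deqn{\psi_t = \alpha c_{t-1} + \beta \phi_t,\qquad
#'       \phi_{t+1} = c_t r_t + e^{-1/\tau}\phi_t,}
#' with choices \eqn{c_t \in \{-1, +1\}} and rewards \eqn{r_t \in \{0, 1\}}:
#' `alpha` weighs repeating the last action (perseveration), `beta` weighs
#' the exponentially decaying action-reward evidence, and `tau` (in trials)
#' sets how fast that evidence decays.
#'
#' @param alpha perseveration weight.
#' @param beta evidence weight.
#' @param tau evidence decay constant in trials, > 0.
#' @param phi0 initial evidence (default 0).
#' @param policy generative policy: `"rflr"` (default) or one of the
#'   reference agents `"random"`, `"wsls"` (win-stay lose-shift),
#'   `"always_high"`, `"constant"`.
#' @param constant_choice the fixed choice for `policy = "constant"`.
#' @return classed parameter list.
#' @examples
#' agentParams(alpha = 1, beta = 2, tau = 1.5)
#' @export
agentParams <- function(alpha = 1.0, beta = 2.0, tau = 1.5, phi0 = 0,
                        policy = c("rflr", "random", "wsls", "always_high",
                                   "constant"),
                        constant_choice = -1) {
  policy <- match.arg(policy)
  stopIf(tau <= 0, "tau must be > 0")
  stopIf(!all(is.finite(c(alpha, beta, tau, phi0))),
         "agent parameters must be finite")
  structure(list(alpha = alpha, beta = beta, tau = tau, phi0 = phi0,
                 policy = policy, constant_choice = constant_choice),
            class = "agentParams")
}

#' @export
print.agentParams <- function(x, ...) {
  cat(sprintf("RFLR agent (%s): alpha = %.3g, beta = %.3g, tau = %.3g\n",
              x$policy, x$alpha, x$beta, x$tau))
  invisible(x)
}

#' Recursive evidence series
#'
#' Computes the latent evidence \eqn{\phi} of the RFLR:
#' \eqn{\phi_{t+1} = c_t r_t + e^{-1/\tau} \phi_t} with \eqn{\phi_0 =}
#' `phi0`. Element `t` of the returned vector is the evidence available
#' *before* trial `t` (so it is a valid regressor for predicting choice t);
#' the vector has length `n + 1`, the last element being the post-session
#' state.
#'
#' @param choices signed binary choices (-1/+1), length n.
#' @param rewards binary rewards (0/1), length n.
#' @param tau decay constant, > 0.
#' @param phi0 initial evidence.
#' @return numeric vector of length n + 1.
#' @examples
#' evidenceSeries(c(1, 1, -1), c(1, 0, 1), tau = 2)
#' @export
evidenceSeries <- function(choices, rewards, tau, phi0 = 0) {
  stopIf(length(choices) != length(rewards),
         "choices and rewards must have equal length")
  stopIf(tau <= 0, "tau must be > 0")
  assertChoices(choices)
  n <- length(choices)
  phi <- numeric(n + 1)
  phi[1] <- phi0
  decay <- exp(-1 / tau)
  for (t in seq_len(n))
    phi[t + 1] <- choices[t] * rewards[t] + decay * phi[t]
  phi
}

#' RFLR choice log-odds
#'
#' \eqn{\psi = \alpha c_{prev} + \beta \phi}; the probability of choosing
#' right is `plogis(psi)`.
#'
#' @param params an [agentParams()].
#' @param c_prev previous choice (-1/+1, or 0 when there is none).
#' @param phi current evidence.
#' @return the log-odds \eqn{\psi} (vectorized).
#' @export
choiceLogodds <- function(params, c_prev, phi) {
  params$alpha * c_prev + params$beta * phi
}

#' Fit the RFLR to a session by profile likelihood over tau
#'
#' For each `tau` in the grid the evidence series is rebuilt and the
#' Bernoulli log-likelihood of the observed choices is maximized over
#' `(alpha, beta)` by logistic regression on the regressors
#' \eqn{[c_{t-1}, \phi_t]} (no intercept: the model carries no side bias).
#' The grid optimum is then refined by one-dimensional likelihood
#' optimization over `tau`. The first trial, having no predecessor, is
#' excluded from the likelihood. Deterministic given the data.
#'
#' @param trials trial table with `choice` and `reward` columns, or a list
#'   of trial tables fitted as concatenated sessions (evidence is reset at
#'   each session boundary).
#' @param tau_grid grid of decay constants profiled over (default 25
#'   log-spaced points in [0.25, 10]).
#' @param refine refine tau by 1-D optimization around the grid optimum
#'   (default TRUE).
#' @return a classed list: `params` ([agentParams()]), `log_likelihood`,
#'   `n_trials`, `converged`, `predicted_choice_prob` (per-trial P(right),
#'   NA on first trials), `se` (standard errors for alpha, beta),
#'   `tau_profile` (data.frame of the profiled grid).
#' @examples
#' sess <- simulateSession(taskConfig(n_trials = 400), agentParams(), seed = 2)
#' fit <- fitRFLR(sess$trials)
#' fit$params
#' @export
fitRFLR <- function(trials, tau_grid = exp(seq(log(0.25), log(10),
                                               length.out = 25)),
                    refine = TRUE) {
  if (is.data.frame(trials)) trials <- list(trials)
  stopIf(length(tau_grid) == 0, "tau_grid must be non-empty")
  n_tot <- sum(vapply(trials, nrow, 1L))
  stopIf(n_tot < 50, "need at least 50 trials to fit the RFLR")

  regressors <- function(tau) {
    parts <- lapply(trials, function(tr) {
      n <- nrow(tr)
      phi <- evidenceSeries(tr$choice, tr$reward, tau)
      idx <- seq(2, n)  # trials with a predecessor
      data.frame(y = (tr$choice[idx] + 1) / 2, c_prev = tr$choice[idx - 1],
                 phi = phi[idx])
    })
    do.call(rbind, parts)
  }

  fit_at <- function(tau) {
    d <- regressors(tau)
    fit <- suppressWarnings(
      stats::glm(y ~ 0 + c_prev + phi, family = stats::binomial(), data = d))
    list(ll = as.numeric(stats::logLik(fit)), fit = fit, d = d)
  }

  prof <- vapply(tau_grid, function(tau) fit_at(tau)$ll, numeric(1))
  best <- which.max(prof)
  tau_hat <- tau_grid[best]
  if (refine && length(tau_grid) > 1) {
    lo <- tau_grid[max(1, best - 1)]
    hi <- tau_grid[min(length(tau_grid), best + 1)]
    opt <- stats::optimize(function(tau) fit_at(tau)$ll, c(lo, hi),
                           maximum = TRUE, tol = 1e-4)
    if (opt$objective >= prof[best]) tau_hat <- opt$maximum
  }
  final <- fit_at(tau_hat)
  co <- stats::coef(final$fit)
  se <- sqrt(diag(stats::vcov(final$fit)))
  degenerate <- !final$fit$converged || any(!is.finite(co)) ||
    any(abs(co) > 50)
  pred <- rep(NA_real_, n_tot)
  pos <- cumsum(c(0, vapply(trials, nrow, 1L)))
  k <- 0
  for (s in seq_along(trials)) {
    ns <- nrow(trials[[s]])
    if (ns >= 2)
      pred[pos[s] + 2:ns] <- stats::fitted(final$fit)[k + seq_len(ns - 1)]
    k <- k + max(ns - 1, 0)
  }
  structure(list(
    params = agentParams(alpha = unname(co["c_prev"]),
                         beta = unname(co["phi"]), tau = tau_hat),
    log_likelihood = final$ll, n_trials = n_tot,
    converged = !degenerate, predicted_choice_prob = pred,
    se = c(alpha = unname(se["c_prev"]), beta = unname(se["phi"])),
    z = c(alpha = unname(co["c_prev"] / se["c_prev"]),
          beta = unname(co["phi"] / se["phi"])),
    tau_profile = data.frame(tau = tau_grid, log_likelihood = prof)),
    class = "rflrFit")
}

#' @export
print.rflrFit <- function(x, ...) {
  cat(sprintf(
    "RFLR fit (n = %d trials): alpha = %.3f, beta = %.3f, tau = %.3f\n",
    x$n_trials, x$params$alpha, x$params$beta, x$params$tau))
  cat(sprintf("  log-likelihood = %.2f%s\n", x$log_likelihood,
              if (!x$converged) " (NOT converged / degenerate)" else ""))
  invisible(x)
}

#' Serialize an RFLR fit to JSON
#' @param fit an object from [fitRFLR()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRFLRFit <- function(fit, path) {
  jsonlite::write_json(list(
    alpha = fit$params$alpha, beta = fit$params$beta, tau = fit$params$tau,
    log_likelihood = fit$log_likelihood, n_trials = fit$n_trials,
    converged = fit$converged), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Behavioural dynamics around block transitions
#'
#' Empirical P(switch) and P(high port) at trial offsets around each block
#' switch (offset 0 = first trial of the new block; negative offsets index
#' into the ending block), with binomial standard errors.
#'
#' @param trials trial table.
#' @param window maximum |offset| (default 10).
#' @return data.frame with columns `offset`, `p_switch`, `se_switch`,
#'   `p_high`, `se_high`, `n`.
#' @export
blockTransitionSummary <- function(trials, window = 10L) {
  stopIf(length(unique(trials$block_id)) < 2, "need at least 2 blocks")
  n <- nrow(trials)
  if (window >= n) {
    warning("window exceeds available trials; truncating")
    window <- n - 1L
  }
  switches <- which(diff(trials$block_id) != 0) + 1L
  sw <- c(NA, as.numeric(trials$choice[-1] != trials$choice[-n]))
  hi <- as.numeric(trials$choice == trials$high_port)
  ## P(high) before a switch is membership in the *ending* block's port
  offs <- seq(-window, window)
  res <- lapply(offs, function(o) {
    idx <- switches + o
    idx <- idx[idx >= 1 & idx <= n]
    s <- sw[idx]; h <- hi[idx]
    data.frame(offset = o,
               p_switch = mean(s, na.rm = TRUE),
               se_switch = stats::sd(s, na.rm = TRUE) / sqrt(sum(!is.na(s))),
               p_high = mean(h), se_high = stats::sd(h) / sqrt(length(h)),
               n = length(idx))
  })
  do.call(rbind, res)
}

#' History-conditioned switch probabilities
#'
#' P(switch on the current trial) conditioned on the previous `k` trials'
#' (stay/switch, outcome) word. Words with zero support are absent from the
#' result rather than reported as zero.
#'
#' @param trials trial table.
#' @param k history length, 1 to 3.
#' @return data.frame with columns `word`, `n`, `p_switch`.
#' @export
conditionalSwitchTable <- function(trials, k = 1L) {
  stopIf(!k %in% 1:3, "k must be 1, 2 or 3")
  n <- nrow(trials)
  stay <- c(NA, trials$choice[-1] == trials$choice[-n])
  outc <- ifelse(trials$reward == 1, "W", "L")
  tok <- ifelse(stay, "stay", "switch")
  eligible <- seq(k + 2L, n)  # need k history trials each with a predecessor
  word <- vapply(eligible, function(t)
    paste(paste0(tok[(t - k):(t - 1)], outc[(t - k):(t - 1)]),
          collapse = "-"), "")
  sw <- as.numeric(trials$choice[eligible] != trials$choice[eligible - 1L])
  agg <- stats::aggregate(sw, by = list(word = word),
                          FUN = function(v) c(n = length(v), p = mean(v)))
  out <- data.frame(word = agg$word, n = agg$x[, "n"], p_switch = agg$x[, "p"])
  out[order(out$word), ]
}
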