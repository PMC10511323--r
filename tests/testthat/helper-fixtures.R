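## Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## A mid-sized RFLR-agent session under the default task conditions.
fixSession <- function() fixture("session", {
  simulateSession(taskConfig(n_trials = 300), agentParams(), seed = 31)
})

## Clean linear-generator traces (no history gains, no amplitude jitter,
## no coupling): the configuration whose kernels OLS should recover.
fixCleanSynth <- function() fixture("clean_synth", {
  spec <- generatorSpec(coupling = list(gain = 0, lag = 0.108),
                        history_effects = FALSE, amplitude_cv = 0)
  synthesizeTraces(fixSession()$trials, spec, seed = 32)
})

## Default-generator traces (history gains, amplitude jitter, coupling on).
fixDefaultSynth <- function() fixture("default_synth", {
  synthesizeTraces(fixSession()$trials, generatorSpec(), seed = 32)
})

fixTensors <- function() fixture("tensors", {
  s <- fixSession()
  out <- fixDefaultSynth()
  da <- alignTrials(zscoreSession(out$da), s$trials, window = c(1, 2))
  ach <- alignTrials(zscoreSession(out$ach), s$trials, window = c(1, 2))
  list(da = da, ach = ach,
       outcome = ifelse(s$trials$reward[trialIndex(da)] == 1,
                        "rewarded", "unrewarded"))
})

## A hand-made tensor with known content.
makeTensor <- function(data, window = c(1, 2), bin = 0.054,
                       channel = "test") {
  new("TrialTensor", data = data, alignEvent = "t_side_entry",
      window = window, binWidth = bin,
      trialIndex = seq_len(nrow(data)), channel = channel)
}

## A single fully specified trial table (times on the 54 ms grid).
singleTrial <- function(reward = 1, licks = c(3.456, 3.564)) {
  tr <- data.frame(trial = 1L, choice = 1, reward = reward, high_port = 1,
                   t_centre_entry = 1.08, t_centre_exit = 1.296,
                   t_side_entry = 2.16, t_side_exit = 4.32,
                   lick_times = if (reward == 1)
                     paste(sprintf("%.9f", licks), collapse = ";") else "",
                   aborted = FALSE, stringsAsFactors = FALSE)
  BanditPhotometry:::annotateTrials(tr)
}
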