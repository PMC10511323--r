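#' Task configuration for the two-armed bandit
#'
#' Parameters of the probabilistic two-armed bandit task (2ABT): a centre
#' poke initiates the trial, a side poke within the choice window yields
#' water with probability `p_high` on the current high-probability port and
#' `1 - p_high` on the other; the high port reverses after `rewards_per_block`
#' rewards have been collected in the block; side-port withdrawal starts the
#' inter-trial interval.
#'
#' @param p_high reward probability on the high port, in (0.5, 1]. Default
#'   0.95, the probabilistic stage of training.
#' @param rewards_per_block rewards collected before the block reverses
#'   (default 30).
#' @param choice_window seconds allowed for the side poke (default 5).
#' @param iti minimum inter-trial interval in seconds (default 1).
#' @param n_trials number of trials to simulate (default 500).
#' @param timing_params list of inter-event latency parameters: lognormal
#'   `centre_dwell` and `approach` (centre exit to side entry), lognormal
#'   side `occupancy_rewarded` / `occupancy_unrewarded`, exponential
#'   `iti_jitter_rate` added to the minimum ITI, Poisson `lick_rate` (Hz)
#'   during rewarded side occupancy and `unrewarded_lick_prob` for a 0/1
#'   lick on unrewarded trials.
#' @return A classed list of validated task parameters.
#' @examples
#' cfg <- taskConfig(n_trials = 100)
#' cfg$p_high
#' @export
taskConfig <- function(p_high = 0.95, rewards_per_block = 30L,
                       choice_window = 5, iti = 1, n_trials = 500L,
                       timing_params = list()) {
  stopIf(p_high <= 0.5 || p_high > 1,
         "p_high must be in (0.5, 1]: the other port has probability 1 - p_high and must be the low port")
  stopIf(rewards_per_block < 1, "rewards_per_block must be >= 1")
  stopIf(n_trials < 1, "n_trials must be positive")
  stopIf(iti < 0 || choice_window <= 0, "iti and choice_window must be positive")
  tp <- utils::modifyList(list(
    centre_dwell = c(meanlog = log(0.15), sdlog = 0.25),
    approach = c(meanlog = log(0.5), sdlog = 0.3),
    occupancy_rewarded = c(meanlog = log(1.5), sdlog = 0.25),
    occupancy_unrewarded = c(meanlog = log(0.5), sdlog = 0.35),
    iti_jitter_rate = 2,
    lick_rate = 7,
    unrewarded_lick_prob = 0.3), timing_params)
  stopIf(tp$iti_jitter_rate <= 0 || tp$lick_rate <= 0,
         "latency parameters must be strictly positive")
  structure(list(p_high = p_high,
                 rewards_per_block = as.integer(rewards_per_block),
                 choice_window = choice_window, iti = iti,
                 n_trials = as.integer(n_trials), timing_params = tp),
            class = "taskConfig")
}

#' @export
print.taskConfig <- function(x, ...) {
  cat(sprintf("2ABT task config: p_high = %.2f, %d rewards/block, %d trials, ITI %g s\n",
              x$p_high, x$rewards_per_block, x$n_trials, x$iti))
  invisible(x)
}

## Derived trial-table columns that are deterministic functions of
## (choice, reward, high_port): block identity, trials since the block
## switch, and the eight stay/switch x previous-outcome x current-outcome
## history labels. Shared between the simulator and the event-stream
## reconstruction so the round trip is exact.
annotateTrials <- function(df) {
  n <- nrow(df)
  block_id <- cumsum(c(1L, as.integer(df$high_port[-1] != df$high_port[-n])))
  tfs <- integer(n)
  for (i in seq_len(n))
    tfs[i] <- if (i == 1L || block_id[i] != block_id[i - 1L]) 0L else tfs[i - 1L] + 1L
  stay <- c(NA, df$choice[-1] == df$choice[-n])
  prev_r <- c(NA, df$reward[-n])
  lab <- ifelse(is.na(stay), NA_character_,
                paste0(ifelse(stay, "stay", "switch"), "_",
                       ifelse(prev_r == 1, "win", "lose"), "_",
                       ifelse(df$reward == 1, "win", "lose")))
  df$block_id <- block_id
  df$trials_from_block_switch <- tfs
  df$history_label <- lab
  df
}

agentChoose <- function(agent, c_prev, phi, high_port, last_reward) {
  switch(agent$policy,
    rflr = {
      p_right <- stats::plogis(agent$alpha * c_prev + agent$beta * phi)
      if (stats::runif(1) < p_right) 1 else -1
    },
    random = if (stats::runif(1) < 0.5) 1 else -1,
    wsls = {
      if (c_prev == 0) { if (stats::runif(1) < 0.5) 1 else -1 }
      else if (last_reward == 1) c_prev else -c_prev
    },
    always_high = high_port,
    constant = agent$constant_choice,
    stop("unknown agent policy: ", agent$policy))
}

#' Simulate a 2ABT session
#'
#' Runs an agent through the block-structured probabilistic task, drawing
#' rewards from `p_high` / `1 - p_high` on the chosen port, reversing the
#' high port after `rewards_per_block` rewards, and drawing all port-entry
#' latencies, side occupancy and licks from the configured distributions.
#' Deterministic given `seed`.
#'
#' @param config a [taskConfig()].
#' @param agent an [agentParams()] (the generative RFLR agent by default, or
#'   one of the reference policies).
#' @param seed integer seed; all randomness in the session flows from it.
#' @return A list with elements `trials` (the trial table: one row per trial
#'   with choice in -1/+1, reward 0/1, high_port, block identity, history
#'   label, the four port timestamps and semicolon-separated lick times) and
#'   `events` (the ordered event stream, see [eventsFromTrials()]).
#' @examples
#' sess <- simulateSession(taskConfig(n_trials = 50), agentParams(), seed = 1)
#' head(sess$trials)
#' @export
simulateSession <- function(config = taskConfig(), agent = agentParams(),
                            seed = 1L) {
  stopifnot(inherits(config, "taskConfig"), inherits(agent, "agentParams"))
  n <- config$n_trials
  tp <- config$timing_params
  withSeed(seed, {
    choice <- reward <- numeric(n)
    high <- numeric(n)
    t_ce <- t_cx <- t_se <- t_sx <- numeric(n)
    licks <- vector("list", n)
    phi <- agent$phi0
    c_prev <- 0
    last_reward <- 0
    cur_high <- if (stats::runif(1) < 0.5) 1 else -1
    block_rewards <- 0L
    t_prev_exit <- 0
    for (i in seq_len(n)) {
      high[i] <- cur_high
      t_ce[i] <- t_prev_exit + config$iti +
        stats::rexp(1, rate = tp$iti_jitter_rate)
      t_cx[i] <- t_ce[i] + stats::rlnorm(1, tp$centre_dwell["meanlog"],
                                         tp$centre_dwell["sdlog"])
      t_se[i] <- t_cx[i] + stats::rlnorm(1, tp$approach["meanlog"],
                                         tp$approach["sdlog"])
      choice[i] <- agentChoose(agent, c_prev, phi, cur_high, last_reward)
      p_r <- if (choice[i] == cur_high) config$p_high else 1 - config$p_high
      reward[i] <- as.numeric(stats::runif(1) < p_r)
      occ <- if (reward[i] == 1) tp$occupancy_rewarded else tp$occupancy_unrewarded
      t_sx[i] <- t_se[i] + stats::rlnorm(1, occ["meanlog"], occ["sdlog"])
      if (reward[i] == 1) {
        span <- t_sx[i] - t_se[i] - 0.1
        nl <- stats::rpois(1, tp$lick_rate * max(span, 0))
        licks[[i]] <- if (nl > 0)
          sort(t_se[i] + 0.1 + stats::runif(nl) * span) else numeric(0)
      } else {
        licks[[i]] <- if (stats::runif(1) < tp$unrewarded_lick_prob)
          t_se[i] + 0.1 + stats::runif(1) * (t_sx[i] - t_se[i] - 0.1)
        else numeric(0)
      }
      ## evidence update after outcome; block reverses after the quota
      phi <- choice[i] * reward[i] + exp(-1 / agent$tau) * phi
      c_prev <- choice[i]
      last_reward <- reward[i]
      block_rewards <- block_rewards + as.integer(reward[i])
      if (block_rewards >= config$rewards_per_block) {
        cur_high <- -cur_high
        block_rewards <- 0L
      }
      t_prev_exit <- t_sx[i]
    }
    trials <- data.frame(
      trial = seq_len(n), choice = choice, reward = reward, high_port = high,
      t_centre_entry = t_ce, t_centre_exit = t_cx,
      t_side_entry = t_se, t_side_exit = t_sx,
      lick_times = vapply(licks, function(l) paste(sprintf("%.9f", l),
                                                   collapse = ";"), ""),
      aborted = FALSE, stringsAsFactors = FALSE)
    trials <- annotateTrials(trials)
    list(trials = trials, events = eventsFromTrials(trials))
  })
}

#' Parse semicolon-separated lick times from a trial table row
#' @param x character vector of semicolon-joined times.
#' @return list of numeric vectors.
#' @export
lickTimes <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE),
         function(s) as.numeric(s[nzchar(s)]))
}

sideLabel <- function(choice) ifelse(choice > 0, "R", "L")
sideCode <- function(label) ifelse(label == "R", 1, -1)

#' Convert a trial table to an ordered event stream
#'
#' Emits, per trial: the four port events (side entries/exits carry the
#' chosen side, centre entries carry the current high port so the stream
#' round-trips losslessly), a reward event at side entry on rewarded trials,
#' and lick onset/offset pairs. The inverse is [trialsFromEvents()].
#'
#' @param trials a trial table from [simulateSession()].
#' @param lick_duration seconds between lick onset and offset (default 0.03).
#' @return data.frame with columns `event`, `time`, `value`, ordered by time.
#' @export
eventsFromTrials <- function(trials, lick_duration = 0.03) {
  stopIf(nrow(trials) > 1 &&
           any(diff(trials$t_centre_entry) <= 0), "overlapping trials")
  with_ok <- c("t_centre_entry", "t_centre_exit", "t_side_entry", "t_side_exit")
  stopIf(any(!with_ok %in% names(trials)), "missing mandatory timestamps")
  bad <- trials$t_centre_entry >= trials$t_centre_exit |
    trials$t_centre_exit >= trials$t_side_entry |
    trials$t_side_entry >= trials$t_side_exit
  stopIf(any(bad), "timestamps must satisfy centre_entry < centre_exit < side_entry < side_exit")
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    lk <- lickTimes(tr$lick_times)[[1]]
    ev <- data.frame(
      event = c("centre_entry", "centre_exit", "side_entry", "side_exit"),
      time = c(tr$t_centre_entry, tr$t_centre_exit, tr$t_side_entry,
               tr$t_side_exit),
      value = c(sideLabel(tr$high_port), "", sideLabel(tr$choice),
                sideLabel(tr$choice)),
      stringsAsFactors = FALSE)
    if (tr$reward == 1)
      ev <- rbind(ev, data.frame(event = "reward", time = tr$t_side_entry,
                                 value = sideLabel(tr$choice)))
    if (length(lk))
      ev <- rbind(ev,
                  data.frame(event = "lick_on", time = lk, value = ""),
                  data.frame(event = "lick_off", time = lk + lick_duration,
                             value = ""))
    ev
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(event = character(0), time = numeric(0),
                      value = character(0), stringsAsFactors = FALSE))
  out <- out[order(out$time, match(out$event,
          c("centre_entry", "centre_exit", "side_entry", "reward",
            "lick_on", "lick_off", "side_exit"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconstruct a trial table from an event stream
#'
#' Inverse of [eventsFromTrials()]: trials are delimited by centre entries;
#' choice, reward, high port, timestamps and lick times are read back and
#' the derived columns (block identity, history labels) are recomputed,
#' giving an exact round trip.
#'
#' @param events event stream data.frame (`event`, `time`, `value`).
#' @return trial table data.frame.
#' @export
trialsFromEvents <- function(events) {
  if (nrow(events) == 0)
    return(annotateTrials(data.frame(trial = integer(0), choice = numeric(0),
      reward = numeric(0), high_port = numeric(0), t_centre_entry = numeric(0),
      t_centre_exit = numeric(0), t_side_entry = numeric(0),
      t_side_exit = numeric(0), lick_times = character(0),
      aborted = logical(0))[0, ]))
  stopIf(is.unsorted(events$time), "event timestamps must be non-decreasing")
  starts <- which(events$event == "centre_entry")
  ends <- c(starts[-1] - 1L, nrow(events))
  rows <- lapply(seq_along(starts), function(i) {
    ev <- events[starts[i]:ends[i], ]
    pick <- function(e) ev$time[match(e, ev$event)]
    lk <- ev$time[ev$event == "lick_on"]
    data.frame(
      trial = i,
      choice = sideCode(ev$value[ev$event == "side_entry"][1]),
      reward = as.numeric(any(ev$event == "reward")),
      high_port = sideCode(ev$value[ev$event == "centre_entry"][1]),
      t_centre_entry = pick("centre_entry"),
      t_centre_exit = pick("centre_exit"),
      t_side_entry = pick("side_entry"),
      t_side_exit = pick("side_exit"),
      lick_times = paste(sprintf("%.9f", lk), collapse = ";"),
      aborted = FALSE, stringsAsFactors = FALSE)
  })
  annotateTrials(do.call(rbind, rows))
}

#' Read/write trial tables and event streams as CSV
#'
#' Plain-text serialization with the documented headers; lick times are kept
#' as a semicolon-separated field.
#'
#' @param trials,events objects to write.
#' @param path file path.
#' @return the object read, or the path invisibly for writers.
#' @export
writeTrialsCSV <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialsCSV
#' @export
readTrialsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(lick_times = "character"))
  df$lick_times[is.na(df$lick_times)] <- ""
  df
}

#' @rdname writeTrialsCSV
#' @export
writeEventsCSV <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialsCSV
#' @export
readEventsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  df$value[is.na(df$value)] <- ""
  df
}
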