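# Shared fixtures: hand-built minimal sessions and brute-force oracles.

# A tiny hand-assembled session: `n` trials with regular timing, spikes
# supplied by the caller (or a homogeneous Poisson train).
toy_events <- function(n = 3, t0 = 10, gap = 10) {
  vc <- t0 + (seq_len(n) - 1) * gap
  task_events(
    time_s = c(0, vc, vc + 3, vc + 3.01, vc + 5),
    kind = c("RULE_CHANGE", rep("VC_ON_PD", n), rep("RWD_PD", n),
             rep("REWARD", n), rep("RTN_PD", n)),
    side = c(NA, rep("L", n), rep("L", n), rep("L", n), rep("L", n)),
    payload = c("VC", rep("", 4 * n)))
}

toy_session <- function(n = 3, spike_times = numeric(0), t0 = 10,
                        gap = 10, with_tracking = FALSE) {
  ev <- toy_events(n, t0, gap)
  trials <- build_trials(ev)
  tracking <- if (with_tracking) {
    tt <- seq(0, t0 + n * gap, by = 0.033)
    data.frame(time_s = tt, x_cm = tt * 2, y_cm = 0)
  } else {
    data.frame(time_s = numeric(), x_cm = numeric(), y_cm = numeric())
  }
  lc_session(maze = maze_config(),
             spikes = list(spike_train("u1", spike_times, 0.8)),
             tracking = tracking, events = ev, trials = trials,
             meta = list(turn_side = "R"))
}

# Brute-force PETH oracle: explicit double loop over trials and bins.
peth_oracle <- function(spike_times, anchors, window, bin_width) {
  nb <- round((window[2] - window[1]) / bin_width)
  counts <- matrix(0L, length(anchors), nb)
  for (i in seq_along(anchors)) {
    for (b in seq_len(nb)) {
      lo <- anchors[i] + window[1] + (b - 1) * bin_width
      hi <- lo + bin_width
      counts[i, b] <- sum(spike_times >= lo & spike_times < hi)
    }
  }
  counts
}

# Reward-contingency oracle used to re-check trial rewarded flags.
reward_oracle <- function(rule, cue, choice, turn_side = "R") {
  if (rule == "VC") choice == cue else choice == turn_side
}

# Homogeneous Poisson spike train on [0, t_end).
poisson_train <- function(rate, t_end) {
  n <- rpois(1, rate * t_end)
  sort(runif(n, 0, t_end))
}
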