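# Synthetic session generator: constrained pseudorandom cue sequences, a
# criterion-driven rule-switching agent, maze-path kinematics with
# pre-photodetector acceleration bumps, and inhomogeneous-Poisson LC spikes
# (event-locked gains, acceleration coupling at a configurable lead, and
# reward-site suppression).

#' Generate a constrained pseudorandom cue sequence
#'
#' Produces the left/right sequence of lit screens under the task's three
#' constraints: (i) the same side is never lit on more than 2 consecutive
#' trials; (ii) a strict two-trial L/R alternation does not repeat more
#' than twice (no strictly alternating stretch longer than 4 trials);
#' (iii) any 8 successive trials contain at most 5 with the screen lit on
#' the same side. Generation is a backtracking search with randomized
#' branch order, so it terminates for every `n_trials`.
#'
#' @param n_trials Number of trials (>= 1). Uses the current RNG state.
#' @return Character vector of `"L"`/`"R"` of length `n_trials`.
#' @examples
#' set.seed(1)
#' generate_cue_sequence(12)
#' @export
generate_cue_sequence <- function(n_trials) {
  if (n_trials < 1) stop("generate_cue_sequence: n_trials must be >= 1",
                         call. = FALSE)
  seqs <- character(n_trials)
  tried <- vector("list", n_trials)
  k <- 1L
  while (k <= n_trials) {
    if (is.null(tried[[k]])) {
      tried[[k]] <- character(0)
    }
    cand <- setdiff(sample(SIDES), tried[[k]])
    placed <- FALSE
    for (side in cand) {
      tried[[k]] <- c(tried[[k]], side)
      seqs[k] <- side
      if (cue_prefix_ok(seqs, k)) {
        placed <- TRUE
        break
      }
    }
    if (placed) {
      k <- k + 1L
    } else {
      # dead end: unwind and retry the previous position
      tried[[k]] <- NULL
      seqs[k] <- ""
      k <- k - 1L
      if (k < 1L) stop("generate_cue_sequence: search failed",
                       call. = FALSE)  # unreachable: constraints satisfiable
    }
  }
  seqs
}

# Incremental constraint check on the prefix s[1..k] (only windows ending
# at k can be newly violated).
cue_prefix_ok <- function(s, k) {
  if (k >= 3 && s[k] == s[k - 1] && s[k] == s[k - 2]) return(FALSE)
  if (k >= 5) {
    w <- s[(k - 4):k]
    if (all(w[-1] != w[-5])) return(FALSE)     # 5-long strict alternation
  }
  if (k >= 8) {
    w <- s[(k - 7):k]
    n_l <- sum(w == "L")
    if (max(n_l, 8 - n_l) > 5) return(FALSE)
  }
  TRUE
}

#' Check a cue sequence against all three task constraints
#'
#' Exhaustive scan over every window; the independent validator used in
#' tests and QC (not the incremental check used during generation).
#'
#' @param s Character vector of `"L"`/`"R"`.
#' @return List with `ok` plus the measured `max_run`,
#'   `max_alternation_run`, and `max_count_in_8` diagnostics.
#' @export
check_cue_constraints <- function(s) {
  n <- length(s)
  r <- rle(s)
  max_run <- max(r$lengths)
  alt <- 1L
  max_alt <- 1L
  if (n >= 2) {
    for (i in 2:n) {
      alt <- if (s[i] != s[i - 1]) alt + 1L else 1L
      max_alt <- max(max_alt, alt)
    }
  }
  max8 <- 0L
  if (n >= 8) {
    for (i in 8:n) {
      w <- s[(i - 7):i]
      max8 <- max(max8, sum(w == "L"), sum(w == "R"))
    }
  } else max8 <- max(sum(s == "L"), sum(s == "R"))
  list(ok = max_run <= 2 && max_alt <= 4 && (n < 8 || max8 <= 5),
       max_run = max_run, max_alternation_run = max_alt,
       max_count_in_8 = max8)
}

#' Behavior-agent parameters
#'
#' The agent attends to one rule at a time. On each trial it follows the
#' attended rule's prescription with probability `p_follow_rule`, otherwise
#' it guesses, choosing its preferred side with probability `side_bias`.
#' After an (unsignalled) rule change, the attended rule updates only
#' `attended_rule_lag` trials later, emulating gradual strategy shifts.
#'
#' @param p_follow_rule Probability of following the attended rule.
#' @param attended_rule_lag Trials after a rule change before the agent's
#'   attended rule updates.
#' @param side_bias Probability of the preferred side when guessing.
#' @param preferred_side Preferred side when guessing (`"L"` by default;
#'   the Turn-rule rewarded side is the non-preferred one).
#' @return An `lc_agent_params` list.
#' @export
agent_params <- function(p_follow_rule = 0.9, attended_rule_lag = 10,
                         side_bias = 0.6, preferred_side = "L") {
  stopifnot(p_follow_rule >= 0, p_follow_rule <= 1,
            side_bias >= 0, side_bias <= 1,
            attended_rule_lag >= 0, preferred_side %in% SIDES)
  structure(list(p_follow_rule = p_follow_rule,
                 attended_rule_lag = as.integer(attended_rule_lag),
                 side_bias = side_bias, preferred_side = preferred_side),
            class = "lc_agent_params")
}

#' Rule-schedule policy
#'
#' @param initial_rule Rule in force at session start (`"VC"` or `"TURN"`).
#' @param turn_side Rewarded arm under the Turn rule.
#' @param max_switches Maximum number of criterion-driven rule switches.
#' @param criterion_correct,criterion_window The moving-window switching
#'   criterion: switch once at least `criterion_correct` of the last
#'   `criterion_window` trials (counted within the current rule epoch) are
#'   correct.
#' @return An `lc_rule_policy` list.
#' @export
rule_policy <- function(initial_rule = "VC", turn_side = "R",
                        max_switches = 1, criterion_correct = 18,
                        criterion_window = 20) {
  stopifnot(initial_rule %in% RULES, turn_side %in% SIDES,
            criterion_correct <= criterion_window)
  structure(list(initial_rule = initial_rule, turn_side = turn_side,
                 max_switches = max_switches,
                 criterion_correct = criterion_correct,
                 criterion_window = criterion_window),
            class = "lc_rule_policy")
}

#' Simulate choice behavior with criterion-driven rule switches
#'
#' Runs the behavior agent over a cue sequence. After each trial the
#' moving-window criterion is evaluated over the trials since the last
#' switch; when at least `criterion_correct` of the last
#' `criterion_window` trials are correct (and the window is full), the rule
#' is switched starting from the next trial, up to `max_switches` times.
#' The agent's attended rule updates `attended_rule_lag` trials after each
#' switch (a strategy change).
#'
#' @param cues Cue side sequence (from [generate_cue_sequence()]).
#' @param agent [agent_params()].
#' @param policy [rule_policy()].
#' @return List with `trials` (per-trial `cue_side`, `chosen_side`,
#'   `rewarded`, `rule`, `attended_rule`), `rule_change_trials`,
#'   `strategy_change_trials`, and `blocks` (block table delimited at rule
#'   and strategy changes).
#' @export
simulate_behavior <- function(cues, agent = agent_params(),
                              policy = rule_policy()) {
  n <- length(cues)
  rule <- policy$initial_rule
  attended <- rule
  pending_attend <- NULL  # c(trial at which attended updates, new rule)
  choice <- character(n); rewarded <- logical(n)
  rule_vec <- character(n); attended_vec <- character(n)
  rule_changes <- integer(0); strategy_changes <- integer(0)
  since_switch <- 0L
  correct_hist <- logical(0)
  n_switch <- 0L
  other <- function(s) ifelse(s == "L", "R", "L")
  for (t in seq_len(n)) {
    if (!is.null(pending_attend) && t >= pending_attend$trial) {
      attended <- pending_attend$rule
      pending_attend <- NULL
    }
    prescribed <- if (attended == "VC") cues[t] else policy$turn_side
    choice[t] <- if (runif(1) < agent$p_follow_rule) prescribed else {
      if (runif(1) < agent$side_bias) agent$preferred_side
      else other(agent$preferred_side)
    }
    rewarded[t] <- rewarded_under_rule(rule, cues[t], choice[t],
                                       policy$turn_side)
    rule_vec[t] <- rule; attended_vec[t] <- attended
    since_switch <- since_switch + 1L
    correct_hist <- c(correct_hist, rewarded[t])
    w <- policy$criterion_window
    if (since_switch >= w && n_switch < policy$max_switches &&
          sum(tail(correct_hist, w)) >= policy$criterion_correct &&
          t < n) {
      rule <- setdiff(RULES, rule)
      n_switch <- n_switch + 1L
      rule_changes <- c(rule_changes, t + 1L)
      lag_t <- t + 1L + agent$attended_rule_lag
      if (lag_t <= n) strategy_changes <- c(strategy_changes, lag_t)
      pending_attend <- list(trial = lag_t, rule = rule)
      since_switch <- 0L
      correct_hist <- logical(0)
    }
  }
  if (!length(rule_changes) && policy$max_switches > 0)
    message("simulate_behavior: switching criterion never reached; ",
            "no rule switch emitted")
  bounds <- sort(unique(c(1L, rule_changes, strategy_changes,
                          n + 1L)))
  blocks <- data.frame(
    start_trial = head(bounds, -1),
    end_trial = tail(bounds, -1) - 1L,
    stringsAsFactors = FALSE)
  blocks$label <- paste0("rule:", rule_vec[blocks$start_trial],
                         "/attend:", attended_vec[blocks$start_trial])
  list(trials = data.frame(cue_side = cues, chosen_side = choice,
                           rewarded = rewarded, rule = rule_vec,
                           attended_rule = attended_vec,
                           stringsAsFactors = FALSE),
       rule_change_trials = rule_changes,
       strategy_change_trials = strategy_changes,
       blocks = blocks)
}

#' Kinematic profile parameters for the trajectory generator
#'
#' The simulated rat runs the canonical maze path at `cruise_cm_s` with a
#' slowly wandering set-point (AR(1) multiplicative jitter), launches a
#' half-sine acceleration bump of amplitude `bump_amp` and duration
#' `bump_dur` beginning `bump_lead` seconds before each photodetector
#' crossing, brakes smoothly into the reward well and the start area, and
#' dwells there (`reward_dwell_s`, `start_dwell_s`).
#'
#' @param cruise_cm_s Cruise speed, cm/s.
#' @param bump_amp Acceleration bump amplitude, cm/s^2 (>= 0).
#' @param bump_dur Bump duration, s.
#' @param bump_rise_frac Fraction of `bump_dur` spent in the (quarter-sine)
#'   rise; the remainder falls as a quarter-cosine. Locomotor acceleration
#'   onsets are abrupt, so the rise is much faster than the decay.
#' @param bump_lead Lead of bump start before the predicted PD crossing, s.
#' @param accel_ramp Magnitude bound of the speed-controller acceleration,
#'   cm/s^2 (also the launch acceleration out of dwells).
#' @param ctrl_tau_s Relaxation time constant of the speed controller, s:
#'   the speed decays toward the set-point as `(set - v) / ctrl_tau_s`, so
#'   post-bump speed excess bleeds off smoothly instead of braking hard.
#' @param reward_dwell_s Dwell at the reward well, s.
#' @param start_dwell_s Dwell in the start area between trials, s.
#' @param cruise_jitter Relative SD of the cruise set-point wander.
#' @param jitter_tau_s Time constant of the set-point wander, s.
#' @param track_noise_cm SD of white positional noise added to the emitted
#'   LED coordinates, cm (0 = noiseless tracking).
#' @return An `lc_kin_params` list.
#' @export
kinematics_params <- function(cruise_cm_s = 35, bump_amp = 40,
                              bump_dur = 0.5, bump_rise_frac = 0.25,
                              bump_lead = 0.5,
                              accel_ramp = 80, ctrl_tau_s = 1,
                              reward_dwell_s = 2.5,
                              start_dwell_s = 1.5, cruise_jitter = 0.08,
                              jitter_tau_s = 0.5, track_noise_cm = 0) {
  if (cruise_cm_s <= 0 || bump_amp < 0 || bump_dur <= 0 || bump_lead < 0 ||
        accel_ramp <= 0 || bump_rise_frac <= 0 || bump_rise_frac >= 1)
    stop("kinematics_params: speed/acceleration parameters imply an ",
         "invalid (non-positive-speed) profile", call. = FALSE)
  structure(list(cruise_cm_s = cruise_cm_s, bump_amp = bump_amp,
                 bump_dur = bump_dur, bump_rise_frac = bump_rise_frac,
                 bump_lead = bump_lead,
                 accel_ramp = accel_ramp, ctrl_tau_s = ctrl_tau_s,
                 reward_dwell_s = reward_dwell_s,
                 start_dwell_s = start_dwell_s,
                 cruise_jitter = cruise_jitter, jitter_tau_s = jitter_tau_s,
                 track_noise_cm = track_noise_cm),
            class = "lc_kin_params")
}

#' Generate a maze trajectory and exact photodetector crossing times
#'
#' Integrates the kinematic profile on the video frame grid, trial by
#' trial, and reports both the emitted 2-D head-LED tracking and the exact
#' (sub-frame, linearly interpolated) PD crossing times, which are
#' therefore consistent with the tracking to within one frame.
#'
#' @param chosen_sides Per-trial chosen arm (`"L"`/`"R"`).
#' @param maze [maze_config()].
#' @param kin [kinematics_params()].
#' @return List: `tracking` (`time_s`, `x_cm`, `y_cm`), `crossings`
#'   (per-trial `vc_on_time`, `rwd_pd_time`, `rtn_pd_time`, `well_time`),
#'   and `truth` (frame-grid `time_s`, ground-truth `speed` and `accel`).
#' @export
generate_trajectory <- function(chosen_sides, maze = maze_config(),
                                kin = kinematics_params()) {
  dt <- maze$video_dt
  n_tr <- length(chosen_sides)
  pd <- maze$pd_positions
  stops <- c(maze$well_position, maze$path_length)
  rho <- exp(-dt / kin$jitter_tau_s)
  sig <- kin$cruise_jitter * sqrt(1 - rho^2)
  # generous preallocation: frames per trial ~ travel + dwells
  est <- ceiling((maze$path_length / kin$cruise_cm_s +
                    kin$reward_dwell_s + kin$start_dwell_s + 6) / dt)
  N <- est * (n_tr + 1)
  res <- .traj_integrate(
    n_trials = n_tr, dt = dt,
    pd_seq = c(pd[["VC_ON_PD"]], pd[["RWD_PD"]], pd[["RTN_PD"]]),
    stops = stops, rho = rho, sig = sig, cruise = kin$cruise_cm_s,
    ramp = kin$accel_ramp, ctrl_tau = kin$ctrl_tau_s,
    bump_amp = kin$bump_amp,
    bump_dur = kin$bump_dur,
    bump_rise = kin$bump_rise_frac * kin$bump_dur,
    bump_lead = kin$bump_lead,
    n_dwell_reward = round(kin$reward_dwell_s / dt),
    n_dwell_start = round(kin$start_dwell_s / dt), n_alloc = N)
  t_v <- res$t; d_v <- res$d; v_v <- res$v; a_v <- res$a
  side_v <- ifelse(res$trial == 0L, "L", chosen_sides[pmax(res$trial, 1)])
  k <- length(t_v)
  crossings <- data.frame(vc_on_time = res$cross[, 1],
                          rwd_pd_time = res$cross[, 2],
                          rtn_pd_time = res$cross[, 3],
                          well_time = res$cross[, 4])
  # wrap the path coordinate per-lap into 2-D; lap resets at d = 0
  xy <- maze_path_to_xy(d_v, side_v, maze)
  if (kin$track_noise_cm > 0) {
    xy[, 1] <- xy[, 1] + rnorm(k, 0, kin$track_noise_cm)
    xy[, 2] <- xy[, 2] + rnorm(k, 0, kin$track_noise_cm)
  }
  list(tracking = data.frame(time_s = t_v, x_cm = xy[, 1], y_cm = xy[, 2]),
       crossings = crossings,
       truth = data.frame(time_s = t_v, path_cm = d_v, speed = v_v,
                          accel = a_v))
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic session generator. The firing
#' intensity of each unit is
#' \deqn{\lambda(t) = b \, g_{ev}(t) \, s_{rwd}(t) +
#'       \gamma \, \max(0, a(t + \delta))}
#' where `b` is the baseline rate, the event gain \eqn{g_{ev}} multiplies
#' the baseline by `event_gain["VC_ON_PD"]` over the 0.5 s before each VC
#' onset and by `event_gain["RTN_PD"]` over the 0.5 s before each return
#' PD crossing, the reward suppression \eqn{s_{rwd}} multiplies it by
#' `reward_suppression` over \[1, 2) s after each reward-PD crossing,
#' \eqn{\gamma} is the acceleration coupling (Hz per cm/s^2, positive
#' accelerations only), and \eqn{\delta =} `firing_lead_s` makes firing
#' precede acceleration.
#'
#' @param n_trials Number of trials.
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param baseline_rate_hz Baseline (tonic) firing rate `b`, Hz.
#' @param event_gain Named multiplicative gains for `VC_ON_PD`, `RTN_PD`
#'   (applied over \[-0.5, 0) s before the event).
#' @param reward_suppression Suppression factor in (0, 1\] over \[1, 2) s
#'   after `RWD_PD`.
#' @param accel_coupling Hz per (cm/s^2) of positive acceleration.
#' @param firing_lead_s Firing-to-acceleration lead `delta`, s.
#' @param n_units Number of (independent) units to synthesize.
#' @param waveform_ms Waveform duration stored with each unit, ms.
#' @param agent [agent_params()].
#' @param policy [rule_policy()].
#' @param kin [kinematics_params()].
#' @param maze [maze_config()].
#' @param opto `NULL`, or `list(n_pulses =, gain =)` to append a 2 Hz /
#'   100 ms laser opto-tagging block after the maze epoch.
#' @return An `lc_sim_config` list.
#' @export
sim_config <- function(n_trials = 60, seed = 1, baseline_rate_hz = 2,
                       event_gain = c(VC_ON_PD = 1.5, RTN_PD = 1.4),
                       reward_suppression = 0.44, accel_coupling = 0.3,
                       firing_lead_s = 0.035, n_units = 1,
                       waveform_ms = 0.8, agent = agent_params(),
                       policy = rule_policy(), kin = kinematics_params(),
                       maze = maze_config(), opto = NULL) {
  if (baseline_rate_hz < 0 || any(event_gain < 0) || accel_coupling < 0)
    stop("sim_config: rates and gains must be >= 0", call. = FALSE)
  if (!(reward_suppression > 0 && reward_suppression <= 1))
    stop("sim_config: reward_suppression must be in (0, 1]", call. = FALSE)
  if (!all(c("VC_ON_PD", "RTN_PD") %in% names(event_gain)))
    stop("sim_config: event_gain must name VC_ON_PD and RTN_PD",
         call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 baseline_rate_hz = baseline_rate_hz,
                 event_gain = event_gain,
                 reward_suppression = reward_suppression,
                 accel_coupling = accel_coupling,
                 firing_lead_s = firing_lead_s,
                 n_units = as.integer(n_units), waveform_ms = waveform_ms,
                 agent = agent, policy = policy, kin = kin, maze = maze,
                 opto = opto),
            class = "lc_sim_config")
}

# Evaluate the generator's intensity function at times tt (vector).
sim_intensity <- function(tt, cfg, crossings, truth) {
  b <- cfg$baseline_rate_hz
  gain <- rep(1, length(tt))
  windows_mult <- function(gain, starts, ends, f) {
    for (i in seq_along(starts)) {
      m <- tt >= starts[i] & tt < ends[i]
      gain[m] <- gain[m] * f
    }
    gain
  }
  gain <- windows_mult(gain, crossings$vc_on_time - 0.5,
                       crossings$vc_on_time, cfg$event_gain[["VC_ON_PD"]])
  gain <- windows_mult(gain, crossings$rtn_pd_time - 0.5,
                       crossings$rtn_pd_time, cfg$event_gain[["RTN_PD"]])
  gain <- windows_mult(gain, crossings$rwd_pd_time + 1,
                       crossings$rwd_pd_time + 2, cfg$reward_suppression)
  # acceleration at t + delta, piecewise constant on the frame grid; each
  # truth sample is the mean over the frame ending at its stamp, so index
  # by the frame whose center sits at t + delta
  shifted <- tt + cfg$firing_lead_s + cfg$maze$video_dt / 2
  idx <- findInterval(shifted, truth$time_s)
  acc <- ifelse(idx >= 1 & idx <= nrow(truth), truth$accel[pmax(idx, 1)], 0)
  b * gain + cfg$accel_coupling * pmax(acc, 0)
}

#' Draw inhomogeneous-Poisson spikes for one unit by thinning
#'
#' Samples an inhomogeneous Poisson process with the generator intensity
#' (see [sim_config()]) by thinning a homogeneous process at the
#' configuration's intensity envelope.
#'
#' @param cfg [sim_config()].
#' @param crossings Per-trial PD crossing times (from
#'   [generate_trajectory()]).
#' @param truth Frame-grid ground-truth kinematics (same source).
#' @param t_end Session end time, s.
#' @return Numeric vector of spike times (s), sorted.
#' @export
generate_spikes <- function(cfg, crossings, truth, t_end) {
  lam_max <- cfg$baseline_rate_hz *
    max(1, cfg$event_gain[["VC_ON_PD"]], cfg$event_gain[["RTN_PD"]]) +
    cfg$accel_coupling * max(0, truth$accel)
  if (!is.finite(lam_max))
    stop("generate_spikes: non-finite intensity envelope", call. = FALSE)
  if (lam_max <= 0) return(numeric(0))
  n_cand <- rpois(1, lam_max * t_end)
  tt <- unique(sort(runif(n_cand, 0, t_end)))
  n_cand <- length(tt)
  lam <- sim_intensity(tt, cfg, crossings, truth)
  if (any(lam > lam_max + 1e-9))
    stop("generate_spikes: intensity exceeds thinning envelope",
         call. = FALSE)
  tt[runif(n_cand) < lam / lam_max]
}

#' Simulate a 2 Hz opto-tagging stimulation block
#'
#' Laser pulses at 2 Hz (0.5 s spacing) with 100 ms duration; within-pulse
#' firing rate is `gain` times `baseline_rate_hz`, sampled by thinning.
#'
#' @param baseline_rate_hz Baseline rate, Hz.
#' @param gain Within-pulse rate multiplier.
#' @param n_pulses Number of pulses (>= 1).
#' @param t_start Time of the first pulse onset, s.
#' @param pulse_dur_s Pulse duration, s (default 0.1).
#' @return List with `spike_times`, `pulse_times`, `t_end`.
#' @export
simulate_opto_tagging <- function(baseline_rate_hz, gain, n_pulses,
                                  t_start = 0, pulse_dur_s = 0.1) {
  stopifnot(n_pulses >= 1)
  pulses <- t_start + (seq_len(n_pulses) - 1) * 0.5
  t_end <- pulses[n_pulses] + 0.5
  lam_max <- baseline_rate_hz * max(1, gain)
  n_cand <- rpois(1, lam_max * (t_end - t_start))
  tt <- unique(sort(runif(n_cand, t_start, t_end)))
  n_cand <- length(tt)
  in_pulse <- vapply(tt, function(x)
    any(x >= pulses & x < pulses + pulse_dur_s), logical(1))
  lam <- ifelse(in_pulse, baseline_rate_hz * gain, baseline_rate_hz)
  list(spike_times = tt[runif(n_cand) < lam / lam_max],
       pulse_times = pulses, t_end = t_end)
}

#' Simulate a complete session
#'
#' Composes the cue sequencer, behavior agent, trajectory generator and
#' spike synthesis into a fully validated [lc_session()]. All randomness
#' derives from `config$seed`, so the same configuration reproduces the
#' session exactly.
#'
#' @param config [sim_config()].
#' @return A validated [lc_session()] whose `meta` records the seed and
#'   generator parameters.
#' @examples
#' s <- simulate_session(sim_config(n_trials = 5, seed = 42))
#' s
#' @export
simulate_session <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "lc_sim_config"))
  set.seed(cfg$seed)
  cues <- generate_cue_sequence(cfg$n_trials)
  beh <- simulate_behavior(cues, cfg$agent, cfg$policy)
  traj <- generate_trajectory(beh$trials$chosen_side, cfg$maze, cfg$kin)
  cr <- traj$crossings
  n <- cfg$n_trials
  ev_list <- list(
    data.frame(time_s = 0, kind = "RULE_CHANGE", side = NA_character_,
               payload = cfg$policy$initial_rule, stringsAsFactors = FALSE),
    data.frame(time_s = cr$vc_on_time, kind = "VC_ON_PD",
               side = beh$trials$cue_side, payload = "",
               stringsAsFactors = FALSE),
    data.frame(time_s = cr$rwd_pd_time, kind = "RWD_PD",
               side = beh$trials$chosen_side, payload = "",
               stringsAsFactors = FALSE),
    data.frame(time_s = cr$rtn_pd_time, kind = "RTN_PD",
               side = beh$trials$chosen_side, payload = "",
               stringsAsFactors = FALSE))
  if (any(beh$trials$rewarded))
    ev_list <- c(ev_list, list(
      data.frame(time_s = cr$rwd_pd_time[beh$trials$rewarded] + 0.01,
                 kind = "REWARD",
                 side = beh$trials$chosen_side[beh$trials$rewarded],
                 payload = "", stringsAsFactors = FALSE)))
  rules_after <- vapply(beh$rule_change_trials, function(r)
    beh$trials$rule[r], character(1))
  if (length(beh$rule_change_trials))
    ev_list <- c(ev_list, list(
      data.frame(time_s = cr$vc_on_time[beh$rule_change_trials] - 1e-3,
                 kind = "RULE_CHANGE", side = NA_character_,
                 payload = rules_after, stringsAsFactors = FALSE)))
  if (length(beh$strategy_change_trials))
    ev_list <- c(ev_list, list(
      data.frame(time_s = cr$vc_on_time[beh$strategy_change_trials] - 1e-3,
                 kind = "STRATEGY_CHANGE", side = NA_character_,
                 payload = "", stringsAsFactors = FALSE)))
  t_end <- max(traj$tracking$time_s)
  spikes <- vector("list", cfg$n_units)
  for (u in seq_len(cfg$n_units)) {
    st <- generate_spikes(cfg, cr, traj$truth, t_end)
    spikes[[u]] <- spike_train(sprintf("u%02d", u), st, cfg$waveform_ms)
    spikes[[u]]$opto_status <- "untested"
  }
  if (!is.null(cfg$opto)) {
    tag <- simulate_opto_tagging(cfg$baseline_rate_hz, cfg$opto$gain,
                                 cfg$opto$n_pulses, t_start = t_end + 5)
    ev_list <- c(ev_list, list(
      data.frame(time_s = tag$pulse_times, kind = "LASER_PULSE",
                 side = NA_character_, payload = "",
                 stringsAsFactors = FALSE)))
    st1 <- spikes[[1]]
    merged <- sort(c(st1$times, tag$spike_times))
    spikes[[1]] <- spike_train(st1$unit_id, merged, st1$waveform_ms)
    spikes[[1]]$opto_status <- "entrained"
  }
  events <- task_events(
    time_s = unlist(lapply(ev_list, `[[`, "time_s")),
    kind = unlist(lapply(ev_list, `[[`, "kind")),
    side = unlist(lapply(ev_list, `[[`, "side")),
    payload = unlist(lapply(ev_list, `[[`, "payload")))
  trials <- build_trials(events)
  meta <- list(rat_id = "synthetic", seed = cfg$seed,
               turn_side = cfg$policy$turn_side,
               sim_config = list(
                 n_trials = cfg$n_trials,
                 baseline_rate_hz = cfg$baseline_rate_hz,
                 event_gain = as.list(cfg$event_gain),
                 reward_suppression = cfg$reward_suppression,
                 accel_coupling = cfg$accel_coupling,
                 firing_lead_s = cfg$firing_lead_s))
  lc_session(maze = cfg$maze, spikes = spikes, tracking = traj$tracking,
             events = events, trials = trials, blocks = beh$blocks,
             meta = meta)
}
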