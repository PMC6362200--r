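#' @importFrom stats aggregate coef cor cor.test lm p.adjust pt quantile
#'   rbinom rexp rnorm rpois runif sd t.test var wilcox.test setNames
#' @importFrom utils read.csv head tail
NULL

EVENT_KINDS <- c("VC_ON_PD", "RWD_PD", "RTN_PD", "REWARD",
                 "RULE_CHANGE", "STRATEGY_CHANGE", "LASER_PULSE")
SIDES <- c("L", "R")
RULES <- c("VC", "TURN")

#' Construct a spike train
#'
#' @param unit_id Unit identifier (coerced to character).
#' @param times Strictly increasing, non-negative spike timestamps (s,
#'   session clock).
#' @param waveform_ms Mean spike waveform duration (ms), used by the
#'   LC quality-control duration filter; `NA` if unknown.
#' @return An object of class `lc_spike_train`.
#' @export
spike_train <- function(unit_id, times, waveform_ms = NA_real_) {
  times <- as.numeric(times)
  if (length(times) && (any(!is.finite(times)) || any(times < 0)))
    stop("spike_train: times must be finite and non-negative", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike_train: times must be strictly increasing", call. = FALSE)
  structure(list(unit_id = as.character(unit_id), times = times,
                 waveform_ms = as.numeric(waveform_ms)),
            class = "lc_spike_train")
}

#' @export
print.lc_spike_train <- function(x, ...) {
  cat(sprintf("Spike train '%s': %d spikes", x$unit_id, length(x$times)))
  if (length(x$times))
    cat(sprintf(" over [%.2f, %.2f] s, mean rate %.2f Hz",
                min(x$times), max(x$times),
                length(x$times) / max(diff(range(x$times)), 1e-9)))
  cat(sprintf("; waveform %.2f ms\n", x$waveform_ms))
  invisible(x)
}

#' Construct a task-event table
#'
#' Events are the timestamped outputs of the maze controller: photodetector
#' crossings (`VC_ON_PD`, `RWD_PD`, `RTN_PD`), reward deliveries, rule and
#' strategy changes, and laser pulses.
#'
#' @param time_s Event times (s).
#' @param kind Event kinds, from the closed set of maze event types.
#' @param side `"L"`/`"R"` for arm-specific events, `NA` otherwise.
#' @param payload Free-text payload (rule name for `RULE_CHANGE`).
#' @return A `data.frame` with columns `time_s`, `kind`, `side`, `payload`,
#'   sorted by time.
#' @export
task_events <- function(time_s, kind, side = NA_character_,
                        payload = "") {
  n <- length(time_s)
  ev <- data.frame(time_s = as.numeric(time_s),
                   kind = as.character(kind),
                   side = rep_len(as.character(side), n),
                   payload = rep_len(as.character(payload), n),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(ev$kind), EVENT_KINDS)
  if (length(bad))
    stop("task_events: unknown event kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  oks <- is.na(ev$side) | ev$side %in% SIDES
  if (!all(oks))
    stop("task_events: side must be 'L', 'R' or NA", call. = FALSE)
  ev[order(ev$time_s), , drop = FALSE]
}

#' Assemble a recording session
#'
#' Bundles all components of one (recorded or synthetic) session and
#' validates their mutual consistency: every trial's three photodetector
#' times must exist in the event table, blocks must tile the trials, and
#' rewarded flags must be consistent with the rule in force.
#'
#' @param maze An [maze_config()] object.
#' @param spikes A list of [spike_train()] objects.
#' @param tracking `data.frame` with `time_s`, `x_cm`, `y_cm` (head-LED
#'   tracking at ~30 Hz); may have zero rows.
#' @param events Event table from [task_events()].
#' @param trials Trial table, usually from [build_trials()].
#' @param blocks Block table (`start_trial`, `end_trial`, `label`), or
#'   `NULL` to derive a single all-trials block.
#' @param meta Named list of provenance (rat id, generator config, seed).
#' @return An object of class `lc_session`.
#' @seealso [build_trials()], [read_session()], [simulate_session()]
#' @export
lc_session <- function(maze, spikes, tracking, events, trials,
                       blocks = NULL, meta = list()) {
  if (inherits(spikes, "lc_spike_train")) spikes <- list(spikes)
  if (is.null(blocks)) {
    blocks <- if (nrow(trials)) {
      data.frame(start_trial = 1L, end_trial = nrow(trials),
                 label = "all", stringsAsFactors = FALSE)
    } else {
      data.frame(start_trial = integer(), end_trial = integer(),
                 label = character(), stringsAsFactors = FALSE)
    }
  }
  s <- structure(list(maze = maze, spikes = spikes, tracking = tracking,
                      events = events, trials = trials, blocks = blocks,
                      meta = meta),
                 class = "lc_session")
  validate_session(s)
  s
}

#' Validate a session's invariants
#'
#' @param session An `lc_session`.
#' @return The session, invisibly; stops with an informative error naming
#'   the offending trial/event on violation.
#' @export
validate_session <- function(session) {
  s <- session
  stopifnot(inherits(s, "lc_session"))
  validate_maze_config(s$maze)
  for (tr in s$spikes) {
    if (!inherits(tr, "lc_spike_train"))
      stop("session: spikes must be lc_spike_train objects", call. = FALSE)
    if (length(tr$times) > 1 && any(diff(tr$times) <= 0))
      stop("session: spike times not strictly increasing for unit ",
           tr$unit_id, call. = FALSE)
  }
  if (!all(c("time_s", "x_cm", "y_cm") %in% names(s$tracking)))
    stop("session: tracking needs columns time_s, x_cm, y_cm", call. = FALSE)
  if (nrow(s$tracking) > 1 && any(diff(s$tracking$time_s) <= 0))
    stop("session: tracking times not strictly increasing", call. = FALSE)
  tr <- s$trials
  if (nrow(tr)) {
    bad <- which(!(tr$vc_on_time < tr$rwd_pd_time &
                     tr$rwd_pd_time < tr$rtn_pd_time))
    if (length(bad))
      stop("session: trial ", bad[1],
           " violates vc_on_time < rwd_pd_time < rtn_pd_time", call. = FALSE)
    evt <- s$events$time_s
    for (col in c("vc_on_time", "rwd_pd_time", "rtn_pd_time")) {
      miss <- which(!sapply(tr[[col]], function(t)
        any(abs(evt - t) < 1e-9)))
      if (length(miss))
        stop("session: trial ", miss[1], " ", col,
             " has no matching event", call. = FALSE)
    }
    exp_rwd <- rewarded_under_rule(tr$rule_in_force, tr$cue_side,
                                   tr$chosen_side,
                                   turn_side = s$meta$turn_side %||% "R")
    bad <- which(tr$rewarded != exp_rwd)
    if (length(bad))
      stop("session: trial ", bad[1],
           " rewarded flag inconsistent with rule/cue/choice", call. = FALSE)
    bl <- s$blocks[order(s$blocks$start_trial), , drop = FALSE]
    covered <- unlist(Map(seq.int, bl$start_trial, bl$end_trial))
    if (!identical(sort(covered), seq_len(nrow(tr))))
      stop("session: blocks must contiguously tile trials 1..n",
           call. = FALSE)
  }
  invisible(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reward contingency oracle: VC rule rewards choosing the lit side; the
# Turn rule rewards the fixed (non-preferred) side regardless of the cue.
rewarded_under_rule <- function(rule, cue_side, chosen_side,
                                turn_side = "R") {
  ifelse(rule == "VC", chosen_side == cue_side, chosen_side == turn_side)
}

#' @export
print.lc_session <- function(x, ...) {
  cat("LC T-maze session\n")
  cat(sprintf("  %d unit(s), %d trial(s), %d block(s), %d event(s)\n",
              length(x$spikes), nrow(x$trials), nrow(x$blocks),
              nrow(x$events)))
  if (nrow(x$tracking))
    cat(sprintf("  tracking: %d frames over %.1f s\n", nrow(x$tracking),
                diff(range(x$tracking$time_s))))
  if (length(x$meta$rat_id)) cat("  rat:", x$meta$rat_id, "\n")
  if (length(x$meta$seed)) cat("  synthetic, seed", x$meta$seed, "\n")
  invisible(x)
}

#' @export
summary.lc_session <- function(object, ...) {
  x <- object
  print(x)
  if (nrow(x$trials)) {
    cat(sprintf("  rewarded: %d/%d trials (%.0f%%)\n",
                sum(x$trials$rewarded), nrow(x$trials),
                100 * mean(x$trials$rewarded)))
    rc <- x$events[x$events$kind == "RULE_CHANGE" & x$events$time_s > 0, ]
    cat(sprintf("  rule changes (excluding initial rule): %d\n", nrow(rc)))
  }
  for (tr in x$spikes) print(tr)
  invisible(x)
}

#' Build the trial table from the event log
#'
#' One trial is constructed per `VC_ON_PD` event that is followed by a
#' `RWD_PD` and then a `RTN_PD` before the next `VC_ON_PD`. A trial is
#' rewarded iff a `REWARD` event falls between its reward-PD and return-PD
#' crossings. The rule in force is the most recent `RULE_CHANGE` payload at
#' VC onset. Malformed triples (out-of-order, or a backtrack producing a
#' second `VC_ON_PD` before `RWD_PD`) are excluded with a warning.
#'
#' @param events Event table ([task_events()]), time-ordered.
#' @return Trial `data.frame` with columns `index`, `vc_on_time`,
#'   `cue_side`, `chosen_side`, `rwd_pd_time`, `rtn_pd_time`, `rewarded`,
#'   `rule_in_force`.
#' @export
build_trials <- function(events) {
  ev <- events[order(events$time_s), , drop = FALSE]
  vc <- ev[ev$kind == "VC_ON_PD", , drop = FALSE]
  out <- vector("list", nrow(vc))
  n_bad <- 0L
  for (i in seq_len(nrow(vc))) {
    t0 <- vc$time_s[i]
    t_next <- if (i < nrow(vc)) vc$time_s[i + 1] else Inf
    win <- ev[ev$time_s > t0 & ev$time_s < t_next, , drop = FALSE]
    rwd <- win[win$kind == "RWD_PD", , drop = FALSE]
    rtn <- win[win$kind == "RTN_PD", , drop = FALSE]
    if (!nrow(rwd) || !nrow(rtn) || rtn$time_s[1] <= rwd$time_s[1]) {
      n_bad <- n_bad + 1L
      next
    }
    t_rwd <- rwd$time_s[1]; t_rtn <- rtn$time_s[1]
    got_reward <- any(win$kind == "REWARD" &
                        win$time_s >= t_rwd & win$time_s <= t_rtn)
    rc <- ev[ev$kind == "RULE_CHANGE" & ev$time_s <= t0, , drop = FALSE]
    rule <- if (nrow(rc)) rc$payload[nrow(rc)] else "VC"
    out[[i]] <- data.frame(
      vc_on_time = t0, cue_side = vc$side[i],
      chosen_side = rwd$side[1], rwd_pd_time = t_rwd, rtn_pd_time = t_rtn,
      rewarded = got_reward, rule_in_force = rule,
      stringsAsFactors = FALSE)
  }
  if (n_bad)
    warning(sprintf("build_trials: %d malformed trial(s) excluded", n_bad),
            call. = FALSE)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(index = integer(), vc_on_time = numeric(),
                      cue_side = character(), chosen_side = character(),
                      rwd_pd_time = numeric(), rtn_pd_time = numeric(),
                      rewarded = logical(), rule_in_force = character(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, out)
  tab <- cbind(index = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Filter units by spike waveform duration
#'
#' LC units are required to have broad spikes; trains whose mean waveform
#' duration is below the threshold are rejected. Units with a missing
#' duration are retained and flagged with a warning.
#'
#' @param spikes List of [spike_train()] objects.
#' @param min_ms Minimum waveform duration (ms); the threshold itself is
#'   retained (inclusive).
#' @return Filtered list of spike trains.
#' @export
filter_units_by_duration <- function(spikes, min_ms = 0.6) {
  if (!length(spikes)) return(spikes)
  keep <- vapply(spikes, function(tr) {
    if (is.na(tr$waveform_ms)) {
      warning("filter_units_by_duration: unit ", tr$unit_id,
              " has no waveform duration; retained and flagged",
              call. = FALSE)
      return(TRUE)
    }
    tr$waveform_ms >= min_ms
  }, logical(1))
  spikes[keep]
}

#' Classify a unit as opto-entrained (noradrenergic)
#'
#' A unit is classified as a noradrenergic LC unit if its mean firing rate
#' within laser pulse windows, averaged over all pulses, is at least twice
#' its baseline rate (boundary inclusive).
#'
#' @param train A [spike_train()].
#' @param pulse_times Laser pulse onset times (s); at least 10 pulses.
#' @param pulse_dur_ms Pulse duration (ms), default 100.
#' @param baseline_window Length-2 numeric `[a, b)` (s) disjoint from the
#'   stimulation period, used for the baseline rate.
#' @return List with `entrained` (logical, or `NA` if unclassifiable),
#'   `status` (`"ok"` or `"unclassifiable"`), `pulse_rate_hz`,
#'   `baseline_rate_hz`.
#' @export
classify_opto_unit <- function(train, pulse_times, pulse_dur_ms = 100,
                               baseline_window) {
  if (length(pulse_times) < 10)
    stop("classify_opto_unit: need at least 10 pulses", call. = FALSE)
  dur <- pulse_dur_ms / 1000
  if (any(pulse_times + dur > baseline_window[1] &
            pulse_times < baseline_window[2]))
    stop("classify_opto_unit: baseline window overlaps stimulation",
         call. = FALSE)
  st <- train$times
  n_in <- sum(vapply(pulse_times, function(p)
    sum(st >= p & st < p + dur), numeric(1)))
  pulse_rate <- n_in / (length(pulse_times) * dur)
  bw <- baseline_window
  base_rate <- sum(st >= bw[1] & st < bw[2]) / (bw[2] - bw[1])
  if (base_rate <= 0) {
    return(list(entrained = NA, status = "unclassifiable",
                pulse_rate_hz = pulse_rate, baseline_rate_hz = 0))
  }
  list(entrained = pulse_rate >= 2 * base_rate, status = "ok",
       pulse_rate_hz = pulse_rate, baseline_rate_hz = base_rate)
}
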