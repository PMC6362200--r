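# Firing-rate / acceleration coupling: paired event-window and
# outside-event bins, regressions on positive accelerations, the 20 ms-step
# lag scan, and percentile-threshold onset detection with onset-triggered
# cross-correlograms.

anchor_times_for_kind <- function(session, kind) {
  tr <- session$trials
  switch(kind,
         VC_ON_PD = tr$vc_on_time,
         RWD_PD = tr$rwd_pd_time,
         RTN_PD = tr$rtn_pd_time,
         stop("unknown anchor kind: ", kind, call. = FALSE))
}

# Precomputed lookup structures for fast paired-bin construction. The
# firing rate is a Gaussian-smoothed instantaneous-rate series (spike
# counts on a fine grid converted to Hz and smoothed with the kinematics
# kernel); sampling bins then average that series, so bins are
# continuous-valued rather than sparse raw counts. Windowed means of both
# series use cumulative sums over the sorted sample grids.
paired_env <- function(st, kin, rate_bin = 0.05, rate_kernel_sd = 0.1) {
  t0 <- min(kin$time_s); t1 <- max(kin$time_s)
  edges <- seq(t0, t1, by = rate_bin)
  cnt <- tabulate(findInterval(st[st >= t0 & st < max(edges)], edges),
                  nbins = length(edges) - 1)
  rate <- gaussian_smooth(cnt / rate_bin, rate_kernel_sd, rate_bin)
  rt <- edges[-length(edges)] + rate_bin / 2
  ok <- !is.na(kin$accel)
  rok <- !is.na(rate)
  list(st = st, rt = rt,
       cs_rate = c(0, cumsum(ifelse(rok, rate, 0))),
       cs_rn = c(0, cumsum(as.numeric(rok))),
       kt = kin$time_s,
       cs_val = c(0, cumsum(ifelse(ok, kin$accel, 0))),
       cs_n = c(0, cumsum(as.numeric(ok))))
}

# count of values in `sorted` that are < x, vectorized over x
n_less_than <- function(x, sorted) findInterval(x, sorted, left.open = TRUE)

# windowed means over a cumsum pair, NA when no samples fall in [lo, hi)
cs_mean <- function(lo, hi, tt, cs_v, cs_n) {
  j1 <- n_less_than(lo, tt)
  j2 <- n_less_than(hi, tt)
  nk <- cs_n[j2 + 1] - cs_n[j1 + 1]
  sv <- cs_v[j2 + 1] - cs_v[j1 + 1]
  ifelse(nk > 0, sv / pmax(nk, 1), NA_real_)
}

# Paired (rate, accel) bins around anchors; accel windows can be displaced
# by `accel_shift` (s) relative to the rate bins (used by the lag scan).
# Each bin carries two rate estimates: `rate`, the raw spike count over the
# bin width (independent across bins, used by the regressions), and
# `rate_smooth`, the bin mean of the smoothed instantaneous-rate series
# (used by the lag scan and by the 0.1 Hz exclusion, which removes
# genuinely silent stretches rather than every zero-count bin).
paired_bins_raw <- function(env, anchors, window, width, accel_shift = 0,
                            min_rate_hz = 0.1,
                            exclude_on = c("raw", "smooth")) {
  exclude_on <- match.arg(exclude_on)
  nb <- round((window[2] - window[1]) / width)
  starts <- window[1] + (seq_len(nb) - 1) * width
  lo <- rep(anchors, each = nb) + starts
  hi <- lo + width
  cnt <- n_less_than(hi, env$st) - n_less_than(lo, env$st)
  rate_smooth <- cs_mean(lo, hi, env$rt, env$cs_rate, env$cs_rn)
  amean <- cs_mean(lo + accel_shift, hi + accel_shift, env$kt,
                   env$cs_val, env$cs_n)
  pb <- data.frame(anchor_index = rep(seq_along(anchors), each = nb),
                   t_bin = lo, bin_start = rep(starts, length(anchors)),
                   rate = cnt / width, rate_smooth = rate_smooth,
                   accel = amean)
  keep_rate <- if (exclude_on == "raw") pb$rate else pb$rate_smooth
  pb[!is.na(keep_rate) & keep_rate >= min_rate_hz & !is.na(pb$accel), ,
     drop = FALSE]
}

#' Collect paired firing-rate / acceleration bins around task events
#'
#' 200 ms bins spanning `[-1, 1)` s around every anchor of the requested
#' kind: per-bin raw firing rate (spike count over the bin width), the
#' bin mean of the Gaussian-smoothed instantaneous-rate series, and the
#' per-bin mean acceleration. Bins with firing rates below 0.1 Hz -- i.e.
#' zero-spike bins -- are removed, and z-scored copies are computed per
#' unit-session over the surviving bins (before any pooling across
#' sessions).
#'
#' @param session An [lc_session()].
#' @param kind Anchor kind: `"VC_ON_PD"`, `"RWD_PD"` or `"RTN_PD"`.
#' @param unit Unit index.
#' @param kin Session kinematics ([session_kinematics()]); computed if
#'   `NULL`.
#' @param window,width Bin grid around each anchor, s.
#' @return An `lc_paired_bins` data.frame: `anchor_index`, `t_bin`,
#'   `bin_start`, `rate`, `accel`, `zrate`, `zaccel`.
#' @export
collect_event_bins <- function(session, kind = "VC_ON_PD", unit = 1,
                               kin = NULL, window = c(-1, 1), width = 0.2) {
  anchors <- anchor_times_for_kind(session, kind)
  if (!length(anchors)) stop("collect_event_bins: no anchors", call. = FALSE)
  if (is.null(kin)) kin <- session_kinematics(session)
  env <- paired_env(session$spikes[[unit]]$times, kin)
  pb <- paired_bins_raw(env, anchors, window, width, exclude_on = "raw")
  add_zscores(pb, kind)
}

add_zscores <- function(pb, scope) {
  if (nrow(pb) >= 2 && sd(pb$rate) > 0 && sd(pb$accel) > 0) {
    pb$zrate <- zscore(pb$rate)
    pb$zaccel <- zscore(pb$accel)
  } else {
    pb$zrate <- rep(NA_real_, nrow(pb))
    pb$zaccel <- rep(NA_real_, nrow(pb))
  }
  attr(pb, "scope") <- scope
  class(pb) <- c("lc_paired_bins", "data.frame")
  pb
}

#' Collect paired bins outside all task-event windows
#'
#' 100 ms bins over the session excluding +/- 1 s around every VC-onset
#' and return-arm PD crossing and +/- 0.5 s around every reward-arm PD
#' crossing (each bin must lie wholly outside every exclusion window).
#' Bins with firing rates below 0.1 Hz (no spikes) are removed, then the
#' surviving
#' bins are down-sampled uniformly at random (without replacement) to
#' `match_n` to match the event-window sample size.
#'
#' @param session An [lc_session()].
#' @param match_n Target number of bins after down-sampling.
#' @param unit Unit index.
#' @param kin Session kinematics; computed if `NULL`.
#' @param width Bin width, s (default 0.1).
#' @return An `lc_paired_bins` data.frame (scope `"OUTSIDE"`).
#' @export
collect_outside_bins <- function(session, match_n, unit = 1, kin = NULL,
                                 width = 0.1) {
  if (is.null(kin)) kin <- session_kinematics(session)
  tr <- session$trials
  excl <- rbind(cbind(tr$vc_on_time - 1, tr$vc_on_time + 1),
                cbind(tr$rtn_pd_time - 1, tr$rtn_pd_time + 1),
                cbind(tr$rwd_pd_time - 0.5, tr$rwd_pd_time + 0.5))
  t0 <- min(session$tracking$time_s)
  t1 <- max(session$tracking$time_s)
  starts <- seq(t0, t1 - width, by = width)
  keep <- rep(TRUE, length(starts))
  for (i in seq_len(nrow(excl)))
    keep <- keep & (starts + width <= excl[i, 1] | starts >= excl[i, 2])
  starts <- starts[keep]
  if (!length(starts))
    stop("collect_outside_bins: no time outside exclusion windows",
         call. = FALSE)
  env <- paired_env(session$spikes[[unit]]$times, kin)
  cnt <- n_less_than(starts + width, env$st) - n_less_than(starts, env$st)
  rate_smooth <- cs_mean(starts, starts + width, env$rt, env$cs_rate,
                         env$cs_rn)
  amean <- cs_mean(starts, starts + width, env$kt, env$cs_val, env$cs_n)
  pb <- data.frame(anchor_index = NA_integer_, t_bin = starts,
                   bin_start = starts, rate = cnt / width,
                   rate_smooth = rate_smooth, accel = amean)
  pb <- pb[!is.na(pb$rate) & pb$rate >= 0.1 & !is.na(pb$accel), ,
           drop = FALSE]
  if (nrow(pb) > match_n) {
    pb <- pb[sort(sample.int(nrow(pb), match_n)), , drop = FALSE]
  } else if (nrow(pb) < match_n) {
    warning(sprintf(
      "collect_outside_bins: only %d bins survive (requested %d); using all",
      nrow(pb), match_n), call. = FALSE)
  }
  add_zscores(pb, "OUTSIDE")
}

#' Regress firing rate on acceleration over paired bins
#'
#' Ordinary least squares of z-scored rate on z-scored acceleration,
#' restricted (by default) to bins with positive raw acceleration.
#'
#' @param bins An `lc_paired_bins` data.frame.
#' @param positive_only Keep only bins with raw `accel > 0`.
#' @return List: `slope`, `r`, `p` (two-sided, slope), `n`, `scope`.
#' @export
regress_rate_on_accel <- function(bins, positive_only = TRUE) {
  b <- bins
  if (positive_only) b <- b[b$accel > 0, , drop = FALSE]
  if (nrow(b) < 3)
    stop("regress_rate_on_accel: need n >= 3 after filtering",
         call. = FALSE)
  if (sd(b$zrate) == 0 || sd(b$zaccel) == 0 ||
        any(is.na(b$zrate)) || any(is.na(b$zaccel)))
    stop("regress_rate_on_accel: degenerate variance", call. = FALSE)
  fit <- summary(lm(zrate ~ zaccel, data = b))
  list(slope = fit$coefficients[2, 1],
       r = cor(b$zaccel, b$zrate),
       p = fit$coefficients[2, 4],
       n = nrow(b),
       scope = attr(bins, "scope") %||% "unknown")
}

#' Scan firing/acceleration correlation over time shifts
#'
#' Displaces the acceleration series relative to the firing-rate bins in
#' 20 ms steps over +/- 1 s, rebuilding the paired bins at each shift, and
#' reports the shift maximizing the Pearson correlation. Positive shifts
#' mean firing precedes acceleration. Ties break toward the smallest
#' absolute shift.
#'
#' @param session An [lc_session()].
#' @param kind Anchor kind (as [collect_event_bins()]).
#' @param unit Unit index.
#' @param kin Session kinematics; computed if `NULL`.
#' @param step Shift step, s (default 0.02).
#' @param span Maximum |shift|, s (default 1).
#' @param window,width Rate-bin grid around anchors.
#' @param positive_only Restrict to positive-acceleration bins at each
#'   shift, as the regressions do. Default `FALSE`: the scan correlates
#'   the full paired series, since a shift-dependent selection on the
#'   displaced acceleration adds argmax noise.
#' @return An `lc_lag_scan`: data.frame `scan` (`shift_ms`, `r`, `n`), and
#'   `best_shift_ms`.
#' @export
lag_scan <- function(session, kind = "VC_ON_PD", unit = 1, kin = NULL,
                     step = 0.02, span = 1, window = c(-1, 1),
                     width = 0.2, positive_only = FALSE) {
  anchors <- anchor_times_for_kind(session, kind)
  if (is.null(kin)) kin <- session_kinematics(session)
  env <- paired_env(session$spikes[[unit]]$times, kin)
  shifts <- seq(-span, span, by = step)
  rs <- rep(NA_real_, length(shifts))
  ns <- integer(length(shifts))
  for (i in seq_along(shifts)) {
    pb <- paired_bins_raw(env, anchors, window, width,
                          accel_shift = shifts[i], exclude_on = "smooth")
    if (positive_only) pb <- pb[pb$accel > 0, , drop = FALSE]
    ns[i] <- nrow(pb)
    if (nrow(pb) >= 3 && sd(pb$rate_smooth) > 0 && sd(pb$accel) > 0)
      rs[i] <- cor(pb$rate_smooth, pb$accel)
  }
  if (all(is.na(rs)))
    stop("lag_scan: degenerate data at every shift", call. = FALSE)
  best_r <- max(rs, na.rm = TRUE)
  cand <- which(!is.na(rs) & abs(rs - best_r) < 1e-12)
  best <- cand[which.min(abs(shifts[cand]))]
  structure(list(scan = data.frame(shift_ms = shifts * 1000, r = rs,
                                   n = ns),
                 best_shift_ms = shifts[best] * 1000,
                 best_r = rs[best], kind = kind),
            class = "lc_lag_scan")
}

#' @export
print.lc_lag_scan <- function(x, ...) {
  cat(sprintf("Lag scan (%s): best shift %+g ms (r = %.3f)\n",
              x$kind, x$best_shift_ms, x$best_r))
  cat("  positive shift = firing precedes acceleration\n")
  invisible(x)
}

#' @export
plot.lc_lag_scan <- function(x, ...) {
  graphics::plot(x$scan$shift_ms, x$scan$r, type = "l",
                 xlab = "acceleration shift (ms)",
                 ylab = "Pearson r",
                 main = sprintf("Firing/acceleration lag scan (%s)",
                                x$kind), ...)
  graphics::abline(v = x$best_shift_ms, lty = 2)
  invisible(x)
}

# Upward threshold crossings with hysteresis: after an onset, no new onset
# until the series falls back below the threshold.
threshold_onsets <- function(times, values, threshold) {
  ok <- !is.na(values)
  t <- times[ok]; v <- values[ok]
  if (length(v) < 2) return(numeric(0))
  above <- v > threshold
  onset_idx <- which(!above[-length(above)] & above[-1]) + 1
  # linear interpolation of the crossing instant
  vapply(onset_idx, function(i) {
    dv <- v[i] - v[i - 1]
    if (dv <= 0) return(t[i])
    t[i - 1] + (threshold - v[i - 1]) / dv * (t[i] - t[i - 1])
  }, numeric(1))
}

#' Detect onsets of firing-rate increases
#'
#' Estimates an instantaneous firing rate on a 50 ms grid (counts
#' converted to Hz, Gaussian-smoothed with the kinematics kernel), takes
#' the 95th percentile of that session-wide rate distribution as the
#' onset threshold, and returns the upward threshold crossings (with
#' hysteresis). Sessions whose threshold is at or below `exclude_le_hz`
#' (4 Hz, the level a single spike can reach in this rate estimate) are
#' marked excluded.
#'
#' @param spike_times Spike timestamps, s.
#' @param t_range Session time range `c(t0, t1)`, s.
#' @param bin Rate-grid bin width, s (default 0.05).
#' @param kernel_sd Gaussian kernel SD, s (default 0.1, the kinematics
#'   smoothing kernel).
#' @param percentile Threshold percentile (default 0.95).
#' @param exclude_le_hz Exclusion level for the threshold, Hz.
#' @return An `lc_onsets`: `onsets` (s), `threshold_hz`, `excluded`,
#'   `percentile`, `kind = "firing"`.
#' @export
detect_firing_onsets <- function(spike_times, t_range, bin = 0.05,
                                 kernel_sd = 0.1, percentile = 0.95,
                                 exclude_le_hz = 4) {
  edges <- seq(t_range[1], t_range[2], by = bin)
  if (length(edges) < 3) stop("detect_firing_onsets: range too short",
                              call. = FALSE)
  cnt <- tabulate(findInterval(
    spike_times[spike_times >= t_range[1] & spike_times < max(edges)],
    edges), nbins = length(edges) - 1)
  rate <- gaussian_smooth(cnt / bin, kernel_sd, bin)
  tt <- edges[-length(edges)] + bin / 2
  thr <- unname(quantile(rate, percentile, na.rm = TRUE, names = FALSE))
  structure(list(onsets = threshold_onsets(tt, rate, thr),
                 threshold_hz = thr, excluded = thr <= exclude_le_hz,
                 percentile = percentile, kind = "firing",
                 rate_times = tt, rate_hz = rate),
            class = "lc_onsets")
}

#' Detect onsets of acceleration increases
#'
#' Upward crossings of the 97.5th percentile of the session-wide
#' acceleration distribution (same crossing logic as firing onsets).
#'
#' @param kin Session kinematics ([session_kinematics()]).
#' @param percentile Threshold percentile (default 0.975).
#' @return An `lc_onsets` with `kind = "accel"`.
#' @export
detect_accel_onsets <- function(kin, percentile = 0.975) {
  acc <- kin$accel
  thr <- unname(quantile(acc, percentile, na.rm = TRUE, names = FALSE))
  structure(list(onsets = threshold_onsets(kin$time_s, acc, thr),
                 threshold = thr, excluded = FALSE,
                 percentile = percentile, kind = "accel"),
            class = "lc_onsets")
}

#' @export
print.lc_onsets <- function(x, ...) {
  thr <- if (x$kind == "firing") sprintf("%.2f Hz", x$threshold_hz)
  else sprintf("%.2f cm/s^2", x$threshold)
  cat(sprintf("%s onsets: %d crossings, threshold %s (%.3g percentile)%s\n",
              x$kind, length(x$onsets), thr, 100 * x$percentile,
              if (isTRUE(x$excluded)) " [session excluded]" else ""))
  invisible(x)
}

#' Onset-triggered cross-correlogram of acceleration vs. firing onsets
#'
#' For every firing-increase onset, collects all acceleration-increase
#' onsets within +/- `window` s; positive lags mean acceleration follows
#' firing. Optionally restricts firing onsets to +/- 1 s around the three
#' photodetector event kinds.
#'
#' @param firing_onsets,accel_onsets `lc_onsets` objects (or numeric
#'   vectors of onset times).
#' @param window Half-width of the lag window, s (default 0.5).
#' @param bin Histogram bin width, s (default 0.02).
#' @param scope `"session"` or `"events"`.
#' @param session Required for `scope = "events"` (provides PD times).
#' @return An `lc_onset_xcorr`: `lags_ms`, histogram (`breaks_ms`,
#'   `counts`), `mean_lag_ms`, `n_pairs`, `empty` flag.
#' @export
onset_lag_crosscorr <- function(firing_onsets, accel_onsets, window = 0.5,
                                bin = 0.02, scope = c("session", "events"),
                                session = NULL) {
  scope <- match.arg(scope)
  f <- if (inherits(firing_onsets, "lc_onsets")) firing_onsets$onsets
  else firing_onsets
  a <- if (inherits(accel_onsets, "lc_onsets")) accel_onsets$onsets
  else accel_onsets
  if (!length(f) || !length(a))
    stop("onset_lag_crosscorr: need >= 1 onset of each type", call. = FALSE)
  if (scope == "events") {
    if (is.null(session))
      stop("onset_lag_crosscorr: scope='events' needs the session",
           call. = FALSE)
    tr <- session$trials
    ev <- c(tr$vc_on_time, tr$rwd_pd_time, tr$rtn_pd_time)
    near <- vapply(f, function(x) any(abs(x - ev) <= 1), logical(1))
    f <- f[near]
  }
  lags <- unlist(lapply(f, function(x) {
    d <- a - x
    d[abs(d) <= window]
  }))
  breaks <- seq(-window, window, by = bin)
  if (!length(lags)) {
    return(structure(list(lags_ms = numeric(0), breaks_ms = breaks * 1000,
                          counts = integer(length(breaks) - 1),
                          mean_lag_ms = NA_real_, n_pairs = 0L,
                          scope = scope, empty = TRUE),
                     class = "lc_onset_xcorr"))
  }
  h <- graphics::hist(lags, breaks = breaks, plot = FALSE)
  structure(list(lags_ms = lags * 1000, breaks_ms = breaks * 1000,
                 counts = h$counts, mean_lag_ms = mean(lags) * 1000,
                 n_pairs = length(lags), scope = scope, empty = FALSE),
            class = "lc_onset_xcorr")
}

#' @export
print.lc_onset_xcorr <- function(x, ...) {
  if (x$empty) {
    cat("Onset cross-correlogram: no onset pairs in window\n")
  } else {
    cat(sprintf(
      "Onset cross-correlogram (%s): mean lag %+.1f ms over %d pairs\n",
      x$scope, x$mean_lag_ms, x$n_pairs))
    cat("  positive lag = acceleration onset after firing onset\n")
  }
  invisible(x)
}

#' @export
plot.lc_onset_xcorr <- function(x, ...) {
  mids <- (head(x$breaks_ms, -1) + tail(x$breaks_ms, -1)) / 2
  graphics::barplot(x$counts, width = diff(x$breaks_ms)[1], space = 0,
                    col = "grey40", border = NA,
                    xlab = "acceleration onset lag (ms)", ylab = "count",
                    main = "Acceleration onsets relative to firing onsets",
                    ...)
  if (!x$empty)
    graphics::abline(v = (x$mean_lag_ms - x$breaks_ms[1]) /
                       diff(x$breaks_ms)[1], lty = 2)
  invisible(x)
}
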