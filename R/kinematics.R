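# Speed/acceleration from head-LED tracking, Gaussian smoothing, binning
# and z-score primitives shared by all firing/kinematics analyses.

#' Compute instantaneous speed from LED tracking
#'
#' Speed at sample *i* is the Euclidean distance from sample *i - 1*
#' divided by the elapsed time (backward difference, assigned to the later
#' timestamp). Samples separated by more than `max_gap` (default twice the
#' nominal video interval) are treated as gaps: the sample after a gap has
#' no speed and is masked invalid rather than interpolated.
#'
#' @param tracking `data.frame` with `time_s`, `x_cm`, `y_cm`.
#' @param video_dt Nominal sampling interval, s.
#' @param max_gap Largest inter-sample interval across which speed is
#'   still computed, s; default `2 * video_dt`.
#' @return An `lc_kinematics` data.frame: `time_s`, `speed` (cm/s),
#'   `accel` (NA until [compute_acceleration()]), `valid`.
#' @export
compute_speed <- function(tracking, video_dt = 0.033,
                          max_gap = 2 * video_dt) {
  n <- nrow(tracking)
  if (n < 2) {
    warning("compute_speed: fewer than 2 samples; empty result",
            call. = FALSE)
    return(structure(data.frame(time_s = numeric(), speed = numeric(),
                                accel = numeric(), valid = logical()),
                     class = c("lc_kinematics", "data.frame")))
  }
  dtv <- diff(tracking$time_s)
  dist <- sqrt(diff(tracking$x_cm)^2 + diff(tracking$y_cm)^2)
  speed <- dist / dtv
  valid <- dtv <= max_gap & dtv > 0
  speed[!valid] <- NA_real_
  structure(data.frame(time_s = tracking$time_s[-1], speed = speed,
                       accel = NA_real_, valid = valid),
            class = c("lc_kinematics", "data.frame"))
}

#' Gaussian-smooth a uniformly sampled series
#'
#' Discrete Gaussian convolution with the kernel truncated at +/- 3 SD and
#' renormalized at edges and around missing values, so a constant series
#' maps to itself. `NA` inputs stay `NA` and are excluded from their
#' neighbours' kernels.
#'
#' @param x Numeric series sampled at interval `dt`.
#' @param sd Kernel standard deviation, s.
#' @param dt Sampling interval, s.
#' @return Smoothed series, same length as `x`.
#' @export
gaussian_smooth <- function(x, sd, dt) {
  stopifnot(sd > 0, dt > 0)
  if (sd < dt) {
    warning("gaussian_smooth: sd below the sample interval; no-op",
            call. = FALSE)
    return(x)
  }
  h <- ceiling(3 * sd / dt)
  n <- length(x)
  w <- exp(-0.5 * ((-h:h) * dt / sd)^2)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  num <- as.numeric(stats::filter(x0, w, sides = 2))
  den <- as.numeric(stats::filter(as.numeric(ok), w, sides = 2))
  # stats::filter leaves NA at the edges; recompute there with the kernel
  # truncated to the available samples
  edge <- unique(c(seq_len(min(h, n)), seq(max(n - h + 1, 1), n)))
  for (i in edge) {
    j <- max(1, i - h):min(n, i + h)
    ww <- w[j - i + h + 1]
    num[i] <- sum(ww * x0[j])
    den[i] <- sum(ww * ok[j])
  }
  out <- num / den
  out[!ok] <- NA_real_
  out[is.nan(out) | is.infinite(out)] <- NA_real_
  out
}

#' Compute acceleration from a speed series
#'
#' Backward difference of (optionally smoothed) speed divided by the time
#' step, assigned to the later timestamp; masked across tracking gaps.
#'
#' @param kin An `lc_kinematics` data.frame from [compute_speed()].
#' @param smooth_sd Gaussian kernel SD (s) applied to speed before
#'   differencing; `0` disables smoothing.
#' @param video_dt Nominal sampling interval, s.
#' @return The input with `accel` filled and `valid` updated (acceleration
#'   requires two consecutive valid speed samples).
#' @export
compute_acceleration <- function(kin, smooth_sd = 0.1, video_dt = 0.033) {
  n <- nrow(kin)
  if (n < 2) return(kin)
  sp <- kin$speed
  if (smooth_sd > 0) sp <- gaussian_smooth(sp, smooth_sd, video_dt)
  dtv <- diff(kin$time_s)
  acc <- c(NA_real_, diff(sp) / dtv)
  acc[c(FALSE, dtv > 2 * video_dt)] <- NA_real_
  kin$accel <- acc
  kin$smoothed_speed <- sp
  kin$valid <- kin$valid & !is.na(acc)
  kin
}

#' Session kinematics in one call
#'
#' Convenience wrapper: [compute_speed()] then [compute_acceleration()]
#' using the session's video interval.
#'
#' @param session An [lc_session()].
#' @param smooth_sd Speed-smoothing kernel SD, s.
#' @return An `lc_kinematics` data.frame.
#' @export
session_kinematics <- function(session, smooth_sd = 0.1) {
  kin <- compute_speed(session$tracking, video_dt = session$maze$video_dt)
  compute_acceleration(kin, smooth_sd = smooth_sd,
                       video_dt = session$maze$video_dt)
}

#' Bin samples around an anchor into fixed-width means
#'
#' Half-open bins `[bin_start, bin_start + width)` covering
#' `[window[1], window[2])` relative to `anchor`. Empty bins are reported
#' with `n_samples = 0` and `NA` value (excluded, not zero-filled, by
#' downstream consumers).
#'
#' @param times Sample timestamps, s.
#' @param values Sample values (same length).
#' @param window Length-2 `[a, b)` window relative to `anchor`, s.
#' @param width Bin width, s; must divide `b - a`.
#' @param anchor Anchor time, s (default 0 for absolute binning).
#' @return `data.frame` with `bin_start` (relative to anchor), `value`
#'   (per-bin mean), `n_samples`.
#' @export
bin_mean <- function(times, values, window, width, anchor = 0) {
  nb <- (window[2] - window[1]) / width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_mean: width must divide the window length", call. = FALSE)
  nb <- round(nb)
  rel <- times - anchor
  idx <- floor((rel - window[1]) / width) + 1
  keep <- rel >= window[1] & rel < window[2] & !is.na(values)
  idx <- idx[keep]
  v <- values[keep]
  sums <- numeric(nb); cnt <- integer(nb)
  if (length(idx)) {
    agg_s <- tapply(v, idx, sum)
    agg_n <- tapply(rep(1L, length(idx)), idx, sum)
    pos <- as.integer(names(agg_s))
    inb <- pos >= 1 & pos <= nb
    sums[pos[inb]] <- agg_s[inb]; cnt[pos[inb]] <- agg_n[inb]
  }
  data.frame(bin_start = window[1] + (seq_len(nb) - 1) * width,
             value = ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_),
             n_samples = cnt)
}

#' z-score a sample vector
#'
#' Centers to mean 0 and scales to sample SD 1.
#'
#' @param x Numeric vector, length >= 2, nonzero variance.
#' @return Standardized vector.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("zscore: need at least 2 values", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("zscore: zero variance (degenerate input)", call. = FALSE)
  (x - mean(x)) / s
}
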