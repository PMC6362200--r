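# Peri-event rasters/PETHs, windowed response-ratio statistics with their
# population tests, the first-rule-shift comparison and block-wise firing
# comparisons.

#' Build a peri-event time histogram
#'
#' Counts spikes on a fixed half-open bin grid around each anchor:
#' `counts[trial, bin]` is the number of spikes with `spike - anchor` in
#' `[bin_start, bin_start + width)`. A spike exactly at the anchor falls in
#' the bin starting at 0.
#'
#' @param spike_times Spike timestamps, s.
#' @param anchors Alignment event times, s (one per trial).
#' @param window Length-2 `[a, b)` window around each anchor, s.
#' @param bin_width Bin width, s; must divide `b - a`.
#' @return An `lc_peth` object: `counts` (trials x bins), `rates` (per-bin
#'   mean rate, Hz), `bin_starts`, `window`, `bin_width`, `n_trials`.
#' @export
build_peth <- function(spike_times, anchors, window = c(-2, 2),
                       bin_width = 0.1) {
  if (!length(anchors)) stop("build_peth: no anchors", call. = FALSE)
  nb <- (window[2] - window[1]) / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("build_peth: bin_width must divide the window length",
         call. = FALSE)
  nb <- round(nb)
  counts <- matrix(0L, nrow = length(anchors), ncol = nb)
  for (i in seq_along(anchors)) {
    rel <- spike_times - anchors[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      idx <- floor((rel - window[1]) / bin_width) + 1
      tab <- tabulate(idx, nbins = nb)
      counts[i, ] <- tab
    }
  }
  structure(list(counts = counts,
                 rates = colMeans(counts) / bin_width,
                 bin_starts = window[1] + (seq_len(nb) - 1) * bin_width,
                 window = window, bin_width = bin_width,
                 n_trials = length(anchors)),
            class = "lc_peth")
}

#' @export
print.lc_peth <- function(x, ...) {
  cat(sprintf("PETH: %d trials, %d bins of %g s over [%g, %g) s\n",
              x$n_trials, length(x$rates), x$bin_width,
              x$window[1], x$window[2]))
  cat(sprintf("  peak rate %.2f Hz at %+.2f s\n", max(x$rates),
              x$bin_starts[which.max(x$rates)] + x$bin_width / 2))
  invisible(x)
}

#' @export
plot.lc_peth <- function(x, main = "Peri-event time histogram", ...) {
  graphics::barplot(x$rates, width = x$bin_width, space = 0,
                    names.arg = NULL, col = "grey40", border = NA,
                    xlab = "time from event (s)", ylab = "rate (Hz)",
                    main = main, ...)
  nb <- length(x$rates)
  at <- pretty(c(0, nb)) * x$bin_width
  graphics::axis(1, at = at / x$bin_width,
                 labels = sprintf("%g", x$window[1] + at))
  graphics::abline(v = -x$window[1] / x$bin_width, lty = 2)
  invisible(x)
}

# Mean rate (Hz) over all trials in a half-open window relative to anchors.
window_mean_rate <- function(spike_times, anchors, window) {
  cnt <- vapply(anchors, function(a)
    sum(spike_times >= a + window[1] & spike_times < a + window[2]),
    numeric(1))
  mean(cnt) / (window[2] - window[1])
}

#' Windowed response ratio for one task event
#'
#' The four statistics share one baseline: the mean rate in `[-1.5, -1) s`
#' before VC onset. Numerators: `VC_ONSET` and `VC_OFF` take the greater of
#' the mean rates in the two 0.5 s bins `[-1, -0.5)` and `[-0.5, 0)` before
#' the VC-onset / return-arm PD crossing respectively; `RWD_PD` the mean
#' rate in `[-0.5, 0)` before the reward-arm PD; `REWARD_SITE` the mean
#' rate in `[1, 2)` after the reward-arm PD. Ratios are ratios of
#' trial-mean rates, not means of per-trial ratios.
#'
#' @param session An [lc_session()].
#' @param kind One of `"VC_ONSET"`, `"VC_OFF"`, `"RWD_PD"`,
#'   `"REWARD_SITE"`.
#' @param unit Unit index into `session$spikes`.
#' @return An `lc_response_ratio` list: `kind`, `peak_rate_hz`,
#'   `baseline_rate_hz`, `ratio`, `windows`.
#' @export
response_ratio <- function(session, kind = c("VC_ONSET", "VC_OFF",
                                             "RWD_PD", "REWARD_SITE"),
                           unit = 1) {
  kind <- match.arg(kind)
  tr <- session$trials
  if (!nrow(tr)) stop("response_ratio: session has no trials",
                      call. = FALSE)
  st <- session$spikes[[unit]]$times
  baseline <- window_mean_rate(st, tr$vc_on_time, c(-1.5, -1))
  if (baseline <= 0)
    stop("response_ratio: zero baseline rate; ratio undefined",
         call. = FALSE)
  res <- switch(kind,
    VC_ONSET = {
      r1 <- window_mean_rate(st, tr$vc_on_time, c(-1, -0.5))
      r2 <- window_mean_rate(st, tr$vc_on_time, c(-0.5, 0))
      list(peak = max(r1, r2), win = "max of [-1,-0.5), [-0.5,0) pre VC_ON")
    },
    VC_OFF = {
      r1 <- window_mean_rate(st, tr$rtn_pd_time, c(-1, -0.5))
      r2 <- window_mean_rate(st, tr$rtn_pd_time, c(-0.5, 0))
      list(peak = max(r1, r2), win = "max of [-1,-0.5), [-0.5,0) pre RTN_PD")
    },
    RWD_PD = {
      list(peak = window_mean_rate(st, tr$rwd_pd_time, c(-0.5, 0)),
           win = "[-0.5,0) pre RWD_PD")
    },
    REWARD_SITE = {
      list(peak = window_mean_rate(st, tr$rwd_pd_time, c(1, 2)),
           win = "[1,2) post RWD_PD")
    })
  structure(list(kind = kind, peak_rate_hz = res$peak,
                 baseline_rate_hz = baseline,
                 ratio = res$peak / baseline,
                 windows = paste0(res$win, "; baseline [-1.5,-1) pre VC_ON"),
                 n_trials = nrow(tr)),
            class = "lc_response_ratio")
}

#' @export
print.lc_response_ratio <- function(x, ...) {
  cat(sprintf("%s response ratio: %.3f (peak %.2f Hz / baseline %.2f Hz, %d trials)\n",
              x$kind, x$ratio, x$peak_rate_hz, x$baseline_rate_hz,
              x$n_trials))
  cat(" windows:", x$windows, "\n")
  invisible(x)
}

#' One-sample population test of response ratios against 1
#'
#' Two-sided one-sample t-test of per-session ratios against the
#' no-change value 1.
#'
#' @param ratios Numeric vector of per-session response ratios (n >= 2).
#' @return List: `mean`, `sem`, `t`, `df`, `p`, `n`.
#' @export
ratio_population_test <- function(ratios) {
  n <- length(ratios)
  if (n < 2) stop("ratio_population_test: need n >= 2", call. = FALSE)
  if (sd(ratios) == 0) {
    if (all(ratios == 1))
      return(list(mean = 1, sem = 0, t = 0, df = n - 1, p = 1, n = n))
    stop("ratio_population_test: zero variance; degenerate test",
         call. = FALSE)
  }
  ht <- t.test(ratios, mu = 1)
  list(mean = mean(ratios), sem = sd(ratios) / sqrt(n),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, n = n)
}

#' Correlate two sets of response ratios across sessions
#'
#' Pearson correlation (with two-sided p) and least-squares slope of `y`
#' on `x`, as used to relate the return-arm (VC OFF) and VC-onset response
#' ratios across recordings.
#'
#' @param x,y Paired per-session ratios (n >= 3).
#' @return List: `r`, `df`, `p`, `slope`, `n`.
#' @export
ratio_ratio_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("ratio_ratio_regression: need paired n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("ratio_ratio_regression: constant input", call. = FALSE)
  ct <- cor.test(x, y)
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, slope = unname(coef(fit)[2]), n = length(x))
}

#' Rule-shift comparison of post-VC-onset spike counts
#'
#' Splits trials at the first rule change and compares per-trial spike
#' counts in the `[0, window)` s interval after VC onset before vs. after
#' the shift with a two-sided Wilcoxon rank-sum test.
#'
#' The rank-sum p-value is computed by Monte-Carlo permutation of the
#' group labels (`n_perm` draws): spike counts in short windows are
#' heavily tied, where the usual normal approximation is conservative,
#' while the permutation distribution of the rank-sum statistic remains
#' exact. Set `n_perm = 0` to fall back to [stats::wilcox.test()].
#'
#' @param session An [lc_session()] containing at least one `RULE_CHANGE`
#'   after time 0 and at least `min_trials` trials on each side.
#' @param window Count window length after VC onset, s (default 0.5).
#' @param unit Unit index.
#' @param min_trials Minimum trials required pre and post.
#' @param n_perm Monte-Carlo permutations for the p-value (uses the
#'   current RNG state); 0 for the normal approximation.
#' @return List: `W`, `p`, `pre_mean`, `post_mean`, `n_pre`, `n_post`,
#'   `degenerate` (TRUE when all counts are zero).
#' @export
rule_shift_test <- function(session, window = 0.5, unit = 1,
                            min_trials = 5, n_perm = 999) {
  ev <- session$events
  rc <- ev$time_s[ev$kind == "RULE_CHANGE" & ev$time_s > 0]
  if (!length(rc)) stop("rule_shift_test: no rule change in session",
                        call. = FALSE)
  shift_t <- rc[1]
  tr <- session$trials
  st <- session$spikes[[unit]]$times
  cnt <- vapply(tr$vc_on_time, function(a)
    sum(st >= a & st < a + window), numeric(1))
  pre <- cnt[tr$vc_on_time < shift_t]
  post <- cnt[tr$vc_on_time > shift_t]
  if (length(pre) < min_trials || length(post) < min_trials)
    stop("rule_shift_test: need >= ", min_trials,
         " trials on each side of the shift", call. = FALSE)
  if (all(cnt == 0))
    return(list(W = NA_real_, p = NA_real_, pre_mean = 0, post_mean = 0,
                n_pre = length(pre), n_post = length(post),
                degenerate = TRUE))
  ht <- suppressWarnings(wilcox.test(post, pre))
  if (n_perm > 0) {
    pooled <- rank(c(post, pre))
    n1 <- length(post)
    w_obs <- sum(pooled[seq_len(n1)])
    dev <- abs(w_obs - n1 * (length(pooled) + 1) / 2)
    w_perm <- replicate(n_perm, sum(sample(pooled, n1)))
    dev_perm <- abs(w_perm - n1 * (length(pooled) + 1) / 2)
    p <- (1 + sum(dev_perm >= dev - 1e-9)) / (n_perm + 1)
  } else {
    p <- ht$p.value
  }
  list(W = unname(ht$statistic), p = p,
       pre_mean = mean(pre), post_mean = mean(post),
       n_pre = length(pre), n_post = length(post), degenerate = FALSE)
}

#' Block-wise comparison of pre-event firing rates
#'
#' For each photodetector event kind, computes per-trial firing rates in
#' its pre-event window (1 s before VC-onset and return-arm crossings,
#' 0.5 s before reward-arm crossings), then Welch t-tests every pair of
#' blocks, with Holm-Bonferroni adjustment over all pairs within the
#' session. Also reports whether the earliest block's mean rate exceeds
#' each later block's.
#'
#' @param session An [lc_session()] with >= 2 blocks of >= 2 trials each.
#' @param unit Unit index.
#' @param windows Named list of pre-event windows (s) per anchor column.
#' @return An `lc_block_comparison`: `tests` data.frame (`kind`, `block_a`,
#'   `block_b`, `t`, `df`, `p`, `p_adj`), `block_means`, and
#'   `earliest_higher` (logical matrix-style data.frame per kind/block).
#' @export
block_rate_comparison <- function(session, unit = 1,
                                  windows = list(vc_on_time = c(-1, 0),
                                                 rtn_pd_time = c(-1, 0),
                                                 rwd_pd_time = c(-0.5, 0))) {
  bl <- session$blocks
  tr <- session$trials
  if (nrow(bl) < 2)
    stop("block_rate_comparison: need >= 2 blocks", call. = FALSE)
  sizes <- bl$end_trial - bl$start_trial + 1
  if (any(sizes < 2))
    stop("block_rate_comparison: every block needs >= 2 trials",
         call. = FALSE)
  st <- session$spikes[[unit]]$times
  rows <- list(); means <- list(); flags <- list()
  for (kind in names(windows)) {
    w <- windows[[kind]]
    rate <- vapply(tr[[kind]], function(a)
      sum(st >= a + w[1] & st < a + w[2]), numeric(1)) / (w[2] - w[1])
    per_block <- lapply(seq_len(nrow(bl)), function(b)
      rate[bl$start_trial[b]:bl$end_trial[b]])
    means[[kind]] <- data.frame(kind = kind, block = seq_len(nrow(bl)),
                                mean_hz = vapply(per_block, mean,
                                                 numeric(1)),
                                n = sizes, stringsAsFactors = FALSE)
    for (a in seq_len(nrow(bl) - 1)) {
      for (b in (a + 1):nrow(bl)) {
        va <- per_block[[a]]; vb <- per_block[[b]]
        if (sd(va) == 0 && sd(vb) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            kind = kind, block_a = a, block_b = b, t = NA_real_,
            df = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        } else {
          ht <- t.test(va, vb)
          rows[[length(rows) + 1]] <- data.frame(
            kind = kind, block_a = a, block_b = b,
            t = unname(ht$statistic), df = unname(ht$parameter),
            p = ht$p.value, stringsAsFactors = FALSE)
        }
      }
    }
    flags[[kind]] <- data.frame(
      kind = kind, later_block = 2:nrow(bl),
      earliest_higher = means[[kind]]$mean_hz[1] >
        means[[kind]]$mean_hz[-1],
      stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  tests$p_adj <- NA_real_
  ok <- !is.na(tests$p)
  tests$p_adj[ok] <- p.adjust(tests$p[ok], method = "holm")
  structure(list(tests = tests, block_means = do.call(rbind, means),
                 earliest_higher = do.call(rbind, flags)),
            class = "lc_block_comparison")
}

#' @export
print.lc_block_comparison <- function(x, ...) {
  cat("Block-wise pre-event firing comparison (Welch t, Holm-adjusted)\n")
  sig <- x$tests[!is.na(x$tests$p_adj) & x$tests$p_adj < 0.05, ]
  cat(sprintf("  %d pairwise tests, %d significant after adjustment\n",
              nrow(x$tests), nrow(sig)))
  print(x$block_means, row.names = FALSE)
  invisible(x)
}
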