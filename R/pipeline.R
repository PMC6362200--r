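# Orchestration: simulate -> analyze -> report over on-disk session
# bundles, fully determined by (config, seed).

#' Simulate a session and write its bundle
#'
#' @param config An [sim_config()], or a path to a YAML/JSON file with its
#'   scalar fields.
#' @param out Output bundle directory.
#' @return The session, invisibly; writes the bundle plus a `manifest.json`
#'   recording the seed and package version.
#' @export
lc_simulate <- function(config, out) {
  if (is.character(config)) config <- load_sim_config(config)
  s <- simulate_session(config)
  write_session(s, out)
  manifest <- list(seed = config$seed, n_trials = config$n_trials,
                   package = "lcmaze",
                   version = as.character(utils::packageVersion("lcmaze")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out, "manifest.json"), useBytes = TRUE)
  invisible(s)
}

# Minimal config-file loader: JSON or YAML with any subset of
# sim_config's scalar fields (missing fields take the defaults); named
# sublists map to the corresponding parameter constructors.
load_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("load_sim_config: the 'yaml' package is required for YAML ",
           "configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  args <- list()
  scalars <- c("n_trials", "seed", "baseline_rate_hz",
               "reward_suppression", "accel_coupling", "firing_lead_s",
               "n_units", "waveform_ms")
  for (f in scalars) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$event_gain)) args$event_gain <- unlist(raw$event_gain)
  if (!is.null(raw$agent)) args$agent <- do.call(agent_params, raw$agent)
  if (!is.null(raw$policy)) args$policy <- do.call(rule_policy, raw$policy)
  if (!is.null(raw$kin)) args$kin <- do.call(kinematics_params, raw$kin)
  if (!is.null(raw$opto)) args$opto <- raw$opto
  unknown <- setdiff(names(raw),
                     c(scalars, "event_gain", "agent", "policy", "kin",
                       "opto"))
  if (length(unknown))
    stop("load_sim_config: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(sim_config, args)
}

#' Analyze a session bundle and write tidy result CSVs
#'
#' Runs the full analysis battery on a bundle: kinematics (cached as
#' `kinematics.csv`), the four response ratios per unit (`ratios.csv`),
#' the rule-shift and block tests (`tests.csv`), event-window and
#' outside-event regressions (`regressions.csv`), the lag scan
#' (`lagscan.csv`), onset detection (`onsets.csv`) and the onset
#' cross-correlogram (`crosscorr.csv`). Exclusions (low-rate bins, onset
#' threshold at or below 4 Hz) are recorded in `analysis_log.txt`. A
#' bundle without tracking still produces the event analyses; kinematic
#' analyses are skipped with a logged reason.
#'
#' @param bundle Path of a session bundle ([write_session()]).
#' @param out Output directory for result CSVs.
#' @param seed Seed for the outside-bin down-sampling.
#' @return Named list of the result tables, invisibly.
#' @export
lc_analyze <- function(bundle, out, seed = 1) {
  s <- read_session(bundle)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  set.seed(seed)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  has_tracking <- nrow(s$tracking) >= 2
  kin <- NULL
  if (has_tracking) {
    kin <- session_kinematics(s)
    write_csv_exact(data.frame(time_s = kin$time_s,
                               speed_cm_s = kin$speed,
                               accel_cm_s2 = kin$accel,
                               valid = kin$valid),
                    file.path(out, "kinematics.csv"))
  } else {
    note("tracking absent or too short: kinematic analyses skipped")
  }
  sid <- s$meta$rat_id %||% basename(bundle)
  ratios <- list(); tests <- list()
  for (u in seq_along(s$spikes)) {
    uid <- s$spikes[[u]]$unit_id
    for (k in c("VC_ONSET", "VC_OFF", "RWD_PD", "REWARD_SITE")) {
      rr <- tryCatch(response_ratio(s, k, unit = u), error = function(e) e)
      if (inherits(rr, "error")) {
        note("response_ratio %s unit %s: %s", k, uid, conditionMessage(rr))
        next
      }
      ratios[[length(ratios) + 1]] <- data.frame(
        session = sid, unit = uid, kind = k, peak_hz = rr$peak_rate_hz,
        baseline_hz = rr$baseline_rate_hz, ratio = rr$ratio,
        stringsAsFactors = FALSE)
    }
    rs <- tryCatch(rule_shift_test(s, unit = u), error = function(e) e)
    if (inherits(rs, "error")) {
      note("rule_shift_test unit %s: %s", uid, conditionMessage(rs))
    } else if (isTRUE(rs$degenerate)) {
      note("rule_shift_test unit %s: all counts zero; degenerate", uid)
    } else {
      tests[[length(tests) + 1]] <- data.frame(
        session = sid, unit = uid, test = "rule_shift_wilcoxon",
        statistic = rs$W, df = NA_real_, p = rs$p, adjusted_p = NA_real_,
        stringsAsFactors = FALSE)
    }
    bc <- tryCatch(block_rate_comparison(s, unit = u),
                   error = function(e) e)
    if (inherits(bc, "error")) {
      note("block_rate_comparison unit %s: %s", uid, conditionMessage(bc))
    } else {
      bt <- bc$tests[!is.na(bc$tests$p), , drop = FALSE]
      if (nrow(bt))
        tests[[length(tests) + 1]] <- data.frame(
          session = sid, unit = uid,
          test = sprintf("block_t_%s_b%d_vs_b%d", bt$kind, bt$block_a,
                         bt$block_b),
          statistic = bt$t, df = bt$df, p = bt$p, adjusted_p = bt$p_adj,
          stringsAsFactors = FALSE)
    }
  }
  empty_df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  ratios <- if (length(ratios)) do.call(rbind, ratios) else
    empty_df(session = character(), unit = character(), kind = character(),
             peak_hz = numeric(), baseline_hz = numeric(),
             ratio = numeric())
  tests <- if (length(tests)) do.call(rbind, tests) else
    empty_df(session = character(), unit = character(), test = character(),
             statistic = numeric(), df = numeric(), p = numeric(),
             adjusted_p = numeric())
  write_csv_exact(ratios, file.path(out, "ratios.csv"))
  write_csv_exact(tests, file.path(out, "tests.csv"))
  regs <- list(); lag_rows <- list(); onset_rows <- list(); xc <- NULL
  if (has_tracking) {
    for (u in seq_along(s$spikes)) {
      uid <- s$spikes[[u]]$unit_id
      n_event_bins <- 0L
      for (k in c("VC_ON_PD", "RTN_PD", "RWD_PD")) {
        pb <- tryCatch(collect_event_bins(s, k, unit = u, kin = kin),
                       error = function(e) e)
        if (inherits(pb, "error")) {
          note("collect_event_bins %s unit %s: %s", k, uid,
               conditionMessage(pb))
          next
        }
        n_event_bins <- max(n_event_bins, nrow(pb))
        rg <- tryCatch(regress_rate_on_accel(pb), error = function(e) e)
        if (inherits(rg, "error")) {
          note("regression %s unit %s: %s", k, uid, conditionMessage(rg))
        } else {
          regs[[length(regs) + 1]] <- data.frame(
            session = sid, unit = uid, scope = k, slope = rg$slope,
            r = rg$r, p = rg$p, n = rg$n, stringsAsFactors = FALSE)
        }
        ls <- tryCatch(lag_scan(s, k, unit = u, kin = kin),
                       error = function(e) e)
        if (inherits(ls, "error")) {
          note("lag_scan %s unit %s: %s", k, uid, conditionMessage(ls))
        } else {
          lag_rows[[length(lag_rows) + 1]] <- data.frame(
            session = sid, unit = uid, scope = k,
            shift_ms = ls$scan$shift_ms, r = ls$scan$r, n = ls$scan$n,
            best_shift_ms = ls$best_shift_ms, stringsAsFactors = FALSE)
        }
      }
      ob <- tryCatch(collect_outside_bins(s, match_n = n_event_bins,
                                          unit = u, kin = kin),
                     error = function(e) e)
      if (inherits(ob, "error")) {
        note("collect_outside_bins unit %s: %s", uid, conditionMessage(ob))
      } else {
        rg <- tryCatch(regress_rate_on_accel(ob), error = function(e) e)
        if (inherits(rg, "error")) {
          note("outside regression unit %s: %s", uid, conditionMessage(rg))
        } else {
          regs[[length(regs) + 1]] <- data.frame(
            session = sid, unit = uid, scope = "OUTSIDE", slope = rg$slope,
            r = rg$r, p = rg$p, n = rg$n, stringsAsFactors = FALSE)
        }
      }
      t_range <- range(s$tracking$time_s)
      fo <- detect_firing_onsets(s$spikes[[u]]$times, t_range)
      ao <- detect_accel_onsets(kin)
      if (fo$excluded)
        note("unit %s: firing onset threshold %.2f Hz <= 4 Hz; excluded",
             uid, fo$threshold_hz)
      if (length(fo$onsets))
        onset_rows[[length(onset_rows) + 1]] <- data.frame(
          session = sid, unit = uid, kind = "firing", time_s = fo$onsets,
          threshold = fo$threshold_hz, excluded = fo$excluded,
          stringsAsFactors = FALSE)
      if (length(ao$onsets))
        onset_rows[[length(onset_rows) + 1]] <- data.frame(
          session = sid, unit = uid, kind = "accel", time_s = ao$onsets,
          threshold = ao$threshold, excluded = FALSE,
          stringsAsFactors = FALSE)
      if (u == 1 && !fo$excluded && length(fo$onsets) &&
            length(ao$onsets)) {
        xc <- onset_lag_crosscorr(fo, ao)
      }
    }
  }
  regs <- if (length(regs)) do.call(rbind, regs) else
    empty_df(session = character(), unit = character(), scope = character(),
             slope = numeric(), r = numeric(), p = numeric(),
             n = integer())
  write_csv_exact(regs, file.path(out, "regressions.csv"))
  lag_tab <- if (length(lag_rows)) do.call(rbind, lag_rows) else
    empty_df(session = character(), unit = character(), scope = character(),
             shift_ms = numeric(), r = numeric(), n = integer(),
             best_shift_ms = numeric())
  write_csv_exact(lag_tab, file.path(out, "lagscan.csv"))
  onset_tab <- if (length(onset_rows)) do.call(rbind, onset_rows) else
    empty_df(session = character(), unit = character(), kind = character(),
             time_s = numeric(), threshold = numeric(),
             excluded = logical())
  write_csv_exact(onset_tab, file.path(out, "onsets.csv"))
  xc_tab <- if (!is.null(xc) && !xc$empty) {
    mids <- (head(xc$breaks_ms, -1) + tail(xc$breaks_ms, -1)) / 2
    data.frame(lag_bin_ms = mids, count = xc$counts,
               mean_lag_ms = xc$mean_lag_ms, stringsAsFactors = FALSE)
  } else {
    empty_df(lag_bin_ms = numeric(), count = integer(),
             mean_lag_ms = numeric())
  }
  write_csv_exact(xc_tab, file.path(out, "crosscorr.csv"))
  writeLines(c(sprintf("lc_analyze seed=%d", seed), log),
             file.path(out, "analysis_log.txt"), useBytes = TRUE)
  invisible(list(ratios = ratios, tests = tests, regressions = regs,
                 lagscan = lag_tab, onsets = onset_tab,
                 crosscorr = xc_tab, log = log))
}

#' Summarize analysis outputs as a text report
#'
#' Renders a human-readable markdown summary whose numbers are read back
#' from the analysis CSVs (so report and CSVs always agree), plus figure
#' files (PETH-style ratio summary, lag-scan curve, onset lag histogram)
#' when plotting is possible.
#'
#' @param results Directory written by [lc_analyze()].
#' @param file Optional output file; default `report.md` inside `results`.
#' @return The report lines, invisibly.
#' @export
lc_report <- function(results, file = file.path(results, "report.md")) {
  need <- file.path(results, c("ratios.csv", "tests.csv",
                               "regressions.csv"))
  if (!all(file.exists(need)))
    stop("lc_report: missing analysis outputs in ", results, call. = FALSE)
  ratios <- read_csv_exact(file.path(results, "ratios.csv"),
                           c("peak_hz", "baseline_hz", "ratio"))
  tests <- read_csv_exact(file.path(results, "tests.csv"),
                          c("statistic", "df", "p", "adjusted_p"))
  regs <- read_csv_exact(file.path(results, "regressions.csv"),
                         c("slope", "r", "p", "n"))
  xc <- read_csv_exact(file.path(results, "crosscorr.csv"),
                       c("lag_bin_ms", "count", "mean_lag_ms"))
  lag_tab <- if (file.exists(file.path(results, "lagscan.csv")))
    read_csv_exact(file.path(results, "lagscan.csv"),
                   c("shift_ms", "r", "n", "best_shift_ms"))
  else NULL
  lines <- c("# Session analysis report", "")
  if (!nrow(ratios) && !nrow(tests) && !nrow(regs)) {
    lines <- c(lines, "nothing to report: all result tables are empty")
  } else {
    if (nrow(ratios)) {
      lines <- c(lines, "## Response ratios", "",
                 "| unit | event | peak (Hz) | baseline (Hz) | ratio |",
                 "|------|-------|-----------|---------------|-------|",
                 sprintf("| %s | %s | %.4g | %.4g | %.4g |",
                         ratios$unit, ratios$kind, ratios$peak_hz,
                         ratios$baseline_hz, ratios$ratio), "")
    }
    if (nrow(tests)) {
      lines <- c(lines, "## Statistical tests", "",
                 "| unit | test | statistic | p | adjusted p |",
                 "|------|------|-----------|---|------------|",
                 sprintf("| %s | %s | %.4g | %.3g | %s |",
                         tests$unit, tests$test, tests$statistic, tests$p,
                         ifelse(is.na(tests$adjusted_p), "-",
                                sprintf("%.3g", tests$adjusted_p))), "")
    }
    if (nrow(regs)) {
      lines <- c(lines, "## Firing-rate vs. acceleration regressions", "",
                 "| unit | scope | slope | r | p | n |",
                 "|------|-------|-------|---|---|---|",
                 sprintf("| %s | %s | %.4g | %.4g | %.3g | %d |",
                         regs$unit, regs$scope, regs$slope, regs$r,
                         regs$p, as.integer(regs$n)), "")
    }
    if (!is.null(lag_tab) && nrow(lag_tab)) {
      best <- unique(lag_tab[, c("unit", "scope", "best_shift_ms")])
      lines <- c(lines, "## Lag scan (positive = firing leads)", "",
                 sprintf("- unit %s, %s: best shift %+g ms", best$unit,
                         best$scope, best$best_shift_ms), "")
    }
    if (nrow(xc)) {
      lines <- c(lines, "## Onset cross-correlation",
                 sprintf("- mean acceleration-onset lag: %+.1f ms over %d pairs",
                         xc$mean_lag_ms[1], sum(xc$count)), "")
    }
  }
  writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}
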