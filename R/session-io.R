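# On-disk session bundle: a directory of plain-text files
#   meta.json      rat id, maze config, seed, rule schedule, provenance
#   events.csv     time_s, kind, side, payload
#   spikes.csv     unit_id, time_s
#   units.json     unit_id, waveform_ms, opto_status
#   tracking.csv   time_s, x_cm, y_cm
#   blocks.csv     start_trial, end_trial, label
# All CSVs carry a header row, UTF-8, '.' decimal separator. Numerics are
# written with 17 significant digits so a write -> read round trip is exact.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_csv_exact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    }
  })
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")) else character())
  writeLines(lines, path, useBytes = TRUE)
}

read_csv_exact <- function(path, numeric_cols) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  for (cc in intersect(numeric_cols, names(df))) {
    v <- df[[cc]]
    v[v == ""] <- NA
    df[[cc]] <- as.numeric(v)
  }
  for (cc in setdiff(names(df), numeric_cols)) df[[cc]][df[[cc]] == ""] <- NA
  df
}

#' Write a session bundle to disk
#'
#' Serializes a validated session to the documented plain-text bundle
#' (meta.json, events.csv, spikes.csv, units.json, tracking.csv,
#' blocks.csv). Writing the same session twice produces byte-identical
#' files; numerics are stored at full precision.
#'
#' @param session An [lc_session()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (!dir.exists(path) &&
        !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("write_session: cannot create directory ", path, call. = FALSE)
  s <- session
  meta <- s$meta
  meta$maze <- unclass(s$maze)
  meta$maze$pd_positions <- as.list(meta$maze$pd_positions)
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, file.path(path, "meta.json"), useBytes = TRUE)
  write_csv_exact(s$events, file.path(path, "events.csv"))
  sp <- if (length(s$spikes)) {
    do.call(rbind, lapply(s$spikes, function(tr)
      data.frame(unit_id = rep(tr$unit_id, length(tr$times)),
                 time_s = tr$times, stringsAsFactors = FALSE)))
  } else data.frame(unit_id = character(), time_s = numeric())
  write_csv_exact(sp, file.path(path, "spikes.csv"))
  units <- lapply(s$spikes, function(tr)
    list(unit_id = tr$unit_id, waveform_ms = tr$waveform_ms,
         opto_status = tr$opto_status %||% "untested"))
  writeLines(jsonlite::toJSON(units, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "units.json"), useBytes = TRUE)
  write_csv_exact(s$tracking, file.path(path, "tracking.csv"))
  write_csv_exact(s$blocks, file.path(path, "blocks.csv"))
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Loads the plain-text bundle written by [write_session()], rebuilds the
#' trial table from the event log with [build_trials()], and validates all
#' session invariants.
#'
#' @param path Bundle directory.
#' @return A validated [lc_session()].
#' @export
read_session <- function(path) {
  need <- c("meta.json", "events.csv", "spikes.csv", "units.json",
            "tracking.csv", "blocks.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("read_session: missing file '", f, "' in ", path, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"),
                             simplifyVector = TRUE)
  mz <- meta$maze
  maze <- maze_config(
    central_arm_length = mz$central_arm_length,
    reward_arm_length = mz$reward_arm_length,
    arm_width = mz$arm_width,
    start_area = unlist(mz$start_area),
    reward_volume_ul = mz$reward_volume_ul,
    video_dt = mz$video_dt,
    pd_positions = unlist(mz$pd_positions))
  meta$maze <- NULL
  events <- read_csv_exact(file.path(path, "events.csv"), "time_s")
  events$payload[is.na(events$payload)] <- ""
  sp <- read_csv_exact(file.path(path, "spikes.csv"), "time_s")
  units <- jsonlite::fromJSON(file.path(path, "units.json"),
                              simplifyVector = FALSE)
  spikes <- lapply(units, function(u) {
    tr <- spike_train(u$unit_id,
                      sp$time_s[sp$unit_id == u$unit_id],
                      u$waveform_ms %||% NA_real_)
    tr$opto_status <- u$opto_status %||% "untested"
    tr
  })
  tracking <- read_csv_exact(file.path(path, "tracking.csv"),
                             c("time_s", "x_cm", "y_cm"))
  blocks <- read_csv_exact(file.path(path, "blocks.csv"),
                           c("start_trial", "end_trial"))
  blocks$start_trial <- as.integer(blocks$start_trial)
  blocks$end_trial <- as.integer(blocks$end_trial)
  trials <- build_trials(events)
  lc_session(maze = maze, spikes = spikes, tracking = tracking,
             events = events, trials = trials, blocks = blocks,
             meta = meta)
}
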