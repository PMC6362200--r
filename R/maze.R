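#' Maze geometry configuration
#'
#' Describes the automated T-maze with return arms as a one-dimensional
#' canonical path (start area -> central arm -> chosen reward arm -> return
#' arm -> start area) plus the 2-D skeleton used to emit head-LED tracking.
#' Photodetector (PD) positions are coordinates (cm) along that path.
#'
#' The canonical path is laid out as: 20 cm of start area, the central arm
#' (default 100 cm), the reward arm (default 50 cm, reward well at its end),
#' and the return path back to the start point. The VC-onset PD sits on the
#' central arm, the reward PD in the middle of the reward arm, and the
#' return PD halfway down the return path.
#'
#' @param central_arm_length Central arm length, cm.
#' @param reward_arm_length Reward arm length, cm.
#' @param arm_width Arm width, cm.
#' @param start_area Start area width x length, cm.
#' @param reward_volume_ul Reward volume per delivery, microlitres.
#' @param video_dt Nominal video tracking sampling interval, s (~30 Hz).
#' @param pd_positions Named numeric vector with path coordinates (cm) of
#'   `VC_ON_PD`, `RWD_PD` and `RTN_PD`. Defaults are derived from the arm
#'   lengths.
#' @return An object of class `lc_maze_config`.
#' @examples
#' mz <- maze_config()
#' mz$pd_positions
#' @export
maze_config <- function(central_arm_length = 100,
                        reward_arm_length = 50,
                        arm_width = 8,
                        start_area = c(35, 40),
                        reward_volume_ul = 30,
                        video_dt = 0.033,
                        pd_positions = NULL) {
  start_run <- 20                       # start point -> central arm entry
  well <- start_run + central_arm_length + reward_arm_length
  return_len <- central_arm_length + start_run + reward_arm_length
  path_length <- well + return_len
  if (is.null(pd_positions)) {
    pd_positions <- c(
      VC_ON_PD = start_run + 0.5 * central_arm_length,
      RWD_PD   = start_run + central_arm_length + reward_arm_length / 2,
      RTN_PD   = well + return_len / 2
    )
  }
  cfg <- structure(list(
    central_arm_length = central_arm_length,
    reward_arm_length = reward_arm_length,
    arm_width = arm_width,
    start_area = start_area,
    reward_volume_ul = reward_volume_ul,
    video_dt = video_dt,
    start_run = start_run,
    well_position = well,
    path_length = path_length,
    pd_positions = pd_positions
  ), class = "lc_maze_config")
  validate_maze_config(cfg)
  cfg
}

validate_maze_config <- function(cfg) {
  stopifnot(inherits(cfg, "lc_maze_config"))
  lens <- c(cfg$central_arm_length, cfg$reward_arm_length, cfg$arm_width,
            cfg$start_area, cfg$path_length)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("maze_config: all lengths must be finite and > 0", call. = FALSE)
  if (cfg$video_dt <= 0)
    stop("maze_config: video_dt must be > 0", call. = FALSE)
  pd <- cfg$pd_positions
  need <- c("VC_ON_PD", "RWD_PD", "RTN_PD")
  if (!all(need %in% names(pd)))
    stop("maze_config: pd_positions must name VC_ON_PD, RWD_PD, RTN_PD",
         call. = FALSE)
  if (any(pd <= 0) || any(pd >= cfg$path_length))
    stop("maze_config: pd_positions must lie on the path (0, path_length)",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.lc_maze_config <- function(x, ...) {
  cat("T-maze configuration\n")
  cat(sprintf("  central arm %g cm, reward arms %g cm, width %g cm\n",
              x$central_arm_length, x$reward_arm_length, x$arm_width))
  cat(sprintf("  canonical path length %g cm; reward well at %g cm\n",
              x$path_length, x$well_position))
  cat("  photodetectors (cm along path):\n")
  for (k in names(x$pd_positions))
    cat(sprintf("    %-9s %g\n", k, x$pd_positions[[k]]))
  cat(sprintf("  video sampling interval %g s\n", x$video_dt))
  invisible(x)
}

# Map a path coordinate (cm) and arm side ("L"/"R") to 2-D coordinates.
# Start point is (0, -start_run); central arm runs north along x = 0;
# left reward arm at negative x as seen from the start area.
maze_path_to_xy <- function(d, side, cfg) {
  s0 <- cfg$start_run
  ca <- cfg$central_arm_length
  ra <- cfg$reward_arm_length
  sgn <- ifelse(side == "L", -1, 1)
  n <- length(d)
  x <- numeric(n); y <- numeric(n)
  # segment break distances along the path
  b1 <- s0 + ca              # junction
  b2 <- b1 + ra              # reward well (corner to return arm)
  b3 <- b2 + ca + s0         # bottom of return corridor
  b4 <- b3 + ra              # back at start point (= path_length)
  seg <- findInterval(d, c(0, b1, b2, b3, b4), rightmost.closed = TRUE)
  i <- seg == 1  # up the central arm (includes start run)
  x[i] <- 0; y[i] <- d[i] - s0
  i <- seg == 2  # along the reward arm
  x[i] <- sgn[i] * (d[i] - b1); y[i] <- ca
  i <- seg == 3  # down the return corridor
  x[i] <- sgn[i] * ra; y[i] <- ca - (d[i] - b2)
  i <- seg >= 4  # back toward the start point
  x[i] <- sgn[i] * pmax(ra - (d[i] - b3), 0)
  y[i] <- -s0
  cbind(x = x, y = y)
}
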