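#' Generate a synthetic open-field trajectory
#'
#' Produces a smooth random foraging walk inside a circular enclosure,
#' statistically emulating a rat exploring an open arena: the turning rate
#' and the speed each follow a mean-reverting (Ornstein-Uhlenbeck) process,
#' speed is clipped to `[0, speed_max]`, and encounters with the wall
#' deflect the heading inward. The walk is simulated on a coarse control
#' grid (10 ms) and linearly interpolated to the simulation timestep, which
#' keeps headings smooth at 1 ms resolution.
#'
#' @param duration Trajectory length, seconds.
#' @param params A [grid_params()] object (enclosure diameter, maximum
#'   speed, timestep).
#' @param seed Optional integer seed.
#' @param speed_mean,speed_sd,speed_tau Stationary mean (m/s), stationary sd
#'   and relaxation time (s) of the speed process.
#' @param turn_sd,turn_tau Stationary sd (rad/s) and relaxation time (s) of
#'   the turning-rate process.
#' @param start Optional starting position (cm); default the arena center.
#' @return A tibble of class `trajectory`: `time_ms`, `x`, `y` (cm,
#'   enclosure-centered), `vx`, `vy` (m/s, forward differences of position).
#' @export
generate_trajectory <- function(duration, params = grid_params(), seed = NULL,
                                speed_mean = 0.35, speed_sd = 0.15,
                                speed_tau = 1, turn_sd = 3, turn_tau = 0.3,
                                start = c(0, 0)) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  R <- params$enclosure_diameter / 2    # cm
  vmax <- params$speed_max              # m/s
  dtc <- 0.01                           # control-grid step, s
  nc <- ceiling(duration / dtc) + 1L
  x <- y <- numeric(nc)
  x[1] <- start[1]; y[1] <- start[2]
  heading <- stats::runif(1, 0, 2 * pi)
  speed <- min(max(stats::rnorm(1, speed_mean, speed_sd), 0), vmax)
  omega <- stats::rnorm(1, 0, turn_sd)
  margin <- 0.97 * R
  for (i in 2:nc) {
    omega <- omega + (-omega / turn_tau) * dtc +
      turn_sd * sqrt(2 * dtc / turn_tau) * stats::rnorm(1)
    speed <- speed + ((speed_mean - speed) / speed_tau) * dtc +
      speed_sd * sqrt(2 * dtc / speed_tau) * stats::rnorm(1)
    speed <- min(max(speed, 0), vmax)
    heading <- heading + omega * dtc
    step_cm <- speed * 100 * dtc
    xn <- x[i - 1] + step_cm * cos(heading)
    yn <- y[i - 1] + step_cm * sin(heading)
    if (sqrt(xn^2 + yn^2) > margin) {
      # deflect inward: blend heading toward the arena center
      to_center <- atan2(-y[i - 1], -x[i - 1])
      dh <- atan2(sin(to_center - heading), cos(to_center - heading))
      heading <- heading + 0.5 * dh + 0.1 * stats::rnorm(1)
      omega <- 0
      xn <- x[i - 1] + step_cm * cos(heading)
      yn <- y[i - 1] + step_cm * sin(heading)
      if (sqrt(xn^2 + yn^2) > R) { xn <- x[i - 1]; yn <- y[i - 1] }
    }
    x[i] <- xn; y[i] <- yn
  }
  tc <- (seq_len(nc) - 1) * dtc * 1000  # ms
  nsteps <- round(duration * 1000 / params$dt)
  tms <- seq_len(nsteps + 1) * params$dt - params$dt
  xi <- stats::approx(tc, x, xout = tms)$y
  yi <- stats::approx(tc, y, xout = tms)$y
  new_trajectory(tms, xi, yi, params)
}

# assemble the trajectory tibble with forward-difference velocities
new_trajectory <- function(time_ms, x, y, params) {
  nt <- length(time_ms)
  dt_s <- diff(time_ms) / 1000
  vx <- c(diff(x) / dt_s, 0) / 100   # cm -> m
  vy <- c(diff(y) / dt_s, 0) / 100
  vx[nt] <- vx[nt - 1]; vy[nt] <- vy[nt - 1]
  out <- tibble::tibble(time_ms = time_ms, x = x, y = y, vx = vx, vy = vy)
  class(out) <- c("trajectory", class(out))
  attr(out, "enclosure_diameter") <- params$enclosure_diameter
  out
}

#' Load a trajectory from columnar text
#'
#' Reads a plain-text table with columns `time` (s), `x`, `y` (cm,
#' enclosure-centered; a header line is optional), validates it against the
#' enclosure and speed limits, and resamples it to the simulation timestep
#' by linear interpolation. Velocities are central differences of the
#' resampled positions.
#'
#' @param path Path to a whitespace- or comma-delimited text file.
#' @param params A [grid_params()] object.
#' @return A `trajectory` tibble as in [generate_trajectory()].
#' @examples
#' f <- system.file("extdata", "example_trajectory.tsv",
#'                  package = "gridmodules")
#' traj <- load_trajectory(f)
#' head(traj)
#' @export
load_trajectory <- function(path, params = grid_params()) {
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#", fill = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) > 0 && all(is.na(suppressWarnings(as.numeric(raw[1, ])))))
    raw <- raw[-1, , drop = FALSE]  # header line
  if (nrow(raw) == 0) stop("empty trajectory file", call. = FALSE)
  if (ncol(raw) < 3) {
    raw <- utils::read.table(path, header = FALSE, sep = ",",
                             comment.char = "#", stringsAsFactors = FALSE)
    if (nrow(raw) > 0 && all(is.na(suppressWarnings(as.numeric(raw[1, ])))))
      raw <- raw[-1, , drop = FALSE]
  }
  if (ncol(raw) < 3) stop("need time, x, y columns", call. = FALSE)
  tt <- as.numeric(raw[[1]]); x <- as.numeric(raw[[2]]); y <- as.numeric(raw[[3]])
  if (any(is.na(tt)) || any(is.na(x)) || any(is.na(y)))
    stop("non-numeric trajectory entries", call. = FALSE)
  if (length(tt) < 2) stop("need at least two trajectory points", call. = FALSE)
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  R <- params$enclosure_diameter / 2
  if (any(sqrt(x^2 + y^2) > R + 1e-9))
    stop("trajectory leaves the enclosure", call. = FALSE)
  seg_speed <- sqrt(diff(x)^2 + diff(y)^2) / diff(tt) / 100
  if (any(seg_speed > params$speed_max + 1e-9))
    stop("trajectory speed exceeds speed_max", call. = FALSE)
  tms <- seq(tt[1], tt[length(tt)], by = params$dt / 1000) * 1000
  xi <- stats::approx(tt * 1000, x, xout = tms)$y
  yi <- stats::approx(tt * 1000, y, xout = tms)$y
  new_trajectory(tms - tms[1], xi, yi, params)
}

#' Write a trajectory to columnar text
#'
#' @param traj A `trajectory` tibble.
#' @param path Output path; written as `time x y` with time in seconds.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_tsv(
    tibble::tibble(time = traj$time_ms / 1000, x = traj$x, y = traj$y),
    path)
  invisible(path)
}

#' Velocity matrix of a trajectory
#'
#' @param traj A `trajectory` tibble.
#' @return A `steps x 2` matrix of velocities (m/s) for [advance()]; row `i`
#'   is the velocity applied during step `i`.
#' @export
trajectory_velocities <- function(traj) {
  cbind(traj$vx, traj$vy)[-nrow(traj), , drop = FALSE]
}
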