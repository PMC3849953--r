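# Minimum-jerk reference trajectories -----------------------------------------

#' Minimum-jerk time-scaling polynomial
#'
#' The quintic blend \eqn{\sigma(s) = 10 s^3 - 15 s^4 + 6 s^5} that carries a
#' point-to-point movement from 0 to 1 over normalised time \eqn{s \in [0, 1]}
#' with zero velocity and acceleration at both ends. It is the unique quintic
#' minimising integrated squared jerk under those boundary conditions, and is
#' the standard model for smooth human reaching.
#'
#' @param s Normalised time, in `[0, 1]`.
#' @return Fraction of the path completed, in `[0, 1]`.
#' @seealso [mjt_position()]
#' @export
mjt_sigma <- function(s) {
  stopifnot(is.numeric(s))
  10 * s^3 - 15 * s^4 + 6 * s^5
}

#' @rdname mjt_sigma
#' @details `mjt_sigma_dot()` is the derivative with respect to `s`; the peak
#'   value \eqn{\sigma'(1/2) = 1.875} fixes the peak speed of a movement of
#'   length L and duration D at `1.875 * L / D`.
#' @export
mjt_sigma_dot <- function(s) {
  30 * s^2 - 60 * s^3 + 30 * s^4
}

#' Position on a minimum-jerk point-to-point trajectory
#'
#' The reference path is the straight line from `source` to `target`, traversed
#' with minimum-jerk time scaling: at time `t` of a movement of duration
#' `duration`, the position is `source + (target - source) * mjt_sigma(t / duration)`.
#'
#' @param source,target Numeric length-3 positions (metres), `c(x, y, z)`.
#' @param duration Movement duration in seconds, > 0.
#' @param t Time since movement onset, seconds; each value must lie in
#'   `[0, duration]`. May be a vector.
#' @return For scalar `t`, a named numeric length-3 position; for vector `t`,
#'   a matrix with one row per time and columns `x`, `y`, `z`.
#' @examples
#' mjt_position(c(0, 0, 0), c(1, 0, 0), duration = 1, t = 0.5)
#' @export
mjt_position <- function(source, target, duration, t) {
  source <- as_point3(source)
  target <- as_point3(target)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number", call. = FALSE)
  }
  if (any(t < 0) || any(t > duration)) {
    stop("`t` must lie within [0, duration]", call. = FALSE)
  }
  frac <- mjt_sigma(t / duration)
  if (length(t) == 1L) {
    out <- source + frac * (target - source)
    names(out) <- c("x", "y", "z")
    return(out)
  }
  out <- outer(frac, target - source) + rep(source, each = length(t))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Velocity on a minimum-jerk trajectory
#'
#' Analytic time derivative of [mjt_position()]: zero at both endpoints,
#' maximal at mid-movement.
#'
#' @inheritParams mjt_position
#' @return As [mjt_position()], with columns/names `vx`, `vy`, `vz`
#'   (metres/second).
#' @export
mjt_velocity <- function(source, target, duration, t) {
  source <- as_point3(source)
  target <- as_point3(target)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a single positive number", call. = FALSE)
  }
  if (any(t < 0) || any(t > duration)) {
    stop("`t` must lie within [0, duration]", call. = FALSE)
  }
  frac <- mjt_sigma_dot(t / duration) / duration
  if (length(t) == 1L) {
    out <- frac * (target - source)
    names(out) <- c("vx", "vy", "vz")
    return(out)
  }
  out <- outer(frac, target - source)
  colnames(out) <- c("vx", "vy", "vz")
  out
}

# validate / coerce a 3D point
as_point3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p))) {
    stop("a 3D point must be three finite coordinates", call. = FALSE)
  }
  p
}

#' Sampling time grid for a movement
#'
#' Times `0, dt, 2 dt, ...` with the final sample forced to land exactly at
#' `duration`, so endpoint identities hold exactly even when `duration` is not
#' a multiple of `dt`.
#'
#' @param duration Movement duration, seconds.
#' @param dt Sampling interval, seconds; must satisfy `dt < duration`.
#' @return Strictly increasing numeric vector of sample times.
#' @keywords internal
sample_times <- function(duration, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (dt >= duration) {
    stop("`dt` must be smaller than `duration` (need at least one interval)",
         call. = FALSE)
  }
  ts <- seq(0, duration, by = dt)
  if (duration - ts[length(ts)] > 1e-12) ts <- c(ts, duration)
  ts[length(ts)] <- duration
  ts
}

#' Sample a segment's minimum-jerk reference trajectory
#'
#' Evaluates the minimum-jerk reference for a [segment()] at a regular sampling
#' grid, mirroring a robot controller that computes the reference position at
#' the start of every sampling interval.
#'
#' @param segment A [segment()] with source and target endpoints.
#' @param duration Movement duration in seconds (defaults to the segment's
#'   default duration).
#' @param dt Sampling interval in seconds. The default 0.01 s (100 Hz) is
#'   configurable; all sign-based decisions downstream are insensitive to it.
#' @return A tibble with columns `t`, `x`, `y`, `z`, `vx`, `vy`, `vz`.
#' @examples
#' seg <- cube_segments()[[1]]
#' head(sample_trajectory(seg, duration = 2, dt = 0.5))
#' @export
sample_trajectory <- function(segment, duration = segment$default_duration,
                              dt = 0.01) {
  stopifnot(inherits(segment, "reachadapt_segment"))
  ts <- sample_times(duration, dt)
  pos <- mjt_position(segment$source, segment$target, duration, ts)
  vel <- mjt_velocity(segment$source, segment$target, duration, ts)
  tibble::tibble(
    t = ts,
    x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
    vx = vel[, "vx"], vy = vel[, "vy"], vz = vel[, "vz"]
  )
}

#' Read / write trajectory CSV files
#'
#' Plain CSV interchange for sampled trajectories: header `t,x,y,z` with
#' optional `vx,vy,vz`, SI units, '.' decimal separator.
#'
#' @param trajectory A tibble with at least columns `t`, `x`, `y`, `z`.
#' @param path File path.
#' @return `read_trajectory_csv()` returns a tibble; `write_trajectory_csv()`
#'   returns `path` invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  keep <- intersect(c("t", "x", "y", "z", "vx", "vy", "vz"), names(trajectory))
  if (!all(c("t", "x", "y", "z") %in% keep)) {
    stop("trajectory must have columns t, x, y, z", call. = FALSE)
  }
  utils::write.csv(as.data.frame(trajectory)[keep], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "x", "y", "z") %in% names(df))) {
    stop("trajectory CSV must have header t,x,y,z[,vx,vy,vz]", call. = FALSE)
  }
  if (is.unsorted(df$t, strictly = TRUE)) {
    stop("trajectory sample times must be strictly increasing", call. = FALSE)
  }
  tibble::as_tibble(df)
}
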