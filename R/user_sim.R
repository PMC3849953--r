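# Synthetic participant models --------------------------------------------------

.behaviors <- c("cooperative", "leading", "passive_lag")

#' Synthetic participant model
#'
#' A generative stand-in for a human interacting with the robot, used to close
#' the adaptive loop without hardware. The model follows its own minimum-jerk
#' clock: a `leading` user executes each segment at their intrinsic preferred
#' duration regardless of the robot's set duration; a `cooperative` user tracks
#' the robot (or their preferred duration when one is set); a `passive_lag`
#' user is dragged by the robot and trails the reference by a pure response
#' delay. Isotropic Gaussian position noise is added per sample.
#'
#' @param behavior One of `"cooperative"`, `"leading"`, `"passive_lag"`. Sets
#'   the default scenario; sessions override it per mode.
#' @param preferred_duration Intrinsic preferred duration in seconds: a scalar
#'   applied to every segment, or a named numeric vector mapping segment ids
#'   (`"1"`, `"2"`, ...) to seconds. `NULL` means "follow the robot's set
#'   duration".
#' @param noise_sd Additive isotropic position-noise SD, metres (>= 0).
#' @param response_lag Pure delay of a passive user behind the reference,
#'   seconds (>= 0).
#' @param condition_factors Optional named list of multiplicative factors on
#'   the preferred duration keyed by condition labels, e.g.
#'   `list(embedded = 0.8, reach = 1.2)` to plant faster embedded-target and
#'   slower reaching movements. Recognised names: `embedded`, `virtual`,
#'   `reach`, `return`, `against`, `towards`, `ground`, `small`, `large`.
#' @return An object of class `user_model`.
#' @export
user_model <- function(behavior = c("cooperative", "leading", "passive_lag"),
                       preferred_duration = NULL, noise_sd = 0,
                       response_lag = 0, condition_factors = NULL) {
  behavior <- match.arg(behavior)
  if (!is.null(preferred_duration)) {
    stopifnot(is.numeric(preferred_duration), all(preferred_duration > 0))
  }
  stopifnot(is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(response_lag), response_lag >= 0)
  if (!is.null(condition_factors)) {
    stopifnot(is.list(condition_factors),
              all(unlist(condition_factors) > 0))
  }
  structure(
    list(behavior = behavior, preferred_duration = preferred_duration,
         noise_sd = noise_sd, response_lag = response_lag,
         condition_factors = condition_factors),
    class = "user_model"
  )
}

#' @export
print.user_model <- function(x, ...) {
  pd <- if (is.null(x$preferred_duration)) "follows robot"
        else paste(format(x$preferred_duration), collapse = ", ")
  cat(sprintf("<user_model> %s | preferred: %s s | noise %.3g m | lag %.2g s\n",
              x$behavior, pd, x$noise_sd, x$response_lag))
  invisible(x)
}

# resolve the user's effective preferred duration for a segment
preferred_duration_for <- function(user, segment, robot_duration) {
  pd <- user$preferred_duration
  base <- if (is.null(pd)) {
    robot_duration
  } else if (!is.null(names(pd))) {
    got <- pd[as.character(segment$id)]
    if (is.na(got)) robot_duration else unname(got)
  } else {
    pd[1]
  }
  cf <- user$condition_factors
  if (!is.null(cf)) {
    pick <- c(if (segment$embedded) "embedded" else "virtual",
              if (segment$reach) "reach" else "return",
              segment$gravity, segment$cross_body)
    for (nm in pick) if (!is.null(cf[[nm]])) base <- base * cf[[nm]]
  }
  base
}

#' Simulate one segment execution by a synthetic participant
#'
#' Generates the achieved end-effector trajectory on the reference sampling
#' grid for one execution of a segment at the robot's set duration. The
#' deterministic part is a minimum-jerk profile along the segment axis at the
#' user's effective clock, clamped to the segment (the user waits at the
#' source before onset and holds at the target after completing early);
#' Gaussian noise is then added to every coordinate.
#'
#' @param segment A [segment()] with endpoints.
#' @param robot_duration The robot's set duration for this execution, seconds.
#' @param user A [user_model()].
#' @param dt Sampling interval, seconds.
#' @param seed Integer seed for the noise draw; identical seeds give
#'   bit-identical trajectories. `NULL` uses the current RNG stream.
#' @param behavior Optional override of `user$behavior` (sessions force the
#'   scenario per mode: passive, assisted, lead-encouraged).
#' @return A tibble with columns `t`, `x`, `y`, `z` on the same grid as
#'   [sample_trajectory()] at (`robot_duration`, `dt`).
#' @export
simulate_segment <- function(segment, robot_duration, user, dt = 0.01,
                             seed = NULL, behavior = NULL) {
  stopifnot(inherits(segment, "reachadapt_segment"),
            inherits(user, "user_model"), robot_duration > 0)
  behavior <- if (is.null(behavior)) user$behavior
              else match.arg(behavior, .behaviors)
  ts <- sample_times(robot_duration, dt)
  frac <- switch(
    behavior,
    passive_lag = mjt_sigma(pmin(pmax((ts - user$response_lag) / robot_duration, 0), 1)),
    {
      # cooperative and leading users follow their own minimum-jerk clock
      d_eff <- preferred_duration_for(user, segment, robot_duration)
      mjt_sigma(pmin(ts / d_eff, 1))
    }
  )
  pos <- outer(frac, segment$target - segment$source) +
    rep(segment$source, each = length(ts))
  if (user$noise_sd > 0) {
    draw <- function() matrix(stats::rnorm(length(pos), sd = user$noise_sd),
                              nrow = nrow(pos))
    noise <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    pos <- pos + noise
  }
  tibble::tibble(t = ts, x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Simulate a cohort of full sessions
#'
#' Runs the full experimental session once per simulated participant, with
#' per-participant user models supplied by a factory function, reproducibly
#' from a single master seed.
#'
#' @param n_participants Number of participants (>= 0).
#' @param protocol A [protocol()].
#' @param user_factory Function `(participant_id, seed) -> user_model` (the
#'   seed argument lets the factory draw randomised traits reproducibly), or a
#'   single [user_model()] used for everyone.
#' @param config An [adaptation_config()].
#' @param seed Master integer seed.
#' @param dt Sampling interval, seconds.
#' @return An object of class `cohort_log`: a list of session logs (see
#'   [run_session()]), one per participant, named by participant id.
#' @export
simulate_cohort <- function(n_participants, protocol, user_factory, config,
                            seed = 1L, dt = 0.01) {
  stopifnot(n_participants >= 0)
  if (inherits(user_factory, "user_model")) {
    fixed <- user_factory
    user_factory <- function(id, seed) fixed
  }
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    u <- user_factory(i, seed + 104729L * i)
    stopifnot(inherits(u, "user_model"))
    out[[i]] <- run_session(protocol, u, config,
                            seed = seed + 15485863L + i, dt = dt)
    out[[i]]$participant <- i
  }
  names(out) <- as.character(seq_len(n_participants))
  class(out) <- "cohort_log"
  out
}

#' @export
print.cohort_log <- function(x, ...) {
  cat(sprintf("<cohort_log> %d participants\n", length(x)))
  invisible(x)
}
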