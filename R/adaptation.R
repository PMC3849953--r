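# Assist-as-needed duration adaptation -----------------------------------------

#' Configuration of the duration-update rule
#'
#' Parameters of the adaptive loop that tunes each segment's execution duration
#' to the participant's lead/lag performance. The per-iteration adjustment is
#' `delta = clip(gain * |sum_delta_effort|, delta_min, delta_max)`, added to
#' the current duration when the participant lags and subtracted when they
#' lead.
#'
#' @param gain Seconds of duration change per metre of aggregate effort
#'   difference (> 0). The default 0.05 s/m is calibrated for raw-sample
#'   aggregates at the default 100 Hz sampling: the step saturates at
#'   `delta_max` once the mean lead/lag exceeds roughly an eighth of a typical
#'   0.4 m segment, which lets the loop traverse the 4 s to 1.6 s range seen in
#'   recorded sessions within five repetitions. `gain * dt` is the physical
#'   constant; rescale `gain` if you change `dt` with raw-sample aggregates,
#'   or use time-weighted aggregates and multiply `gain` by 1/dt.
#' @param delta_min,delta_max Bounds on the per-iteration adjustment, seconds.
#'   Defaults 0.0 and 1.0 s.
#' @param duration_floor Smallest admissible duration, seconds (> 0). Prevents
#'   the update from driving the duration non-positive.
#' @param quantum Rounding step for updated durations, seconds; 0 disables.
#'   The default 0.2 s reproduces the granularity of recorded sessions.
#' @param initial_duration Duration of the first iteration, seconds.
#' @return An object of class `adaptation_config`.
#' @export
adaptation_config <- function(gain = 0.05, delta_min = 0, delta_max = 1,
                              duration_floor = 0.5, quantum = 0.2,
                              initial_duration = 4) {
  stopifnot(is.numeric(gain), gain > 0,
            delta_min >= 0, delta_min < delta_max,
            duration_floor > 0, quantum >= 0,
            initial_duration >= duration_floor)
  structure(
    list(gain = gain, delta_min = delta_min, delta_max = delta_max,
         duration_floor = duration_floor, quantum = quantum,
         initial_duration = initial_duration),
    class = "adaptation_config"
  )
}

#' @export
print.adaptation_config <- function(x, ...) {
  cat(sprintf(
    "<adaptation_config> gain %.3g s/m, delta in [%.2g, %.2g] s, floor %.2g s, quantum %.2g s, initial %.2g s\n",
    x$gain, x$delta_min, x$delta_max, x$duration_floor, x$quantum,
    x$initial_duration))
  invisible(x)
}

#' One step of the duration-update rule
#'
#' Applies the adaptive rule to a segment's current duration given the
#' aggregate lead/lag measure of the latest execution: when
#' `sum_delta_effort > 0` the participant lagged and the duration is increased
#' by `delta`; otherwise the participant led (or matched) and the duration is
#' decreased by `delta`, with `delta = clip(gain * |sum_delta_effort|,
#' delta_min, delta_max)`. The result is rounded to the configured quantum and
#' clamped at the duration floor.
#'
#' @param current Current duration, seconds (>= `config$duration_floor`).
#' @param sum_delta_effort Aggregate effort difference of the last execution,
#'   metres (positive = lagging).
#' @param config An [adaptation_config()].
#' @return A list with `duration` (the updated value) and `delta` (the
#'   magnitude applied, for logging).
#' @examples
#' cfg <- adaptation_config(gain = 10, quantum = 0)
#' update_duration(4, 0.05, cfg)  # lagging: 4 + 0.5
#' @export
update_duration <- function(current, sum_delta_effort, config) {
  stopifnot(inherits(config, "adaptation_config"),
            current >= config$duration_floor)
  delta <- min(max(config$gain * abs(sum_delta_effort), config$delta_min),
               config$delta_max)
  out <- if (sum_delta_effort > 0) current + delta else current - delta
  if (config$quantum > 0) out <- round(out / config$quantum) * config$quantum
  out <- max(out, config$duration_floor)
  list(duration = out, delta = delta)
}

#' Run the adaptive loop over repeated executions of one segment
#'
#' Simulates `iterations` executions of a segment against a synthetic
#' participant, updating the duration between iterations with
#' [update_duration()]. Iteration 1 runs at `config$initial_duration`; each
#' subsequent iteration runs at the duration produced by the previous
#' iteration's aggregate effort difference. Convergence is assessed with
#' [is_constant_optimum()] on the resulting duration sequence.
#'
#' @param segment A [segment()] with endpoints.
#' @param user A [user_model()].
#' @param config An [adaptation_config()].
#' @param iterations Number of executions (>= 1); 5 in the standard protocol.
#' @param seed Integer seed; each iteration's noise draw is derived from it.
#' @param dt Sampling interval, seconds.
#' @param behavior Optional override of the user's behaviour for these
#'   executions (see [simulate_segment()]).
#' @param min_run,tol Passed to [is_constant_optimum()].
#' @return An object of class `duration_sequence`: list with `segment_id`,
#'   `durations`, `sum_delta_effort`, `delta_applied` (per iteration),
#'   `converged` and `optimum`.
#' @export
run_adaptation <- function(segment, user, config, iterations = 5L,
                           seed = 1L, dt = 0.01, behavior = NULL,
                           min_run = 2L, tol = 1e-6) {
  stopifnot(iterations >= 1L)
  d <- config$initial_duration
  durations <- sums <- deltas <- numeric(iterations)
  for (i in seq_len(iterations)) {
    ref <- sample_trajectory(segment, d, dt)
    act <- simulate_segment(segment, d, user, dt = dt,
                            seed = seed + 7919L * i, behavior = behavior)
    es <- summarize_efforts(ref, act, segment)
    durations[i] <- d
    sums[i] <- es$sum_delta_effort
    upd <- update_duration(d, es$sum_delta_effort, config)
    deltas[i] <- upd$delta
    d <- upd$duration
  }
  conv <- is_constant_optimum(durations, min_run = min_run, tol = tol)
  structure(
    list(segment_id = segment$id, durations = durations,
         sum_delta_effort = sums, delta_applied = deltas,
         converged = conv$converged, optimum = conv$optimum),
    class = "duration_sequence"
  )
}

#' @export
print.duration_sequence <- function(x, ...) {
  cat(sprintf("<duration_sequence> segment %d: %s%s\n",
              x$segment_id, paste(format(x$durations), collapse = " -> "),
              if (x$converged) sprintf("  [optimum %.2f s]", x$optimum) else "  [not converged]"))
  invisible(x)
}
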