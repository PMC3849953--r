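# Lead/lag performance measures ------------------------------------------------

#' Normalised segment time
#'
#' Maps a time inside a segment's execution window linearly onto `[-1, 1]`:
#' -1 at segment start, +1 at segment end. Used to compare progress across
#' segments of different durations.
#'
#' @param t_start,t_end Segment start and end times, seconds; `t_end > t_start`.
#' @param t Time(s) to map; each must lie in `[t_start, t_end]`.
#' @return Values in `[-1, 1]`.
#' @export
tau <- function(t_start, t_end, t) {
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`", call. = FALSE)
  if (any(t < t_start) || any(t > t_end)) {
    stop("`t` must lie within [t_start, t_end]", call. = FALSE)
  }
  2 * (t - t_start) / (t_end - t_start) - 1
}

#' Signed effort projection along a segment
#'
#' Scalar projection of the displacement from the segment source onto the unit
#' source-to-target vector. This is the "effort" coordinate: 0 at the source,
#' the segment length at the target, negative behind the source and larger
#' than the length on overshoot.
#'
#' @param position Numeric length-3 position, or an n-by-3 matrix of positions.
#' @param source,target Segment endpoints (must be distinct).
#' @return Signed distance(s) along the segment axis, metres.
#' @examples
#' effort_projection(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0)) # 1
#' @export
effort_projection <- function(position, source, target) {
  source <- as_point3(source)
  target <- as_point3(target)
  axis <- target - source
  len <- sqrt(sum(axis^2))
  if (len == 0) stop("degenerate segment: source and target coincide",
                     call. = FALSE)
  u <- axis / len
  if (is.matrix(position)) {
    drop(sweep(position, 2, source) %*% u)
  } else {
    sum((as_point3(position) - source) * u)
  }
}

#' Per-sample lead/lag effort difference
#'
#' Difference between the reference (robot) effort projection and the achieved
#' (participant) effort projection at the same sample time. Positive values
#' mean the participant is behind the reference (lagging); negative values mean
#' the participant is ahead (leading).
#'
#' @param reference_position,actual_position Length-3 positions at a common
#'   sample time.
#' @inheritParams effort_projection
#' @return Signed effort difference, metres.
#' @export
delta_effort <- function(reference_position, actual_position, source, target) {
  effort_projection(reference_position, source, target) -
    effort_projection(actual_position, source, target)
}

#' Summarise lead/lag effort over a segment execution
#'
#' Computes the per-sample effort projections of a reference and an achieved
#' trajectory, their difference, and the segment aggregate
#' `sum_delta_effort` whose sign indicates whether the participant led
#' (negative) or lagged (positive) for the major part of the segment. The
#' achieved trajectory is resampled onto the reference time base by linear
#' interpolation with clamped extrapolation at the ends, so logger and
#' controller clocks need not align.
#'
#' @param reference,actual Tibbles/data frames with columns `t`, `x`, `y`, `z`.
#' @param segment The [segment()] being executed (supplies the axis).
#' @param time_weighted If `TRUE`, each sample's effort difference is weighted
#'   by its time step so the aggregate approximates a time integral
#'   (metre-seconds) and is invariant to sampling density. The default `FALSE`
#'   sums raw samples; sign-based decisions are identical either way.
#' @return An object of class `effort_summary`: a list with `segment_id`,
#'   `series` (tibble `t`, `tau`, `effort_mjt`, `effort_actual`,
#'   `delta_effort`), `sum_delta_effort` and `n_samples`.
#' @export
summarize_efforts <- function(reference, actual, segment,
                              time_weighted = FALSE) {
  stopifnot(inherits(segment, "reachadapt_segment"))
  for (nm in c("t", "x", "y", "z")) {
    if (!nm %in% names(reference) || !nm %in% names(actual)) {
      stop("trajectories need columns t, x, y, z", call. = FALSE)
    }
  }
  if (nrow(reference) < 2L || nrow(actual) < 1L) {
    stop("trajectories must be non-empty (reference needs >= 2 samples)",
         call. = FALSE)
  }
  if (min(actual$t) > max(reference$t) || max(actual$t) < min(reference$t)) {
    stop("reference and actual trajectories do not overlap in time",
         call. = FALSE)
  }
  ts <- reference$t
  interp <- function(col) {
    if (nrow(actual) == 1L) rep(actual[[col]], length(ts))
    else stats::approx(actual$t, actual[[col]], xout = ts, rule = 2)$y
  }
  act <- cbind(x = interp("x"), y = interp("y"), z = interp("z"))
  ref <- cbind(x = reference$x, y = reference$y, z = reference$z)
  e_mjt <- effort_projection(ref, segment$source, segment$target)
  e_act <- effort_projection(act, segment$source, segment$target)
  d <- e_mjt - e_act
  w <- if (time_weighted) c(diff(ts), 0) else rep(1, length(ts))
  series <- tibble::tibble(
    t = ts,
    tau = tau(ts[1], ts[length(ts)], ts),
    effort_mjt = e_mjt,
    effort_actual = e_act,
    delta_effort = d
  )
  structure(
    list(segment_id = segment$id, series = series,
         sum_delta_effort = sum(d * w), n_samples = length(ts)),
    class = "effort_summary"
  )
}

#' @export
print.effort_summary <- function(x, ...) {
  role <- if (x$sum_delta_effort > 0) "lagging" else if (x$sum_delta_effort < 0)
    "leading" else "neutral"
  cat(sprintf("<effort_summary> segment %d: %d samples, sum(dEffort) = %.4g m (%s)\n",
              x$segment_id, x$n_samples, x$sum_delta_effort, role))
  invisible(x)
}

#' Euclidean distance between two points
#'
#' @param A,B Length-3 positions, metres.
#' @return Distance in metres.
#' @export
segment_magnitude <- function(A, B) {
  sqrt(sum((as_point3(B) - as_point3(A))^2))
}

#' Duration per unit segment length
#'
#' Normalises a recorded segment duration by the segment's Euclidean length so
#' that execution speed can be compared across segments of different lengths.
#'
#' @param recorded Recorded duration, seconds.
#' @param magnitude Segment length, metres (> 0).
#' @return Normalised duration, seconds per metre.
#' @export
normalized_duration <- function(recorded, magnitude) {
  if (any(magnitude <= 0)) {
    stop("degenerate segment: magnitude must be positive", call. = FALSE)
  }
  recorded / magnitude
}

#' Constant-optimum detection on a duration sequence
#'
#' A segment's duration is considered to have reached a constant optimum when
#' it stays constant for `min_run` or more iterations *without further change
#' as the iterations progress*, i.e. the constant run must be the trailing run
#' of the sequence. A mid-sequence plateau followed by further change does not
#' qualify.
#'
#' @param durations Ordered numeric vector of per-iteration durations, seconds.
#' @param min_run Minimum length of the trailing constant run (>= 2).
#' @param tol Equality tolerance in seconds. Recorded durations are quantised
#'   (0.2 s grid in the published sessions), so the default is exact-equality
#'   semantics up to floating-point noise.
#' @return A list with `converged` (logical), `optimum` (the constant value,
#'   `NA` when not converged) and `run_length`.
#' @examples
#' is_constant_optimum(c(3, 2, 1.6, 1.6, 1.6))   # converged at 1.6
#' is_constant_optimum(c(3.4, 2.4, 2.2, 1.6, 1.8)) # not converged
#' @export
is_constant_optimum <- function(durations, min_run = 2L, tol = 1e-6) {
  stopifnot(length(durations) >= 1L, all(durations > 0), min_run >= 2L)
  n <- length(durations)
  run <- 1L
  while (run < n && abs(durations[n - run] - durations[n]) <= tol) {
    run <- run + 1L
  }
  conv <- run >= min_run
  list(converged = conv,
       optimum = if (conv) durations[n] else NA_real_,
       run_length = run)
}

#' Count converged duration sequences
#'
#' @param sequences A list whose elements are either numeric duration vectors,
#'   results of [is_constant_optimum()], or `duration_sequence` objects from
#'   [run_adaptation()].
#' @param ... Passed to [is_constant_optimum()] for raw numeric elements.
#' @return Integer number of sequences flagged converged.
#' @export
count_converged_segments <- function(sequences, ...) {
  flags <- vapply(sequences, function(s) {
    if (is.list(s) && !is.null(s$converged)) isTRUE(s$converged)
    else is_constant_optimum(as.numeric(s), ...)$converged
  }, logical(1))
  sum(flags)
}

#' Export an effort series to CSV
#'
#' Writes the per-sample series with header
#' `segment_id,t,tau,effort_mjt,effort_actual,delta_effort`.
#'
#' @param summary An `effort_summary` from [summarize_efforts()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_effort_csv <- function(summary, path) {
  stopifnot(inherits(summary, "effort_summary"))
  df <- cbind(segment_id = summary$segment_id,
              as.data.frame(summary$series))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
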