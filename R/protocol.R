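# Session protocol and orchestration -------------------------------------------

.mode_names <- c("passive", "AA1", "AA2")

#' Mode of robot operation
#'
#' The three operating modes of the actual-performance phase: `passive` (robot
#' executes the segment, participant remains passive — the lagging scenario),
#' `AA1` (first active-assisted run: the participant initiates and robot and
#' participant work together), and `AA2` (second active-assisted run: the
#' participant is encouraged to lead; the only mode in which duration
#' adaptation is enabled).
#'
#' @param name One of `"passive"`, `"AA1"`, `"AA2"`.
#' @return A list with `name`, `robot_active`, `user_initiates`,
#'   `adaptation_enabled`.
#' @export
mode_spec <- function(name) {
  name <- match.arg(name, .mode_names)
  list(
    name = name,
    robot_active = TRUE,
    user_initiates = name != "passive",
    adaptation_enabled = name == "AA2"
  )
}

# scenario the synthetic user plays in each mode
.mode_behavior <- c(passive = "passive_lag", AA1 = "cooperative",
                    AA2 = "leading")

#' Experimental session protocol
#'
#' The schedule of the actual-performance phase: an ordered list of
#' (mode, repetitions) blocks executed over the same fixed segment order. The
#' default is the standard session — passive and AA1 once at the start, five
#' adaptive AA2 repetitions, then passive and AA1 once more at the end — over
#' the 13-segment cube workspace.
#'
#' @param segments List of [segment()] objects executed, in order, in every
#'   mode. Defaults to [cube_segments()].
#' @param schedule Data frame with columns `mode` and `reps` giving the mode
#'   blocks in execution order.
#' @param warmup Number of familiarisation passes preceding the recorded
#'   session. Warm-up executions are excluded from logs and analysis; the
#'   default 0 skips them entirely.
#' @return An object of class `reachadapt_protocol`.
#' @export
protocol <- function(segments = cube_segments(),
                     schedule = data.frame(
                       mode = c("passive", "AA1", "AA2", "passive", "AA1"),
                       reps = c(1, 1, 5, 1, 1)),
                     warmup = 0) {
  stopifnot(is.list(segments), length(segments) >= 1L,
            all(vapply(segments, inherits, logical(1), "reachadapt_segment")),
            is.data.frame(schedule),
            all(c("mode", "reps") %in% names(schedule)),
            all(schedule$reps >= 0), warmup >= 0)
  if (!all(schedule$mode %in% .mode_names)) {
    stop("unknown mode(s) in schedule: ",
         paste(setdiff(schedule$mode, .mode_names), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(segments = segments, schedule = schedule, warmup = warmup),
    class = "reachadapt_protocol"
  )
}

#' @export
print.reachadapt_protocol <- function(x, ...) {
  blocks <- paste(sprintf("%s x%d", x$schedule$mode, x$schedule$reps),
                  collapse = ", ")
  cat(sprintf("<protocol> %d segments | %s\n", length(x$segments), blocks))
  invisible(x)
}

#' Run one full session against a synthetic participant
#'
#' Executes the protocol schedule over all segments. In each mode the
#' synthetic user plays the scenario that mode elicits (passive: dragged with
#' a response lag; AA1/AA2: moving on their own clock). Duration adaptation is
#' active only during AA2 repetitions: every AA2 execution's aggregate effort
#' difference feeds [update_duration()] and the updated duration applies to
#' that segment's next AA2 iteration. Non-adaptive modes run at each segment's
#' default duration.
#'
#' The first AA2 iteration is seeded by applying one update to the initial
#' duration using the preceding AA1 pass's effort aggregate (set
#' `seed_aa2_from_aa1 = FALSE` to start AA2 at the raw initial duration
#' instead), reflecting that recorded sessions already show the first adaptive
#' repetition below the default duration.
#'
#' @param protocol A [protocol()].
#' @param user A [user_model()].
#' @param config An [adaptation_config()].
#' @param seed Integer seed; all randomness in the session derives from it.
#' @param dt Sampling interval, seconds.
#' @param seed_aa2_from_aa1 Seed the first AA2 duration from the last AA1
#'   pass (default `TRUE`).
#' @param keep_trajectories Keep every sampled trajectory in the log (memory
#'   heavy; default `FALSE`).
#' @return An object of class `session_log`: list with `log` (one tibble row
#'   per segment execution: `mode`, `pass`, `iteration`, `seg`, `duration_s`,
#'   `sum_delta_effort`, `delta_applied`), `aa2` (per-segment
#'   `duration_sequence` objects), and optionally `trajectories`.
#' @examples
#' \donttest{
#' u <- user_model("leading", preferred_duration = 1.6)
#' s <- run_session(protocol(), u, adaptation_config(), seed = 1)
#' s$aa2$seg1
#' }
#' @export
run_session <- function(protocol, user, config, seed = 1L, dt = 0.01,
                        seed_aa2_from_aa1 = TRUE, keep_trajectories = FALSE) {
  stopifnot(inherits(protocol, "reachadapt_protocol"),
            inherits(user, "user_model"),
            inherits(config, "adaptation_config"))
  segs <- protocol$segments
  nseg <- length(segs)
  cur <- rep(config$initial_duration, nseg)
  last_aa1_sum <- rep(NA_real_, nseg)
  aa2_seeded <- FALSE
  rows <- list()
  trajs <- list()
  pass_no <- 0L
  for (b in seq_len(nrow(protocol$schedule))) {
    mode <- protocol$schedule$mode[b]
    for (rep_i in seq_len(protocol$schedule$reps[b])) {
      pass_no <- pass_no + 1L
      if (mode == "AA2" && !aa2_seeded) {
        if (seed_aa2_from_aa1 && !anyNA(last_aa1_sum)) {
          for (k in seq_len(nseg)) {
            cur[k] <- update_duration(cur[k], last_aa1_sum[k], config)$duration
          }
        }
        aa2_seeded <- TRUE
      }
      for (k in seq_len(nseg)) {
        sg <- segs[[k]]
        dur <- if (mode == "AA2") cur[k] else sg$default_duration
        ref <- sample_trajectory(sg, dur, dt)
        act <- simulate_segment(sg, dur, user, dt = dt,
                                seed = seed + 1009L * pass_no + 31L * k,
                                behavior = .mode_behavior[[mode]])
        es <- summarize_efforts(ref, act, sg)
        delta <- NA_real_
        if (mode == "AA2") {
          upd <- update_duration(dur, es$sum_delta_effort, config)
          delta <- upd$delta
          cur[k] <- upd$duration
        } else if (mode == "AA1") {
          last_aa1_sum[k] <- es$sum_delta_effort
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mode = mode, pass = pass_no, iteration = rep_i, seg = sg$id,
          duration_s = dur, sum_delta_effort = es$sum_delta_effort,
          delta_applied = delta
        )
        if (keep_trajectories) {
          trajs[[length(trajs) + 1L]] <- list(
            mode = mode, pass = pass_no, seg = sg$id,
            reference = ref, actual = act)
        }
      }
    }
  }
  log <- do.call(rbind, rows)
  aa2 <- list()
  aa2_log <- log[log$mode == "AA2", ]
  if (nrow(aa2_log) > 0) {
    for (k in seq_len(nseg)) {
      sub <- aa2_log[aa2_log$seg == segs[[k]]$id, ]
      conv <- is_constant_optimum(sub$duration_s)
      aa2[[paste0("seg", segs[[k]]$id)]] <- structure(
        list(segment_id = segs[[k]]$id, durations = sub$duration_s,
             sum_delta_effort = sub$sum_delta_effort,
             delta_applied = sub$delta_applied,
             converged = conv$converged, optimum = conv$optimum),
        class = "duration_sequence")
    }
  }
  out <- list(log = log, aa2 = aa2, participant = NA_integer_)
  if (keep_trajectories) out$trajectories <- trajs
  class(out) <- "session_log"
  out
}

#' @export
print.session_log <- function(x, ...) {
  nconv <- count_converged_segments(x$aa2)
  cat(sprintf("<session_log> %d executions, %d/%d segments converged in AA2\n",
              nrow(x$log), nconv, length(x$aa2)))
  invisible(x)
}

#' Export a session's adaptation log to CSV
#'
#' Header: `participant,mode,pass,iteration,seg,duration_s,sum_delta_effort,delta_applied,converged`.
#'
#' @param session A `session_log` from [run_session()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "session_log"))
  conv <- vapply(session$aa2, function(s) s$converged, logical(1))
  seg_ids <- vapply(session$aa2, function(s) s$segment_id, integer(1))
  df <- as.data.frame(session$log)
  df$converged <- conv[match(df$seg, seg_ids)]
  df <- cbind(participant = session$participant, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
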