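# Condition coding and duration regression -------------------------------------

.main_dummies <- c("EV1", "RR1", "G1", "G2", "CB1")
.interaction_dummies <- c("EV1G1", "EV1G2", "RR1G1", "RR1G2",
                          "RR1CB1", "G1CB1", "G2CB1")

#' Dummy-code a condition profile
#'
#' Encodes the four segment conditions as 0/1 dummy variables against the
#' reference categories: Virtual (EV0), Return (RR0), Against Gravity (G0) and
#' Large cross-body (CB0). The all-reference profile is the zero vector, so a
#' regression intercept is the predicted duration for a virtual, returning,
#' against-gravity, large-cross-body segment. Interaction dummies are the
#' products of the main dummies.
#'
#' @param embedded Logical: embedded target (EV1 = 1) vs virtual (reference).
#' @param reach Logical: reaching movement (RR1 = 1) vs returning (reference).
#' @param gravity `"against"` (reference), `"towards"` (G1 = 1) or `"ground"`
#'   (G2 = 1).
#' @param cross_body `"large"` (reference) or `"small"` (CB1 = 1).
#' @param include_interactions Append the seven interaction dummies
#'   (`EV1G1`, `EV1G2`, `RR1G1`, `RR1G2`, `RR1CB1`, `G1CB1`, `G2CB1`).
#' @return Named numeric 0/1 vector.
#' @examples
#' condition_profile(embedded = TRUE, reach = FALSE, gravity = "towards",
#'                   cross_body = "small")
#' @export
condition_profile <- function(embedded = FALSE, reach = FALSE,
                              gravity = c("against", "towards", "ground"),
                              cross_body = c("large", "small"),
                              include_interactions = TRUE) {
  gravity <- match.arg(gravity)
  cross_body <- match.arg(cross_body)
  stopifnot(is.logical(embedded), is.logical(reach))
  v <- c(EV1 = as.numeric(embedded),
         RR1 = as.numeric(reach),
         G1 = as.numeric(gravity == "towards"),
         G2 = as.numeric(gravity == "ground"),
         CB1 = as.numeric(cross_body == "small"))
  if (include_interactions) {
    v <- c(v,
           EV1G1 = v[["EV1"]] * v[["G1"]],
           EV1G2 = v[["EV1"]] * v[["G2"]],
           RR1G1 = v[["RR1"]] * v[["G1"]],
           RR1G2 = v[["RR1"]] * v[["G2"]],
           RR1CB1 = v[["RR1"]] * v[["CB1"]],
           G1CB1 = v[["G1"]] * v[["CB1"]],
           G2CB1 = v[["G2"]] * v[["CB1"]])
  }
  v
}

#' Recover condition labels from a dummy profile
#'
#' Inverse of [condition_profile()] on the main dummies.
#'
#' @param profile Named numeric vector containing `EV1`, `RR1`, `G1`, `G2`,
#'   `CB1`.
#' @return List with `embedded`, `reach`, `gravity`, `cross_body`.
#' @export
decode_profile <- function(profile) {
  stopifnot(all(.main_dummies %in% names(profile)))
  if (profile[["G1"]] == 1 && profile[["G2"]] == 1) {
    stop("invalid profile: G1 and G2 cannot both be 1", call. = FALSE)
  }
  list(
    embedded = profile[["EV1"]] == 1,
    reach = profile[["RR1"]] == 1,
    gravity = if (profile[["G1"]] == 1) "towards"
              else if (profile[["G2"]] == 1) "ground" else "against",
    cross_body = if (profile[["CB1"]] == 1) "small" else "large"
  )
}

#' Dummy-code one segment execution
#'
#' Builds the full predictor vector for a segment executed by a participant:
#' condition dummies (and optionally interactions) from the segment's labels,
#' plus one 0/1 participant dummy per non-reference participant.
#'
#' @param segment A [segment()].
#' @param participant_id Integer id of the executing participant, or `NULL`
#'   to omit participant dummies.
#' @param participants Integer vector of all participant ids in the design
#'   (needed so every row has the same columns).
#' @param reference_participant Participant coded as all-zero dummies.
#' @param include_interactions Append interaction dummies.
#' @return Named numeric 0/1 vector.
#' @examples
#' segs <- cube_segments()
#' encode_segment(segs$seg6)   # embedded, return, towards gravity, small
#' @export
encode_segment <- function(segment, participant_id = NULL,
                           participants = NULL, reference_participant = 1L,
                           include_interactions = TRUE) {
  stopifnot(inherits(segment, "reachadapt_segment"))
  v <- condition_profile(segment$embedded, segment$reach, segment$gravity,
                         segment$cross_body,
                         include_interactions = include_interactions)
  if (!is.null(participant_id)) {
    if (is.null(participants)) participants <- participant_id
    others <- sort(setdiff(unique(participants), reference_participant))
    pd <- as.numeric(others == participant_id)
    names(pd) <- paste0("P", others)
    v <- c(v, pd)
  }
  v
}

# first-order autocorrelation diagnostic on a residual sequence
durbin_watson <- function(residuals) {
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Fit the duration-by-condition regression
#'
#' Ordinary least squares regression of segment execution duration on the
#' dummy-coded conditions (optionally with condition-by-condition interaction
#' variables) and participant dummies. This is the model behind the
#' condition-effect analysis: the intercept is the predicted duration for the
#' all-reference profile, and each coefficient is the duration shift (seconds)
#' attached to its dummy.
#'
#' @param records Data frame with one row per segment execution: `duration_s`,
#'   condition labels (`embedded`, `reach` logicals; `gravity`, `cross_body`
#'   character), and optionally `participant`.
#' @param include_interactions Include the seven interaction dummies (the
#'   richer of the two standard models).
#' @param reference_participant Participant coded as the reference (no dummy).
#' @return An object of class `regression_fit`: list with `model` (the `lm`
#'   fit), `coefficients` (tibble `term`, `b`, `se`, `beta`, `t`, `p`),
#'   `r_squared`, `adj_r_squared`, `durbin_watson`, `n`, `n_predictors`,
#'   `terms`.
#' @export
fit_duration_model <- function(records, include_interactions = FALSE,
                               reference_participant = 1L) {
  req <- c("duration_s", "embedded", "reach", "gravity", "cross_body")
  if (!all(req %in% names(records))) {
    stop("records need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  stopifnot(n >= 3L)
  prof <- t(mapply(function(e, r, g, cb)
    condition_profile(e, r, g, cb, include_interactions = include_interactions),
    records$embedded, records$reach, records$gravity, records$cross_body))
  X <- as.data.frame(prof)
  if ("participant" %in% names(records)) {
    others <- sort(setdiff(unique(records$participant), reference_participant))
    for (p in others) {
      X[[paste0("P", p)]] <- as.numeric(records$participant == p)
    }
  }
  # drop dummies with no variation in this design (absent categories)
  constant <- vapply(X, function(col) length(unique(col)) < 2L, logical(1))
  X <- X[!constant]
  dat <- cbind(duration_s = records$duration_s, X)
  fit <- stats::lm(duration_s ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- rownames(ct)
  sdy <- stats::sd(records$duration_s)
  beta <- vapply(terms, function(tm) {
    if (tm == "(Intercept)") NA_real_
    else ct[tm, "Estimate"] * stats::sd(dat[[tm]]) / sdy
  }, numeric(1))
  structure(
    list(
      model = fit,
      coefficients = tibble::tibble(
        term = terms, b = ct[, "Estimate"], se = ct[, "Std. Error"],
        beta = unname(beta), t = ct[, "t value"], p = ct[, "Pr(>|t|)"]),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      durbin_watson = durbin_watson(stats::residuals(fit)),
      n = n,
      n_predictors = length(X),
      terms = names(X)
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> n = %d, %d predictors, R^2 = %.3f (adj %.3f), DW = %.3f\n",
    x$n, x$n_predictors, x$r_squared, x$adj_r_squared, x$durbin_watson))
  invisible(x)
}

#' Nested-model change statistics
#'
#' R-squared change and the F test for the additional predictors of a full
#' model over a restricted model fitted to the same observations:
#' `F = ((R2_full - R2_restricted) / df1) / ((1 - R2_full) / df2)` with
#' `df1` the number of added predictors and `df2` the full model's residual
#' degrees of freedom.
#'
#' @param restricted,full `regression_fit` objects; the restricted model's
#'   predictors must be a subset of the full model's, fitted on the same `n`.
#' @return A list with `r2_change`, `f_change`, `df1`, `df2`, `p`.
#' @export
change_statistics <- function(restricted, full) {
  stopifnot(inherits(restricted, "regression_fit"),
            inherits(full, "regression_fit"))
  if (restricted$n != full$n) {
    stop("models were fitted on different numbers of observations",
         call. = FALSE)
  }
  if (!all(restricted$terms %in% full$terms)) {
    stop("models are not nested: restricted has predictors absent from full",
         call. = FALSE)
  }
  df1 <- full$n_predictors - restricted$n_predictors
  df2 <- full$n - full$n_predictors - 1L
  f_change(restricted$r_squared, full$r_squared, df1, df2)
}

#' @rdname change_statistics
#' @param r2_restricted,r2_full R-squared of the two nested models.
#' @param df1 Number of predictors added by the full model.
#' @param df2 Residual degrees of freedom of the full model.
#' @details `f_change()` computes the same statistic directly from two
#'   R-squared values and degrees of freedom, e.g. from a published model
#'   summary.
#' @export
f_change <- function(r2_restricted, r2_full, df1, df2) {
  stopifnot(r2_full >= r2_restricted - 1e-12, df1 >= 0, df2 > 0)
  r2c <- r2_full - r2_restricted
  f <- if (df1 == 0) 0 else (r2c / df1) / ((1 - r2_full) / df2)
  p <- if (df1 == 0) NA_real_ else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(r2_change = r2c, f_change = f, df1 = df1, df2 = df2, p = p)
}

# normalise coefficient containers to a named numeric vector with "(Intercept)"
as_coef_vector <- function(coefficients) {
  v <- if (inherits(coefficients, "regression_fit")) {
    stats::setNames(coefficients$coefficients$b, coefficients$coefficients$term)
  } else if (is.data.frame(coefficients)) {
    key <- if ("symbol" %in% names(coefficients)) coefficients$symbol
           else coefficients$term
    stats::setNames(coefficients$b, key)
  } else if (is.numeric(coefficients) && !is.null(names(coefficients))) {
    coefficients
  } else {
    stop("cannot interpret `coefficients`", call. = FALSE)
  }
  ic <- names(v) %in% c("(Intercept)", "(Constant)", "Constant", "b0")
  if (sum(ic) != 1L) stop("coefficients need exactly one intercept term",
                          call. = FALSE)
  names(v)[ic] <- "(Intercept)"
  v
}

#' Predicted duration for a condition profile
#'
#' Evaluates the fitted linear model at a dummy profile:
#' `b0 + sum(b_i * x_i)`. Coefficients may come from [fit_duration_model()],
#' from the packaged published-coefficients fixture, or be a named numeric
#' vector with an intercept.
#'
#' @param coefficients A `regression_fit`, a data frame with columns
#'   `symbol`/`term` and `b`, or a named numeric vector including an
#'   intercept term.
#' @param profile Named numeric dummy vector, e.g. from [condition_profile()].
#'   Every nonzero entry must have a matching coefficient.
#' @return Predicted duration in seconds.
#' @examples
#' coefs <- load_fixture("model2_coefficients")
#' predict_duration(coefs, condition_profile(embedded = TRUE,
#'                                           gravity = "towards"))
#' @export
predict_duration <- function(coefficients, profile) {
  v <- as_coef_vector(coefficients)
  stopifnot(is.numeric(profile), !is.null(names(profile)))
  active <- names(profile)[profile != 0]
  missing <- setdiff(active, names(v))
  if (length(missing) > 0) {
    stop("profile activates predictors with no coefficient: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unname(v[["(Intercept)"]] + sum(v[active] * profile[active]))
}

#' Predicted-duration grid over presentation/movement-type and gravity
#'
#' Evaluates the interaction model over the standard 4 x 3 grid of condition
#' combinations: rows Virtual, Embedded, Return, Reach; columns against,
#' towards and ground-level gravity. Each cell activates only the named
#' condition(s) and their interaction, with everything else at reference
#' (Virtual and Return rows therefore coincide: both are all-reference on
#' their factor).
#'
#' @inheritParams predict_duration
#' @param digits Rounding for the reported cells (default 3).
#' @return Tibble with columns `condition`, `against`, `towards`, `ground`.
#' @export
condition_duration_table <- function(coefficients, digits = 3) {
  rows <- list(
    Virtual  = list(embedded = FALSE, reach = FALSE),
    Embedded = list(embedded = TRUE,  reach = FALSE),
    Return   = list(embedded = FALSE, reach = FALSE),
    Reach    = list(embedded = FALSE, reach = TRUE)
  )
  gl <- c("against", "towards", "ground")
  cells <- sapply(gl, function(g) {
    vapply(rows, function(r) {
      predict_duration(coefficients,
                       condition_profile(embedded = r$embedded,
                                         reach = r$reach, gravity = g))
    }, numeric(1), USE.NAMES = FALSE)
  })
  tibble::tibble(
    condition = names(rows),
    against = round(cells[, "against"], digits),
    towards = round(cells[, "towards"], digits),
    ground = round(cells[, "ground"], digits)
  )
}

#' Build regression records from simulated sessions
#'
#' Flattens a cohort of session logs into the analysis input: one row per AA2
#' segment execution with the recorded duration and the segment's condition
#' labels.
#'
#' @param cohort A `cohort_log` from [simulate_cohort()] (or a list of
#'   `session_log`s).
#' @param segments The segment list the sessions were run over.
#' @param modes Which modes to keep (default `"AA2"`, the adaptive records).
#' @return Tibble with columns `participant`, `seg`, `iteration`,
#'   `duration_s`, `embedded`, `reach`, `gravity`, `cross_body`.
#' @export
session_records <- function(cohort, segments = cube_segments(),
                            modes = "AA2") {
  seg_ids <- vapply(segments, function(s) s$id, integer(1))
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    lg <- s$log[s$log$mode %in% modes, ]
    k <- match(lg$seg, seg_ids)
    tibble::tibble(
      participant = if (is.na(s$participant)) i else s$participant,
      seg = lg$seg, iteration = lg$iteration, duration_s = lg$duration_s,
      embedded = vapply(k, function(j) segments[[j]]$embedded, logical(1)),
      reach = vapply(k, function(j) segments[[j]]$reach, logical(1)),
      gravity = vapply(k, function(j) segments[[j]]$gravity, character(1)),
      cross_body = vapply(k, function(j) segments[[j]]$cross_body, character(1))
    )
  })
  do.call(rbind, rows)
}

#' Convergence summaries across a cohort
#'
#' `iteration_level_summary()` counts, per participant, how many segments
#' reached a constant optimum duration within the AA2 repetitions;
#' `segment_level_summary()` counts, per segment, how many participants did.
#'
#' @param cohort A `cohort_log` (or list of `session_log`s).
#' @return A tibble: `participant`, `n_converged` (iteration level) or
#'   `seg`, `n_converged` (segment level).
#' @export
iteration_level_summary <- function(cohort) {
  tibble::tibble(
    participant = vapply(seq_along(cohort), function(i) {
      p <- cohort[[i]]$participant
      if (is.na(p)) i else p
    }, numeric(1)),
    n_converged = vapply(cohort, function(s)
      count_converged_segments(s$aa2), numeric(1), USE.NAMES = FALSE)
  )
}

#' @rdname iteration_level_summary
#' @export
segment_level_summary <- function(cohort) {
  stopifnot(length(cohort) >= 1L)
  seg_ids <- vapply(cohort[[1]]$aa2, function(s) s$segment_id, integer(1),
                    USE.NAMES = FALSE)
  counts <- vapply(seq_along(seg_ids), function(k) {
    sum(vapply(cohort, function(s) s$aa2[[k]]$converged, logical(1)))
  }, numeric(1))
  tibble::tibble(seg = seg_ids, n_converged = counts)
}
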