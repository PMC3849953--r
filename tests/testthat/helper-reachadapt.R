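# Shared fixtures and independent oracles for the test suite

# a simple unit segment along x with ground-level labels
toy_segment <- function(length = 1, id = 1L, duration = 4) {
  segment(id, source = c(0, 0, 0), target = c(length, 0, 0),
          embedded = FALSE, reach = TRUE, gravity = "ground",
          cross_body = "small", default_duration = duration)
}

# brute-force OLS by normal equations (independent of lm)
ols_brute <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# independent dummy coding written out longhand (oracle for condition_profile)
dummies_longhand <- function(embedded, reach, gravity, cross_body,
                             interactions = FALSE) {
  ev1 <- if (embedded) 1 else 0
  rr1 <- if (reach) 1 else 0
  g1 <- if (gravity == "towards") 1 else 0
  g2 <- if (gravity == "ground") 1 else 0
  cb1 <- if (cross_body == "small") 1 else 0
  out <- c(EV1 = ev1, RR1 = rr1, G1 = g1, G2 = g2, CB1 = cb1)
  if (interactions) {
    out <- c(out, EV1G1 = ev1 * g1, EV1G2 = ev1 * g2, RR1G1 = rr1 * g1,
             RR1G2 = rr1 * g2, RR1CB1 = rr1 * cb1, G1CB1 = g1 * cb1,
             G2CB1 = g2 * cb1)
  }
  out
}

# shift a trajectory in time by `lag` seconds, clamping at the endpoints:
# the shifted trace holds the first sample before onset and the last after
shift_trajectory <- function(traj, lag) {
  shifted <- traj$t - lag
  interp <- function(col) stats::approx(traj$t, traj[[col]], xout = shifted,
                                        rule = 2)$y
  tibble::tibble(t = traj$t, x = interp("x"), y = interp("y"),
                 z = interp("z"))
}

# random rigid transform (rotation + translation), seeded by the caller
random_rigid <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, shift = stats::rnorm(3, sd = 0.5))
}

apply_rigid <- function(points, rt) {
  if (is.matrix(points)) {
    sweep(points %*% t(rt$R), 2, -rt$shift)
  } else {
    drop(rt$R %*% points) + rt$shift
  }
}
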