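test_that("tau maps the segment window linearly onto [-1, 1]", {
  expect_equal(tau(2, 6, 2), -1)
  expect_equal(tau(2, 6, 6), 1)
  expect_equal(tau(2, 6, 4), 0)
  expect_equal(tau(0, 1, c(0, 0.25, 0.5, 1)), c(-1, -0.5, 0, 1))
  expect_error(tau(2, 6, 6.5), "within")
  expect_error(tau(2, 2, 2), "exceed")
})

test_that("effort projection is the signed axial coordinate", {
  src <- c(0, 0, 0); tgt <- c(2, 0, 0)
  expect_equal(effort_projection(src, src, tgt), 0)
  expect_equal(effort_projection(tgt, src, tgt), 2)
  expect_equal(effort_projection(c(1, 1, 0), src, tgt), 1)
  # behind source and overshoot are signed
  expect_equal(effort_projection(c(-0.5, 3, 1), src, tgt), -0.5)
  expect_equal(effort_projection(c(2.4, 0, 0), src, tgt), 2.4)
  expect_error(effort_projection(c(1, 1, 0), src, src), "degenerate")
})

test_that("delta effort is positive when the participant is behind", {
  src <- c(0, 0, 0); tgt <- c(0, 0.4, 0)
  expect_equal(delta_effort(c(0, 0.2, 0), c(0, 0.2, 0), src, tgt), 0)
  expect_equal(delta_effort(tgt, src, src, tgt), 0.4)   # maximal lag
  expect_equal(delta_effort(src, tgt, src, tgt), -0.4)  # maximal lead
})

test_that("effort summary matches a brute-force oracle on a toy trajectory", {
  seg <- toy_segment(length = 1, duration = 1)
  ref <- sample_trajectory(seg, 1, dt = 1 / 9)  # 10 samples
  expect_equal(summarize_efforts(ref, ref, seg)$sum_delta_effort, 0)

  lag <- 2 / 9  # two sample intervals, so the shifted times stay on the grid
  delayed <- shift_trajectory(ref, lag)
  # oracle: explicit per-sample loop over axial positions
  expected <- 0
  for (i in seq_len(nrow(ref))) {
    t_shift <- max(ref$t[i] - lag, 0)
    expected <- expected + mjt_sigma(ref$t[i]) - mjt_sigma(t_shift)
  }
  got <- summarize_efforts(ref, delayed, seg)
  expect_equal(got$sum_delta_effort, expected, tolerance = 1e-9)
  expect_gt(got$sum_delta_effort, 0)
  expect_equal(got$n_samples, 10L)
  expect_equal(got$series$delta_effort,
               got$series$effort_mjt - got$series$effort_actual)
  expect_equal(got$series$tau[c(1, 10)], c(-1, 1))

  advanced <- shift_trajectory(ref, -lag)
  expect_lt(summarize_efforts(ref, advanced, seg)$sum_delta_effort, 0)
})

test_that("swapping reference and achieved negates every effort difference", {
  seg <- toy_segment(0.4, duration = 2)
  ref <- sample_trajectory(seg, 2, 0.05)
  act <- shift_trajectory(ref, 0.3)
  a <- summarize_efforts(ref, act, seg)
  b <- summarize_efforts(act, ref, seg)
  expect_equal(b$series$delta_effort, -a$series$delta_effort, tolerance = 1e-12)
  expect_equal(b$sum_delta_effort, -a$sum_delta_effort, tolerance = 1e-12)
})

test_that("effort projections are invariant under rigid motion", {
  seg <- toy_segment(0.4, duration = 2)
  ref <- sample_trajectory(seg, 2, 0.1)
  act <- shift_trajectory(ref, 0.25)
  base <- summarize_efforts(ref, act, seg)
  withr::with_seed(7, {
    for (i in 1:5) {
      rt <- random_rigid()
      seg2 <- segment(seg$id, source = apply_rigid(seg$source, rt),
                      target = apply_rigid(seg$target, rt),
                      embedded = seg$embedded, reach = seg$reach,
                      gravity = seg$gravity, cross_body = seg$cross_body)
      tf <- function(tr) {
        m <- apply_rigid(cbind(tr$x, tr$y, tr$z), rt)
        tibble::tibble(t = tr$t, x = m[, 1], y = m[, 2], z = m[, 3])
      }
      moved <- summarize_efforts(tf(ref), tf(act), seg2)
      expect_equal(moved$series$delta_effort, base$series$delta_effort,
                   tolerance = 1e-9)
    }
  })
})

test_that("sampling density scales the raw aggregate but not its sign", {
  seg <- toy_segment(0.4, duration = 2)
  sums <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    ref <- sample_trajectory(seg, 2, dt)
    summarize_efforts(ref, shift_trajectory(ref, 0.3), seg)$sum_delta_effort
  }, numeric(1))
  expect_true(all(sums > 0))
  # halving dt roughly doubles the raw aggregate
  expect_equal(sums[2] / sums[1], 2, tolerance = 0.02)
  expect_equal(sums[3] / sums[2], 2, tolerance = 0.02)
  # the time-weighted aggregate is density-invariant
  tw <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    ref <- sample_trajectory(seg, 2, dt)
    summarize_efforts(ref, shift_trajectory(ref, 0.3), seg,
                      time_weighted = TRUE)$sum_delta_effort
  }, numeric(1))
  expect_equal(tw[1], tw[3], tolerance = 1e-3)
})

test_that("segment magnitude and normalised duration follow their formulas", {
  expect_equal(segment_magnitude(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(segment_magnitude(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(segment_magnitude(c(0, 0, 0), c(1, 1, 1)), sqrt(3))
  expect_equal(normalized_duration(4, 0.4), 10)
  # final recorded duration of the worked-example session over its length
  expect_equal(normalized_duration(1.6, 0.320), 5.0)
  expect_equal(normalized_duration(0, 0.3), 0)
  expect_error(normalized_duration(2, 0), "degenerate")
})

test_that("constant-optimum rule keys on the trailing run only", {
  r <- is_constant_optimum(c(3, 2, 1.6, 1.6, 1.6))
  expect_true(r$converged); expect_equal(r$optimum, 1.6)
  expect_false(is_constant_optimum(c(3.4, 2.4, 2.2, 1.6, 1.8))$converged)
  # a mid-sequence plateau does not count; the trailing run does
  r2 <- is_constant_optimum(c(3, 2.8, 2.8, 2.6, 2.6))
  expect_true(r2$converged); expect_equal(r2$optimum, 2.6)
  expect_false(is_constant_optimum(c(2, 2, 2, 1.8))$converged)
  expect_false(is_constant_optimum(c(3, 2.5, 2))$converged)
  # prepending anything before a qualifying trailing run never changes it
  withr::with_seed(3, {
    for (i in 1:10) {
      run <- rep(round(runif(1, 1, 3), 1), sample(2:4, 1))
      prefix <- round(runif(sample(0:5, 1), 1, 4), 1)
      r <- is_constant_optimum(c(prefix, run))
      expect_true(r$converged)
      expect_equal(r$optimum, run[1])
    }
  })
  # longer min_run is stricter
  expect_false(is_constant_optimum(c(3, 1.6, 1.6), min_run = 3)$converged)
  expect_true(is_constant_optimum(c(1.6, 1.6, 1.6), min_run = 3)$converged)
})

test_that("converged-segment counting accepts vectors and sequence objects", {
  expect_equal(count_converged_segments(replicate(13, rep(2, 5),
                                                  simplify = FALSE)), 13)
  dec <- lapply(1:5, function(i) seq(4, 2, length.out = 5))
  expect_equal(count_converged_segments(dec), 0)
  mixed <- list(c(3, 2, 2), c(3, 2, 1), is_constant_optimum(c(2, 2)))
  expect_equal(count_converged_segments(mixed), 2)
})
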