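test_that("segment condition coding matches the reference-category scheme", {
  segs <- cube_segments()
  # embedded, return, towards gravity, small cross-body
  v6 <- encode_segment(segs$seg6)
  expect_equal(v6[c("EV1", "RR1", "G1", "G2", "CB1")],
               c(EV1 = 1, RR1 = 0, G1 = 1, G2 = 0, CB1 = 1))
  expect_equal(v6[c("EV1G1", "G1CB1")], c(EV1G1 = 1, G1CB1 = 1))
  expect_equal(sum(v6), 5)  # no other dummy active
  # all-reference profile: virtual, return, against gravity, large
  expect_equal(sum(encode_segment(segs$seg13)), 0)
  # embedded, reach, ground level, large
  v1 <- encode_segment(segs$seg1)
  expect_equal(v1[v1 != 0],
               c(EV1 = 1, RR1 = 1, G2 = 1, EV1G2 = 1, RR1G2 = 1))
  # participant dummies: one column per non-reference participant
  vp <- encode_segment(segs$seg13, participant_id = 3, participants = 1:4)
  expect_equal(vp[c("P2", "P3", "P4")], c(P2 = 0, P3 = 1, P4 = 0))
  expect_false("P1" %in% names(vp))
})

test_that("coding agrees with a longhand oracle and round-trips labels", {
  segs <- cube_segments()
  for (s in segs) {
    expect_equal(
      encode_segment(s),
      dummies_longhand(s$embedded, s$reach, s$gravity, s$cross_body,
                       interactions = TRUE))
    lab <- decode_profile(condition_profile(s$embedded, s$reach, s$gravity,
                                            s$cross_body))
    expect_equal(lab$embedded, s$embedded)
    expect_equal(lab$reach, s$reach)
    expect_equal(lab$gravity, s$gravity)
    expect_equal(lab$cross_body, s$cross_body)
  }
  expect_error(decode_profile(c(EV1 = 0, RR1 = 0, G1 = 1, G2 = 1, CB1 = 0)),
               "both")
})

# every combination of the four condition labels
all_label_combos <- function() {
  expand.grid(embedded = c(FALSE, TRUE), reach = c(FALSE, TRUE),
              gravity = c("against", "towards", "ground"),
              cross_body = c("large", "small"),
              stringsAsFactors = FALSE)
}

test_that("known coefficients are recovered from near-noiseless data", {
  b_true <- c(6, -3.5, 4.4, 0.1, 1.8, 0.7, 4.2, 2.8, -2.7, -3.8, -1.4, -0.4, 0.3)
  combos <- all_label_combos()
  X <- t(mapply(condition_profile, combos$embedded, combos$reach,
                combos$gravity, combos$cross_body))
  recs <- tibble::as_tibble(combos)
  withr::with_seed(13, {
    recs$duration_s <- drop(cbind(1, X) %*% b_true) + rnorm(nrow(X), sd = 1e-8)
  })
  fit <- fit_duration_model(recs, include_interactions = TRUE)
  expect_equal(unname(fit$coefficients$b), b_true, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("degenerate designs collapse to the intercept or are rejected", {
  # all records share one condition profile: intercept-only fit
  recs <- tibble::tibble(embedded = TRUE, reach = TRUE, gravity = "towards",
                         cross_body = "small", duration_s = c(2, 3, 4, 7))
  fit <- fit_duration_model(recs)
  expect_equal(fit$coefficients$b[fit$coefficients$term == "(Intercept)"],
               mean(recs$duration_s))
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$n_predictors, 0)
})

test_that("OLS estimates match normal-equations brute force on random designs", {
  combos <- all_label_combos()
  done <- 0
  withr::with_seed(17, {
    while (done < 50) {
      rows <- combos[sample(nrow(combos), 10, replace = TRUE), ]
      recs <- tibble::as_tibble(rows)
      recs$duration_s <- runif(10, 1, 9)
      fit <- tryCatch(fit_duration_model(recs), error = function(e) NULL)
      if (is.null(fit)) next  # rank-deficient draw; try another design
      Xo <- t(mapply(dummies_longhand, rows$embedded, rows$reach,
                     rows$gravity, rows$cross_body))
      Xo <- Xo[, fit$terms, drop = FALSE]  # same non-constant columns
      expect_equal(unname(fit$coefficients$b),
                   unname(ols_brute(cbind(1, Xo), recs$duration_s)),
                   tolerance = 1e-9)
      done <- done + 1
    }
  })
  expect_equal(done, 50)
})

simulated_records <- function() {
  u <- user_model("leading", preferred_duration = 2, noise_sd = 0.002,
                  condition_factors = list(embedded = 0.85, reach = 1.2,
                                           towards = 0.95))
  sched <- data.frame(mode = c("AA1", "AA2"), reps = c(1, 4))
  co <- simulate_cohort(4, protocol(schedule = sched), u, adaptation_config(),
                        seed = 31, dt = 0.02)
  session_records(co)
}

test_that("fit statistics behave like OLS and match independent diagnostics", {
  recs <- simulated_records()
  fit1 <- fit_duration_model(recs)
  fit2 <- fit_duration_model(recs, include_interactions = TRUE)
  # adjusted R^2 never exceeds R^2; R^2 never decreases with more predictors
  expect_lte(fit1$adj_r_squared, fit1$r_squared)
  expect_lte(fit2$adj_r_squared, fit2$r_squared)
  expect_gte(fit2$r_squared, fit1$r_squared - 1e-12)
  # with an intercept the fitted values average to the sample mean
  expect_equal(mean(fitted(fit1$model)), mean(recs$duration_s),
               tolerance = 1e-9)
  # Durbin-Watson agrees with the standard test statistic
  expect_equal(fit1$durbin_watson,
               unname(lmtest::dwtest(fit1$model)$statistic),
               tolerance = 1e-9)
  # planted effects are recovered with the right signs:
  # embedded targets shorten durations, reaching lengthens them
  b <- setNames(fit1$coefficients$b, fit1$coefficients$term)
  expect_lt(b[["EV1"]], 0)
  expect_gt(b[["RR1"]], 0)
})

test_that("nested-model change statistics follow the F formula", {
  recs <- simulated_records()
  fit1 <- fit_duration_model(recs)
  fit2 <- fit_duration_model(recs, include_interactions = TRUE)
  cs <- change_statistics(fit1, fit2)
  expect_equal(cs$r2_change, fit2$r_squared - fit1$r_squared)
  expect_equal(cs$df1, fit2$n_predictors - fit1$n_predictors)
  # cross-check against the residual-sum-of-squares form of the same test
  av <- anova(fit1$model, fit2$model)
  expect_equal(cs$f_change, av$F[2], tolerance = 1e-9)
  expect_equal(cs$p, av$`Pr(>F)`[2], tolerance = 1e-9)
  # identical models: zero change
  same <- change_statistics(fit1, fit1)
  expect_equal(same$r2_change, 0)
  expect_equal(same$f_change, 0)
  # non-nested rejection
  expect_error(change_statistics(fit2, fit1), "nested")
})

test_that("adding a pure-noise predictor yields well-calibrated p-values", {
  withr::with_seed(41, {
    ps <- replicate(200, {
      n <- 40
      x <- rnorm(n); z <- rnorm(n)
      y <- 1 + 0.5 * x + rnorm(n)
      r2r <- summary(lm(y ~ x))$r.squared
      r2f <- summary(lm(y ~ x + z))$r.squared
      f_change(r2r, r2f, 1, n - 3)$p
    })
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("published coefficients reproduce the worked substitution examples", {
  coefs <- load_fixture("model2_coefficients")
  # embedded x towards-gravity: b0 + b_EV1 + b_G1 + b_EV1G1
  expect_equal(
    predict_duration(coefs, condition_profile(embedded = TRUE,
                                              gravity = "towards")),
    6.358 - 3.477 + 0.117 + 4.193, tolerance = 1e-12)
  expect_equal(round(predict_duration(
    coefs, condition_profile(embedded = TRUE, gravity = "towards")), 3), 7.191)
  # all-reference profile: the constant
  expect_equal(predict_duration(coefs, condition_profile()), 6.358)
  # embedded main effect only
  expect_equal(round(predict_duration(
    coefs, condition_profile(embedded = TRUE)), 3), 2.881)
  # a profile naming an unknown predictor is rejected
  expect_error(predict_duration(coefs, c(EV9 = 1)), "no coefficient")
})

test_that("the condition-duration grid reproduces the exactly-derivable cells", {
  tab <- condition_duration_table(load_fixture("model2_coefficients"))
  expect_equal(tab$against[tab$condition == "Virtual"], 6.358)
  expect_equal(tab$towards[tab$condition == "Virtual"], 6.475)
  expect_equal(tab$against[tab$condition == "Embedded"], 2.881)
  expect_equal(tab$towards[tab$condition == "Embedded"], 7.191)
  expect_equal(tab$ground[tab$condition == "Embedded"], 7.543)
  # Return is all-reference on its factor, so it equals the Virtual row
  expect_equal(tab[tab$condition == "Return", -1],
               tab[tab$condition == "Virtual", -1])
})

test_that("cohort summaries count converged segments at both levels", {
  sched <- data.frame(mode = "AA2", reps = 3)
  co <- simulate_cohort(3, protocol(schedule = sched),
                        user_model("cooperative"), adaptation_config(),
                        seed = 8, dt = 0.05)
  it <- iteration_level_summary(co)
  expect_equal(it$n_converged, rep(13, 3))  # perfect followers converge at 4 s
  sg <- segment_level_summary(co)
  expect_equal(sg$n_converged, rep(3, 13))
  expect_equal(sg$seg, 1:13)
})
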