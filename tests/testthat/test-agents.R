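test_that("agent parameter validation enforces the declared invariants", {
  expect_error(agent_params(hit_prob_congruent = 0.2,
                            hit_prob_incongruent = 0.5), ">=")
  expect_error(agent_params(gaze_noise_sd = -1), ">= 0")
  expect_error(agent_params(response_zeta = 0), "> 0")
})

test_that("pupil traces follow the closed-form kernel when noiseless", {
  ag <- agent_params(pupil_noise_sd = 0, blink_rate = 0,
                     pupil_baseline = 3.5, pupil_gain = 1)
  t <- seq(-0.5, 4, by = 1 / 90)

  # zero surprise: flat at baseline
  tr <- synth_pupil_trace(0, ag, t, seed = 1)
  expect_equal(tr$pupil_left_mm, rep(3.5, length(t)))
  expect_identical(tr$pupil_left_mm, tr$pupil_right_mm)

  # peak delta equals gain * surprise * max(kernel); the kernel max of 1
  # falls exactly on the grid at 1 s post-release
  tr <- synth_pupil_trace(0.69, ag, t, seed = 1)
  expect_equal(max(tr$pupil_left_mm) - 3.5, 0.69, tolerance = 1e-12)
  expect_equal(tr$t_s[which.max(tr$pupil_left_mm)], 1)
  # no pre-release response
  expect_equal(tr$pupil_left_mm[tr$t_s <= 0], rep(3.5, sum(t <= 0)))
})

test_that("blinks appear as missing runs at the configured rate", {
  ag <- agent_params(blink_rate = 40)
  t <- seq(-0.5, 4, by = 1 / 90)
  tr <- synth_pupil_trace(1, ag, t, seed = 3)
  expect_true(any(!tr$valid_left))
  expect_true(all(is.na(tr$pupil_left_mm[!tr$valid_left])))
  expect_true(all(!tr$valid_left == !tr$valid_right))
  # a blink-free agent has full validity
  tr0 <- synth_pupil_trace(1, agent_params(blink_rate = 0), t, seed = 3)
  expect_true(all(tr0$valid_left))
})

test_that("gaze traces fixate the chosen hole and pursue the ball", {
  geom <- court_geometry()
  ball <- ball_flight("right", geom)
  t <- seq(-0.5, 1.5, by = 1 / 90)

  # noiseless, congruent, zero lag: gaze rides the ball, min error 0
  ag0 <- agent_params(gaze_noise_sd = 0, pursuit_lag = 0)
  g <- synth_gaze_trace("right", ball, ag0, geom, t, seed = 1)
  expect_equal(g$gaze_x_m[t < 0], rep(3.67, sum(t < 0)))
  gd <- dir_from_yaw_pitch(g$gaze_yaw_deg, g$gaze_pitch_deg)
  fl <- t >= 0 & t <= attr(ball, "flight_time")
  bx <- stats::approx(ball$t_s, ball$ball_x_m, t[fl])$y
  by <- stats::approx(ball$t_s, ball$ball_y_m, t[fl])$y
  bz <- stats::approx(ball$t_s, ball$ball_z_m, t[fl])$y
  yp <- yaw_pitch_from_point(bx, by, bz, c(0, geom$eye_height, 0))
  bd <- dir_from_yaw_pitch(yp$yaw_deg, yp$pitch_deg)
  expect_equal(min_gaze_ball_error(gd[fl, ], bd), 0, tolerance = 1e-9)

  # fixation mean lies within noise of the hole position
  ag <- agent_params(gaze_noise_sd = 0.1)
  g <- synth_gaze_trace("left", ball, ag, geom, t, seed = 2)
  pre <- g$gaze_x_m[t < 0]
  expect_lt(abs(mean(pre) + 3.67), 4 * 0.1 / sqrt(length(pre)) + 0.05)

  # incongruent fixation: initial gaze-ball separation is the inter-hole
  # angle (~85 degrees)
  g <- synth_gaze_trace("left", ball, ag0, geom, t, seed = 1)
  gd <- dir_from_yaw_pitch(g$gaze_yaw_deg, g$gaze_pitch_deg)
  i0 <- which(t >= 0)[1]
  yp0 <- yaw_pitch_from_point(ball$ball_x_m[1], ball$ball_y_m[1],
                              ball$ball_z_m[1], c(0, geom$eye_height, 0))
  bd0 <- dir_from_yaw_pitch(yp0$yaw_deg, yp0$pitch_deg)
  a0 <- min_gaze_ball_error(gd[i0, , drop = FALSE], bd0)
  expect_equal(a0, 85, tolerance = 3)
})

test_that("sessions are reproducible and respect the trial schedule", {
  ag <- agent_params()
  s1 <- simulate_session(ag, seed = 9)
  s2 <- simulate_session(ag, seed = 9)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$timeseries, s2$timeseries)
  s3 <- simulate_session(ag, seed = 10)
  expect_false(identical(s1$trials, s3$trials))

  counts <- dplyr::count(s1$trials, block, congruency_label)
  expect_equal(counts$n[counts$block == "pbac"], c(40, 10))
  # one timeseries per scheduled trial
  keys_tr <- unique(paste(s1$trials$block, s1$trials$trial_index))
  keys_ts <- unique(paste(s1$timeseries$block, s1$timeseries$trial_index))
  expect_setequal(keys_tr, keys_ts)
  # matched block replicates the pbac side sequence bit for bit
  expect_identical(s1$trials$release_side[s1$trials$block == "matched"],
                   s1$trials$release_side[s1$trials$block == "pbac"])
})

test_that("a decisive left-biased agent yields 40 left / 10 right releases", {
  ag <- agent_params(
    response_zeta = Inf,
    model_params = hgf_params(mu2_0 = 5, sigma2_0 = 0.1, omega2 = -40,
                              omega3 = -40, sigma3_0 = 1e-6))
  s <- simulate_session(ag, design = list(likely_side = "left"), seed = 4)
  pb <- dplyr::filter(s$trials, block == "pbac")
  expect_true(all(pb$gaze_side == "left"))
  expect_equal(sum(pb$release_side == "left"), 40)
  expect_equal(sum(pb$release_side == "right"), 10)
})

test_that("hit rates track the congruency-dependent probabilities", {
  ag <- agent_params(hit_prob_congruent = 0.8, hit_prob_incongruent = 0.3)
  s <- simulate_session(ag, seed = 21)
  tr <- dplyr::filter(s$trials, condition != "practice")
  congruent <- tr$gaze_side == tr$release_side
  p_hat <- mean(tr$hit[congruent])
  n <- sum(congruent)
  expect_lt(abs(p_hat - 0.8), 4 * sqrt(0.8 * 0.2 / n))
  p_hat_i <- mean(tr$hit[!congruent])
  expect_lt(abs(p_hat_i - 0.3), 4 * sqrt(0.3 * 0.7 / sum(!congruent)))
})

test_that("unexpected PbAC trials carry strictly larger surprisal", {
  ag <- agent_params(response_zeta = Inf)
  s <- simulate_session(ag, seed = 6)
  pb <- dplyr::filter(s$trials, block == "pbac")
  # with gaze locked to the belief side, every unexpected outcome is at
  # least as improbable under the agent's prediction as any expected one
  expect_gte(min(pb$surprise[pb$congruency_label == "unexpected"]),
             max(pb$surprise[pb$congruency_label == "expected"]))
  expect_gt(mean(pb$surprise[pb$congruency_label == "unexpected"]),
            mean(pb$surprise[pb$congruency_label == "expected"]))
})

test_that("open-loop choices are reproducible and graded in the prediction", {
  u <- as.integer(make_congruency_schedule(100, 20, 3) == "expected")
  ch1 <- simulate_agent_choices(u, agent_params(), seed = 2)
  ch2 <- simulate_agent_choices(u, agent_params(), seed = 2)
  expect_identical(ch1, ch2)
  expect_true(all(ch1$p_choice >= 0 & ch1$p_choice <= 1))
  # decisive agents follow their beliefs exactly
  chd <- simulate_agent_choices(u, agent_params(response_zeta = Inf),
                                seed = 2)
  expect_true(all(chd$y == as.integer(chd$muhat1 > 0.5) |
                    chd$muhat1 == 0.5))
})
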