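test_that("gaze filtering preserves constants and kills spikes", {
  expect_equal(filter_gaze(rep(2.5, 200)), rep(2.5, 200), tolerance = 1e-6)

  x <- rep(0, 200)
  x[100] <- 50  # single-sample spike of arbitrary amplitude
  y <- filter_gaze(x)
  expect_lt(max(abs(y)), 1e-9)

  expect_error(filter_gaze(rep(NA_real_, 10)), "missing")
})

test_that("a 30 Hz sinusoid is attenuated below a quarter of its input", {
  # 30 Hz is twice the cutoff: the squared 2nd-order Butterworth response
  # there is 1/17, far below 0.25. At 90 Hz sampling the 3-frame median
  # additionally collapses a 30 Hz tone toward a constant, so the check is
  # on the 30 Hz component remaining in the output.
  t <- seq(0, 2, by = 1 / 90)
  x <- sin(2 * pi * 30 * t + 0.4)
  y <- filter_gaze(x)
  keep <- 30:(length(y) - 30)
  fit <- stats::lm(y[keep] ~ sin(2 * pi * 30 * t[keep]) +
                     cos(2 * pi * 30 * t[keep]))
  amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
  expect_lt(amp, 0.25)
})

test_that("missing samples are excluded and restored as missing", {
  x <- sin(seq(0, 4, by = 1 / 90))
  x[c(40:45, 200)] <- NA
  y <- filter_gaze(x)
  expect_true(all(is.na(y[c(40:45, 200)])))
  expect_false(anyNA(y[-c(40:45, 200)]))
})

test_that("filtering commutes with windowing on interior samples", {
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(600), rep(1 / 8, 8), sides = 1))
  x[1:8] <- 0
  whole <- filter_gaze(x)[201:400]
  part <- filter_gaze(x[151:450])[51:250]
  expect_equal(whole[40:160], part[40:160], tolerance = 1e-6)
})

test_that("predictive gaze averages the final 50 ms and signs the side", {
  t <- seq(-0.2, 0.1, by = 1 / 90)
  pg <- predictive_gaze(t, rep(1, length(t)))
  expect_equal(pg$gaze_x, 1)
  expect_identical(pg$side, "right")

  pg <- predictive_gaze(t, rep(-0.2, length(t)))
  expect_equal(pg$gaze_x, -0.2)
  expect_identical(pg$side, "left")

  # explicit four-sample window: mean of {-0.1, 0.3, 0.4, 0.2} = 0.2
  t4 <- c(-0.045, -0.034, -0.023, -0.012)
  pg <- predictive_gaze(t4, c(-0.1, 0.3, 0.4, 0.2))
  expect_equal(pg$gaze_x, 0.2)
  expect_identical(pg$side, "right")

  # half-open window: the sample at release is excluded
  pg <- predictive_gaze(c(-0.01, 0), c(1, -100))
  expect_equal(pg$gaze_x, 1)

  # zero mean classifies left
  expect_identical(predictive_gaze(t4, c(-1, 1, -1, 1))$side, "left")

  # empty window yields missing metrics
  pg <- predictive_gaze(c(-0.5, -0.4), c(1, 1))
  expect_true(is.na(pg$gaze_x) && is.na(pg$side))
})

test_that("recoding toward the likely side signs visual angles correctly", {
  geom <- court_geometry()
  half <- geom$separation_deg / 2
  expect_equal(recode_toward_likely(3.67, "right", geom), half)
  expect_equal(recode_toward_likely(-3.67, "left", geom), half)
  expect_equal(recode_toward_likely(0, "right", geom), 0)
  expect_equal(recode_toward_likely(-0.4, "right", geom), -5.71,
               tolerance = 0.01)
})

test_that("minimum gaze-ball error matches hand-built angle cases", {
  b <- rbind(vec_at_angle(0), vec_at_angle(0), vec_at_angle(0))
  g <- rbind(vec_at_angle(40), vec_at_angle(12), vec_at_angle(25))
  expect_equal(min_gaze_ball_error(g, b), 12, tolerance = 1e-10)

  expect_equal(min_gaze_ball_error(rbind(c(0, 0, 1)), rbind(c(0, 0, 1))), 0)
  expect_equal(min_gaze_ball_error(rbind(c(1, 0, 0)), rbind(c(0, 0, 1))),
               90)
  # invariant to a common rotation of both vector sets
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  expect_equal(min_gaze_ball_error(g %*% R, b %*% R),
               min_gaze_ball_error(g, b), tolerance = 1e-10)
  # all-missing frames yield NA
  expect_true(is.na(min_gaze_ball_error(rbind(c(NA, NA, NA)),
                                        rbind(c(0, 0, 1)))))
})

test_that("pupil preprocessing averages eyes and repairs gaps on a line", {
  n <- 450
  l <- rep(3, n); r <- rep(4, n)
  out <- preprocess_pupil(l, r)
  expect_equal(out[50:(n - 50)], rep(3.5, n - 99), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(out, "missing_fraction"), 0)

  # 200 ms gap on a ramp: least-squares line restores it exactly
  t <- seq_len(n)
  ramp <- 3 + 0.002 * t
  gap <- 200:217
  miss <- logical(n); miss[gap] <- TRUE
  padded <- pbac:::pad_missing_runs(miss, 14)
  x <- ramp; x[padded] <- NA
  rep_line <- pbac:::interpolate_gaps(x, max_flank = 9)
  expect_lt(max(abs(rep_line - ramp)), 1e-6)

  # end to end, the binocular mean stays on the ramp away from the edges
  v <- !miss
  out <- preprocess_pupil(ramp, ramp, v, v)
  expect_lt(max(abs(out[60:(n - 60)] - ramp[60:(n - 60)])), 1e-3)
  expect_equal(attr(out, "missing_fraction"),
               mean(pbac:::pad_missing_runs(miss, 14)))
})

test_that("surprisal peak is baseline-corrected and windowed post-release", {
  t <- seq(-0.5, 4, by = 1 / 90)
  arrival <- 0.5
  flat <- rep(3, length(t))
  expect_equal(pupil_surprisal_peak(t, flat, arrival_t = arrival), 0)

  # smooth bump peaking 1 s post-release
  bump <- 3 + 0.4 * exp(-(t - 1)^2 / (2 * 0.3^2))
  expect_equal(pupil_surprisal_peak(t, bump, arrival_t = arrival), 0.4,
               tolerance = 0.01)

  # a bump entirely before release cannot produce a positive peak
  pre_bump <- 3 + 0.4 * exp(-(t + 0.3)^2 / (2 * 0.05^2))
  expect_lte(pupil_surprisal_peak(t, pre_bump, arrival_t = arrival), 0)

  # insufficient coverage: no baseline samples
  expect_true(is.na(pupil_surprisal_peak(t[t >= 0], flat[t >= 0],
                                         arrival_t = arrival)))
})

test_that("trial metrics carry the full pipeline per trial", {
  s <- local_cohort()[[1]]
  m <- compute_trial_metrics(s)
  expect_s3_class(m, "pbac_metrics")
  expect_equal(nrow(m), nrow(s$trials))
  expect_true(all(m$min_gaze_ball_error >= 0, na.rm = TRUE))
  expect_true(all(m$missing_fraction >= 0 & m$missing_fraction <= 1))
  # predictions point at a hole: classified sides match the fixated hole
  agree <- mean(m$predicted_side == s$trials$gaze_side, na.rm = TRUE)
  expect_gt(agree, 0.95)
})
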