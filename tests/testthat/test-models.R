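test_that("first-trial prediction is 0.5 for a neutral starting belief", {
  traj <- hgf_filter(c(1, 0), hgf_params(mu2_0 = 0))
  expect_equal(traj$muhat1[1], 0.5)
})

test_that("single HGF update matches the hand-derived closed form", {
  # u = 1, mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1, kappa = 1,
  # omega2 = -2: sigmahat2 = 1 + e^-1, delta1 = 0.5, pi2 = 0.9811,
  # mu2 = 0.5096
  p <- hgf_params(n_levels = 3, kappa = 1, omega2 = -2, omega3 = -6,
                  mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1)
  traj <- hgf_filter(1, p)
  expect_equal(traj$sigmahat2, 1 + exp(-1), tolerance = 1e-10)
  expect_equal(traj$sigmahat2, 1.3679, tolerance = 1e-4)
  expect_equal(traj$delta1, 0.5)
  pi2_exact <- 1 / (1 + exp(-1)) + 0.25
  expect_equal(1 / traj$alpha2, pi2_exact, tolerance = 1e-10)
  expect_equal(1 / traj$alpha2, 0.9811, tolerance = 1e-3)
  expect_equal(traj$mu2, 0.5 / pi2_exact, tolerance = 1e-10)
  expect_equal(traj$mu2, 0.5096, tolerance = 1e-3)
})

test_that("HGF trajectories match the independent oracle on a grid", {
  u <- c(1, 0, 1)
  grid <- expand.grid(omega2 = seq(-4, -1, length.out = 5),
                      omega3 = seq(-6, -2, length.out = 5),
                      mu2_0 = c(-0.5, 0.5),
                      mu3_0 = c(0.5, 1.5))
  expect_gte(nrow(grid), 100)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    traj <- hgf_filter(u, hgf_params(
      n_levels = 3, kappa = 1, omega2 = g$omega2, omega3 = g$omega3,
      mu2_0 = g$mu2_0, sigma2_0 = 1, mu3_0 = g$mu3_0, sigma3_0 = 1))
    orc <- hgf3_oracle(u, 1, g$omega2, g$omega3, g$mu2_0, 1, g$mu3_0, 1)
    for (col in c("muhat1", "mu2", "sigma2", "mu3", "sigma3", "delta1",
                  "delta2", "eps2", "eps3", "alpha2")) {
      expect_equal(traj[[col]], orc[[col]], tolerance = 1e-10,
                   label = paste(col, "at row", i))
    }
  }
})

test_that("eps2 is the level-2 belief increment and precisions stay valid", {
  u <- as.integer(make_congruency_schedule(80, 16, 4) == "expected")
  traj <- hgf_filter(u, hgf_params())
  expect_equal(traj$eps2, traj$mu2 - traj$muhat2)
  expect_true(all(traj$muhat1 > 0 & traj$muhat1 < 1))
  expect_true(all(traj$sigma2 > 0))
  expect_true(all(traj$sigma3 > 0))
  expect_true(all(traj$alpha2 > 0))
})

test_that("vanishing level-2 volatility freezes beliefs", {
  u <- rep(1L, 40)
  traj <- hgf_filter(u, hgf_params(n_levels = 2, omega2 = -40,
                                   mu2_0 = 0, sigma2_0 = 1e-6))
  expect_lt(max(abs(traj$mu2 - 0)), 1e-4)
})

test_that("the 4-level filter runs and its lower levels stay coherent", {
  u <- c(1, 1, 0, 1, 0, 1)
  traj4 <- hgf_filter(u, hgf_params(n_levels = 4))
  expect_true(all(is.finite(traj4$mu4)))
  expect_true(all(traj4$sigma4 > 0))
  expect_equal(traj4$eps2, traj4$mu2 - traj4$muhat2)
})

test_that("Rescorla-Wagner matches its recurrence and limits", {
  expect_equal(rw_filter(1, alpha = 0.2, v0 = 0.5)$v, 0.6)
  expect_equal(rw_filter(rep(1, 10), alpha = 0)$v, rep(0.5, 10))

  u <- rep(c(0, 1), 25)
  traj <- rw_filter(u, alpha = 0.35, v0 = 0.5)
  expect_equal(traj$vhat, rw_oracle(u, 0.35, 0.5), tolerance = 1e-12)
  # alternating input converges to a 2-cycle around 0.5
  late <- traj$v[41:50]
  cyc <- unique(round(late, 4))
  expect_length(cyc, 2)
  expect_true(min(cyc) < 0.5 && max(cyc) > 0.5)
  expect_equal(mean(late), 0.5, tolerance = 0.02)
  expect_error(rw_filter(u, alpha = 1.2), "0, 1")
})

test_that("Sutton K1 matches its recurrence and reduces to RW at mu = 0", {
  u <- as.integer(make_congruency_schedule(60, 12, 9) == "expected")
  k1 <- sk1_filter(u, mu = 0.1, beta0 = log(0.1), v0 = 0.5, h0 = 0)
  expect_equal(k1$vhat, sk1_oracle(u, 0.1, log(0.1), 0.5, 0),
               tolerance = 1e-12)

  # mu = 0: exact reduction to RW with alpha = exp(beta0)
  k1_0 <- sk1_filter(u, mu = 0, beta0 = log(0.25))
  rw <- rw_filter(u, alpha = 0.25)
  expect_identical(k1_0$vhat, rw$vhat)
  expect_identical(k1_0$v, rw$v)

  # constant input at V0: zero error, constant trajectory
  k1_c <- sk1_filter(rep(1, 20), mu = 0.1, beta0 = log(0.1), v0 = 1)
  expect_equal(k1_c$v, rep(1, 20))

  # two hand-computed steps from V0 = 0.5, beta0 = log 0.1, u = [1, 1]
  k2 <- sk1_filter(c(1, 1), mu = 0.1, beta0 = log(0.1), v0 = 0.5, h0 = 0)
  # step 1: d = .5, beta unchanged (h = 0), a = .1, V = .55, h = .05 * .9
  expect_equal(k2$v[1], 0.55)
  # step 2: d = .45, beta = log(.1) + .1 * .45 * .045, a = exp(beta)
  a2 <- exp(log(0.1) + 0.1 * 0.45 * 0.045)
  expect_equal(k2$v[2], 0.55 + a2 * 0.45, tolerance = 1e-12)
})

test_that("three-level HGF with frozen volatility reproduces the 2-level", {
  u <- as.integer(make_congruency_schedule(100, 20, 2) == "expected")
  t2 <- hgf_filter(u, hgf_params(n_levels = 2, omega2 = -2.5,
                                 mu2_0 = 0, sigma2_0 = 1))
  t3 <- hgf_filter(u, hgf_params(n_levels = 3, omega2 = -2.5, omega3 = -40,
                                 mu2_0 = 0, sigma2_0 = 1,
                                 mu3_0 = 0, sigma3_0 = 1e-8))
  expect_equal(t3$mu2, t2$mu2, tolerance = 1e-6)
  expect_equal(t3$muhat1, t2$muhat1, tolerance = 1e-6)
  expect_equal(t3$alpha2, t2$alpha2, tolerance = 1e-6)
})

test_that("unstable parameter points are rejected, not returned", {
  u <- as.integer(make_congruency_schedule(150, 30, 1) == "expected")
  expect_error(hgf_filter(u, hgf_params(omega2 = -2, omega3 = 0,
                                        sigma3_0 = 4)),
               "rejected")
})

test_that("the unit-square sigmoid response model behaves as specified", {
  # zeta = 1 is probability matching
  m <- c(0.2, 0.5, 0.8)
  expect_equal(exp(vapply(m, function(x) response_loglik(x, 1, 1),
                          numeric(1))), m)
  # muhat1 = 0.5 gives p = 0.5 for any zeta
  for (z in c(0.5, 1, 5, 50)) {
    expect_equal(exp(response_loglik(0.5, 1, z)), 0.5)
  }
  # muhat1 = 0.8, zeta = 2: p = 0.64 / 0.68
  expect_equal(exp(response_loglik(0.8, 1, 2)), 0.64 / 0.68,
               tolerance = 1e-12)
  expect_equal(exp(response_loglik(0.8, 1, 2)), 0.9412, tolerance = 1e-4)
  # complementary outcomes sum to one
  p1 <- exp(response_loglik(0.7, 1, 3))
  p0 <- exp(response_loglik(0.7, 0, 3))
  expect_equal(p1 + p0, 1)
  # degenerate predictions are clamped, not NaN
  expect_true(is.finite(response_loglik(c(0, 1), c(0, 1), 2)))
  expect_error(response_loglik(0.5, 1, -1), "zeta")
})
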