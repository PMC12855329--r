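# Independent reference implementations used as oracles. These are written
# directly from the closed-form update equations in plain R, separately from
# the package's compiled filters.

# One three-level HGF update step.
hgf3_step_oracle <- function(u, st, kappa, omega2, omega3) {
  mh1 <- 1 / (1 + exp(-st$mu2))
  v2 <- exp(kappa * st$mu3 + omega2)
  sh2 <- st$sigma2 + v2
  d1 <- u - mh1
  pi2 <- 1 / sh2 + mh1 * (1 - mh1)
  mu2 <- st$mu2 + d1 / pi2
  s2 <- 1 / pi2
  d2 <- (s2 + (mu2 - st$mu2)^2) / sh2 - 1
  sh3 <- st$sigma3 + exp(omega3)
  w2 <- v2 / sh2
  pi3 <- 1 / sh3 + kappa^2 / 2 * w2 * (w2 + (2 * w2 - 1) * d2)
  mu3 <- st$mu3 + kappa / (2 * pi3) * w2 * d2
  s3 <- 1 / pi3
  list(muhat1 = mh1, sigmahat2 = sh2, delta1 = d1, pi2 = pi2,
       mu2 = mu2, sigma2 = s2, delta2 = d2, mu3 = mu3, sigma3 = s3,
       eps2 = mu2 - st$mu2, eps3 = mu3 - st$mu3, alpha2 = 1 / pi2)
}

# Full-sequence oracle: fold hgf3_step_oracle over u.
hgf3_oracle <- function(u, kappa, omega2, omega3,
                        mu2_0, sigma2_0, mu3_0, sigma3_0) {
  st <- list(mu2 = mu2_0, sigma2 = sigma2_0, mu3 = mu3_0,
             sigma3 = sigma3_0)
  out <- vector("list", length(u))
  for (t in seq_along(u)) {
    step <- hgf3_step_oracle(u[t], st, kappa, omega2, omega3)
    out[[t]] <- step
    st <- list(mu2 = step$mu2, sigma2 = step$sigma2, mu3 = step$mu3,
               sigma3 = step$sigma3)
  }
  as.data.frame(do.call(rbind, lapply(out, function(s) {
    unlist(s[c("muhat1", "mu2", "sigma2", "mu3", "sigma3", "delta1",
               "delta2", "eps2", "eps3", "alpha2")])
  })))
}

# Plain-R Rescorla-Wagner recurrence.
rw_oracle <- function(u, alpha, v0) {
  V <- v0
  vhat <- numeric(length(u))
  for (t in seq_along(u)) {
    vhat[t] <- V
    V <- V + alpha * (u[t] - V)
  }
  vhat
}

# Plain-R Sutton K1 recurrence.
sk1_oracle <- function(u, mu, beta0, v0, h0) {
  V <- v0; beta <- beta0; h <- h0
  vhat <- numeric(length(u))
  for (t in seq_along(u)) {
    vhat[t] <- V
    d <- u[t] - V
    beta <- beta + mu * d * h
    a <- min(exp(beta), 1)
    V <- V + a * d
    h <- (h + a * d) * max(0, 1 - a)
  }
  vhat
}

# Unit vector at a given angle (degrees) from +z in the xz-plane.
vec_at_angle <- function(deg) {
  r <- deg * pi / 180
  c(sin(r), 0, cos(r))
}

# Small simulated cohort shared between pipeline-level tests (memoised so
# several test files can reuse it without re-simulating).
local_cohort <- local({
  cache <- NULL
  function(n_agents = 3, seed = 42) {
    if (is.null(cache)) {
      cache <<- pbac_simulate(list(n_agents = n_agents), seed = seed)
    }
    cache
  }
})
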