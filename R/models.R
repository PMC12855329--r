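#' Hierarchical Gaussian Filter parameters
#'
#' Parameter container for the binary HGF. Level 2 tracks the (logit-scale)
#' tendency of the outcome toward side 1; level 3 its log-volatility; level 4
#' the drift of that volatility. `kappa` couples adjacent levels and is fixed
#' at 1 (zero variance) in the study configuration to limit model complexity
#' at modest trial counts; the `omega` values are constant log-volatility
#' offsets. Starting beliefs default to wide, relatively uninformative
#' variances.
#'
#' @param n_levels 2, 3 or 4.
#' @param kappa Level coupling (> 0); fixed, not estimated.
#' @param omega2,omega3,omega4 Log-volatility offsets per level (omega3/4
#'   ignored below their level).
#' @param mu2_0,sigma2_0,mu3_0,sigma3_0,mu4_0,sigma4_0 Prior means and
#'   variances of the starting beliefs (variances > 0).
#' @param zeta Response-model exponent (> 0): decisiveness of the unit-square
#'   sigmoid mapping predictions to choice probabilities.
#' @return A list of class `pbac_hgf_params`.
#' @export
hgf_params <- function(n_levels = 3, kappa = 1,
                       omega2 = -3, omega3 = -6, omega4 = -6,
                       mu2_0 = 0, sigma2_0 = 4,
                       mu3_0 = 1, sigma3_0 = 4,
                       mu4_0 = 1, sigma4_0 = 4,
                       zeta = 1) {
  if (!n_levels %in% 2:4) stop("n_levels must be 2, 3 or 4", call. = FALSE)
  if (any(c(sigma2_0, sigma3_0, sigma4_0) <= 0)) {
    stop("prior variances must be > 0", call. = FALSE)
  }
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (zeta <= 0) stop("zeta must be > 0", call. = FALSE)
  structure(list(n_levels = n_levels, kappa = kappa,
                 omega2 = omega2, omega3 = omega3, omega4 = omega4,
                 mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 mu3_0 = mu3_0, sigma3_0 = sigma3_0,
                 mu4_0 = mu4_0, sigma4_0 = sigma4_0,
                 zeta = zeta),
            class = "pbac_hgf_params")
}

#' Run the binary Hierarchical Gaussian Filter
#'
#' Filters a binary input sequence through the 2-, 3- or 4-level HGF,
#' producing per-trial predictions, posterior beliefs, prediction errors,
#' precision-weighted updates and the effective level-2 learning rate.
#'
#' Per trial, the predictions are the previous posteriors
#' (`muhat_k = mu_k(t-1)`) and `muhat1 = logistic(muhat2)`; the predicted
#' level-2 variance is `sigmahat2 = sigma2(t-1) + exp(kappa * mu3(t-1) +
#' omega2)` (`exp(omega2)` alone for the 2-level model). The level-2 update
#' uses precision `pi2 = 1/sigmahat2 + muhat1 * (1 - muhat1)`, giving
#' `mu2 = muhat2 + delta1 / pi2` with `delta1 = u - muhat1`, and higher
#' levels are driven by the volatility prediction errors. The
#' precision-weighted prediction errors are the belief increments
#' `eps_k = mu_k - muhat_k`, and `alpha2 = 1/pi2` is the trial-wise
#' effective learning rate applied to `delta1`.
#'
#' @param u Binary input vector (0/1), coded 1 = the most probable side as
#'   defined by the block-1 counterbalance.
#' @param params A [hgf_params()] object.
#' @return A tibble of class `pbac_trajectories` with one row per trial:
#'   `trial`, `u`, `muhat1`, `muhat2`, `mu2`, `sigma2`, `sigmahat2`,
#'   `mu3`, `sigma3`, `mu4`, `sigma4` (NA below their level), `delta1`,
#'   `delta2`, `eps2`, `eps3`, `alpha2`.
#' @examples
#' traj <- hgf_filter(c(1, 1, 0, 1), hgf_params(n_levels = 3))
#' traj$muhat1[1]  # 0.5 for mu2_0 = 0
#' @export
hgf_filter <- function(u, params = hgf_params()) {
  check_binary(u)
  p <- params
  res <- hgf_filter_cpp(as.numeric(u), p$n_levels, p$kappa,
                        p$omega2, p$omega3, p$omega4,
                        p$mu2_0, p$sigma2_0, p$mu3_0, p$sigma3_0,
                        p$mu4_0, p$sigma4_0)
  if (!res$ok) {
    stop("HGF update produced a non-positive posterior precision; ",
         "parameter point rejected", call. = FALSE)
  }
  out <- tibble::tibble(
    trial = seq_along(u), u = as.numeric(u),
    muhat1 = res$muhat1, muhat2 = res$muhat2,
    mu2 = res$mu2, sigma2 = res$sigma2, sigmahat2 = res$sigmahat2,
    mu3 = if (p$n_levels >= 3) res$mu3 else NA_real_,
    sigma3 = if (p$n_levels >= 3) res$sigma3 else NA_real_,
    mu4 = if (p$n_levels >= 4) res$mu4 else NA_real_,
    sigma4 = if (p$n_levels >= 4) res$sigma4 else NA_real_,
    delta1 = res$delta1, delta2 = res$delta2,
    eps2 = res$eps2,
    eps3 = if (p$n_levels >= 3) res$eps3 else NA_real_,
    alpha2 = res$alpha2
  )
  class(out) <- c("pbac_trajectories", class(out))
  attr(out, "params") <- p
  out
}

#' Rescorla-Wagner value filter
#'
#' Fixed-learning-rate delta rule: `V(t+1) = V(t) + alpha * (u(t) - V(t))`.
#' The prediction for trial t is the pre-update value `V(t)`.
#'
#' @param u Binary input vector (0/1).
#' @param alpha Learning rate in \[0, 1\].
#' @param v0 Initial value (default 0.5, a neutral starting belief).
#' @return A tibble with `trial`, `u`, `vhat` (prediction), `v`
#'   (post-update value), `delta` (prediction error).
#' @examples
#' rw_filter(1, alpha = 0.2, v0 = 0.5)$v  # 0.6
#' @export
rw_filter <- function(u, alpha, v0 = 0.5) {
  check_binary(u)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  res <- rw_filter_cpp(as.numeric(u), alpha, v0)
  tibble::tibble(trial = seq_along(u), u = as.numeric(u),
                 vhat = res$vhat, v = res$v, delta = res$delta)
}

#' Sutton K1 value filter
#'
#' Delta rule with a state-dependent (meta-learned) learning rate: the
#' log-rate moves with the correlation between current and recent prediction
#' errors,
#' `beta(t+1) = beta(t) + mu * delta(t) * h(t)`;
#' `alpha(t+1) = exp(beta(t+1))` (clipped at 1 and flagged if it diverges);
#' `V(t+1) = V(t) + alpha(t+1) * delta(t)`;
#' `h(t+1) = (h(t) + alpha(t+1) * delta(t)) * max(0, 1 - alpha(t+1))`.
#' With meta-rate `mu = 0` this reduces exactly to [rw_filter()] with
#' `alpha = exp(beta0)`.
#'
#' @param u Binary input vector (0/1).
#' @param mu Meta learning rate (>= 0).
#' @param beta0 Initial log learning rate.
#' @param v0 Initial value.
#' @param h0 Initial error trace.
#' @return A tibble with `trial`, `u`, `vhat`, `v`, `delta`, `alpha`
#'   (trial-wise rate), and attribute `clipped`.
#' @export
sk1_filter <- function(u, mu = 0.1, beta0 = log(0.1), v0 = 0.5, h0 = 0) {
  check_binary(u)
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0", call. = FALSE)
  res <- sk1_filter_cpp(as.numeric(u), mu, beta0, v0, h0)
  out <- tibble::tibble(trial = seq_along(u), u = as.numeric(u),
                        vhat = res$vhat, v = res$v, delta = res$delta,
                        alpha = res$alpha)
  attr(out, "clipped") <- res$clipped
  if (res$clipped) message("SK1 learning rate exceeded 1 and was clipped")
  out
}

#' Unit-square sigmoid response log-likelihood
#'
#' Maps the perceptual prediction `muhat1 = p(u = 1)` to a choice probability
#' through the unit-square sigmoid
#' `p(y = 1) = muhat1^zeta / (muhat1^zeta + (1 - muhat1)^zeta)`,
#' where `zeta > 0` controls decisiveness (`zeta = 1` is probability
#' matching; large `zeta` approaches argmax). Returns the summed log
#' probability of the observed binary responses. Degenerate predictions are
#' clamped to `[1e-9, 1 - 1e-9]`.
#'
#' @param muhat1 Vector of predictions in (0, 1).
#' @param y Binary response vector, same length.
#' @param zeta Response exponent (> 0).
#' @return Scalar log-likelihood.
#' @examples
#' # muhat1 = 0.8, zeta = 2: p(y = 1) = 0.64 / 0.68
#' exp(response_loglik(0.8, 1, 2))
#' @export
response_loglik <- function(muhat1, y, zeta) {
  check_binary(y)
  if (!is.finite(zeta) || zeta <= 0) stop("zeta must be > 0", call. = FALSE)
  if (length(muhat1) != length(y)) {
    stop("muhat1 and y must have equal length", call. = FALSE)
  }
  m <- pmin(pmax(muhat1, 1e-9), 1 - 1e-9)
  # log p(y=1) = zeta*log m - log(m^zeta + (1-m)^zeta), computed stably
  la <- zeta * log(m)
  lb <- zeta * log1p(-m)
  lz <- pmax(la, lb) + log1p(exp(-abs(la - lb)))
  sum(ifelse(y == 1, la, lb) - lz)
}

check_binary <- function(x) {
  if (length(x) == 0 || !all(x %in% c(0, 1))) {
    stop("input must be a non-empty binary (0/1) vector", call. = FALSE)
  }
  invisible(x)
}
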