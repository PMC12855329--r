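#' Random-effects Bayesian model selection
#'
#' Compares models across participants by treating the model identity as a
#' random effect: model frequencies in the population get a Dirichlet prior
#' (uniform, all concentrations 1) and the posterior is obtained by the
#' standard variational scheme over the participants x models log-model
#' evidence table. Exceedance probabilities (probability that each model is
#' the most frequent) are computed by Monte-Carlo sampling of the fitted
#' Dirichlet (analytically via the Beta distribution when only two models
#' are compared). The Bayes omnibus risk (BOR) is the posterior probability
#' that all models are equally frequent, from the free-energy comparison of
#' the random-effects model against the null; the protected exceedance
#' probability blends the two:
#' `PXP_k = EP_k * (1 - BOR) + BOR / K`.
#'
#' @param lme_table Numeric matrix or data frame, participants x models, of
#'   log-model evidences; column names identify the models. All entries must
#'   be finite.
#' @param n_draws Monte-Carlo draws for the exceedance probabilities
#'   (default 1e6).
#' @param seed Integer seed for the draws.
#' @return An object of class `pbac_bms`: list with `models`,
#'   `dirichlet_alpha`, `expected_frequencies`, `exceedance_probabilities`,
#'   `bor`, `protected_exceedance`, `n_participants`.
#' @examples
#' lme <- cbind(m1 = c(-100, -102, -98), m2 = c(-105, -107, -103))
#' bms_random_effects(lme, n_draws = 1e4, seed = 1)
#' @export
bms_random_effects <- function(lme_table, n_draws = 1e6, seed = 1L) {
  L <- as.matrix(lme_table)
  if (ncol(L) < 2) stop("need at least 2 models", call. = FALSE)
  if (!all(is.finite(L))) stop("non-finite log-model evidences", call. = FALSE)
  K <- ncol(L); N <- nrow(L)
  models <- colnames(L)
  if (is.null(models)) models <- paste0("model", seq_len(K))

  alpha0 <- rep(1, K)
  vb <- bms_vb(L, alpha0)
  alpha <- vb$alpha
  ef <- alpha / sum(alpha)

  ep <- exceedance_prob(alpha, n_draws = n_draws, seed = seed)

  # Bayes omnibus risk: F(null: equal frequencies) vs F(random effects)
  F1 <- bms_free_energy(L, vb$g, alpha, alpha0)
  F0 <- sum(apply(L, 1, function(r) {
    m <- max(r); m + log(mean(exp(r - m)))
  }))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- ep * (1 - bor) + bor / K

  structure(list(models = models,
                 dirichlet_alpha = stats::setNames(alpha, models),
                 expected_frequencies = stats::setNames(ef, models),
                 exceedance_probabilities = stats::setNames(ep, models),
                 bor = bor,
                 protected_exceedance = stats::setNames(pxp, models),
                 n_participants = N),
            class = "pbac_bms")
}

# Variational update of the Dirichlet posterior (Stephan et al. scheme).
bms_vb <- function(L, alpha0, tol = 1e-8, max_iter = 500) {
  K <- ncol(L); N <- nrow(L)
  alpha <- alpha0
  g <- matrix(1 / K, N, K)
  for (it in seq_len(max_iter)) {
    elog <- digamma(alpha) - digamma(sum(alpha))
    lg <- sweep(L, 2, elog, `+`)
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg) / rowSums(exp(lg))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  list(alpha = alpha, g = g)
}

# Variational free energy of the random-effects model.
bms_free_energy <- function(L, g, alpha, alpha0) {
  elog <- digamma(alpha) - digamma(sum(alpha))
  elj <- lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum((alpha0 - 1) * elog) +
    sum(g * (sweep(L, 2, elog, `+`)))
  sqf <- sum(lgamma(alpha)) - lgamma(sum(alpha)) -
    sum((alpha - 1) * elog)
  sqm <- -sum(g * log(g + .Machine$double.eps))
  elj + sqf + sqm
}

# P(model k has the largest sampled frequency) under Dirichlet(alpha).
exceedance_prob <- function(alpha, n_draws = 1e6, seed = 1L) {
  K <- length(alpha)
  if (K == 2) {
    # r1 ~ Beta(a1, a2); EP1 = P(r1 > 1/2)
    ep1 <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    return(c(ep1, 1 - ep1))
  }
  with_local_seed(seed, {
    counts <- integer(K)
    remaining <- n_draws
    chunk <- 2e5
    while (remaining > 0) {
      m <- min(chunk, remaining)
      x <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
      w <- max.col(x, ties.method = "first")
      counts <- counts + tabulate(w, K)
      remaining <- remaining - m
    }
    counts / n_draws
  })
}

#' @export
print.pbac_bms <- function(x, ...) {
  cat(sprintf("<pbac_bms> %d participants, %d models (BOR = %.3f)\n",
              x$n_participants, length(x$models), x$bor))
  df <- tidy(x)
  print(as.data.frame(df), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pbac_bms <- function(x, ...) {
  tibble::tibble(model = x$models,
                 dirichlet_alpha = unname(x$dirichlet_alpha),
                 expected_frequency = unname(x$expected_frequencies),
                 exceedance_probability = unname(x$exceedance_probabilities),
                 protected_exceedance = unname(x$protected_exceedance))
}

#' @exportS3Method generics::glance
glance.pbac_bms <- function(x, ...) {
  tibble::tibble(n_participants = x$n_participants,
                 n_models = length(x$models),
                 bor = x$bor,
                 best_model = x$models[which.max(x$protected_exceedance)])
}

#' Group Bayes factor from per-participant log-model evidences
#'
#' `exp(sum(lme_a - lme_b))`: the product of per-participant evidence ratios
#' for model A over model B. When the summed log difference would overflow,
#' the ratio is reported on the log scale with `overflow = TRUE`.
#'
#' @param lme_a,lme_b Equal-length numeric vectors of log-model evidences.
#' @return A tibble with `log_bf`, `bf` (NA when overflowed) and `overflow`.
#' @examples
#' group_bayes_factor(c(-10, -12), c(-12, -13))  # exp(3)
#' @export
group_bayes_factor <- function(lme_a, lme_b) {
  if (length(lme_a) != length(lme_b)) {
    stop("lme vectors must have equal length", call. = FALSE)
  }
  log_bf <- sum(lme_a - lme_b)
  overflow <- abs(log_bf) > log(.Machine$double.xmax)
  tibble::tibble(log_bf = log_bf,
                 bf = if (overflow) NA_real_ else exp(log_bf),
                 overflow = overflow)
}

#' Per-condition learning-rate and prediction-error summaries
#'
#' Splits HGF belief trajectories by trial expectedness and summarises the
#' effective learning rate and the precision-weighted prediction errors:
#' mean `alpha2`, mean `|eps2|` and mean `|eps3|` over the expected and the
#' unexpected trial subsets. Prediction errors are summarised as magnitudes;
#' under the `alpha2 = 1/pi2` convention the learning rate is positive by
#' construction, so the sign-flip rule for negative rates is a no-op (noted
#' in the output attribute `sign_rule`).
#'
#' @param traj A `pbac_trajectories` tibble from [hgf_filter()].
#' @param labels Character vector of `"expected"` / `"unexpected"`, one per
#'   trial, aligned with `traj`.
#' @return A tibble with one row per expectedness level present: columns
#'   `expectedness`, `n_trials`, `mean_alpha2`, `mean_abs_eps2`,
#'   `mean_abs_eps3`.
#' @export
extract_condition_parameters <- function(traj, labels) {
  if (nrow(traj) != length(labels)) {
    stop("labels must align with trajectories", call. = FALSE)
  }
  check_labels(labels)
  out <- tibble::tibble(expectedness = labels,
                        alpha2 = traj$alpha2,
                        eps2 = traj$eps2,
                        eps3 = traj$eps3) |>
    dplyr::group_by(.data$expectedness) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     mean_alpha2 = mean(abs(.data$alpha2)),
                     mean_abs_eps2 = mean(abs(.data$eps2)),
                     mean_abs_eps3 = mean(abs(.data$eps3)),
                     .groups = "drop")
  attr(out, "sign_rule") <-
    "alpha2 = 1/pi2 is positive by construction; sign flip is a no-op"
  out
}
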