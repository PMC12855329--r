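#' Default priors and fixed settings for model fitting
#'
#' Gaussian priors over the free parameters of each learning model, in the
#' estimation space actually optimised: log-volatility offsets (`omega2`,
#' `omega3`, `omega4`) are estimated natively; the response exponent as
#' `log_zeta`; the Rescorla-Wagner rate as `logit_alpha` (neutral prior mean
#' at alpha = 0.5); the Sutton K1 initial log-rate `beta0` and meta-rate
#' `log_mu`. Priors are deliberately wide. The level coupling `kappa` is
#' fixed at 1 with zero variance and never estimated.
#'
#' @param model One of `"hgf2"`, `"hgf3"`, `"hgf4"`, `"rw"`, `"sk1"`.
#' @return A tibble with columns `param`, `mean`, `sd` (estimation space).
#' @export
default_priors <- function(model = c("hgf3", "hgf2", "hgf4", "rw", "sk1")) {
  model <- match.arg(model)
  pr <- switch(model,
    hgf2 = tibble::tribble(~param, ~mean, ~sd,
                           "omega2", -3, 4,
                           "log_zeta", 0, 2),
    hgf3 = tibble::tribble(~param, ~mean, ~sd,
                           "omega2", -3, 4,
                           "omega3", -6, 4,
                           "log_zeta", 0, 2),
    hgf4 = tibble::tribble(~param, ~mean, ~sd,
                           "omega2", -3, 4,
                           "omega3", -6, 4,
                           "omega4", -6, 4,
                           "log_zeta", 0, 2),
    rw = tibble::tribble(~param, ~mean, ~sd,
                         "logit_alpha", 0, 2,
                         "log_zeta", 0, 2),
    sk1 = tibble::tribble(~param, ~mean, ~sd,
                          "beta0", log(0.1), 2,
                          "log_mu", log(0.1), 2,
                          "log_zeta", 0, 2)
  )
  pr
}

# Fixed (non-estimated) settings shared by all fits: kappa, starting
# beliefs (wide variances), associative-model initial values.
default_init <- function() {
  list(kappa = 1,
       mu2_0 = 0, sigma2_0 = 4,
       mu3_0 = 1, sigma3_0 = 4,
       mu4_0 = 1, sigma4_0 = 4,
       v0 = 0.5, h0 = 0)
}

# Per-trial predictions p(u = 1) for a model at a parameter point.
# Returns NULL for a rejected parameter point.
model_predictions <- function(model, u, theta, init) {
  if (startsWith(model, "hgf")) {
    nl <- as.integer(substring(model, 4))
    res <- hgf_filter_cpp(u, nl, init$kappa,
                          theta[["omega2"]],
                          if (nl >= 3) theta[["omega3"]] else -Inf,
                          if (nl >= 4) theta[["omega4"]] else -Inf,
                          init$mu2_0, init$sigma2_0,
                          init$mu3_0, init$sigma3_0,
                          init$mu4_0, init$sigma4_0)
    if (!res$ok) return(NULL)
    res$muhat1
  } else if (model == "rw") {
    alpha <- stats::plogis(theta[["logit_alpha"]])
    rw_filter_cpp(u, alpha, init$v0)$vhat
  } else if (model == "sk1") {
    sk1_filter_cpp(u, exp(theta[["log_mu"]]), theta[["beta0"]],
                   init$v0, init$h0)$vhat
  } else {
    stop("unknown model: ", model, call. = FALSE)
  }
}

# Log joint density (response likelihood + Gaussian priors) at a parameter
# vector in estimation space. -Inf for rejected points.
log_joint <- function(theta, model, u, y, priors, init) {
  muhat1 <- model_predictions(model, u, theta, init)
  if (is.null(muhat1)) return(-Inf)
  zeta <- exp(theta[["log_zeta"]])
  ll <- response_loglik(muhat1, y, zeta)
  lp <- sum(stats::dnorm(theta[priors$param], priors$mean, priors$sd,
                         log = TRUE))
  ll + lp
}

#' Observing-the-observer MAP fit with Laplace log-model evidence
#'
#' Fits a learning model jointly to the stimulus sequence `u` (ball side)
#' and the binary responses `y` (gaze side) by maximising the log joint of
#' the response likelihood (unit-square sigmoid, [response_loglik()]) and
#' Gaussian priors over the free parameters. Optimisation is derivative-free
#' (Nelder-Mead) with seeded multistarts; the log-model evidence is the
#' Laplace approximation at the MAP,
#' `LME = log joint + (d/2) log 2 pi - 0.5 log det(-H)`,
#' with the Hessian obtained by central finite differences (step 1e-4).
#' Non-positive-definite Hessians are regularised by flooring eigenvalues at
#' 1e-8 and flagged. Parameter points yielding a non-positive posterior
#' precision anywhere along the sequence receive a log joint of `-Inf`.
#'
#' @param u Binary stimulus sequence (1 = most probable side).
#' @param y Binary response sequence, same coding and length.
#' @param model `"hgf2"`, `"hgf3"`, `"hgf4"`, `"rw"` or `"sk1"`.
#' @param priors Prior table as from [default_priors()]; rows define the
#'   free parameters.
#' @param init Fixed settings (kappa, starting beliefs, initial values); see
#'   `default_init`. Starting-belief means may come from
#'   [ideal_observer_priors()].
#' @param free Character vector naming the free parameters (default: all
#'   rows of `priors`). Parameters not listed are pinned to their prior
#'   means; with `free = character(0)` the LME is the log joint exactly.
#' @param n_restarts Number of optimisation multistarts (first at the prior
#'   means, the rest drawn from the priors).
#' @param seed Integer seed for the multistart draws.
#' @return An object of class `pbac_fit`: list with `model`, `map`
#'   (estimation-space MAP), `estimates` (natural-space parameters), `lme`,
#'   `log_joint`, `converged`, `n_restarts_used`, `regularised`, `n_trials`.
#' @examples
#' u <- rep(c(1, 1, 1, 1, 0), 10)
#' y <- u
#' fit <- fit_map_laplace(u, y, "rw", n_restarts = 2, seed = 1)
#' glance(fit)
#' @export
fit_map_laplace <- function(u, y, model = c("hgf3", "hgf2", "hgf4", "rw",
                                            "sk1"),
                            priors = default_priors(model),
                            init = default_init(),
                            free = priors$param,
                            n_restarts = 10, seed = 1L) {
  model <- match.arg(model)
  check_binary(u); check_binary(y)
  if (length(u) != length(y)) stop("u and y must have equal length",
                                   call. = FALSE)
  init <- utils::modifyList(default_init(), init)
  stopifnot(all(free %in% priors$param))
  u <- as.numeric(u); y <- as.numeric(y)

  full_theta <- stats::setNames(priors$mean, priors$param)
  obj <- function(th_free) {
    th <- full_theta
    th[free] <- th_free
    -log_joint(th, model, u, y, priors, init)
  }

  d <- length(free)
  if (d == 0) {
    lj <- log_joint(full_theta, model, u, y, priors, init)
    return(new_pbac_fit(model, full_theta, lj, lme = lj, converged = TRUE,
                        n_restarts_used = 0L, regularised = FALSE,
                        n_trials = length(u), free = free))
  }

  pr_free <- priors[match(free, priors$param), ]
  starts <- with_local_seed(seed, {
    s <- matrix(rep(pr_free$mean, n_restarts), nrow = n_restarts,
                byrow = TRUE)
    if (n_restarts > 1) {
      jitter <- matrix(stats::rnorm((n_restarts - 1) * d, sd = 1),
                       nrow = n_restarts - 1)
      s[-1, ] <- s[-1, ] + jitter * rep(pr_free$sd, each = n_restarts - 1)
    }
    s
  })

  best <- NULL
  n_used <- 0L
  for (i in seq_len(n_restarts)) {
    st <- starts[i, ]
    if (!is.finite(obj(st))) next
    opt <- tryCatch(
      stats::optim(st, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-6, maxit = 2000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    n_used <- n_used + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(new_pbac_fit(model, full_theta, -Inf, lme = -Inf,
                        converged = FALSE, n_restarts_used = 0L,
                        regularised = FALSE, n_trials = length(u),
                        free = free))
  }

  theta_map <- full_theta
  theta_map[free] <- best$par
  lj <- -best$value

  H <- fd_hessian(obj, best$par, h = 1e-4)
  fallback <- FALSE
  if (any(!is.finite(H))) {
    # MAP at the edge of the admissible region: a perturbed point was
    # rejected. Fall back to the prior precisions for the curvature.
    H <- diag(1 / pr_free$sd^2, d)
    fallback <- TRUE
  }
  eig <- eigen(H, symmetric = TRUE)
  regularised <- fallback || any(eig$values < 1e-8)
  vals <- pmax(eig$values, 1e-8)
  lme <- lj + d / 2 * log(2 * pi) - 0.5 * sum(log(vals))

  new_pbac_fit(model, theta_map, lj, lme = lme, converged = TRUE,
               n_restarts_used = n_used, regularised = regularised,
               n_trials = length(u), free = free)
}

# Central finite-difference Hessian of f at x.
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h^2)
    }
  }
  H
}

new_pbac_fit <- function(model, theta, lj, lme, converged, n_restarts_used,
                         regularised, n_trials, free) {
  est <- natural_estimates(theta)
  structure(list(model = model, map = theta, estimates = est, lme = lme,
                 log_joint = lj, converged = converged,
                 n_restarts_used = n_restarts_used,
                 regularised = regularised, n_trials = n_trials,
                 free = free),
            class = "pbac_fit")
}

natural_estimates <- function(theta) {
  est <- as.list(theta)
  if (!is.null(est$log_zeta)) { est$zeta <- exp(est$log_zeta); est$log_zeta <- NULL }
  if (!is.null(est$logit_alpha)) { est$alpha <- stats::plogis(est$logit_alpha); est$logit_alpha <- NULL }
  if (!is.null(est$log_mu)) { est$mu <- exp(est$log_mu); est$log_mu <- NULL }
  est
}

#' @export
print.pbac_fit <- function(x, ...) {
  cat(sprintf("<pbac_fit> model = %s, n = %d trials\n", x$model, x$n_trials))
  cat(sprintf("  LME = %.3f (log joint %.3f)%s\n", x$lme, x$log_joint,
              if (x$regularised) ", Hessian regularised" else ""))
  cat("  MAP (natural space):\n")
  est <- x$estimates
  for (nm in names(est)) cat(sprintf("    %s = %.4f\n", nm, est[[nm]]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pbac_fit <- function(x, ...) {
  tibble::tibble(term = names(x$map),
                 estimate = unname(x$map),
                 natural_term = names(natural_estimates(x$map)),
                 natural_estimate = unlist(natural_estimates(x$map),
                                           use.names = FALSE),
                 free = names(x$map) %in% x$free)
}

#' @exportS3Method generics::glance
glance.pbac_fit <- function(x, ...) {
  tibble::tibble(model = x$model, lme = x$lme, log_joint = x$log_joint,
                 converged = x$converged,
                 n_restarts_used = x$n_restarts_used,
                 regularised = x$regularised, n_trials = x$n_trials)
}

#' Ideal-observer prior means for the HGF
#'
#' Finds HGF settings under which an ideal Bayesian agent would experience
#' the least surprise about the task's input sequences: minimises the summed
#' Shannon surprisal `sum(-log p(u_t))` of the observed inputs under the
#' model's one-step-ahead predictions, over the starting means and omega
#' offsets. The filter is then run at the optimum and the resulting
#' posterior means are returned as prior (starting-belief) means for
#' participant fits.
#'
#' @param u_sequences A binary vector or list of binary vectors (trial
#'   sequences).
#' @param n_levels HGF depth (2, 3 or 4).
#' @return A list with `mu2_0`, `mu3_0`, `mu4_0` (posterior means at the
#'   optimum, averaged over sequences), the optimised `omega2`, `omega3`,
#'   `omega4`, and `converged`. Falls back to neutral values (`mu2_0 = 0`)
#'   with a message if the optimiser fails.
#' @export
ideal_observer_priors <- function(u_sequences, n_levels = 3) {
  if (!is.list(u_sequences)) u_sequences <- list(u_sequences)
  lapply(u_sequences, check_binary)
  init <- default_init()
  nm <- switch(as.character(n_levels),
               "2" = c("mu2_0", "omega2"),
               "3" = c("mu2_0", "mu3_0", "omega2", "omega3"),
               "4" = c("mu2_0", "mu3_0", "mu4_0", "omega2", "omega3",
                       "omega4"),
               stop("n_levels must be 2, 3 or 4", call. = FALSE))
  start <- c(mu2_0 = 0, mu3_0 = 1, mu4_0 = 1,
             omega2 = -3, omega3 = -6, omega4 = -6)[nm]

  surprise <- function(th) {
    tot <- 0
    for (u in u_sequences) {
      ini <- utils::modifyList(init, as.list(th[grep("_0$", names(th))]))
      om <- as.list(th[grep("^omega", names(th))])
      res <- hgf_filter_cpp(as.numeric(u), n_levels, init$kappa,
                            om$omega2 %||% -3,
                            om$omega3 %||% -6,
                            om$omega4 %||% -6,
                            ini$mu2_0, ini$sigma2_0, ini$mu3_0,
                            ini$sigma3_0, ini$mu4_0, ini$sigma4_0)
      if (!res$ok) return(Inf)
      p <- pmin(pmax(res$muhat1, 1e-9), 1 - 1e-9)
      tot <- tot - sum(ifelse(u == 1, log(p), log1p(-p)))
    }
    tot
  }

  opt <- tryCatch(
    stats::optim(start, surprise, method = "Nelder-Mead",
                 control = list(reltol = 1e-8, maxit = 5000)),
    error = function(e) NULL)
  neutral <- list(mu2_0 = 0, mu3_0 = 1, mu4_0 = 1, omega2 = -3,
                  omega3 = -6, omega4 = -6, converged = FALSE)
  if (is.null(opt) || !is.finite(opt$value)) {
    message("ideal-observer optimisation failed; using neutral priors")
    return(neutral)
  }
  th <- opt$par
  # posterior means at the optimum, averaged over sequences
  post <- purrr::map(u_sequences, function(u) {
    ini <- utils::modifyList(init, as.list(th[grep("_0$", names(th))]))
    res <- hgf_filter_cpp(as.numeric(u), n_levels, init$kappa,
                          th["omega2"] %||% -3,
                          if ("omega3" %in% names(th)) th[["omega3"]] else -6,
                          if ("omega4" %in% names(th)) th[["omega4"]] else -6,
                          ini$mu2_0, ini$sigma2_0, ini$mu3_0, ini$sigma3_0,
                          ini$mu4_0, ini$sigma4_0)
    n <- length(u)
    c(mu2 = res$mu2[n],
      mu3 = if (n_levels >= 3) res$mu3[n] else 1,
      mu4 = if (n_levels >= 4) res$mu4[n] else 1)
  })
  pm <- Reduce(`+`, post) / length(post)
  list(mu2_0 = unname(pm["mu2"]), mu3_0 = unname(pm["mu3"]),
       mu4_0 = unname(pm["mu4"]),
       omega2 = unname(th["omega2"]),
       omega3 = if ("omega3" %in% names(th)) unname(th[["omega3"]]) else -6,
       omega4 = if ("omega4" %in% names(th)) unname(th[["omega4"]]) else -6,
       converged = opt$convergence == 0)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
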