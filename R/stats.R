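#' Trial-level quality control
#'
#' Discards trials whose missing-data fraction exceeds 25% (strict
#' inequality: a trial at exactly 25% is retained), and logs per-participant
#' removal counts.
#'
#' @param metrics A per-trial metrics tibble with columns `participant_id`
#'   and `missing_fraction`.
#' @param threshold Missing-fraction limit (default 0.25).
#' @return The retained rows; attribute `qc_log` holds a per-participant
#'   tibble of `n_trials`, `n_removed`.
#' @examples
#' m <- tibble::tibble(participant_id = "a", missing_fraction = c(0.1, 0.3))
#' qc_filter(m)
#' @export
qc_filter <- function(metrics, threshold = 0.25) {
  drop <- metrics$missing_fraction > threshold
  log <- metrics |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_removed = sum(.data$missing_fraction > threshold),
                     .groups = "drop")
  out <- metrics[!drop, , drop = FALSE]
  attr(out, "qc_log") <- log
  out
}

#' Winsorize extreme scores beyond 3 SD
#'
#' Replaces each value more than `z_limit` sample standard deviations from
#' the sample mean (SD with denominator n - 1, computed once from the full
#' sample; single pass) with a value 1% beyond the next most extreme
#' retained score. The tail rule is sign-aware: an upper-tail replacement is
#' the next most extreme value times 1.01 if that value is positive and
#' times 0.99 if negative, mirrored on the lower tail, so the substitute is
#' always slightly more extreme than the retained extreme.
#'
#' Note that with the sample SD the largest attainable |z| in an n-point
#' sample is (n - 1)/sqrt(n), so a 3-SD outlier can only exist for n >= 12;
#' the screen operates on distributions pooled across participants.
#'
#' @param values Numeric vector (>= 3 values; NAs passed through).
#' @param z_limit Outlier threshold in SD units (default 3).
#' @return The vector with outliers replaced. Zero-variance input is
#'   returned unchanged.
#' @examples
#' x <- c(0.1, 0.2, 0.15, 0.18, 0.22, 0.19, 0.21, 0.17, 0.16,
#'        0.14, 0.2, 0.18, 0.19, 0.16, 5.0)
#' winsorize(x)[15]  # 1.01 * 0.22
#' @export
winsorize <- function(values, z_limit = 3) {
  ok <- is.finite(values)
  x <- values[ok]
  if (length(x) < 3) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(values)
  z <- (x - mean(x)) / s
  hi <- z > z_limit
  lo <- z < -z_limit
  if (!any(hi) && !any(lo)) return(values)
  kept <- x[!hi & !lo]
  if (length(kept) == 0) return(values)
  step <- function(v, upper) {
    # 1% beyond v, away from the bulk
    if (upper) { if (v > 0) 1.01 * v else 0.99 * v }
    else { if (v < 0) 1.01 * v else 0.99 * v }
  }
  if (any(hi)) x[hi] <- step(max(kept), upper = TRUE)
  if (any(lo)) x[lo] <- step(min(kept), upper = FALSE)
  values[ok] <- x
  values
}

#' Participant-level exclusion for excessive trial loss
#'
#' Excludes participants for whom more than a third of trials were removed
#' (strict inequality: exactly one third is retained).
#'
#' @param qc_log Tibble with `participant_id`, `n_trials`, `n_removed`
#'   (as produced by [qc_filter()]).
#' @return The log with added columns `excluded` (logical) and `reason`.
#' @examples
#' log <- tibble::tibble(participant_id = c("a", "b"),
#'                       n_trials = c(150, 150), n_removed = c(51, 50))
#' exclude_participants(log)$excluded  # TRUE FALSE
#' @export
exclude_participants <- function(qc_log) {
  qc_log |>
    dplyr::mutate(
      excluded = .data$n_removed / .data$n_trials > 1 / 3,
      reason = dplyr::if_else(.data$excluded,
                              "more than a third of trials removed",
                              NA_character_))
}

#' Condition-by-expectedness session summary
#'
#' Aggregates QC'd per-trial metrics into the participant x condition x
#' expectedness cells used by the inferential analyses: interception rate
#' (%), mean minimum gaze-ball error, mean pupil peak delta, and (when
#' columns are present) mean `alpha2`, mean `|eps2|`, `|eps3|`. Also returns
#' per-condition difference scores; for interception rate the difference is
#' expected minus unexpected (better performance on expected trials is
#' positive), while for gaze error and pupil measures it is unexpected minus
#' expected (greater disruption/surprise on unexpected trials is positive).
#'
#' @param metrics QC'd per-trial metrics (practice trials are dropped).
#' @return A list of class `pbac_summary` with `cells` (one row per
#'   participant x condition x expectedness) and `deltas` (one row per
#'   participant x condition). Empty cells yield NA with a message.
#' @export
summarize_session <- function(metrics) {
  m <- dplyr::filter(metrics, .data$condition != "practice")
  has <- function(col) col %in% names(m)
  cells <- m |>
    dplyr::group_by(.data$participant_id, .data$condition,
                    .data$congruency_label) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      interception_rate = 100 * mean(.data$hit, na.rm = TRUE),
      mean_gaze_error = mean(.data$min_gaze_ball_error, na.rm = TRUE),
      mean_pupil_peak = mean(.data$pupil_peak_delta, na.rm = TRUE),
      mean_alpha2 = if (has("alpha2")) mean(abs(.data$alpha2), na.rm = TRUE)
                    else NA_real_,
      mean_abs_eps2 = if (has("eps2")) mean(abs(.data$eps2), na.rm = TRUE)
                      else NA_real_,
      mean_abs_eps3 = if (has("eps3")) mean(abs(.data$eps3), na.rm = TRUE)
                      else NA_real_,
      .groups = "drop")
  full <- tidyr::expand_grid(
    participant_id = unique(cells$participant_id),
    condition = unique(cells$condition),
    congruency_label = c("expected", "unexpected"))
  missing_cells <- dplyr::anti_join(
    full, cells, by = c("participant_id", "condition", "congruency_label"))
  if (nrow(missing_cells) > 0) {
    message(nrow(missing_cells), " empty cell(s); summaries contain NA")
    cells <- dplyr::bind_rows(cells, missing_cells)
  }
  wide <- cells |>
    tidyr::pivot_wider(id_cols = c("participant_id", "condition"),
                       names_from = "congruency_label",
                       values_from = c("interception_rate",
                                       "mean_gaze_error",
                                       "mean_pupil_peak", "mean_alpha2",
                                       "mean_abs_eps2", "mean_abs_eps3"))
  deltas <- wide |>
    dplyr::transmute(
      .data$participant_id, .data$condition,
      delta_interception = .data$interception_rate_expected -
        .data$interception_rate_unexpected,
      delta_gaze_error = .data$mean_gaze_error_unexpected -
        .data$mean_gaze_error_expected,
      delta_pupil_peak = .data$mean_pupil_peak_unexpected -
        .data$mean_pupil_peak_expected,
      delta_alpha2 = .data$mean_alpha2_unexpected -
        .data$mean_alpha2_expected)
  structure(list(cells = cells, deltas = deltas), class = "pbac_summary")
}

#' @export
print.pbac_summary <- function(x, ...) {
  cat("<pbac_summary>\n")
  print(as.data.frame(
    x$cells |>
      dplyr::group_by(.data$condition, .data$congruency_label) |>
      dplyr::summarise(interception_rate = mean(.data$interception_rate,
                                                na.rm = TRUE),
                       mean_gaze_error = mean(.data$mean_gaze_error,
                                              na.rm = TRUE),
                       mean_pupil_peak = mean(.data$mean_pupil_peak,
                                              na.rm = TRUE),
                       .groups = "drop")),
    row.names = FALSE, digits = 3)
  invisible(x)
}

# Cohen's d for paired/one-sample data with a 95% CI from the noncentral t.
cohens_d_ci <- function(x, conf = 0.95) {
  n <- length(x)
  d <- mean(x) / stats::sd(x)
  t_obs <- d * sqrt(n)
  df <- n - 1
  lim <- function(p) {
    # pt warns about precision at extreme noncentrality; harmless here
    f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp)) - p
    lo <- t_obs - 10 * sqrt(n) - 10
    hi <- t_obs + 10 * sqrt(n) + 10
    tryCatch(stats::uniroot(f, c(lo, hi))$root / sqrt(n),
             error = function(e) NA_real_)
  }
  a <- (1 - conf) / 2
  c(d = d, lo = lim(1 - a), hi = lim(a))
}

paired_t_row <- function(name, x, y = NULL, mu = 0) {
  diffs <- if (is.null(y)) x - mu else x - y
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 3) {
    return(tibble::tibble(test = name, statistic = NA_real_, df = NA_real_,
                          p = NA_real_, effect = NA_real_,
                          effect_lo = NA_real_, effect_hi = NA_real_,
                          note = "too few observations"))
  }
  if (stats::sd(diffs) == 0) {
    return(tibble::tibble(test = name, statistic = NA_real_, df = n - 1,
                          p = NA_real_, effect = NA_real_,
                          effect_lo = NA_real_, effect_hi = NA_real_,
                          note = "degenerate: zero-variance differences"))
  }
  tt <- stats::t.test(diffs)
  dd <- cohens_d_ci(diffs)
  tibble::tibble(test = name, statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 effect = unname(dd["d"]), effect_lo = unname(dd["lo"]),
                 effect_hi = unname(dd["hi"]), note = NA_character_)
}

# Univariate repeated-measures ANOVA via aov Error strata; partial eta^2
# per effect from its own error stratum.
rm_anova_2way <- function(df, dv) {
  df <- df[is.finite(df[[dv]]), ]
  df$participant_id <- factor(df$participant_id)
  df$condition <- factor(df$condition)
  df$congruency_label <- factor(df$congruency_label)
  form <- stats::as.formula(paste(
    dv, "~ condition * congruency_label +",
    "Error(participant_id / (condition * congruency_label))"))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid_i <- which(terms == "Residuals")
    if (length(resid_i) == 0) next
    ss_err <- tab[resid_i, "Sum Sq"]
    df_err <- tab[resid_i, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), resid_i)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        test = paste0("anova:", dv, ":", terms[i]),
        statistic = tab[i, "F value"], df = tab[i, "Df"],
        df_error = df_err, p = tab[i, "Pr(>F)"],
        effect = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_err),
        effect_lo = NA_real_, effect_hi = NA_real_, note = "partial eta^2")
    }
  }
  dplyr::bind_rows(rows)
}

#' Inferential statistics over a session summary
#'
#' Runs the study's inferential battery on a [summarize_session()] result:
#' 3 (condition) x 2 (expectedness) repeated-measures ANOVAs with partial
#' eta squared for interception rate, gaze tracking error and learning rate;
#' a one-way repeated-measures comparison of unexpected-trial pupil peaks
#' across conditions; a one-sample t-test of predictive-gaze recoding
#' toward the likely side (when supplied); paired post-hoc t-tests on the
#' per-condition difference scores with Bonferroni adjustment within each
#' post-hoc family; Cohen's d with 95% CI throughout; and an optional
#' BIC-approximation Bayes factor `exp((BIC_null - BIC_alt) / 2)` (a
#' substitute for fully Bayesian factors -- different priors give different
#' numbers).
#'
#' @param summary A `pbac_summary`.
#' @param predictive_gaze Optional numeric vector, one median predictive
#'   gaze angle (degrees toward the likely side) per participant, for the
#'   one-sample manipulation check.
#' @param bayes_factors Add BIC-approximation Bayes factors to t-test rows.
#' @return A tibble of class `pbac_stats`: one row per test with `test`,
#'   `statistic`, `df`, `p`, `p_adjusted`, `effect` (Cohen's d or partial
#'   eta squared), `effect_lo`, `effect_hi`, `bf_bic`, `note`.
#' @export
inferential_suite <- function(summary, predictive_gaze = NULL,
                              bayes_factors = TRUE) {
  cells <- summary$cells
  deltas <- summary$deltas
  rows <- list()

  for (dv in c("interception_rate", "mean_gaze_error", "mean_alpha2")) {
    if (all(!is.finite(cells[[dv]]))) next
    rows[[length(rows) + 1]] <- rm_anova_2way(cells, dv)
  }

  # one-way (condition) on unexpected-trial pupil peaks
  unexp <- dplyr::filter(cells, .data$congruency_label == "unexpected")
  if (any(is.finite(unexp$mean_pupil_peak))) {
    pup <- unexp
    pup$congruency_label <- NULL
    pup$participant_id <- factor(pup$participant_id)
    pup$condition <- factor(pup$condition)
    fit <- stats::aov(mean_pupil_peak ~ condition +
                        Error(participant_id / condition), data = pup)
    sm <- summary(fit)
    for (stratum in sm) {
      tab <- stratum[[1]]
      terms <- trimws(rownames(tab))
      resid_i <- which(terms == "Residuals")
      if (length(resid_i) == 0 || length(terms) == 1) next
      ss_err <- tab[resid_i, "Sum Sq"]
      for (i in setdiff(seq_len(nrow(tab)), resid_i)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          test = "anova:pupil_peak_unexpected:condition",
          statistic = tab[i, "F value"], df = tab[i, "Df"],
          df_error = tab[resid_i, "Df"], p = tab[i, "Pr(>F)"],
          effect = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_err),
          effect_lo = NA_real_, effect_hi = NA_real_,
          note = "partial eta^2")
      }
    }
  }

  if (!is.null(predictive_gaze)) {
    rows[[length(rows) + 1]] <-
      paired_t_row("t:predictive_gaze_vs_zero", predictive_gaze, mu = 0)
  }

  # post-hoc family: pairwise condition contrasts on each delta score
  conds <- sort(unique(deltas$condition))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  for (dv in c("delta_interception", "delta_gaze_error",
               "delta_pupil_peak")) {
    if (all(!is.finite(deltas[[dv]]))) next
    fam <- purrr::map(pairs, function(pr) {
      w <- deltas |>
        dplyr::filter(.data$condition %in% pr) |>
        tidyr::pivot_wider(id_cols = "participant_id",
                           names_from = "condition",
                           values_from = dplyr::all_of(dv))
      paired_t_row(paste0("posthoc:", dv, ":", pr[1], "_vs_", pr[2]),
                   w[[pr[1]]], w[[pr[2]]])
    }) |> dplyr::bind_rows()
    fam$p_adjusted <- stats::p.adjust(fam$p, method = "bonferroni")
    rows[[length(rows) + 1]] <- fam
  }

  out <- dplyr::bind_rows(rows)
  if (!"p_adjusted" %in% names(out)) out$p_adjusted <- NA_real_
  out$p_adjusted <- dplyr::coalesce(out$p_adjusted, out$p)

  if (bayes_factors) {
    out$bf_bic <- NA_real_
    tidx <- grepl("^(t|posthoc):", out$test)
    # recompute per t-test from its inputs is handled at row build time for
    # ANOVA rows; for t rows use the one-sample BIC approximation on the
    # stored statistic and df
    out$bf_bic[tidx] <- purrr::map2_dbl(
      out$statistic[tidx], out$df[tidx], function(tv, df) {
        if (!is.finite(tv) || !is.finite(df)) return(NA_real_)
        n <- df + 1
        # BIC_null - BIC_alt = n log(1 + t^2/df) - log n
        exp((n * log(1 + tv^2 / df) - log(n)) / 2)
      })
  } else {
    out$bf_bic <- NA_real_
  }
  class(out) <- c("pbac_stats", class(out))
  out
}

#' Correlations between interception and predictive measures
#'
#' Pearson or Spearman correlations between interception rate and another
#' unexpected-trial measure, per condition.
#'
#' @param summary A `pbac_summary`.
#' @param measure Column of the cells table to correlate with interception
#'   rate (on unexpected trials).
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble with one row per condition: estimate, p.
#' @export
correlate_performance <- function(summary,
                                  measure = "mean_gaze_error",
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  unexp <- dplyr::filter(summary$cells,
                         .data$congruency_label == "unexpected")
  unexp |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      estimate = tryCatch(
        stats::cor.test(.data$interception_rate, .data[[measure]],
                        method = method, exact = FALSE)$estimate,
        error = function(e) NA_real_),
      p = tryCatch(
        stats::cor.test(.data$interception_rate, .data[[measure]],
                        method = method, exact = FALSE)$p.value,
        error = function(e) NA_real_),
      .groups = "drop") |>
    dplyr::mutate(measure = measure, method = method)
}
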