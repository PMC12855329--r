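#' Plot belief trajectories
#'
#' Trial-wise HGF states: the level-1 prediction against the observed
#' inputs, with the level-2/3 precision-weighted prediction errors below.
#'
#' @param object A `pbac_trajectories` tibble from [hgf_filter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pbac_trajectories <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("trial", "muhat1", "eps2", "eps3", "alpha2")],
    -"trial", names_to = "state", values_to = "value")
  pts <- tibble::tibble(trial = object$trial, state = "muhat1",
                        value = object$u)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = pts, shape = 3, alpha = 0.5) +
    ggplot2::facet_wrap(~state, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL,
                  title = "HGF belief trajectories") +
    ggplot2::theme_minimal()
}

#' Plot model-selection posteriors
#'
#' Expected model frequencies and protected exceedance probabilities from
#' random-effects Bayesian model selection.
#'
#' @param object A `pbac_bms` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pbac_bms <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("expected_frequency", "protected_exceedance"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Random-effects model selection") +
    ggplot2::theme_minimal()
}

#' Plot condition-by-expectedness summaries
#'
#' @param object A `pbac_summary` from [summarize_session()].
#' @param type `"interception"`, `"gaze_error"` or `"pupil"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pbac_summary <- function(object,
                                  type = c("interception", "gaze_error",
                                           "pupil"),
                                  ...) {
  type <- match.arg(type)
  dv <- switch(type, interception = "interception_rate",
               gaze_error = "mean_gaze_error", pupil = "mean_pupil_peak")
  lab <- switch(type, interception = "interception rate (%)",
                gaze_error = "min gaze-ball error (deg)",
                pupil = "pupil peak delta (mm)")
  df <- object$cells[is.finite(object$cells[[dv]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data[[dv]],
                                   fill = .data$congruency_label)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(0.8),
                          width = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.8),
                        alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = lab, fill = "trial type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
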