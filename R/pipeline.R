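#' Read a pipeline configuration
#'
#' Configurations are YAML files (or lists) with optional sections:
#' `n_agents`, `agent` (arguments to [agent_params()]), `design` (see
#' [simulate_session()]), `geometry` (arguments to [court_geometry()]),
#' `winsorize` (logical), `models` (character vector of models to fit).
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated config list with defaults filled in.
#' @export
read_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(n_agents = 3, agent = list(), design = list(),
                   geometry = list(), winsorize = TRUE,
                   models = c("hgf3", "hgf2", "hgf4", "rw", "sk1"))
  cfg <- utils::modifyList(defaults, config)
  if (length(cfg$geometry) > 0) {
    cfg$design$geometry <- do.call(court_geometry, cfg$geometry)
  }
  cfg
}

#' Simulate a cohort of closed-loop sessions
#'
#' @param config A config list or YAML path (see [read_config()]).
#' @param seed Integer seed; participant i runs at `seed + i`.
#' @param out_dir Optional directory: sessions are written as CSV/JSON
#'   artifacts via [write_session()], plus a plain-text run log.
#' @return A list of `pbac_session` objects (invisibly when writing).
#' @export
pbac_simulate <- function(config = list(), seed = 1L, out_dir = NULL) {
  cfg <- read_config(config)
  agent <- do.call(agent_params, cfg$agent)
  sessions <- purrr::map(seq_len(cfg$n_agents), function(i) {
    simulate_session(agent, cfg$design, seed = seed + i,
                     participant_id = sprintf("agent%02d", i))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::walk(sessions, write_session, dir = out_dir)
    write_run_log(out_dir, "simulate", cfg, seed)
    return(invisible(sessions))
  }
  sessions
}

#' Preprocess sessions into per-trial metrics
#'
#' @param sessions A list of `pbac_session` objects (or a single one).
#' @param out_dir Optional directory for a `trial_metrics.csv` artifact.
#' @return A combined `pbac_metrics` tibble across participants.
#' @export
pbac_preprocess <- function(sessions, out_dir = NULL) {
  if (inherits(sessions, "pbac_session")) sessions <- list(sessions)
  metrics <- purrr::map(sessions, compute_trial_metrics) |>
    dplyr::bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metrics, file.path(out_dir, "trial_metrics.csv"))
  }
  metrics
}

#' Fit the candidate learning models to every participant
#'
#' Builds each participant's binary stimulus/response pair (ball side `u`,
#' gaze side `y`, 1 = the block-1 likely side) over the experimental blocks
#' and fits the requested models by observing-the-observer MAP with Laplace
#' log-model evidence. Also returns the fitted 3-level HGF belief
#' trajectories (at the participant's MAP) aligned with the trial tables.
#'
#' @param sessions A list of `pbac_session` objects.
#' @param models Models to fit.
#' @param n_restarts Optimisation multistarts per fit.
#' @param seed Integer seed.
#' @param out_dir Optional directory for `fits.json`, `lme.csv` and
#'   `trajectories.csv` artifacts.
#' @return A list with `fits` (tibble of per-participant, per-model
#'   glances), `lme` (participants x models matrix) and `trajectories`
#'   (per-trial HGF3 states joined to participant/block/trial keys).
#' @export
pbac_fit <- function(sessions, models = c("hgf3", "hgf2", "hgf4", "rw",
                                          "sk1"),
                     n_restarts = 10, seed = 1L, out_dir = NULL) {
  if (inherits(sessions, "pbac_session")) sessions <- list(sessions)
  per <- purrr::imap(sessions, function(s, i) {
    tr <- dplyr::filter(s$trials, .data$condition != "practice")
    fits <- purrr::map(models, function(m) {
      fit_map_laplace(tr$u, tr$y, model = m, n_restarts = n_restarts,
                      seed = seed + i)
    })
    names(fits) <- models
    gl <- purrr::map(fits, glance) |>
      dplyr::bind_rows() |>
      dplyr::mutate(participant_id = s$participant_id, .before = 1)
    traj <- NULL
    if ("hgf3" %in% models) {
      f <- fits[["hgf3"]]
      est <- f$estimates
      traj <- hgf_filter(tr$u, hgf_params(
        n_levels = 3, omega2 = est$omega2, omega3 = est$omega3,
        zeta = est$zeta,
        mu2_0 = default_init()$mu2_0, sigma2_0 = default_init()$sigma2_0,
        mu3_0 = default_init()$mu3_0, sigma3_0 = default_init()$sigma3_0))
      traj <- dplyr::bind_cols(
        tr[, c("participant_id", "block", "condition", "trial_index",
               "congruency_label")],
        traj[, setdiff(names(traj), "trial")])
    }
    list(glances = gl, traj = traj)
  })
  fits <- purrr::map(per, "glances") |> dplyr::bind_rows()
  lme <- fits |>
    dplyr::select("participant_id", "model", "lme") |>
    tidyr::pivot_wider(names_from = "model", values_from = "lme")
  lme_mat <- as.matrix(lme[, -1])
  rownames(lme_mat) <- lme$participant_id
  trajectories <- purrr::map(per, "traj") |> dplyr::bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(lme, file.path(out_dir, "lme.csv"))
    if (nrow(trajectories) > 0) {
      readr::write_csv(trajectories, file.path(out_dir, "trajectories.csv"))
    }
  }
  list(fits = fits, lme = lme_mat, trajectories = trajectories)
}

#' Compare fitted models by random-effects Bayesian model selection
#'
#' @param fit_result Result of [pbac_fit()] (or an LME matrix).
#' @param n_draws Monte-Carlo draws for exceedance probabilities.
#' @param seed Integer seed.
#' @param out_dir Optional directory for a `bms.json` artifact.
#' @return A `pbac_bms` object.
#' @export
pbac_compare <- function(fit_result, n_draws = 1e6, seed = 1L,
                         out_dir = NULL) {
  lme <- if (is.list(fit_result) && !is.null(fit_result$lme)) {
    fit_result$lme
  } else as.matrix(fit_result)
  bms <- bms_random_effects(lme, n_draws = n_draws, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(tidy(bms), file.path(out_dir, "bms.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bms
}

#' Clean, aggregate and test a cohort's metrics
#'
#' Applies the cleaning rules (trial QC at 25% missing, participant
#' exclusion at one third removed, per-metric per-condition 3-SD
#' Winsorization), joins fitted HGF trajectories when available, aggregates
#' to condition x expectedness cells and runs the inferential battery.
#'
#' @param metrics Per-trial metrics from [pbac_preprocess()].
#' @param fit_result Optional [pbac_fit()] result whose HGF3 trajectories
#'   are joined by participant/block/trial for learning-rate summaries.
#' @param winsorize Apply Winsorization (per metric within participant x
#'   condition x expectedness distributions pooled across participants).
#' @param out_dir Optional directory: writes `summary_cells.csv`,
#'   `summary_deltas.csv`, `stats.json` and figure files.
#' @return A list of class `pbac_report` with `summary` (`pbac_summary`),
#'   `stats` (`pbac_stats`), `qc_log`, `exclusions`.
#' @export
pbac_report <- function(metrics, fit_result = NULL, winsorize = TRUE,
                        out_dir = NULL) {
  if (!is.null(fit_result) && !is.null(fit_result$trajectories) &&
      nrow(fit_result$trajectories) > 0) {
    metrics <- dplyr::left_join(
      metrics,
      fit_result$trajectories[, c("participant_id", "block", "trial_index",
                                  "alpha2", "eps2", "eps3")],
      by = c("participant_id", "block", "trial_index"))
  }
  qcd <- qc_filter(metrics)
  qc_log <- attr(qcd, "qc_log")
  excl <- exclude_participants(qc_log)
  keep <- excl$participant_id[!excl$excluded]
  qcd <- dplyr::filter(qcd, .data$participant_id %in% keep)

  if (winsorize) {
    num_cols <- intersect(c("min_gaze_ball_error", "pupil_peak_delta",
                            "predictive_gaze_toward_likely", "alpha2",
                            "eps2", "eps3"), names(qcd))
    qcd <- qcd |>
      dplyr::group_by(.data$condition, .data$congruency_label) |>
      dplyr::mutate(dplyr::across(
        dplyr::all_of(num_cols),
        function(v) if (sum(is.finite(v)) >= 3) winsorize(v) else v)) |>
      dplyr::ungroup()
  }

  summary <- summarize_session(qcd)
  pg <- qcd |>
    dplyr::filter(.data$condition == "probability") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(pg = stats::median(.data$predictive_gaze_toward_likely,
                                        na.rm = TRUE), .groups = "drop")
  stats_tbl <- inferential_suite(summary, predictive_gaze = pg$pg)

  out <- structure(list(summary = summary, stats = stats_tbl,
                        qc_log = qc_log, exclusions = excl),
                   class = "pbac_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(summary$cells, file.path(out_dir, "summary_cells.csv"))
    readr::write_csv(summary$deltas,
                     file.path(out_dir, "summary_deltas.csv"))
    jsonlite::write_json(stats_tbl, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    for (p in c("interception", "pupil")) {
      fig <- autoplot(summary, type = p)
      ggplot2::ggsave(file.path(out_dir, paste0("figure_", p, ".png")),
                      fig, width = 6, height = 4, dpi = 150)
    }
  }
  out
}

#' @export
print.pbac_report <- function(x, ...) {
  print(x$summary)
  cat("\nTests:\n")
  print(as.data.frame(x$stats[, c("test", "statistic", "df", "p",
                                  "p_adjusted", "effect")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

write_run_log <- function(out_dir, verb, cfg, seed) {
  cfg_plain <- utils::capture.output(utils::str(cfg))
  lines <- c(
    sprintf("verb: %s", verb),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", seed),
    sprintf("config_hash: %s",
            paste0(substr(as.character(sum(utf8ToInt(paste(
              cfg_plain, collapse = "")))), 1, 12))),
    "config:", cfg_plain)
  writeLines(lines, file.path(out_dir, "run_log.txt"))
}
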