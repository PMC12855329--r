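#' Parameters of a closed-loop generative agent
#'
#' A synthetic participant for end-to-end testing: it holds a generative
#' learning model over the ball's side, turns its trial-wise prediction into
#' a gaze side via the unit-square sigmoid response model, fixates the
#' corresponding release hole with Gaussian noise, pursues the ball with a
#' first-order lag after release, intercepts with a congruency-dependent hit
#' probability, and emits a phasic pupil response scaled by the Shannon
#' surprisal of the observed side under its own prediction, with blinks as
#' contiguous missing runs.
#'
#' @param generative_model `"hgf3"`, `"hgf2"`, `"hgf4"` or `"rw"`.
#' @param model_params For HGF models a [hgf_params()] object; for `"rw"` a
#'   list with `alpha` and `v0`.
#' @param response_zeta Decisiveness of the side choice (> 0; `Inf` =
#'   deterministic argmax).
#' @param hit_prob_congruent,hit_prob_incongruent Interception probability
#'   when gaze side does / does not match the release side
#'   (`hit_prob_congruent >= hit_prob_incongruent`).
#' @param pursuit_lag First-order pursuit time constant, seconds (0 = gaze
#'   locked on the ball).
#' @param gaze_noise_sd Fixation/pursuit noise on the gaze point, metres.
#' @param pupil_baseline Tonic pupil diameter, mm.
#' @param pupil_gain Phasic dilation per unit surprisal, mm.
#' @param pupil_kernel Numeric `c(latency, width)`, seconds: the
#'   gamma-shaped impulse response peaks `latency` s after release with
#'   spread `width`.
#' @param pupil_noise_sd Measurement noise per eye, mm.
#' @param blink_rate Blink events per minute; each blink is a missing run of
#'   100-300 ms.
#' @return A list of class `pbac_agent`.
#' @export
agent_params <- function(generative_model = c("hgf3", "hgf2", "hgf4", "rw"),
                         model_params = NULL,
                         response_zeta = 5,
                         hit_prob_congruent = 0.8,
                         hit_prob_incongruent = 0.3,
                         pursuit_lag = 0.12,
                         gaze_noise_sd = 0.1,
                         pupil_baseline = 3.5,
                         pupil_gain = 0.4,
                         pupil_kernel = c(latency = 1, width = 0.7),
                         pupil_noise_sd = 0.02,
                         blink_rate = 10) {
  generative_model <- match.arg(generative_model)
  if (is.null(model_params)) {
    model_params <- if (generative_model == "rw") {
      list(alpha = 0.3, v0 = 0.5)
    } else {
      hgf_params(n_levels = as.integer(substring(generative_model, 4)))
    }
  }
  stopifnot(hit_prob_congruent >= 0, hit_prob_congruent <= 1,
            hit_prob_incongruent >= 0, hit_prob_incongruent <= 1)
  if (hit_prob_congruent < hit_prob_incongruent) {
    stop("hit_prob_congruent must be >= hit_prob_incongruent", call. = FALSE)
  }
  if (any(c(gaze_noise_sd, pupil_noise_sd) < 0) || pursuit_lag < 0 ||
      blink_rate < 0) {
    stop("noise SDs, pursuit_lag and blink_rate must be >= 0", call. = FALSE)
  }
  if (response_zeta <= 0) stop("response_zeta must be > 0", call. = FALSE)
  structure(list(generative_model = generative_model,
                 model_params = model_params,
                 response_zeta = response_zeta,
                 hit_prob_congruent = hit_prob_congruent,
                 hit_prob_incongruent = hit_prob_incongruent,
                 pursuit_lag = pursuit_lag,
                 gaze_noise_sd = gaze_noise_sd,
                 pupil_baseline = pupil_baseline,
                 pupil_gain = pupil_gain,
                 pupil_kernel = pupil_kernel,
                 pupil_noise_sd = pupil_noise_sd,
                 blink_rate = blink_rate),
            class = "pbac_agent")
}

# Unit-square sigmoid choice probability, with the argmax limit.
zeta_sigmoid <- function(muhat1, zeta) {
  if (is.infinite(zeta)) {
    return(ifelse(muhat1 > 0.5, 1, ifelse(muhat1 < 0.5, 0, 0.5)))
  }
  m <- pmin(pmax(muhat1, 1e-9), 1 - 1e-9)
  la <- zeta * log(m); lb <- zeta * log1p(-m)
  1 / (1 + exp(lb - la))
}

# One-step-ahead prediction p(u = 1) given the observed input history.
agent_predict <- function(agent, u_hist) {
  mp <- agent$model_params
  if (agent$generative_model == "rw") {
    if (length(u_hist) == 0) return(mp$v0)
    res <- rw_filter_cpp(as.numeric(u_hist), mp$alpha, mp$v0)
    return(res$v[length(u_hist)])
  }
  nl <- as.integer(substring(agent$generative_model, 4))
  if (length(u_hist) == 0) return(stats::plogis(mp$mu2_0))
  res <- hgf_filter_cpp(as.numeric(u_hist), nl, mp$kappa,
                        mp$omega2, mp$omega3, mp$omega4,
                        mp$mu2_0, mp$sigma2_0, mp$mu3_0, mp$sigma3_0,
                        mp$mu4_0, mp$sigma4_0)
  if (!res$ok) stop("agent generative model rejected its own parameters",
                    call. = FALSE)
  stats::plogis(res$mu2[length(u_hist)])
}

#' Simulate binary side choices from a generative agent on a fixed sequence
#'
#' Open-loop counterpart of [simulate_session()] for model/parameter
#' recovery work: runs the agent's generative model over a fixed binary
#' input sequence and samples a response per trial from the unit-square
#' sigmoid of the model's one-step-ahead prediction.
#'
#' @param u Binary input sequence (1 = most probable side).
#' @param agent An [agent_params()] object.
#' @param seed Integer seed.
#' @return A tibble with `trial`, `u`, `muhat1` (prediction before seeing
#'   `u`), `p_choice` and the sampled binary response `y`.
#' @export
simulate_agent_choices <- function(u, agent = agent_params(), seed = 1L) {
  check_binary(u)
  mp <- agent$model_params
  muhat1 <- if (agent$generative_model == "rw") {
    rw_filter_cpp(as.numeric(u), mp$alpha, mp$v0)$vhat
  } else {
    nl <- as.integer(substring(agent$generative_model, 4))
    res <- hgf_filter_cpp(as.numeric(u), nl, mp$kappa,
                          mp$omega2, mp$omega3, mp$omega4,
                          mp$mu2_0, mp$sigma2_0, mp$mu3_0, mp$sigma3_0,
                          mp$mu4_0, mp$sigma4_0)
    if (!res$ok) stop("agent generative model rejected its own parameters",
                      call. = FALSE)
    res$muhat1
  }
  p <- zeta_sigmoid(muhat1, agent$response_zeta)
  y <- with_local_seed(seed, as.integer(stats::runif(length(u)) < p))
  tibble::tibble(trial = seq_along(u), u = as.numeric(u),
                 muhat1 = muhat1, p_choice = p, y = y)
}

#' Synthesise a pupil-diameter trace for one trial
#'
#' Generates a binocular pupil trace at 90 Hz:
#' `baseline + pupil_gain * surprise * kernel(t - release) + noise`,
#' where the kernel is a gamma-shaped impulse response with maximum 1 at
#' `latency` seconds post-release (`k(t) = (t/L)^a exp(a (1 - t/L))`,
#' shape `a = (latency/width)^2`). Blinks are inserted as contiguous
#' missing runs (100-300 ms) at the agent's blink rate, knocking out both
#' eyes.
#'
#' @param surprise Non-negative surprisal driving the phasic response.
#' @param agent An [agent_params()] object.
#' @param t_s Sample times, seconds (release at `release_t`); must cover the
#'   baseline window through arrival + 3 s for downstream analysis.
#' @param release_t Ball release time, seconds.
#' @param seed Integer seed (NULL = use the current RNG stream).
#' @return A tibble with `t_s`, `pupil_left_mm`, `pupil_right_mm`,
#'   `valid_left`, `valid_right`. Missing samples carry NA diameters and
#'   FALSE validity.
#' @export
synth_pupil_trace <- function(surprise, agent = agent_params(),
                              t_s = seq(-0.5, 4, by = 1 / 90),
                              release_t = 0, seed = NULL) {
  stopifnot(is.finite(surprise), surprise >= 0)
  run <- function() {
    base <- agent$pupil_baseline +
      agent$pupil_gain * surprise * pupil_kernel_fn(t_s - release_t, agent)
    n <- length(t_s)
    left <- base + stats::rnorm(n, sd = agent$pupil_noise_sd)
    right <- base + stats::rnorm(n, sd = agent$pupil_noise_sd)
    miss <- draw_blinks(t_s, agent$blink_rate)
    left[miss] <- NA_real_; right[miss] <- NA_real_
    tibble::tibble(t_s = t_s, pupil_left_mm = left, pupil_right_mm = right,
                   valid_left = !miss, valid_right = !miss)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

pupil_kernel_fn <- function(t, agent) {
  L <- agent$pupil_kernel[[1]]
  w <- agent$pupil_kernel[[2]]
  a <- (L / w)^2
  k <- numeric(length(t))
  pos <- t > 0
  k[pos] <- (t[pos] / L)^a * exp(a * (1 - t[pos] / L))
  k
}

draw_blinks <- function(t_s, blink_rate) {
  n <- length(t_s)
  miss <- logical(n)
  if (blink_rate <= 0) return(miss)
  span <- diff(range(t_s))
  n_blinks <- stats::rpois(1, blink_rate * span / 60)
  if (n_blinks == 0) return(miss)
  onsets <- stats::runif(n_blinks, min(t_s), max(t_s))
  durs <- stats::runif(n_blinks, 0.1, 0.3)
  for (b in seq_len(n_blinks)) {
    miss[t_s >= onsets[b] & t_s <= onsets[b] + durs[b]] <- TRUE
  }
  miss
}

#' Synthesise a gaze trace for one trial
#'
#' Before release the agent fixates the chosen release hole (with Gaussian
#' noise on the fixated point); after release gaze pursues the ball with a
#' first-order lag (`pursuit_lag` = 0 locks gaze onto the ball). On
#' incongruent trials the ball appears at the other hole, so the initial
#' gaze-ball separation is the full inter-hole angle (~85 degrees). The
#' in-world gaze coordinate `gaze_x_m` is the x position of the fixated
#' point; direction vectors are expressed as yaw/pitch from the viewer's eye
#' position.
#'
#' @param chosen_side Side the agent fixates before release (`"left"` /
#'   `"right"`).
#' @param ball A ball-flight tibble from [ball_flight()].
#' @param agent An [agent_params()] object.
#' @param geom A [court_geometry()].
#' @param t_s Sample times (release at 0); times beyond the flight hold the
#'   final ball position.
#' @param seed Integer seed (NULL = current RNG stream).
#' @return A tibble with `t_s`, `gaze_x_m`, `gaze_yaw_deg`,
#'   `gaze_pitch_deg`.
#' @export
synth_gaze_trace <- function(chosen_side, ball, agent = agent_params(),
                             geom = court_geometry(),
                             t_s = seq(-0.5, 4, by = 1 / 90),
                             seed = NULL) {
  check_sides(chosen_side)
  run <- function() {
    sx <- if (chosen_side == "right") 1 else -1
    hole <- c(sx * geom$hole_lateral_offset, geom$hole_height,
              geom$viewer_wall_distance)
    T_fl <- attr(ball, "flight_time")
    bx <- stats::approx(ball$t_s, ball$ball_x_m, xout = pmin(pmax(t_s, 0),
                                                             T_fl))$y
    by <- stats::approx(ball$t_s, ball$ball_y_m, xout = pmin(pmax(t_s, 0),
                                                             T_fl))$y
    bz <- stats::approx(ball$t_s, ball$ball_z_m, xout = pmin(pmax(t_s, 0),
                                                             T_fl))$y
    n <- length(t_s)
    px <- numeric(n); py <- numeric(n); pz <- numeric(n)
    pre <- t_s < 0
    px[pre] <- hole[1]; py[pre] <- hole[2]; pz[pre] <- hole[3]
    cur <- hole
    dt <- stats::median(diff(t_s))
    w <- if (agent$pursuit_lag == 0) 1 else 1 - exp(-dt / agent$pursuit_lag)
    for (i in which(!pre)) {
      target <- c(bx[i], by[i], bz[i])
      cur <- if (agent$pursuit_lag == 0) target else cur + (target - cur) * w
      px[i] <- cur[1]; py[i] <- cur[2]; pz[i] <- cur[3]
    }
    if (agent$gaze_noise_sd > 0) {
      px <- px + stats::rnorm(n, sd = agent$gaze_noise_sd)
      py <- py + stats::rnorm(n, sd = agent$gaze_noise_sd)
    }
    eye <- c(0, geom$eye_height, 0)
    yp <- yaw_pitch_from_point(px, py, pz, eye)
    tibble::tibble(t_s = t_s, gaze_x_m = px,
                   gaze_yaw_deg = yp$yaw_deg, gaze_pitch_deg = yp$pitch_deg)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Simulate a full closed-loop session
#'
#' Runs a synthetic agent through the complete protocol: a 10-trial practice
#' block (8/2 side split) followed by the three 50-trial study conditions in
#' fixed order -- probability-controlled, gaze-contingent (PbAC) and
#' matched-order. On every trial the agent updates its generative model on
#' the previous outcome, samples a gaze side from the response model,
#' fixates that hole with noise, the engine allocates the release side (the
#' PbAC block uses the agent's own gaze at 50 ms before onset), the ball
#' flies, gaze pursues with lag, the hit is drawn from the
#' congruency-dependent probability, and a pupil trace is synthesised with
#' surprise equal to the Shannon surprisal `-log p` of the observed side
#' under the agent's prediction.
#'
#' @param agent An [agent_params()] object.
#' @param design A list of design settings: `likely_side`, `n_trials`,
#'   `n_unexpected`, `practice`, `geometry` (a [court_geometry()]),
#'   `pre_release_s`, `post_arrival_s`. Missing entries take the study
#'   defaults (50 trials, 10 unexpected, practice on).
#' @param seed Integer seed; the same agent, design and seed give an
#'   identical session.
#' @param participant_id Identifier stored in the output tables.
#' @return An object of class `pbac_session`: list with `participant_id`,
#'   `geometry`, `agent`, `trials` (one row per trial: schedule fields plus
#'   `gaze_side`, `u`, `y`, `muhat1`, `surprise`, `hit`, `arrival_s`) and
#'   `timeseries` (long 90 Hz table: `participant_id`, `block`,
#'   `trial_index`, `t_s`, `gaze_x_m`, `gaze_yaw_deg`, `gaze_pitch_deg`,
#'   `ball_x_m`, `ball_y_m`, `ball_z_m`, `pupil_left_mm`, `pupil_right_mm`,
#'   `valid_left`, `valid_right`). Ground-truth surprisal and predictions
#'   live in `trials` for recovery tests.
#' @export
simulate_session <- function(agent = agent_params(), design = list(),
                             seed = 1L, participant_id = "agent01") {
  d <- utils::modifyList(
    list(likely_side = "right", n_trials = 50L, n_unexpected = 10L,
         practice = TRUE, geometry = court_geometry(),
         pre_release_s = 0.5, post_arrival_s = 3),
    design)
  geom <- d$geometry
  sched <- build_session_design(d$likely_side, d$n_trials, d$n_unexpected,
                                d$practice, seed = seed)
  fs <- 90
  flights <- list(left = ball_flight("left", geom),
                  right = ball_flight("right", geom))

  with_local_seed(seed + 7L, {
    u_hist <- numeric(0)
    pbac_sides <- character(d$n_trials)
    trial_rows <- vector("list", nrow(sched))
    ts_rows <- vector("list", nrow(sched))

    for (i in seq_len(nrow(sched))) {
      tr <- sched[i, ]
      muhat1 <- agent_predict(agent, u_hist)
      p_choice <- zeta_sigmoid(muhat1, agent$response_zeta)
      y <- as.integer(stats::runif(1) < p_choice)
      gaze_side <- if (y == 1) tr$likely_side else other_side(tr$likely_side)

      release_side <- tr$release_side
      # pre-release gaze: fixation at the chosen hole; the PbAC gate reads
      # the noisy sample at 50 ms before onset
      sxg <- if (gaze_side == "right") 1 else -1
      n_pre <- round(d$pre_release_s * fs)
      t_pre <- seq(-n_pre, -1) / fs
      gate_x <- NA_real_
      pre_x <- sxg * geom$hole_lateral_offset +
        stats::rnorm(n_pre, sd = agent$gaze_noise_sd)
      gate_idx <- which.min(abs(t_pre + 0.05))
      gate_x <- pre_x[gate_idx]

      if (tr$block == "pbac") {
        release_side <- allocate_pbac(gate_x, tr$congruency_label,
                                      fallback_x = sxg *
                                        geom$hole_lateral_offset)
        pbac_sides[tr$trial_index] <- release_side
      } else if (tr$block == "matched") {
        release_side <- pbac_sides[tr$trial_index]
      }

      u <- as.integer(release_side == tr$likely_side)
      surprise <- -log(if (u == 1) muhat1 else 1 - muhat1)

      ball <- flights[[release_side]]
      T_fl <- attr(ball, "flight_time")
      t_s <- seq(-n_pre, round((T_fl + d$post_arrival_s) * fs)) / fs

      gaze <- synth_gaze_trace(gaze_side, ball, agent, geom, t_s)
      # overwrite the gate-window fixation with the samples the gate saw
      gaze$gaze_x_m[seq_len(n_pre)] <- pre_x
      congruent <- gaze_side == release_side
      hit <- stats::runif(1) <
        if (congruent) agent$hit_prob_congruent else
          agent$hit_prob_incongruent

      pupil <- synth_pupil_trace(surprise, agent, t_s)

      ball_on_grid <- function(col) {
        v <- stats::approx(ball$t_s, ball[[col]], xout = t_s)$y
        v[t_s < 0 | t_s > T_fl] <- NA_real_
        v
      }
      ts_rows[[i]] <- tibble::tibble(
        participant_id = participant_id,
        block = tr$block, trial_index = tr$trial_index, t_s = t_s,
        gaze_x_m = gaze$gaze_x_m, gaze_yaw_deg = gaze$gaze_yaw_deg,
        gaze_pitch_deg = gaze$gaze_pitch_deg,
        ball_x_m = ball_on_grid("ball_x_m"),
        ball_y_m = ball_on_grid("ball_y_m"),
        ball_z_m = ball_on_grid("ball_z_m"),
        pupil_left_mm = pupil$pupil_left_mm,
        pupil_right_mm = pupil$pupil_right_mm,
        valid_left = pupil$valid_left, valid_right = pupil$valid_right)

      trial_rows[[i]] <- tibble::tibble(
        participant_id = participant_id,
        block = tr$block, condition = tr$condition,
        trial_index = tr$trial_index,
        congruency_label = tr$congruency_label,
        likely_side = tr$likely_side, release_side = release_side,
        onset_delay_s = tr$onset_delay_s,
        gaze_side = gaze_side, u = u, y = y,
        muhat1 = muhat1, surprise = surprise,
        hit = hit, arrival_s = T_fl)

      u_hist <- c(u_hist, u)
    }

    structure(list(participant_id = participant_id, geometry = geom,
                   agent = agent,
                   trials = dplyr::bind_rows(trial_rows),
                   timeseries = dplyr::bind_rows(ts_rows)),
              class = "pbac_session")
  })
}

#' @export
print.pbac_session <- function(x, ...) {
  cat(sprintf("<pbac_session> %s: %d trials, %d timeseries samples\n",
              x$participant_id, nrow(x$trials), nrow(x$timeseries)))
  print(dplyr::count(x$trials, .data$block, .data$congruency_label))
  invisible(x)
}

#' Write a session to disk as plain-text artifacts
#'
#' Serialises a session as one trial-table CSV, one long-format timeseries
#' CSV, and a sidecar JSON with the agent ground truth (parameters and
#' per-trial injected surprisal).
#'
#' @param session A `pbac_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pid <- session$participant_id
  paths <- c(
    trials = file.path(dir, paste0(pid, "_trials.csv")),
    timeseries = file.path(dir, paste0(pid, "_timeseries.csv")),
    ground_truth = file.path(dir, paste0(pid, "_ground_truth.json"))
  )
  readr::write_csv(session$trials, paths["trials"])
  readr::write_csv(session$timeseries, paths["timeseries"])
  gt <- list(participant_id = pid,
             agent = session$agent[setdiff(names(session$agent),
                                           "model_params")],
             model_params = unclass(session$agent$model_params),
             surprise = session$trials$surprise,
             muhat1 = session$trials$muhat1)
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
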