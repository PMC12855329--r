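#' Denoise a gaze signal
#'
#' Applies the offline gaze denoising chain: a three-frame moving median
#' filter followed by a second-order low-pass Butterworth filter (15 Hz
#' cutoff by default), run zero-phase (forward-backward) so peaks are not
#' lagged. Data arrive at a constant 90 Hz and are never resampled. Missing
#' samples are excluded from filtering (bridged by linear interpolation for
#' the filter's benefit) and restored as missing afterwards.
#'
#' @param x Numeric signal (NA = missing).
#' @param fs Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz.
#' @return Filtered signal, same length, NA where input was NA.
#' @examples
#' filter_gaze(rep(1, 100))  # constant in, constant out
#' @export
filter_gaze <- function(x, fs = 90, cutoff = 15) {
  na <- !is.finite(x)
  if (all(na)) stop("all samples missing", call. = FALSE)
  xf <- bridge_na(x)
  xf <- stats::runmed(xf, k = 3, endrule = "median")
  xf <- butter_zero_phase(xf, fs, cutoff, order = 2)
  xf[na] <- NA_real_
  xf
}

# Fill NA by linear interpolation (constant extrapolation at the ends).
bridge_na <- function(x) {
  na <- !is.finite(x)
  if (!any(na)) return(x)
  idx <- which(!na)
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

# Zero-phase Butterworth low-pass via forward-backward filtering, with
# odd-reflection padding at both ends to suppress edge transients.
butter_zero_phase <- function(x, fs, cutoff, order = 2) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(x)
  p <- min(n - 1, 45)
  if (p < 2) return(as.numeric(signal::filtfilt(bf, x)))
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x,
          2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1):(p + n)]
}

#' Predictive gaze: mean gaze position in the final 50 ms before release
#'
#' Averages the (filtered) horizontal in-world gaze coordinate over the
#' half-open window `[release - window, release)` and classifies the
#' prediction by sign: > 0 right, < 0 left (exactly 0 classifies left). At
#' 90 Hz the 50 ms window holds 4-5 samples.
#'
#' @param t Sample times, seconds.
#' @param gaze_x Horizontal gaze coordinate, metres (NA = missing).
#' @param release_t Ball release time, seconds (default 0).
#' @param window Window length before release, seconds.
#' @return A list with `gaze_x` (the window mean) and `side`; both NA if no
#'   valid sample falls in the window.
#' @examples
#' predictive_gaze(c(-0.04, -0.03, -0.02, -0.01),
#'                 c(-0.1, 0.3, 0.4, 0.2))
#' @export
predictive_gaze <- function(t, gaze_x, release_t = 0, window = 0.05) {
  sel <- t >= (release_t - window) & t < release_t & is.finite(gaze_x)
  if (!any(sel)) {
    return(list(gaze_x = NA_real_, side = NA_character_))
  }
  m <- mean(gaze_x[sel])
  list(gaze_x = m, side = if (m > 0) "right" else "left")
}

#' Recode a gaze position toward the probabilistically likely side
#'
#' Converts a horizontal gaze coordinate to a signed visual angle with
#' positive values assigned to gaze positions toward the most likely side
#' (the block-1 counterbalance), using the court's viewer-to-wall distance.
#'
#' @param gaze_x Horizontal gaze coordinate, metres (signed, + = right).
#' @param likely_side `"left"` or `"right"`.
#' @param geom A [court_geometry()].
#' @return Signed angle in degrees.
#' @examples
#' geom <- court_geometry()
#' recode_toward_likely(3.67, "right", geom)   # ~ +42.5
#' recode_toward_likely(-0.4, "right", geom)   # ~ -5.7
#' @export
recode_toward_likely <- function(gaze_x, likely_side, geom) {
  check_sides(likely_side)
  a <- visual_angle(gaze_x, geom$viewer_wall_distance)
  ifelse(likely_side == "right", a, -a)
}

#' Minimum gaze-ball angular error
#'
#' Per-frame angle between the gaze and ball direction unit vectors,
#' minimised over the supplied frames (release through ball contact, or
#' until the ball first passes the racquet on misses). Rotation of both
#' vectors together leaves the result unchanged.
#'
#' @param gaze_dir,ball_dir Numeric matrices, frames x 3, of unit vectors
#'   (rows with any non-finite entry are treated as missing).
#' @return Minimum angle in degrees (in \[0, 180\]); NA if no frame has both
#'   vectors valid.
#' @examples
#' g <- matrix(c(0, 0, 1), 1, 3)
#' min_gaze_ball_error(g, g)  # 0
#' @export
min_gaze_ball_error <- function(gaze_dir, ball_dir) {
  gaze_dir <- rbind(gaze_dir); ball_dir <- rbind(ball_dir)
  stopifnot(ncol(gaze_dir) == 3, ncol(ball_dir) == 3,
            nrow(gaze_dir) == nrow(ball_dir))
  ok <- apply(is.finite(gaze_dir), 1, all) &
    apply(is.finite(ball_dir), 1, all)
  if (!any(ok)) return(NA_real_)
  g <- gaze_dir[ok, , drop = FALSE]
  b <- ball_dir[ok, , drop = FALSE]
  g <- g / sqrt(rowSums(g^2))
  b <- b / sqrt(rowSums(b^2))
  d <- pmin(pmax(rowSums(g * b), -1), 1)
  min(acos(d) * 180 / pi)
}

# Direction unit vector from yaw (deg, about +y, 0 = toward the wall along
# +z, positive = rightward) and pitch (deg, positive = up).
dir_from_yaw_pitch <- function(yaw_deg, pitch_deg) {
  yaw <- yaw_deg * pi / 180
  pitch <- pitch_deg * pi / 180
  cbind(x = cos(pitch) * sin(yaw),
        y = sin(pitch),
        z = cos(pitch) * cos(yaw))
}

yaw_pitch_from_point <- function(x, y, z, origin) {
  v <- cbind(x - origin[1], y - origin[2], z - origin[3])
  n <- sqrt(rowSums(v^2))
  v <- v / n
  list(yaw_deg = atan2(v[, 1], v[, 3]) * 180 / pi,
       pitch_deg = asin(pmin(pmax(v[, 2], -1), 1)) * 180 / pi)
}

#' Preprocess a binocular pupil-diameter trace
#'
#' The pupillometry chain: per eye, blink/missing runs are padded by 150 ms
#' on each side and replaced by linear least-squares interpolation (a line
#' fitted to up to 100 ms of valid samples flanking each gap); the repaired
#' signal is low-pass filtered with a second-order 10 Hz Butterworth filter
#' applied zero-phase; finally the two eyes are averaged.
#'
#' @param pupil_left,pupil_right Pupil diameter per eye, mm.
#' @param valid_left,valid_right Logical validity flags per eye (FALSE =
#'   blink/missing).
#' @param fs Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz.
#' @param pad_s Blink padding on each side, seconds.
#' @param interp_window_s Valid-sample window on each side of a gap used for
#'   the least-squares line, seconds.
#' @return Numeric vector: binocular mean pupil diameter, mm. Attribute
#'   `missing_fraction` gives the fraction of samples missing (either eye)
#'   after padding.
#' @export
preprocess_pupil <- function(pupil_left, pupil_right,
                             valid_left = is.finite(pupil_left),
                             valid_right = is.finite(pupil_right),
                             fs = 90, cutoff = 10, pad_s = 0.15,
                             interp_window_s = 0.1) {
  n <- length(pupil_left)
  stopifnot(length(pupil_right) == n, length(valid_left) == n,
            length(valid_right) == n)
  clean <- function(x, valid) {
    x[!valid | !is.finite(x)] <- NA_real_
    miss <- pad_missing_runs(is.na(x), round(pad_s * fs))
    x[miss] <- NA_real_
    list(x = interpolate_gaps(x, max_flank = round(interp_window_s * fs)),
         miss = miss)
  }
  l <- clean(pupil_left, valid_left)
  r <- clean(pupil_right, valid_right)
  filt <- function(x) {
    if (all(is.na(x))) return(x)
    na <- is.na(x)
    y <- butter_zero_phase(bridge_na(x), fs, cutoff, order = 2)
    y[na] <- NA_real_
    y
  }
  lf <- filt(l$x); rf <- filt(r$x)
  out <- rowMeans(cbind(lf, rf), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  attr(out, "missing_fraction") <- mean(l$miss | r$miss)
  out
}

# Extend TRUE runs of `miss` by `pad` samples on each side.
pad_missing_runs <- function(miss, pad) {
  if (!any(miss) || pad <= 0) return(miss)
  idx <- which(miss)
  ext <- unique(unlist(lapply(idx, function(i) (i - pad):(i + pad))))
  ext <- ext[ext >= 1 & ext <= length(miss)]
  out <- logical(length(miss))
  out[ext] <- TRUE
  out
}

# Replace each interior NA run with a least-squares line fitted over up to
# `max_flank` valid samples on each side. Runs touching the ends use the
# available side only (falling back to constant extension).
interpolate_gaps <- function(x, max_flank) {
  na <- is.na(x)
  if (!any(na) || all(na)) return(x)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    gap <- starts[k]:ends[k]
    left <- which(!na & seq_along(x) < starts[k])
    right <- which(!na & seq_along(x) > ends[k])
    left <- utils::tail(left, max_flank)
    right <- utils::head(right, max_flank)
    pts <- c(left, right)
    if (length(pts) == 0) next
    if (length(pts) == 1 || length(unique(pts)) < 2) {
      x[gap] <- x[pts[1]]
    } else {
      fit <- stats::lm.fit(cbind(1, pts), x[pts])
      x[gap] <- fit$coefficients[1] + fit$coefficients[2] * gap
    }
  }
  x
}

#' Baseline-corrected post-release pupil peak (surprisal index)
#'
#' The physiological surprisal measure: the maximum preprocessed pupil
#' diameter between ball release and 3 s after the ball reached the player,
#' minus the mean diameter over the 200 ms immediately before release.
#'
#' @param t Sample times, seconds.
#' @param pupil Preprocessed pupil diameter, mm.
#' @param release_t Ball release time, seconds.
#' @param arrival_t Ball arrival (interception-plane) time, seconds.
#' @param baseline_window Baseline window length before release, seconds.
#' @param post_window Search window after arrival, seconds.
#' @return Peak-minus-baseline difference in mm; NA when either window has
#'   no valid sample.
#' @export
pupil_surprisal_peak <- function(t, pupil, release_t = 0, arrival_t,
                                 baseline_window = 0.2, post_window = 3) {
  base_sel <- t >= (release_t - baseline_window) & t < release_t &
    is.finite(pupil)
  peak_sel <- t >= release_t & t <= (arrival_t + post_window) &
    is.finite(pupil)
  if (!any(base_sel) || !any(peak_sel)) return(NA_real_)
  max(pupil[peak_sel]) - mean(pupil[base_sel])
}

#' Per-trial metrics from a simulated session
#'
#' Runs the full offline pipeline over every trial of a session: gaze
#' denoising ([filter_gaze()]), predictive-gaze extraction and
#' classification, recoding toward the likely side, minimum gaze-ball
#' angular error between release and arrival, pupil preprocessing and the
#' baseline-corrected surprisal peak, plus the per-trial missing-data
#' fraction.
#'
#' @param session A `pbac_session` from [simulate_session()], or a list with
#'   elements `trials` and `timeseries` in the same schemas.
#' @param geom A [court_geometry()] (defaults to the session's).
#' @return A tibble of class `pbac_metrics`, one row per trial:
#'   `participant_id`, `block`, `condition`, `trial_index`,
#'   `congruency_label`, `likely_side`, `release_side`, `hit`,
#'   `predictive_gaze_x`, `predicted_side`, `predictive_gaze_toward_likely`
#'   (degrees), `min_gaze_ball_error` (degrees), `pupil_peak_delta` (mm),
#'   `missing_fraction`.
#' @export
compute_trial_metrics <- function(session, geom = NULL) {
  trials <- session$trials
  ts <- session$timeseries
  if (is.null(geom)) geom <- session$geometry %||% court_geometry()
  eye <- c(0, geom$eye_height, 0)

  ts_split <- split(ts, interaction(ts$block, ts$trial_index, drop = TRUE))
  key <- function(b, i) paste(b, i, sep = ".")

  rows <- purrr::pmap(trials, function(...) {
    tr <- list(...)
    d <- ts_split[[key(tr$block, tr$trial_index)]]
    d <- d[order(d$t_s), ]
    gaze_x_f <- filter_gaze(d$gaze_x_m)
    yaw_f <- filter_gaze(d$gaze_yaw_deg)
    pitch_f <- filter_gaze(d$gaze_pitch_deg)

    pg <- predictive_gaze(d$t_s, gaze_x_f, release_t = 0)
    toward <- if (is.na(pg$gaze_x)) NA_real_ else {
      recode_toward_likely(pg$gaze_x, tr$likely_side, geom)
    }

    in_flight <- d$t_s >= 0 & d$t_s <= tr$arrival_s &
      is.finite(d$ball_x_m)
    err <- if (any(in_flight)) {
      gd <- dir_from_yaw_pitch(yaw_f[in_flight], pitch_f[in_flight])
      yp <- yaw_pitch_from_point(d$ball_x_m[in_flight],
                                 d$ball_y_m[in_flight],
                                 d$ball_z_m[in_flight], eye)
      bd <- dir_from_yaw_pitch(yp$yaw_deg, yp$pitch_deg)
      min_gaze_ball_error(gd, bd)
    } else NA_real_

    pup <- preprocess_pupil(d$pupil_left_mm, d$pupil_right_mm,
                            d$valid_left, d$valid_right)
    peak <- pupil_surprisal_peak(d$t_s, pup, release_t = 0,
                                 arrival_t = tr$arrival_s)

    tibble::tibble(
      participant_id = tr$participant_id,
      block = tr$block, condition = tr$condition,
      trial_index = tr$trial_index,
      congruency_label = tr$congruency_label,
      likely_side = tr$likely_side, release_side = tr$release_side,
      hit = tr$hit,
      predictive_gaze_x = pg$gaze_x, predicted_side = pg$side,
      predictive_gaze_toward_likely = toward,
      min_gaze_ball_error = err,
      pupil_peak_delta = peak,
      missing_fraction = attr(pup, "missing_fraction")
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pbac_metrics", class(out))
  out
}
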