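#' Court geometry for the virtual interception task
#'
#' Builds the geometry of the virtual racquetball court. Two ball release
#' holes sit on the front wall, `hole_lateral_offset` metres either side of
#' the midline, an angular separation `separation_deg` apart as seen from the
#' viewer. The viewer-to-wall distance is never measured directly; it is
#' derived from the printed offset/angle pair via [derive_viewer_distance()].
#' Balls fly from a hole to an interception point `interception_lateral_offset`
#' metres from the midline (same side as release) at `interception_height`,
#' at a mean flight speed `ball_mean_speed` under gravity.
#'
#' The coordinate frame has its origin at the court midline on the floor:
#' x lateral (positive = right), y up, z toward the front wall. The viewer
#' stands at z = 0; the wall is at z = `viewer_wall_distance`.
#'
#' @param hole_lateral_offset Lateral distance of each release hole from the
#'   court midline, metres.
#' @param separation_deg Angular separation of the two holes as seen from the
#'   viewer, degrees.
#' @param hole_height Height of the release holes, metres. Defaults to the
#'   interception height (not independently constrained by the task layout).
#' @param interception_height Height of the interception point, metres.
#' @param interception_lateral_offset Lateral distance of the interception
#'   point from the midline, metres.
#' @param ball_diameter Ball diameter, metres.
#' @param racquet_half_axes Half-axes of the oval racquet face, metres
#'   (a 0.6 x 0.3 m oval has half-axes 0.3 x 0.15).
#' @param ball_mean_speed Mean ball flight speed (arc length / flight time),
#'   metres per second.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param eye_height Viewer eye height used for gaze/ball direction vectors,
#'   metres.
#' @return An object of class `pbac_geometry`: a list with the fields above
#'   plus `viewer_wall_distance` (derived).
#' @examples
#' geom <- court_geometry()
#' geom$viewer_wall_distance
#' @export
court_geometry <- function(hole_lateral_offset = 3.67,
                           separation_deg = 85,
                           hole_height = interception_height,
                           interception_height = 1.5,
                           interception_lateral_offset = 0.75,
                           ball_diameter = 0.057,
                           racquet_half_axes = c(0.3, 0.15),
                           ball_mean_speed = 10,
                           gravity = 9.81,
                           eye_height = 1.6) {
  lengths <- c(hole_lateral_offset, interception_height,
               interception_lateral_offset, ball_diameter,
               racquet_half_axes, ball_mean_speed)
  if (!all(is.finite(lengths)) || any(lengths <= 0)) {
    stop("all lengths and speeds must be finite and strictly positive",
         call. = FALSE)
  }
  if (!is.finite(gravity) || gravity < 0) {
    stop("gravity must be finite and non-negative", call. = FALSE)
  }
  d <- derive_viewer_distance(hole_lateral_offset, separation_deg)
  geom <- structure(
    list(
      hole_lateral_offset = hole_lateral_offset,
      separation_deg = separation_deg,
      viewer_wall_distance = d,
      hole_height = hole_height,
      interception_height = interception_height,
      interception_lateral_offset = interception_lateral_offset,
      ball_diameter = ball_diameter,
      racquet_half_axes = racquet_half_axes,
      ball_mean_speed = ball_mean_speed,
      gravity = gravity,
      eye_height = eye_height
    ),
    class = "pbac_geometry"
  )
  # consistency: offset + separation must reproduce the stored distance
  implied <- 2 * visual_angle(hole_lateral_offset, d)
  if (abs(hole_lateral_offset / tan(implied / 2 * pi / 180) - d) > 0.01) {
    stop("viewer_wall_distance inconsistent with hole offset and separation",
         call. = FALSE)
  }
  geom
}

#' @export
print.pbac_geometry <- function(x, ...) {
  cat("<pbac_geometry>\n")
  cat(sprintf("  holes at x = +/-%.3f m, wall at z = %.3f m (%.1f deg apart)\n",
              x$hole_lateral_offset, x$viewer_wall_distance, x$separation_deg))
  cat(sprintf("  interception point: +/-%.2f m lateral, %.2f m high\n",
              x$interception_lateral_offset, x$interception_height))
  cat(sprintf("  ball: %.1f m/s mean speed, g = %.2f m/s^2\n",
              x$ball_mean_speed, x$gravity))
  invisible(x)
}

#' Viewer-to-wall distance implied by a lateral offset / angular separation pair
#'
#' Solves for the distance `d` at which two points `hole_offset` metres either
#' side of the midline subtend `separation` degrees, i.e.
#' `2 * atan(hole_offset / d) = separation`.
#'
#' @param hole_offset Lateral offset of each point from the midline, metres
#'   (> 0).
#' @param separation Full angular separation, degrees, in (0, 180).
#' @return Distance in metres.
#' @examples
#' derive_viewer_distance(1, 90)     # 1
#' derive_viewer_distance(3.67, 85)  # ~4.005
#' @export
derive_viewer_distance <- function(hole_offset, separation) {
  if (!is.numeric(hole_offset) || !is.numeric(separation) ||
      !is.finite(hole_offset) || !is.finite(separation)) {
    stop("hole_offset and separation must be finite numbers", call. = FALSE)
  }
  if (hole_offset <= 0) stop("hole_offset must be > 0", call. = FALSE)
  if (separation <= 0 || separation >= 180) {
    stop("separation must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  d <- hole_offset / tan(separation / 2 * pi / 180)
  if (!is.finite(d) || d <= 0) {
    stop("degenerate separation: implied distance diverges", call. = FALSE)
  }
  d
}

#' Visual angle subtended by a lateral offset
#'
#' @param lateral_offset Lateral offset from the line of sight, metres
#'   (sign preserved).
#' @param distance Viewing distance, metres (> 0).
#' @return Signed angle in degrees, `atan(lateral_offset / distance)`.
#' @examples
#' visual_angle(1, 1)  # 45
#' visual_angle(0.4, derive_viewer_distance(3.67, 85))  # ~5.70
#' @export
visual_angle <- function(lateral_offset, distance) {
  if (any(!is.finite(distance)) || any(distance <= 0)) {
    stop("distance must be finite and > 0", call. = FALSE)
  }
  atan(lateral_offset / distance) * 180 / pi
}

#' Ballistic ball flight from a release hole to the interception point
#'
#' Solves a no-bounce parabolic trajectory from the release hole
#' (`+/-hole_lateral_offset`, `hole_height`, wall plane) to the interception
#' point (`+/-interception_lateral_offset` on the release side,
#' `interception_height`, viewer plane z = 0). Horizontal velocity is
#' constant; vertical motion is under gravity. The flight time `T` is solved
#' so that the mean speed along the arc, arc length / `T`, equals
#' `geom$ball_mean_speed` to within 1e-6 m/s (the faster of the two
#' admissible arcs is taken).
#'
#' @param release_side `"left"` or `"right"`.
#' @param geom A [court_geometry()].
#' @param dt Sampling interval in seconds (default 1/90, the task frame
#'   period).
#' @return A tibble with columns `t_s`, `ball_x_m`, `ball_y_m`, `ball_z_m`
#'   covering `[0, T]` (final sample exactly at `T`), with attributes
#'   `flight_time`, `arc_length` and `mean_speed`.
#' @examples
#' fl <- ball_flight("right", court_geometry())
#' attr(fl, "mean_speed")   # ~10
#' @export
ball_flight <- function(release_side = c("right", "left"),
                        geom = court_geometry(),
                        dt = 1 / 90) {
  release_side <- match.arg(release_side)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  sx <- if (release_side == "right") 1 else -1
  p0 <- c(sx * geom$hole_lateral_offset, geom$hole_height,
          geom$viewer_wall_distance)
  p1 <- c(sx * geom$interception_lateral_offset, geom$interception_height, 0)
  sol <- solve_flight_time(p0, p1, geom$ball_mean_speed, geom$gravity)
  T_fl <- sol$T
  vy0 <- (p1[2] - p0[2]) / T_fl + geom$gravity * T_fl / 2
  tt <- unique(c(seq(0, T_fl, by = dt), T_fl))
  out <- tibble::tibble(
    t_s = tt,
    ball_x_m = p0[1] + (p1[1] - p0[1]) * tt / T_fl,
    ball_y_m = p0[2] + vy0 * tt - geom$gravity * tt^2 / 2,
    ball_z_m = p0[3] + (p1[3] - p0[3]) * tt / T_fl
  )
  attr(out, "flight_time") <- T_fl
  attr(out, "arc_length") <- sol$arc
  attr(out, "mean_speed") <- sol$arc / T_fl
  attr(out, "release_side") <- release_side
  out
}

# Arc length of the parabolic flight lasting T between p0 and p1.
# Horizontal speed vh is constant; vertical speed runs from vy0 down at g.
# Closed form of integral sqrt(vh^2 + (vy0 - g t)^2) dt.
flight_arc_length <- function(p0, p1, T, g) {
  dh <- sqrt((p1[1] - p0[1])^2 + (p1[3] - p0[3])^2)
  vh <- dh / T
  if (g == 0) return(sqrt(dh^2 + (p1[2] - p0[2])^2))
  vy0 <- (p1[2] - p0[2]) / T + g * T / 2
  F <- function(w) (w * sqrt(vh^2 + w^2) + vh^2 * asinh(w / vh)) / 2
  (F(vy0) - F(vy0 - g * T)) / g
}

solve_flight_time <- function(p0, p1, speed, g, tol = 1e-6) {
  D <- sqrt(sum((p1 - p0)^2))
  if (g == 0) {
    # straight line: mean speed is exactly D / T
    T0 <- D / speed
    return(list(T = T0, arc = D))
  }
  f <- function(T) flight_arc_length(p0, p1, T, g) / T - speed
  # mean speed is decreasing then increasing in T; find the minimum, then
  # take the fast root left of it
  opt <- stats::optimize(function(T) flight_arc_length(p0, p1, T, g) / T,
                         interval = c(D / speed / 10, 60))
  if (opt$objective > speed) {
    stop("unreachable endpoint: no flight attains the requested mean speed ",
         "under the configured gravity", call. = FALSE)
  }
  lo <- D / speed / 10
  if (f(lo) < 0) lo <- lo / 100
  root <- stats::uniroot(f, lower = lo, upper = opt$minimum,
                         tol = 1e-12)
  T_fl <- root$root
  arc <- flight_arc_length(p0, p1, T_fl, g)
  if (abs(arc / T_fl - speed) > tol) {
    stop("flight-time solver failed to meet tolerance", call. = FALSE)
  }
  list(T = T_fl, arc = arc)
}
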