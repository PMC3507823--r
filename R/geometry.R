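#' Angular subtense of a disc
#'
#' Full visual angle of a disc of half-size `half_size` at distance
#' `distance` from the eye: theta = 2 * arctan(half_size / distance).
#'
#' @param half_size Half-size in metres (> 0).
#' @param distance Distance from the eye in metres (> 0; 0 would put the
#'   object at the eye).
#' @return Angle in degrees. Strictly decreasing in distance.
#' @export
#' @examples
#' angular_subtense(0.04, 0.07)  # ~59.5 deg, the disc at the screen
#' angular_subtense(0.04, 10)    # ~0.46 deg at the start of approach
angular_subtense <- function(half_size, distance) {
  if (any(!is.finite(half_size)) || any(half_size <= 0))
    stop("'half_size' must be positive and finite", call. = FALSE)
  if (any(!is.finite(distance)) || any(distance <= 0))
    stop("'distance' must be positive and finite (object at eye?)", call. = FALSE)
  2 * atan(half_size / distance) * 180 / pi
}

#' Angular expansion rate of a looming disc
#'
#' Time derivative of the angular subtense for an object approaching at
#' constant speed, evaluated at time `t_to_collision` before projected
#' collision (distance = speed * t): theta'(t) = 2*l*v / (v^2 t^2 + l^2),
#' returned in degrees per second.
#'
#' @param half_size Half-size l in metres (> 0).
#' @param speed Approach speed v in m/s (> 0).
#' @param t_to_collision Time to projected collision in seconds (> 0).
#' @return Expansion rate in deg/s; increases monotonically as t falls.
#' @export
#' @examples
#' subtense_rate(0.04, 2, 1) * pi / 180  # 0.0400 rad/s
subtense_rate <- function(half_size, speed, t_to_collision) {
  if (any(!is.finite(half_size)) || any(half_size <= 0))
    stop("'half_size' must be positive and finite", call. = FALSE)
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("'speed' must be positive and finite", call. = FALSE)
  if (any(!is.finite(t_to_collision)) || any(t_to_collision <= 0))
    stop("'t_to_collision' must be positive", call. = FALSE)
  2 * half_size * speed / (speed^2 * t_to_collision^2 + half_size^2) * 180 / pi
}

#' Angular time course of a looming stimulus
#'
#' Samples the approach of a looming stimulus from its start distance down to
#' its end distance on a regular grid of time-to-collision. The end-distance
#' sample is always included so the final subtense is exactly the
#' screen-level value regardless of speed.
#'
#' @param stim A [looming_stimulus()].
#' @param dt Sampling step in seconds (> 0, and no larger than the approach
#'   duration).
#' @return A data frame of class `loom_trajectory` with columns
#'   `t_to_collision` (s, strictly decreasing), `distance` (m), `theta_deg`
#'   (disc subtense, strictly increasing), and `theta_wing_deg` (full wing-span
#'   subtense 2*arctan((span/2)/d), `NA` when the stimulus has no wing).
#' @export
#' @examples
#' tr <- loom_trajectory(looming_stimulus(0.04, 15), dt = 0.01)
#' range(tr$t_to_collision)
loom_trajectory <- function(stim, dt) {
  stopifnot(inherits(stim, "looming_stimulus"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  t_start <- stim$start_distance / stim$speed
  t_end <- stim$end_distance / stim$speed
  if (dt > t_start - t_end)
    stop("'dt' exceeds the approach duration", call. = FALSE)
  tt <- seq(t_start, t_end, by = -dt)
  if (tt[length(tt)] > t_end) tt <- c(tt, t_end)
  d <- stim$speed * tt
  out <- data.frame(
    t_to_collision = tt,
    distance = d,
    theta_deg = angular_subtense(stim$half_size, d),
    theta_wing_deg = if (is.null(stim$wing)) NA_real_ else
      angular_subtense(stim$wing$span / 2, d)
  )
  class(out) <- c("loom_trajectory", "data.frame")
  attr(out, "stim_id") <- stim$stim_id
  out
}

#' Per-frame display schedule for a looming stimulus
#'
#' Converts a stimulus into the sequence of on-screen sizes a display running
#' at `refresh_hz` would show to an observer at `viewing_distance`. The frame
#' count is `floor(approach_duration * refresh_hz)` with the approach spanning
#' start to end distance; frames are spaced evenly over the travel so the
#' final frame sits exactly at the end distance. On-screen disc radius is the
#' perspective projection `viewing_distance * half_size / distance` divided by
#' `pixel_pitch`; the wing bar uses the same projection for both dimensions.
#' Sizes exceeding the screen extent are clipped and flagged (with a warning).
#'
#' @param stim A [looming_stimulus()].
#' @param refresh_hz Display refresh rate in Hz. Default 200.
#' @param viewing_distance Eye-to-screen distance in metres. Default 0.07.
#' @param pixel_pitch Physical size of one pixel in metres (required; display
#'   hardware dependent).
#' @param screen_px Screen extent in pixels, `c(width, height)`. Default
#'   640 x 480.
#' @return A data frame of class `frame_schedule` with columns `frame`,
#'   `t_to_collision_s`, `theta_deg`, `radius_px`, `wing_w_px`, `wing_h_px`,
#'   `clipped`. Zero-duration stimuli give zero rows.
#' @export
#' @examples
#' fs <- frame_schedule(looming_stimulus(0.04, 15), pixel_pitch = 4e-4)
#' nrow(fs)  # 132 frames at 200 Hz
frame_schedule <- function(stim, refresh_hz = 200, viewing_distance = 0.07,
                           pixel_pitch, screen_px = c(640, 480)) {
  stopifnot(inherits(stim, "looming_stimulus"))
  if (refresh_hz <= 0) stop("'refresh_hz' must be > 0", call. = FALSE)
  if (missing(pixel_pitch) || !is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stop("'pixel_pitch' must be a positive number (m per pixel)", call. = FALSE)
  duration <- (stim$start_distance - stim$end_distance) / stim$speed
  n <- floor(duration * refresh_hz)
  empty <- data.frame(frame = integer(), t_to_collision_s = numeric(),
                      theta_deg = numeric(), radius_px = numeric(),
                      wing_w_px = numeric(), wing_h_px = numeric(),
                      clipped = logical())
  if (n < 1L) {
    class(empty) <- c("frame_schedule", "data.frame")
    return(empty)
  }
  i <- seq_len(n)
  d <- stim$start_distance - (stim$start_distance - stim$end_distance) * i / n
  radius_px <- viewing_distance * stim$half_size / d / pixel_pitch
  if (is.null(stim$wing)) {
    wing_w <- rep(0, n)
    wing_h <- rep(0, n)
  } else {
    wing_w <- viewing_distance * stim$wing$span / d / pixel_pitch
    wing_h <- viewing_distance * stim$wing$bar_height / d / pixel_pitch
  }
  clipped <- (2 * radius_px > screen_px[1]) | (2 * radius_px > screen_px[2]) |
    (wing_w > screen_px[1]) | (wing_h > screen_px[2])
  if (any(clipped))
    warning(sprintf("%d frame(s) exceed the screen extent; sizes clipped",
                    sum(clipped)), call. = FALSE)
  radius_px <- pmin(radius_px, min(screen_px) / 2)
  wing_w <- pmin(wing_w, screen_px[1])
  wing_h <- pmin(wing_h, screen_px[2])
  out <- data.frame(frame = i, t_to_collision_s = d / stim$speed,
                    theta_deg = angular_subtense(stim$half_size, d),
                    radius_px = radius_px, wing_w_px = wing_w,
                    wing_h_px = wing_h, clipped = clipped)
  class(out) <- c("frame_schedule", "data.frame")
  attr(out, "refresh_hz") <- refresh_hz
  attr(out, "pixel_pitch") <- pixel_pitch
  attr(out, "stim_id") <- stim$stim_id
  out
}
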