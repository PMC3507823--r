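#' Wing specification for a looming stimulus
#'
#' A horizontal black bar added to a looming disc to give it a more bird-like
#' outline. The bar is centred `vertical_offset` metres above the disc centre
#' and does not flap.
#'
#' @param span Full wing span in metres (tip to tip). Default 0.36.
#' @param bar_height Height of the bar in metres. Default 0.02.
#' @param vertical_offset Height of the bar centre-line above the disc centre,
#'   in metres. Default 0.018. The offset affects rendering only; the wing-tip
#'   angular subtense is computed from the span alone.
#' @return An object of class `wing_spec`.
#' @export
#' @examples
#' wing_spec()
wing_spec <- function(span = 0.36, bar_height = 0.02, vertical_offset = 0.018) {
  stopifnot(is.numeric(span), is.numeric(bar_height), is.numeric(vertical_offset))
  if (span <= 0) stop("wing 'span' must be > 0", call. = FALSE)
  if (bar_height <= 0) stop("wing 'bar_height' must be > 0", call. = FALSE)
  if (vertical_offset <= 0) stop("wing 'vertical_offset' must be > 0", call. = FALSE)
  structure(list(span = span, bar_height = bar_height,
                 vertical_offset = vertical_offset),
            class = "wing_spec")
}

#' Looming stimulus: a dark disc on a direct collision course
#'
#' Physical description of a simulated approaching disc, optionally carrying a
#' wing bar. The approach starts `start_distance` metres from the eye and stops
#' at `end_distance` metres (level with the display screen); the projected time
#' of collision is `end_distance / speed` seconds after motion stops.
#'
#' @param half_size Disc half-size l in metres (> 0).
#' @param speed Approach speed |v| in m/s (> 0).
#' @param start_distance Simulated start distance in metres. Default 10.
#' @param end_distance Distance from the eye at which motion stops, metres.
#'   Default 0.07.
#' @param wing Optional [wing_spec()]. The span must exceed the disc diameter
#'   (wings that do not protrude are rejected).
#' @param stim_id Optional label. If `NULL`, one is built from the l/|v| value.
#' @return An object of class `looming_stimulus` with fields `half_size`,
#'   `speed`, `start_distance`, `end_distance`, `wing`, `stim_id`, and the
#'   derived ratio `lov_ms` (= 1000 * half_size / speed, in ms).
#' @export
#' @examples
#' looming_stimulus(0.04, 15)          # fastest disc used at the bench
#' looming_stimulus(0.04, 0.5)$lov_ms  # 80 ms
looming_stimulus <- function(half_size, speed, start_distance = 10,
                             end_distance = 0.07, wing = NULL, stim_id = NULL) {
  if (!is.numeric(half_size) || length(half_size) != 1L || !is.finite(half_size) ||
      half_size <= 0)
    stop("'half_size' must be a single positive number", call. = FALSE)
  if (!is.numeric(speed) || length(speed) != 1L || !is.finite(speed) || speed <= 0)
    stop("'speed' must be a single positive number", call. = FALSE)
  if (end_distance < 0) stop("'end_distance' must be >= 0", call. = FALSE)
  if (start_distance <= end_distance)
    stop("'start_distance' must exceed 'end_distance'", call. = FALSE)
  if (!is.null(wing)) {
    if (!inherits(wing, "wing_spec")) stop("'wing' must be a wing_spec", call. = FALSE)
    if (wing$span <= 2 * half_size)
      stop("wing span must exceed the disc diameter (wings must protrude)",
           call. = FALSE)
  }
  lov <- lov_ratio(half_size, speed)
  if (is.null(stim_id)) {
    stim_id <- sprintf("%s_%.1f", if (is.null(wing)) "disc" else "wing",
                       display_round(lov))
  }
  structure(list(half_size = half_size, speed = speed,
                 start_distance = start_distance, end_distance = end_distance,
                 wing = wing, stim_id = stim_id, lov_ms = lov),
            class = "looming_stimulus")
}

#' @export
print.looming_stimulus <- function(x, ...) {
  cat(sprintf("Looming stimulus '%s': l = %g m, |v| = %g m/s (l/|v| = %.1f ms)\n",
              x$stim_id, x$half_size, x$speed, display_round(x$lov_ms)))
  cat(sprintf("  approach %g m -> %g m%s\n", x$start_distance, x$end_distance,
              if (is.null(x$wing)) "" else
                sprintf("; wings %g x %g m, offset %g m", x$wing$span,
                        x$wing$bar_height, x$wing$vertical_offset)))
  invisible(x)
}

#' Half-size over speed ratio l/|v|
#'
#' The ratio of an object's half-size to its approach speed fully determines
#' the angular expansion profile of a looming disc; lower values mean smaller
#' or faster objects. Returned in milliseconds. Rounding for display is left
#' to [display_round()].
#'
#' @param half_size Object half-size in metres (> 0).
#' @param speed Approach speed in m/s (> 0).
#' @return l/|v| in ms.
#' @export
#' @examples
#' lov_ratio(0.04, 0.5)   # 80
#' lov_ratio(0.068, 17.43)
lov_ratio <- function(half_size, speed) {
  if (any(!is.finite(half_size)) || any(half_size <= 0))
    stop("'half_size' must be positive and finite", call. = FALSE)
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("'speed' must be positive and finite", call. = FALSE)
  1000 * half_size / speed
}

#' Display rounding (round half away from zero)
#'
#' Rounds to `digits` decimal places with halves rounded up in magnitude, the
#' convention used for printed stimulus labels (2.67 -> 2.7, 1.25 -> 1.3).
#' Base R's `round()` rounds half to even and would give 1.2 for 1.25.
#' A relative epsilon guards against binary representation of decimal halves.
#'
#' @param x Numeric vector.
#' @param digits Decimal places. Default 1.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' display_round(c(2.67, 1.25, 16.6259))
display_round <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Offset between end of motion and projected collision
#'
#' Simulated approaches stop level with the display screen, a small distance
#' short of the eye. The time the object would have needed to cover that final
#' gap anchors the "projected time of collision" against which spike and glide
#' times are referenced.
#'
#' @param stim A [looming_stimulus()].
#' @return Time in seconds between motion end and projected collision
#'   (`end_distance / speed`).
#' @export
#' @examples
#' collision_offset(looming_stimulus(0.04, 15))  # ~0.00467 s
collision_offset <- function(stim) {
  stopifnot(inherits(stim, "looming_stimulus"))
  stim$end_distance / stim$speed
}

#' The laboratory disc stimulus battery
#'
#' Builds the set of looming-disc stimuli used at the bench: a 0.08 m diameter
#' disc whose approach speed is varied to produce the printed l/|v| labels
#' 80.0, 40.0, 26.7, 20.0, 16.0, 13.3, 10.0, 8.0, 6.0, 5.3, 4.0, 3.2 and
#' 2.7 ms (speeds 0.5 to 15 m/s).
#'
#' @param lov_ms Vector of l/|v| values in ms used as labels; speeds are
#'   derived as `1000 * half_size / lov_ms`.
#' @param half_size Disc half-size in metres. Default 0.04.
#' @param wing `NULL` for plain discs, or a [wing_spec()] applied to every
#'   stimulus.
#' @param start_distance,end_distance Approach geometry in metres.
#' @return A list of [looming_stimulus()] objects.
#' @export
#' @examples
#' length(stimulus_set())  # 13
stimulus_set <- function(lov_ms = c(80, 40, 26.7, 20, 16, 13.3, 10, 8, 6,
                                    5.3, 4, 3.2, 2.7),
                         half_size = 0.04, wing = NULL,
                         start_distance = 10, end_distance = 0.07) {
  lapply(lov_ms, function(q)
    looming_stimulus(half_size, 1000 * half_size / q,
                     start_distance = start_distance,
                     end_distance = end_distance, wing = wing))
}
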