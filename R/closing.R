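#' Closing speed between two movers
#'
#' Magnitude of the relative velocity of two animals whose heading vectors
#' meet at angle `phi_deg`:
#' `sqrt(v1^2 + v2^2 - 2 v1 v2 cos(phi))`. At 180 degrees (head-on
#' convergence) this is the sum of the speeds; at 0 degrees (a tail chase) it
#' is the absolute difference.
#'
#' @param v_pred Predator speed in m/s (>= 0).
#' @param v_prey Prey speed in m/s (>= 0).
#' @param phi_deg Angle between heading vectors in degrees, 0 to 180.
#' @return Closing speed in m/s.
#' @export
#' @examples
#' closing_speed(12.18, 5.25, 180)  # 17.43, fast kite vs fast locust head-on
#' closing_speed(9.34, 5.25, 0)     # 4.09, slow kite chasing a fast locust
closing_speed <- function(v_pred, v_prey, phi_deg) {
  if (any(v_pred < 0) || any(v_prey < 0))
    stop("speeds must be non-negative", call. = FALSE)
  if (any(phi_deg < 0) || any(phi_deg > 180))
    stop("'phi_deg' must lie in [0, 180]", call. = FALSE)
  sqrt(pmax(v_pred^2 + v_prey^2 - 2 * v_pred * v_prey * cos(phi_deg * pi / 180), 0))
}

#' Predator-prey convergence scenario
#'
#' Speed statistics used to bracket the closing speeds a prey could
#' experience. The fast endpoint uses a fast predator (mean + SD) meeting a
#' fast prey (mean + SD) head-on; the slow endpoint uses a slow predator
#' (mean - SD) chasing a fast prey from behind. Predators whose speed differs
#' between contexts (e.g. low straight flight vs erratic higher flight) may
#' supply a separate chase-context mean/SD.
#'
#' @param predator_mean,predator_sd Predator speed statistics (m/s); SD
#'   defaults to 0.
#' @param prey_mean,prey_sd Prey speed statistics (m/s); SD defaults to 0.
#' @param predator_mean_chase,predator_sd_chase Optional predator statistics
#'   for the tail-chase endpoint; default to the head-on values.
#' @return An object of class `closing_scenario`.
#' @export
#' @examples
#' closing_scenario(10.76, 1.42, prey_mean = 4.6, prey_sd = 0.65)
closing_scenario <- function(predator_mean, predator_sd = 0,
                             prey_mean = 0, prey_sd = 0,
                             predator_mean_chase = predator_mean,
                             predator_sd_chase = predator_sd) {
  vals <- c(predator_mean, predator_sd, prey_mean, prey_sd,
            predator_mean_chase, predator_sd_chase)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("scenario speeds and SDs must be non-negative and finite", call. = FALSE)
  structure(list(predator_mean = predator_mean, predator_sd = predator_sd,
                 prey_mean = prey_mean, prey_sd = prey_sd,
                 predator_mean_chase = predator_mean_chase,
                 predator_sd_chase = predator_sd_chase),
            class = "closing_scenario")
}

#' Predator size profile
#'
#' Holds the wingspan and the thorax-to-wingspan fraction from which the
#' thorax half-size l is derived: the thorax, roughly disc-shaped when seen
#' head-on, is the looming shape a targeted prey faces.
#'
#' @param wingspan Wingspan in metres (> 0). Black kite mean: 1.36.
#' @param thorax_fraction Thorax width as a fraction of wingspan, in (0, 1).
#'   Default 0.10.
#' @return An object of class `predator_profile` with derived
#'   `thorax_half_size_l`.
#' @export
#' @examples
#' predator_profile(1.36)$thorax_half_size_l  # 0.068 m
predator_profile <- function(wingspan, thorax_fraction = 0.10) {
  if (!is.finite(wingspan) || wingspan <= 0)
    stop("'wingspan' must be positive", call. = FALSE)
  if (!is.finite(thorax_fraction) || thorax_fraction <= 0 || thorax_fraction >= 1)
    stop("'thorax_fraction' must be in (0, 1)", call. = FALSE)
  structure(list(wingspan = wingspan, thorax_fraction = thorax_fraction,
                 thorax_half_size_l = wingspan * thorax_fraction / 2),
            class = "predator_profile")
}

#' Thorax half-size of a predator
#'
#' @param profile A [predator_profile()].
#' @return Half-size l in metres (`wingspan * thorax_fraction / 2`).
#' @export
#' @examples
#' thorax_half_size(predator_profile(1.36, 0.10))  # 0.068
thorax_half_size <- function(profile) {
  stopifnot(inherits(profile, "predator_profile"))
  profile$thorax_half_size_l
}

#' l/|v| range for a predator's looming thorax
#'
#' Brackets the l/|v| ratios a prey would experience from an attacking
#' predator: the low endpoint divides the thorax half-size by the fastest
#' closing speed (fast predator meeting fast prey head-on), the high endpoint
#' by the slowest (slow predator overtaking fast prey from behind). Values are
#' returned unrounded, in ms; apply [display_round()] for printed labels.
#'
#' @param scenario A [closing_scenario()].
#' @param profile A [predator_profile()], or a bare half-size in metres.
#' @return Named numeric vector `c(low_ms, high_ms)` with attribute
#'   `closing_speeds` (the max/min closing speeds used).
#' @export
#' @examples
#' sc <- closing_scenario(10.76, 1.42, prey_mean = 4.6, prey_sd = 0.65)
#' display_round(lov_range(sc, predator_profile(1.36)))  # 3.9 16.6
lov_range <- function(scenario, profile) {
  stopifnot(inherits(scenario, "closing_scenario"))
  l <- if (inherits(profile, "predator_profile")) thorax_half_size(profile)
       else as.numeric(profile)
  if (!is.finite(l) || l <= 0) stop("half-size must be positive", call. = FALSE)
  v_max <- closing_speed(scenario$predator_mean + scenario$predator_sd,
                         scenario$prey_mean + scenario$prey_sd, 180)
  v_pred_slow <- scenario$predator_mean_chase - scenario$predator_sd_chase
  v_prey_fast <- scenario$prey_mean + scenario$prey_sd
  if (v_pred_slow <= v_prey_fast)
    stop("slow predator does not overtake the fast prey in a tail chase; ",
         "revise the scenario (chase closing speed would be <= 0)", call. = FALSE)
  v_min <- closing_speed(v_pred_slow, v_prey_fast, 0)
  out <- c(low_ms = lov_ratio(l, v_max), high_ms = lov_ratio(l, v_min))
  attr(out, "closing_speeds") <- c(max = v_max, min = v_min)
  out
}
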