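#' Parameters of the eta-model looming response
#'
#' The eta function models looming-detector firing as the product of the
#' stimulus angular velocity and an exponentially decaying function of its
#' angular size, delayed by a fixed latency:
#' `f(t) = C * theta'(s) * exp(-alpha * theta(s))`, `s = t_to_collision + delta`,
#' with angles in radians. Its peak occurs `alpha * l/|v| - delta` before
#' projected collision, the linear law this generator encodes, and the angle
#' at the peak, `2 * arctan(1 / alpha)`, is independent of l/|v|.
#'
#' Defaults (C = 133, alpha = 4.7, delta = 27 ms) put the peak rate near
#' 400 Hz for an l/|v| of 4 ms with a threshold angle near 24 degrees and a
#' latency of 27 ms, values typical of the looming-detector literature; no
#' claim is made that they reproduce any particular recorded animal.
#'
#' @param scale_C Rate scaling (> 0). Default 133.
#' @param alpha Angular-size sensitivity (dimensionless, > 0). Default 4.7.
#' @param delta_ms Response latency in ms (>= 0). Default 27.
#' @param wing_attenuation Multiplier in (0, 1] applied to the rate during the
#'   final quarter of the approach when the stimulus carries a wing bar,
#'   emulating the depression of late high-frequency firing by winged shapes.
#'   Default 0.85.
#' @return An object of class `eta_params`.
#' @export
eta_params <- function(scale_C = 133, alpha = 4.7, delta_ms = 27,
                       wing_attenuation = 0.85) {
  if (scale_C < 0) stop("'scale_C' must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (delta_ms < 0) stop("'delta_ms' must be >= 0", call. = FALSE)
  if (wing_attenuation <= 0 || wing_attenuation > 1)
    stop("'wing_attenuation' must be in (0, 1]", call. = FALSE)
  structure(list(scale_C = scale_C, alpha = alpha, delta_ms = delta_ms,
                 wing_attenuation = wing_attenuation),
            class = "eta_params")
}

#' Eta-model firing rate for a looming stimulus
#'
#' Evaluates the model rate at times relative to projected collision. The rate
#' is nonzero only while the (latency-shifted) stimulus is in motion, i.e. for
#' `t_to_collision + delta` between `end_distance/speed` and
#' `start_distance/speed`; because of the latency the response outlasts the
#' motion by `delta` and can extend past collision (negative
#' `t_to_collision`). With a winged stimulus the rate is multiplied by
#' `wing_attenuation` while the stimulus is in the final quarter of its
#' approach.
#'
#' @param params An [eta_params()].
#' @param stim A [looming_stimulus()].
#' @param t_to_collision Time(s) to projected collision in seconds (positive
#'   before collision, negative after). Vectorized.
#' @return Firing rate(s) in Hz.
#' @export
#' @examples
#' st <- looming_stimulus(0.04, 4)  # l/|v| = 10 ms
#' eta_rate(eta_params(), st, 0.020)
eta_rate <- function(params, stim, t_to_collision) {
  stopifnot(inherits(params, "eta_params"), inherits(stim, "looming_stimulus"))
  l <- stim$half_size; v <- stim$speed
  s <- t_to_collision + params$delta_ms / 1000    # stimulus time being answered
  s_end <- stim$end_distance / v
  s_start <- stim$start_distance / v
  rate <- numeric(length(s))
  live <- s >= s_end & s <= s_start & s > 0
  if (any(live)) {
    sl <- s[live]
    theta <- 2 * atan(l / (v * sl))                       # rad
    theta_p <- 2 * l * v / (v^2 * sl^2 + l^2)             # rad/s
    r <- params$scale_C * theta_p * exp(-params$alpha * theta)
    if (!is.null(stim$wing)) {
      final_q <- sl <= s_end + 0.25 * (s_start - s_end)
      r[final_q] <- r[final_q] * params$wing_attenuation
    }
    rate[live] <- r
  }
  rate
}

#' Closed-form eta-model peak time
#'
#' The model rate peaks when the stimulus angular acceleration balances the
#' size penalty, at `alpha * l/|v|` before collision on the stimulus clock,
#' i.e. `alpha * l/|v| - delta` before collision once the latency is applied.
#'
#' @param params An [eta_params()].
#' @param stim A [looming_stimulus()].
#' @return Peak time in signed ms relative to projected collision (negative =
#'   before collision): `-(alpha * lov_ms - delta_ms)`.
#' @export
#' @examples
#' eta_peak_time(eta_params(alpha = 5, delta_ms = 0),
#'               looming_stimulus(0.04, 4))  # -50 ms
eta_peak_time <- function(params, stim) {
  stopifnot(inherits(params, "eta_params"), inherits(stim, "looming_stimulus"))
  -(params$alpha * stim$lov_ms - params$delta_ms)
}

#' Rate function of signed milliseconds for a stimulus
#'
#' Convenience wrapper used by the spike-train sampler and glide injector:
#' returns `function(t_ms)` evaluating [eta_rate()] with `t_ms` signed
#' relative to projected collision (negative = before).
#'
#' @inheritParams eta_rate
#' @return A vectorized function of `t_ms` returning Hz.
#' @export
eta_rate_fn <- function(params, stim) {
  force(params); force(stim)
  function(t_ms) eta_rate(params, stim, -t_ms / 1000)
}

#' Recover the peak-time law from sampled spike trains
#'
#' Fits the linear law `t_peak_before_collision = alpha * l/|v| - delta` to
#' pooled spike trains, one pool per stimulus. Per stimulus the peak time is
#' estimated as the mode of the spike-time density, using a Gaussian kernel
#' whose bandwidth is proportional to l/|v| (the model's own time scale) and
#' Richardson extrapolation over two bandwidths to remove the smoothing bias;
#' because the spike-time distribution is the same for every stimulus up to
#' the l/|v| scaling, the residual mode bias is a constant in scaled units and
#' the regression intercept is unbiased. The regression is weighted least
#' squares with weights 1 / (l/|v|)^2, matching the scaling of the estimation
#' error.
#'
#' @param spike_sets List of numeric vectors: pooled signed spike times (ms)
#'   per stimulus, across all presentations.
#' @param lov_ms l/|v| of each stimulus in ms (same length as `spike_sets`).
#' @param bw_factors Two bandwidth factors (fraction of l/|v|) used for the
#'   Richardson extrapolation. Default `c(0.5, 1)`.
#' @return List with `alpha`, `delta_ms` and `peak_time_ms` (per-stimulus
#'   signed peak-time estimates).
#' @export
fit_peak_time_law <- function(spike_sets, lov_ms, bw_factors = c(0.5, 1)) {
  stopifnot(length(spike_sets) == length(lov_ms), length(bw_factors) == 2L,
            all(bw_factors > 0), bw_factors[1] < bw_factors[2])
  kde_mode <- function(x, bw) {
    d <- stats::density(x, bw = bw, n = 4096)
    d$x[which.max(d$y)]
  }
  c1 <- bw_factors[1]^2; c2 <- bw_factors[2]^2
  t_before <- vapply(seq_along(spike_sets), function(j) {
    x <- -spike_sets[[j]]   # ms before collision, positive before
    if (length(x) < 50L)
      stop("too few spikes to estimate a peak time for stimulus ", j, call. = FALSE)
    m1 <- kde_mode(x, bw_factors[1] * lov_ms[j])
    m2 <- kde_mode(x, bw_factors[2] * lov_ms[j])
    (m1 * c2 - m2 * c1) / (c2 - c1)
  }, 0)
  fit <- stats::lm(t_before ~ lov_ms, weights = 1 / lov_ms^2)
  list(alpha = unname(stats::coef(fit)[2]),
       delta_ms = unname(-stats::coef(fit)[1]),
       peak_time_ms = -t_before)
}
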