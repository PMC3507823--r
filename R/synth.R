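#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Draws homogeneous candidates at an upper bound of the rate over the span
#' and keeps each with probability rate/bound. The bound is taken from a grid
#' evaluation inflated by 5%; supply `rate_max_hz` when the analytic maximum
#' is known.
#'
#' @param rate_fn Function of signed time (ms) returning rate in Hz; must be
#'   bounded on the span.
#' @param t_span_ms Length-2 vector, start and end of the sampling span (ms).
#' @param seed Optional integer seed for reproducibility.
#' @param rate_max_hz Optional known bound on the rate (Hz).
#' @param grid_n Grid size used to bound the rate. Default 512.
#' @param individual_id,stim_id,presentation Labels passed to [spike_train()].
#' @return A [spike_train()].
#' @export
sample_spike_train <- function(rate_fn, t_span_ms, seed = NULL,
                               rate_max_hz = NULL, grid_n = 512,
                               individual_id = "ind1", stim_id = NA_character_,
                               presentation = 1L) {
  stopifnot(is.function(rate_fn), length(t_span_ms) == 2L,
            t_span_ms[2] > t_span_ms[1])
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rate_max_hz)) {
    grid <- seq(t_span_ms[1], t_span_ms[2], length.out = grid_n)
    rate_max_hz <- max(rate_fn(grid)) * 1.05
  }
  if (!is.finite(rate_max_hz)) stop("rate is unbounded on the span", call. = FALSE)
  span_s <- (t_span_ms[2] - t_span_ms[1]) / 1000
  if (rate_max_hz <= 0)
    return(spike_train(numeric(), individual_id, stim_id, presentation))
  n <- stats::rpois(1, rate_max_hz * span_s)
  cand <- stats::runif(n, t_span_ms[1], t_span_ms[2])
  keep <- stats::runif(n) < rate_fn(cand) / rate_max_hz
  # generator time resolution is 1 us, matching the 3-decimal ms CSV format;
  # coincident draws collapse to one spike
  spike_train(sort(unique(round(cand[keep], 3))), individual_id, stim_id,
              presentation)
}

#' Sample a rhythmic wingbeat train
#'
#' Events on a regular lattice of `period_ms` plus independent Gaussian
#' jitter, re-sorted. Jitter SDs above one third of the period would make the
#' event ordering ambiguous and are rejected.
#'
#' @param period_ms Wingbeat period in ms (> 0). Default 50 (a 25 ms half
#'   wingbeat).
#' @param jitter_sd_ms Gaussian jitter SD in ms (>= 0). Default 0.
#' @param t_span_ms Length-2 vector: first and last lattice times (ms).
#' @param seed Optional integer seed.
#' @param individual_id,stim_id,presentation,valid_flight Labels passed to
#'   [wingbeat_train()].
#' @return A [wingbeat_train()].
#' @export
sample_wingbeats <- function(period_ms = 50, jitter_sd_ms = 0, t_span_ms,
                             seed = NULL, individual_id = "ind1",
                             stim_id = NA_character_, presentation = 1L,
                             valid_flight = TRUE) {
  if (period_ms <= 0) stop("'period_ms' must be > 0", call. = FALSE)
  if (jitter_sd_ms < 0) stop("'jitter_sd_ms' must be >= 0", call. = FALSE)
  if (jitter_sd_ms > period_ms / 3)
    stop("'jitter_sd_ms' > period/3 makes event ordering ambiguous", call. = FALSE)
  stopifnot(length(t_span_ms) == 2L, t_span_ms[2] > t_span_ms[1])
  if (!is.null(seed)) set.seed(seed)
  lattice <- seq(t_span_ms[1], t_span_ms[2], by = period_ms)
  ev <- sort(lattice + stats::rnorm(length(lattice), 0, jitter_sd_ms))
  wingbeat_train(ev, individual_id, stim_id, presentation, valid_flight)
}

#' Inject a rate-gated glide into a wingbeat train
#'
#' Emulates the summation-gated triggering of glides: at the first wingbeat
#' whose following half-cycle overlaps a model rate at or above
#' `threshold_hz`, a glide is injected with probability `gating_probability`
#' by deleting the next `glide_beats` wingbeat events (default 3, giving a
#' flight pause of roughly 3 periods, consistent with glide durations
#' exceeding 130 ms at a 50 ms period). At most one glide is injected.
#'
#' @param train A [wingbeat_train()].
#' @param rate_fn Function of signed ms returning the model rate in Hz.
#' @param threshold_hz Summation threshold. Default 150.
#' @param gating_probability Probability that a suprathreshold burst coinciding
#'   with wing elevation actually triggers the glide, in `[0, 1]`.
#' @param seed Optional integer seed (drives the single gating draw).
#' @param glide_beats Number of wingbeats deleted. Default 3.
#' @param grid_points Rate evaluations per half-cycle when checking overlap.
#'   Default 8.
#' @return The (possibly modified) [wingbeat_train()], with attribute
#'   `glide_injected_at` (onset ms) when a glide was injected.
#' @export
inject_glides <- function(train, rate_fn, threshold_hz = 150,
                          gating_probability = 1, seed = NULL,
                          glide_beats = 3, grid_points = 8) {
  stopifnot(inherits(train, "wingbeat_train"), is.function(rate_fn))
  if (gating_probability < 0 || gating_probability > 1)
    stop("'gating_probability' must be in [0, 1]", call. = FALSE)
  ev <- train$t_ms
  if (length(ev) < 2L) return(train)
  if (!is.null(seed)) set.seed(seed)
  period <- stats::median(diff(ev))
  half <- period / 2
  # max model rate within (t_i, t_i + half] for each beat
  supra <- vapply(seq_len(length(ev) - 1L), function(i) {
    g <- seq(ev[i], ev[i] + half, length.out = grid_points + 1L)[-1]
    max(rate_fn(g)) >= threshold_hz
  }, TRUE)
  hit <- which(supra)
  if (length(hit) == 0L) return(train)
  if (stats::runif(1) >= gating_probability) return(train)
  i <- hit[1]
  drop <- seq(i + 1L, min(i + glide_beats, length(ev)))
  out <- wingbeat_train(ev[-drop], train$individual_id, train$stim_id,
                        train$presentation, train$valid_flight)
  attr(out, "glide_injected_at") <- ev[i]
  out
}

#' Synthesize a straight-line pixel track
#'
#' A constant-speed, straight-line track in pixel coordinates with i.i.d.
#' Gaussian coordinate noise, for parameter-recovery tests of the speed
#' pipeline.
#'
#' @param true_speed_m_s Ground-truth speed in m/s (> 0).
#' @param heading_deg Heading of travel in degrees. Default 0.
#' @param fps Frame rate. Default 25.
#' @param cal_len_px,cal_len_m Calibration pair (defaults 69.5 px, 0.56 m).
#' @param noise_sd_px Coordinate noise SD in pixels (>= 0). Default 0.
#' @param n_frames Number of digitized frames (>= 2). Default 30.
#' @param seed Optional integer seed.
#' @param kite_id,attack_id,segment_id Labels.
#' @return A [track_segment()].
#' @export
synth_track <- function(true_speed_m_s, heading_deg = 0, fps = 25,
                        cal_len_px = 69.5, cal_len_m = 0.56,
                        noise_sd_px = 0, n_frames = 30, seed = NULL,
                        kite_id = "k1", attack_id = "a1", segment_id = "s1") {
  if (true_speed_m_s <= 0) stop("'true_speed_m_s' must be > 0", call. = FALSE)
  if (n_frames < 2) stop("'n_frames' must be >= 2", call. = FALSE)
  if (noise_sd_px < 0) stop("'noise_sd_px' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  scale <- calibration_scale(cal_len_px, cal_len_m)
  step_px <- true_speed_m_s / (scale * fps)
  h <- heading_deg * pi / 180
  i <- seq_len(n_frames) - 1L
  x <- cos(h) * step_px * i + stats::rnorm(n_frames, 0, noise_sd_px)
  y <- sin(h) * step_px * i + stats::rnorm(n_frames, 0, noise_sd_px)
  track_segment(seq_len(n_frames), x, y, fps = fps,
                cal_len_px = cal_len_px, cal_len_m = cal_len_m,
                kite_id = kite_id, attack_id = attack_id,
                segment_id = segment_id)
}

#' Configuration of a synthetic experiment battery
#'
#' Bundles the stimuli and generator parameters for [scenario_battery()]. The
#' defaults mirror the bench design: the 13-value disc set, 10 individuals, 6
#' presentations each, a 50 ms wingbeat period and a 150 Hz glide-summation
#' threshold. The gating probability linking suprathreshold bursts to glides
#' is a free parameter (no published estimate exists); the default 0.7 places
#' occurrence in the 50-80% band typical of last-ditch escape.
#'
#' @param stimuli List of [looming_stimulus()] objects.
#' @param n_individuals,n_presentations Battery dimensions (>= 1).
#' @param seed Master seed; fans out deterministically to per-presentation
#'   seeds.
#' @param wingbeat_period_ms Wingbeat period (ms). Default 50.
#' @param wingbeat_jitter_sd_ms Wingbeat jitter SD (ms). Default 2.
#' @param glide_threshold_hz Summation threshold. Default 150.
#' @param gating_probability Gating probability in `[0, 1]`. Default 0.7.
#' @param glide_beats Wingbeats deleted per injected glide. Default 3.
#' @param eta An [eta_params()].
#' @param track_noise_px Pixel noise for synthetic tracks. Default 0.5.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(stimuli = stimulus_set(), n_individuals = 10,
                              n_presentations = 6, seed = 1,
                              wingbeat_period_ms = 50,
                              wingbeat_jitter_sd_ms = 2,
                              glide_threshold_hz = 150,
                              gating_probability = 0.7, glide_beats = 3,
                              eta = eta_params(), track_noise_px = 0.5) {
  stopifnot(length(stimuli) >= 1L,
            all(vapply(stimuli, inherits, TRUE, "looming_stimulus")),
            inherits(eta, "eta_params"))
  if (n_individuals < 1 || n_presentations < 1)
    stop("battery dimensions must be >= 1", call. = FALSE)
  if (gating_probability < 0 || gating_probability > 1)
    stop("'gating_probability' must be in [0, 1]", call. = FALSE)
  structure(list(stimuli = stimuli, n_individuals = n_individuals,
                 n_presentations = n_presentations, seed = seed,
                 wingbeat_period_ms = wingbeat_period_ms,
                 wingbeat_jitter_sd_ms = wingbeat_jitter_sd_ms,
                 glide_threshold_hz = glide_threshold_hz,
                 gating_probability = gating_probability,
                 glide_beats = glide_beats, eta = eta,
                 track_noise_px = track_noise_px),
            class = "simulation_config")
}

#' Generate a full synthetic battery
#'
#' For every individual x stimulus x presentation, samples one eta-model spike
#' train and one wingbeat train with a rate-gated glide injected, mirroring a
#' pseudorandom presentation design. The master seed is fanned out to
#' independent per-presentation seeds, so regeneration with the same seed is
#' bit-identical.
#'
#' @param config A [simulation_config()].
#' @return An object of class `loom_battery`: data frames `spikes`
#'   (individual_id, stim_id, presentation, t_ms), `wingbeats` (+
#'   valid_flight), `stimuli`, and `presentation_order`.
#' @export
scenario_battery <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_ind <- config$n_individuals
  n_stim <- length(config$stimuli)
  n_pres <- config$n_presentations
  n_cell <- n_ind * n_stim * n_pres
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_cell * 3L),
                  ncol = 3L)
  order_rows <- lapply(seq_len(n_ind), function(i) {
    data.frame(individual_id = sprintf("ind%02d", i),
               presentation = rep(seq_len(n_pres), each = n_stim),
               order = rep(seq_len(n_stim), n_pres),
               stim_id = unlist(lapply(seq_len(n_pres), function(p)
                 vapply(config$stimuli[sample.int(n_stim)], `[[`, "", "stim_id"))),
               stringsAsFactors = FALSE)
  })
  presentation_order <- do.call(rbind, order_rows)

  period <- config$wingbeat_period_ms
  stim_ids <- vapply(config$stimuli, `[[`, "", "stim_id")

  spike_rows <- vector("list", n_cell)
  wing_rows <- vector("list", n_cell)
  cell <- 0L
  for (i in seq_len(n_ind)) {
    ind <- sprintf("ind%02d", i)
    for (s in seq_len(n_stim)) {
      stim <- config$stimuli[[s]]
      fn <- eta_rate_fn(config$eta, stim)
      s_start <- stim$start_distance / stim$speed
      s_end <- stim$end_distance / stim$speed
      delta <- config$eta$delta_ms
      spike_span <- c(-1000 * s_start + delta, -1000 * s_end + delta)
      # flight starts well before the approach and resumes after a glide, so
      # an injected pause is always followed by wingbeats and detectable
      wing_span <- c(-1000 * s_start - (config$glide_beats + 12) * period,
                     max(spike_span[2], 0) + (config$glide_beats + 4) * period)
      for (p in seq_len(n_pres)) {
        cell <- cell + 1L
        spk <- sample_spike_train(fn, spike_span, seed = seeds[cell, 1],
                                  individual_id = ind, stim_id = stim$stim_id,
                                  presentation = p)
        # wingbeat phase is not locked to the stimulus: shift the lattice by a
        # uniform random fraction of a period each presentation
        set.seed(seeds[cell, 2])
        phase <- stats::runif(1, 0, period)
        wb <- sample_wingbeats(period, config$wingbeat_jitter_sd_ms,
                               wing_span + phase, seed = NULL,
                               individual_id = ind, stim_id = stim$stim_id,
                               presentation = p)
        wb <- inject_glides(wb, fn, config$glide_threshold_hz,
                            config$gating_probability, seed = seeds[cell, 3],
                            glide_beats = config$glide_beats)
        spike_rows[[cell]] <- if (length(spk$t_ms))
          data.frame(individual_id = ind, stim_id = stim$stim_id,
                     presentation = p, t_ms = spk$t_ms,
                     stringsAsFactors = FALSE) else NULL
        wing_rows[[cell]] <- data.frame(individual_id = ind,
                                        stim_id = stim$stim_id,
                                        presentation = p, t_ms = wb$t_ms,
                                        valid_flight = wb$valid_flight,
                                        stringsAsFactors = FALSE)
      }
    }
  }
  stim_df <- stimuli_to_df(config$stimuli)
  structure(list(spikes = do.call(rbind, spike_rows),
                 wingbeats = do.call(rbind, wing_rows),
                 stimuli = stim_df,
                 presentation_order = presentation_order,
                 config = config),
            class = "loom_battery")
}

#' @export
print.loom_battery <- function(x, ...) {
  cat(sprintf("Synthetic battery: %d stimuli x %d individuals x %d presentations (seed %s)\n",
              length(x$config$stimuli), x$config$n_individuals,
              x$config$n_presentations, format(x$config$seed)))
  cat(sprintf("  %d spikes, %d wingbeat events\n",
              nrow(x$spikes), nrow(x$wingbeats)))
  invisible(x)
}
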