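# shared fixtures and independent oracles

# brute-force O(n^2) oracle for the inclusive backward-window rate
oracle_window_rate <- function(t_ms, window_ms = 25) {
  vapply(seq_along(t_ms), function(i)
    sum(t_ms > t_ms[i] - window_ms & t_ms <= t_ms[i]), 0) / (window_ms / 1000)
}

# random spike train with sorted unique times
random_train <- function(n, span = c(-500, 50)) {
  spike_train(sort(unique(stats::runif(n, span[1], span[2]))))
}

# a constant-speed track segment with the given per-segment mean speed
const_speed_segment <- function(speed, kite_id, attack_id, segment_id,
                                n_frames = 11, fps = 25,
                                cal_len_px = 100, cal_len_m = 1) {
  scale <- cal_len_m / cal_len_px
  step <- speed / (scale * fps)
  track_segment(seq_len(n_frames), step * (seq_len(n_frames) - 1),
                rep(0, n_frames), fps = fps, cal_len_px = cal_len_px,
                cal_len_m = cal_len_m, kite_id = kite_id,
                attack_id = attack_id, segment_id = segment_id)
}

# peak model rate over the full response support (peak may fall after collision)
model_peak_rate <- function(st, pp = eta_params()) {
  lo <- st$end_distance / st$speed - pp$delta_ms / 1000
  hi <- st$start_distance / st$speed - pp$delta_ms / 1000
  stats::optimize(function(t) eta_rate(pp, st, t), c(lo, hi),
                  maximum = TRUE, tol = 1e-8)$objective
}

# default battery, built once per test run (about 5 s) and cached
.fixture_cache <- new.env(parent = emptyenv())

cached_battery <- function() {
  if (is.null(.fixture_cache$battery))
    .fixture_cache$battery <- scenario_battery(simulation_config(seed = 1))
  .fixture_cache$battery
}

battery_lovs <- c(80, 40, 26.7, 20, 16, 13.3, 10, 8, 6, 5.3, 4, 3.2, 2.7)

battery_stim_ids <- function() paste0("disc_", sprintf("%.1f", battery_lovs))

# per-stimulus wingbeat trains from a battery data frame
battery_wingbeat_trains <- function(battery, sid) {
  w <- battery$wingbeats[battery$wingbeats$stim_id == sid, ]
  key <- paste(w$individual_id, w$presentation)
  lapply(unique(key), function(k) {
    d <- w[key == k, ]
    wingbeat_train(d$t_ms, d$individual_id[1], sid, d$presentation[1])
  })
}

# per-stimulus spike trains grouped by individual
battery_spike_trains <- function(battery, sid) {
  s <- battery$spikes[battery$spikes$stim_id == sid, ]
  lapply(split(s, s$individual_id), function(d)
    lapply(split(d$t_ms, d$presentation), spike_train))
}
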