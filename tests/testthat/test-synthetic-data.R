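test_that("eta_rate peaks where calculus says it must", {
  # alpha = 5, l/|v| = 10 ms, no latency: peak 50 ms before collision
  p0 <- eta_params(alpha = 5, delta_ms = 0)
  st <- looming_stimulus(0.04, 4)
  expect_equal(eta_peak_time(p0, st), -50)
  opt <- optimize(function(t) eta_rate(p0, st, t), c(0.001, 0.5), maximum = TRUE)
  expect_equal(opt$maximum * 1000, 50, tolerance = 0.1)

  # the subtense at the peak is 2*arctan(1/alpha), independent of l/|v|
  for (st_i in stimulus_set()[c(1, 7, 13)]) {
    t_star <- 5 * st_i$lov_ms / 1000
    expect_equal(angular_subtense(st_i$half_size, st_i$speed * t_star),
                 2 * atan(1 / 5) * 180 / pi)
  }

  expect_equal(eta_rate(eta_params(scale_C = 0), st, c(0.01, 0.1, 0.3)),
               rep(0, 3))
  # zero outside the (latency-shifted) motion span
  pp <- eta_params()
  expect_equal(eta_rate(pp, st, 10 / 4), 0)      # before motion reaches the eye
  expect_gt(eta_rate(pp, st, 10 / 4 - 0.028), 0)
})

test_that("closed-form peak time matches numeric maximization across the set", {
  pp <- eta_params()
  for (st in stimulus_set()) {
    s_lo <- st$end_distance / st$speed - pp$delta_ms / 1000
    s_hi <- st$start_distance / st$speed - pp$delta_ms / 1000
    opt <- optimize(function(t) eta_rate(pp, st, t), c(s_lo, s_hi),
                    maximum = TRUE, tol = 1e-7)
    expect_equal(-opt$maximum * 1000, eta_peak_time(pp, st), tolerance = 0.5)
  }
})

test_that("model peak rates fall as l/|v| rises", {
  peaks <- vapply(stimulus_set(), model_peak_rate, 0)
  expect_true(all(diff(peaks) > 0))  # stimulus_set is ordered high -> low l/|v|
})

test_that("sample_spike_train is a seeded thinning sampler", {
  none <- sample_spike_train(function(t) rep(0, length(t)), c(-100, 0), seed = 1)
  expect_length(none$t_ms, 0)
  a <- sample_spike_train(function(t) rep(80, length(t)), c(-500, 0), seed = 7)
  b <- sample_spike_train(function(t) rep(80, length(t)), c(-500, 0), seed = 7)
  expect_identical(a$t_ms, b$t_ms)
  c2 <- sample_spike_train(function(t) rep(80, length(t)), c(-500, 0), seed = 8)
  expect_false(identical(a$t_ms, c2$t_ms))
  expect_error(sample_spike_train(function(t) rep(Inf, length(t)), c(-1, 0)),
               "unbounded")

  # Poisson count calibration: constant 100 Hz over 1 s
  set.seed(43)
  counts <- vapply(1:300, function(i)
    length(sample_spike_train(function(t) rep(100, length(t)),
                              c(-1000, 0))$t_ms), 0)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 300))
})

test_that("sample_wingbeats produces a seeded, jittered lattice", {
  exact <- sample_wingbeats(50, 0, c(-200, 0), seed = 1)
  expect_equal(exact$t_ms, seq(-200, 0, 50))
  a <- sample_wingbeats(50, 2, c(-500, 0), seed = 2)
  expect_identical(a$t_ms, sample_wingbeats(50, 2, c(-500, 0), seed = 2)$t_ms)
  expect_error(sample_wingbeats(50, 20, c(-500, 0)), "ambiguous")
  set.seed(44)
  m <- mean(vapply(1:50, function(i)
    mean(diff(sample_wingbeats(50, 2, c(-2000, 0))$t_ms)), 0))
  expect_equal(m, 50, tolerance = 0.01)
})

test_that("inject_glides gates on rate, probability and injects at most once", {
  low <- function(t) rep(50, length(t))
  high <- function(t) rep(200, length(t))
  wb <- sample_wingbeats(50, 0, c(-500, 200), seed = 3)
  expect_identical(inject_glides(wb, low, seed = 1)$t_ms, wb$t_ms)
  expect_identical(inject_glides(wb, high, gating_probability = 0, seed = 1)$t_ms,
                   wb$t_ms)
  inj <- inject_glides(wb, high, gating_probability = 1, seed = 1)
  expect_length(inj$t_ms, length(wb$t_ms) - 3)
  expect_equal(attr(inj, "glide_injected_at"), wb$t_ms[1])
  expect_equal(max(diff(inj$t_ms)), 200)  # one 4-period gap, nothing else
})

test_that("synth_track recovers the configured speed", {
  clean <- synth_track(10, n_frames = 20)
  expect_equal(as.numeric(frame_speeds(clean)), rep(10, 19))
  rot <- synth_track(10, heading_deg = 137, n_frames = 20)
  expect_equal(as.numeric(frame_speeds(rot)), rep(10, 19))
  a <- synth_track(10, noise_sd_px = 0.5, seed = 5)
  expect_identical(a$x_px, synth_track(10, noise_sd_px = 0.5, seed = 5)$x_px)
  expect_equal(mean(frame_speeds(a)), 10, tolerance = 0.05)
})

test_that("scenario_battery has the product structure and is reproducible", {
  cfg <- simulation_config(stimuli = stimulus_set()[c(1, 7, 13)],
                           n_individuals = 2, n_presentations = 2, seed = 9)
  b1 <- scenario_battery(cfg)
  b2 <- scenario_battery(cfg)
  expect_identical(b1$spikes, b2$spikes)
  expect_identical(b1$wingbeats, b2$wingbeats)
  cells <- unique(b1$wingbeats[c("individual_id", "stim_id", "presentation")])
  expect_equal(nrow(cells), 3 * 2 * 2)
  expect_equal(nrow(b1$presentation_order), 3 * 2 * 2)
  b3 <- scenario_battery(simulation_config(stimuli = stimulus_set()[c(1, 7, 13)],
                                           n_individuals = 2,
                                           n_presentations = 2, seed = 10))
  expect_false(identical(b1$spikes, b3$spikes))
  # battery CSVs regenerate byte-identically under one master seed
  d1 <- tempfile(); d2 <- tempfile()
  write_battery(b1, d1); write_battery(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("wing attenuation strictly delays the 150 Hz crossing", {
  pp <- eta_params()
  for (lov in c(8, 6, 4)) {      # both variants cross at these l/|v|
    v <- 1000 * 0.04 / lov
    plain <- looming_stimulus(0.04, v)
    winged <- looming_stimulus(0.04, v, wing = wing_spec())
    grid <- seq(-200, 40, by = 0.25)
    cross <- function(st) threshold_crossings(
      rate_series(grid, eta_rate(pp, st, -grid / 1000)))$first_crossing
    expect_gt(cross(winged), cross(plain))
  }
})
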