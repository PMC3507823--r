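test_that("lov_ratio reproduces the printed stimulus labels", {
  expect_equal(lov_ratio(0.04, 0.5), 80)
  expect_equal(lov_ratio(0.04, 15), 2.6667, tolerance = 1e-4)
  expect_equal(display_round(lov_ratio(0.04, 15)), 2.7)
  expect_equal(lov_ratio(0.001, 1), 1)
  # the whole label set round-trips through the derived speeds
  labels <- c(80, 40, 26.7, 20, 16, 13.3, 10, 8, 6, 5.3, 4, 3.2, 2.7)
  speeds <- 1000 * 0.04 / labels
  expect_equal(display_round(lov_ratio(0.04, speeds)), labels)
  expect_error(lov_ratio(0, 1), "half_size")
  expect_error(lov_ratio(0.04, 0), "speed")
})

test_that("display_round rounds halves away from zero", {
  expect_equal(display_round(1.25), 1.3)  # round() would give 1.2
  expect_equal(display_round(-1.25), -1.3)
  expect_equal(display_round(2.67), 2.7)
  expect_equal(display_round(16.6259), 16.6)
})

test_that("angular_subtense matches direct evaluation and its invariances", {
  expect_equal(angular_subtense(0.04, 0.07), 2 * atan(4 / 7) * 180 / pi)
  expect_equal(angular_subtense(0.04, 0.07), 59.49, tolerance = 1e-4)
  expect_equal(angular_subtense(0.3, 0.3), 90)           # l = d
  expect_equal(angular_subtense(0.04, 10), 0.4584, tolerance = 1e-3)
  expect_error(angular_subtense(0.04, 0), "distance")

  set.seed(11)
  for (i in 1:20) {
    l <- runif(1, 0.001, 1); d <- runif(1, 0.01, 20); cc <- runif(1, 0.1, 50)
    expect_equal(angular_subtense(cc * l, cc * d), angular_subtense(l, d))
  }
  d <- seq(0.05, 10, length.out = 50)
  expect_true(all(diff(angular_subtense(0.04, d)) < 0))
})

test_that("subtense_rate matches the closed form and a central difference", {
  expect_equal(subtense_rate(0.04, 2, 1) * pi / 180, 2 * 0.04 * 2 / (4 + 0.0016))
  expect_lt(subtense_rate(0.04, 2, 1e3), 1e-4)  # vanishes far from collision
  set.seed(12)
  for (i in 1:20) {
    l <- runif(1, 0.01, 0.5); v <- runif(1, 0.5, 15); t <- runif(1, 0.05, 5)
    h <- t * 1e-5
    fd <- (angular_subtense(l, v * (t - h)) - angular_subtense(l, v * (t + h))) / (2 * h)
    expect_equal(subtense_rate(l, v, t), fd, tolerance = 1e-6)
  }
  tt <- seq(2, 0.1, by = -0.1)
  expect_true(all(diff(subtense_rate(0.04, 5, tt)) > 0))  # rises toward collision
  expect_error(subtense_rate(0.04, 5, 0), "t_to_collision")
})

test_that("loom_trajectory spans the approach and ends at the screen angle", {
  slow <- loom_trajectory(looming_stimulus(0.04, 0.5), dt = 0.05)
  expect_equal(slow$t_to_collision[1], 20)                    # 10 / 0.5
  expect_equal(slow$t_to_collision[nrow(slow)], 0.14)         # 0.07 / 0.5
  fast <- loom_trajectory(looming_stimulus(0.04, 15), dt = 0.001)
  expect_equal(fast$t_to_collision[1], 10 / 15)
  # screen-level subtense is speed-independent
  expect_equal(fast$theta_deg[nrow(fast)], angular_subtense(0.04, 0.07))
  expect_equal(slow$theta_deg[nrow(slow)], angular_subtense(0.04, 0.07))
  # strictly increasing subtense as t falls, distance = v * t
  expect_true(all(diff(fast$theta_deg) > 0))
  expect_equal(fast$distance, 15 * fast$t_to_collision)
  expect_true(all(is.na(fast$theta_wing_deg)))
  winged <- loom_trajectory(looming_stimulus(0.04, 15, wing = wing_spec()),
                            dt = 0.001)
  expect_equal(winged$theta_wing_deg, angular_subtense(0.18, winged$distance))
  expect_error(loom_trajectory(looming_stimulus(0.04, 15), dt = 10),
               "approach duration")
})

test_that("equal l/|v| stimuli share one subtense time course", {
  # the justification for representing a 0.136 m thorax with a 0.08 m disc
  tt <- seq(0.5, 0.01, by = -0.01)
  pairs <- list(c(0.04, 5), c(0.068, 8.5), c(0.02, 2.5))  # all l/|v| = 8 ms
  thetas <- lapply(pairs, function(p) angular_subtense(p[1], p[2] * tt))
  expect_equal(thetas[[2]], thetas[[1]])
  expect_equal(thetas[[3]], thetas[[1]])
})

test_that("collision_offset anchors projected collision", {
  expect_equal(collision_offset(looming_stimulus(0.04, 15)) * 1000, 4.667,
               tolerance = 1e-3)
  expect_equal(collision_offset(looming_stimulus(0.04, 0.5)), 0.14)
  expect_equal(collision_offset(looming_stimulus(0.04, 1, end_distance = 0)), 0)
})

test_that("frame_schedule counts, projects and clips frames", {
  stim <- looming_stimulus(0.04, 15)
  fs <- frame_schedule(stim, refresh_hz = 200, pixel_pitch = 4e-4)
  expect_equal(nrow(fs), floor((10 - 0.07) / 15 * 200))  # 132
  # final frame sits at the end distance: radius = viewing * l / end / pitch
  expect_equal(fs$radius_px[nrow(fs)], 0.07 * 0.04 / 0.07 / 4e-4)
  expect_true(all(diff(fs$radius_px) >= 0))
  expect_true(all(diff(fs$t_to_collision_s) < 0))
  # frame count scales with refresh rate
  fs2 <- frame_schedule(stim, refresh_hz = 400, pixel_pitch = 4e-4)
  expect_lte(abs(nrow(fs2) - 2 * nrow(fs)), 1)
  # wing bar projected with the same perspective rule (pitch chosen unclipped)
  ws <- frame_schedule(looming_stimulus(0.04, 15, wing = wing_spec()),
                       refresh_hz = 200, pixel_pitch = 1e-3)
  expect_equal(ws$wing_w_px / ws$radius_px, rep(0.36 / 0.04, nrow(ws)))
  # clipping flags and clamps oversized frames
  expect_warning(cl <- frame_schedule(stim, pixel_pitch = 1e-5), "clipped")
  expect_true(any(cl$clipped))
  expect_lte(max(cl$radius_px), 240)
  # too-low refresh: no frame fits in the approach
  expect_equal(nrow(frame_schedule(stim, refresh_hz = 1, pixel_pitch = 4e-4)), 0)
})

test_that("stimulus construction enforces its invariants", {
  expect_error(looming_stimulus(-0.04, 1), "half_size")
  expect_error(looming_stimulus(0.04, -1), "speed")
  expect_error(looming_stimulus(0.04, 1, start_distance = 0.05), "start_distance")
  # wings must protrude beyond the disc
  expect_error(looming_stimulus(0.2, 1, wing = wing_spec(span = 0.36)), "protrude")
  st <- looming_stimulus(0.04, 15, wing = wing_spec())
  expect_equal(st$wing$span, 0.36)
  expect_match(st$stim_id, "^wing_")
})
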