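test_that("calibration_scale divides metres by pixels", {
  expect_equal(calibration_scale(69.5, 0.56), 0.56 / 69.5)
  expect_equal(calibration_scale(100, 1), 0.01)
  expect_equal(calibration_scale(1, 1), 1)
  expect_error(calibration_scale(0, 1), "length_px")
  expect_error(calibration_scale(10, -1), "length_m")
})

test_that("frame_speeds converts pixel displacements, handling frame gaps", {
  seg <- track_segment(1:6, seq(0, 50, 10), rep(0, 6), fps = 25,
                       cal_len_px = 100, cal_len_m = 4)
  expect_equal(as.numeric(frame_speeds(seg)), rep(10 * 0.04 * 25, 5))
  expect_false(attr(frame_speeds(seg), "smoothed"))

  still <- track_segment(1:4, rep(3, 4), rep(7, 4), fps = 25,
                         cal_len_px = 100, cal_len_m = 4)
  expect_equal(as.numeric(frame_speeds(still)), rep(0, 3))

  # a skipped frame divides the elapsed time
  gap <- track_segment(c(1, 2, 4), c(0, 10, 30), c(0, 0, 0), fps = 25,
                       cal_len_px = 100, cal_len_m = 4)
  expect_equal(as.numeric(frame_speeds(gap)), rep(10, 2))

  expect_error(track_segment(c(1, 1, 2), 1:3, 1:3, cal_len_px = 1, cal_len_m = 1),
               "duplicate")
})

test_that("smooth_for_display is a flagged 3-point mean with fixed endpoints", {
  expect_equal(as.numeric(smooth_for_display(c(1, 4, 1))), c(1, 2, 1))
  expect_equal(as.numeric(smooth_for_display(c(0, 0, 3, 0, 0))), c(0, 1, 1, 1, 0))
  expect_equal(as.numeric(smooth_for_display(rep(2, 6))), rep(2, 6))
  expect_true(attr(smooth_for_display(c(1, 4, 1)), "smoothed"))
  expect_error(smooth_for_display(c(1, 2)), ">= 3")
})

test_that("hierarchical_mean averages unweighted up the hierarchy", {
  segs <- list(const_speed_segment(8, "k1", "a1", "s1"),
               const_speed_segment(12, "k1", "a1", "s2"))
  hm <- hierarchical_mean(segs)
  expect_equal(hm$kites$mean_speed, 10)
  expect_equal(hm$n_kites, 1)
  expect_true(is.na(hm$grand_sd))

  # unequal sample sizes do not weight the grand mean; SD is the sample SD
  segs2 <- c(lapply(1:5, function(i)
               const_speed_segment(9, "k1", paste0("a", i), "s1")),
             list(const_speed_segment(11, "k2", "a1", "s1")))
  hm2 <- hierarchical_mean(segs2)
  expect_equal(hm2$grand_mean, 10)
  expect_equal(hm2$grand_sd, sd(c(9, 11)))
  expect_equal(hm2$grand_sd, 1.414, tolerance = 1e-3)

  # replicating one individual's attacks leaves the grand stats untouched
  segs3 <- c(segs2, lapply(6:15, function(i)
    const_speed_segment(9, "k1", paste0("a", i), "s1")))
  hm3 <- hierarchical_mean(segs3)
  expect_equal(hm3$grand_mean, hm2$grand_mean)
  expect_equal(hm3$grand_sd, hm2$grand_sd)

  expect_error(hierarchical_mean(list()), "no track segments")
})

test_that("trim keeps only the final seconds of each attack", {
  # 2 s of 5 m/s followed by 1 s of 15 m/s at 25 fps in one segment
  scale <- 0.01
  step1 <- 5 / (scale * 25); step2 <- 15 / (scale * 25)
  x <- cumsum(c(0, rep(step1, 50), rep(step2, 25)))
  seg <- track_segment(seq_along(x), x, rep(0, length(x)), fps = 25,
                       cal_len_px = 100, cal_len_m = 1)
  expect_equal(hierarchical_mean(list(seg), trim_s = 0.9)$grand_mean, 15)
  expect_equal(hierarchical_mean(list(seg), trim_s = Inf)$grand_mean,
               mean(c(rep(5, 50), rep(15, 25))))
})

test_that("closing_speed obeys the head-on / tail-chase geometry", {
  expect_equal(closing_speed(8.6, 4.6, 180), 13.2)
  expect_equal(closing_speed(5, 5, 0), 0)
  expect_equal(closing_speed(7, 0, 63), 7)
  set.seed(21)
  for (i in 1:25) {
    v1 <- runif(1, 0, 20); v2 <- runif(1, 0, 20)
    expect_equal(closing_speed(v1, v2, 180) - closing_speed(v1, v2, 0),
                 2 * min(v1, v2))
    # monotone in the convergence angle
    phis <- seq(0, 180, by = 20)
    expect_true(all(diff(closing_speed(v1, v2, phis)) >= -1e-12))
  }
  expect_error(closing_speed(1, 1, 190), "phi")
  expect_error(closing_speed(-1, 1, 90), "non-negative")
})

test_that("thorax_half_size derives l from wingspan", {
  expect_equal(thorax_half_size(predator_profile(1.36, 0.10)), 0.068)
  # captive kite check: 0.11 m thorax on a 1.42 m wingspan
  expect_equal(thorax_half_size(predator_profile(1.42, 0.11 / 1.42)), 0.055)
  expect_equal(thorax_half_size(predator_profile(2, 0.5)), 0.5)
  expect_error(predator_profile(0), "wingspan")
  expect_error(predator_profile(1, 1.2), "thorax_fraction")
})

test_that("lov_range reproduces the printed predator windows", {
  kite <- lov_range(closing_scenario(10.76, 1.42, 4.6, 0.65),
                    predator_profile(1.36))
  expect_equal(unname(attr(kite, "closing_speeds")), c(17.43, 4.09))
  expect_equal(as.numeric(display_round(kite)), c(3.9, 16.6))

  swallow <- lov_range(closing_scenario(8.6, 0, 4.6, 0,
                                        predator_mean_chase = 6.8), 0.0165)
  expect_equal(as.numeric(display_round(swallow)), c(1.3, 7.5))

  nighthawk <- lov_range(closing_scenario(6.5, 0, 4.6, 0), 0.032)
  expect_equal(as.numeric(display_round(nighthawk)), c(2.9, 16.8))

  expect_true(kite["low_ms"] < kite["high_ms"])
  # a prey faster than the slow predator makes the chase endpoint undefined
  expect_error(lov_range(closing_scenario(5, 1, 4.6, 0.65), 0.068),
               "revise the scenario")
})

test_that("speeds are recovered from noisy synthetic tracks", {
  segs <- lapply(1:10, function(i)
    synth_track(10.76, heading_deg = 36 * i, noise_sd_px = 0.5, n_frames = 30,
                seed = 100 + i, kite_id = paste0("k", i)))
  hm <- hierarchical_mean(segs)
  expect_equal(hm$grand_mean, 10.76, tolerance = 0.02)
})
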