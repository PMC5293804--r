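test_that("low-pass filter passes DC exactly and low frequencies nearly unchanged", {
  expect_equal(lowpass(rep(3.3, 50), 60, 10, 2), rep(3.3, 50), tolerance = 1e-12)
  t <- (0:599) / 60
  y <- lowpass(sin(2 * pi * 2 * t), 60, 10, 2)
  expect_lt(1 - max(abs(y[100:500])), 0.02) # 2 Hz attenuation < 2%
  y2 <- lowpass(sin(2 * pi * 25 * t), 60, 10, 2)
  expect_gt(1 - max(abs(y2[100:500])), 0.90) # 25 Hz attenuation > 90%
})

test_that("low-pass filter validates its arguments", {
  expect_error(lowpass(rnorm(50), 60, 30, 2), "Nyquist")
  expect_error(lowpass(rnorm(50), 60, 40, 2), "Nyquist")
  expect_error(lowpass(rnorm(3), 60, 10, 2), "too short")
})

test_that("zero-phase application agrees with signal::filtfilt away from the edges", {
  set.seed(11)
  x <- cumsum(rnorm(400))
  mine <- lowpass(x, 100, 8, 2)
  bf <- signal::butter(2, 8 / 50)
  ref <- signal::filtfilt(bf, x)
  expect_equal(mine[50:350], ref[50:350], tolerance = 1e-6)
})

test_that("marker speed is exact for uniform and static motion", {
  n <- 30
  t_ms <- (0:(n - 1)) / 60 * 1000
  # straight line, 10 mm per frame at 60 Hz -> 600 mm/s
  tr <- trajectory(t_ms, 10 * (0:(n - 1)) * 0.6, 10 * (0:(n - 1)) * 0.8, rep(0, n))
  expect_equal(marker_speed(tr), rep(600, n), tolerance = 1e-9)
  static <- trajectory(t_ms, rep(1, n), rep(2, n), rep(3, n))
  expect_equal(marker_speed(static), rep(0, n))
  expect_error(marker_speed(trajectory(c(0, 10), 0:1, 0:1, 0:1)), "3 frames")
})

test_that("speed of a minimum-jerk trajectory matches the closed-form peak", {
  v <- speed_profile(0.5, 742.6, 330, 200)
  t_ms <- seq(0, 742.6, length.out = length(v))
  s <- reachgrasp:::beta_path(seq(0, 1, length.out = length(v)), 0.5, 330)
  tr <- trajectory(t_ms, s * 0.6, s * 0.8, rep(0, length(v)))
  expect_lt(abs(max(marker_speed(tr)) - 1.875 * 330 / 0.7426) / 833, 0.01)
})

test_that("displacement-rule reach segmentation finds constructed onsets and tie-breaks offsets", {
  # motion starting at frame 12 with per-axis steps of 0.4 mm
  n <- 40
  t_ms <- (0:(n - 1)) * 1000 / 60
  steps <- matrix(0, n, 3)
  steps[12:25, ] <- 0.4
  steps[26:n, ] <- 0.05
  steps[18:20, ] <- 2 # clear velocity peak inside
  xyz <- apply(steps, 2, cumsum)
  tr <- trajectory(t_ms, xyz[, 1], xyz[, 2], xyz[, 3])
  w <- segment_reach_displacement(tr, grasp_end_ms = t_ms[26], cfg = segmentation_config())
  expect_true(w$ok)
  expect_equal(w$onset_idx, 12L)

  # distinct per-axis settle frames: the candidate closest in time to
  # the grasp end must win the tie-break
  steps2 <- matrix(0.4, n, 3)
  steps2[1:11, ] <- 0
  steps2[18:20, ] <- 2
  steps2[28:n, 1] <- 0.05 # axis 1 settles first
  steps2[31:n, 2] <- 0.05 # axis 2 later
  steps2[34:n, 3] <- 0.05 # axis 3 last
  xyz2 <- apply(steps2, 2, cumsum)
  tr2 <- trajectory(t_ms, xyz2[, 1], xyz2[, 2], xyz2[, 3])
  for (target in c(28L, 31L, 34L)) {
    w2 <- segment_reach_displacement(tr2, grasp_end_ms = t_ms[target],
                                     cfg = segmentation_config())
    expect_true(w2$ok)
    expect_equal(w2$offset_idx, target)
  }
})

test_that("velocity-rule reach segmentation scans first/last suprathreshold frames", {
  sp <- c(0, 0.5, 2, 5, 2, 0.5, 0)
  t_ms <- (0:6) * 5
  w <- segment_reach_velocity(sp, t_ms)
  expect_equal(w$onset_idx, 3L)
  expect_equal(w$offset_idx, 5L)
  # all frames above threshold: window is the full support
  w2 <- segment_reach_velocity(rep(5, 7), t_ms)
  expect_equal(c(w2$onset_idx, w2$offset_idx), c(1L, 7L))
  w3 <- segment_reach_velocity(rep(0.2, 7), t_ms)
  expect_false(w3$ok)
})

test_that("grasp segmentation thresholds from baseline and symmetric apertures peak midway", {
  n <- 61
  t_ms <- (0:(n - 1)) * 1000 / 60
  # triangular aperture rising from 5 mm, first exceeding 5.3 at a known frame
  ap <- c(rep(5, 7), 5 + 0.5 * (1:23), 5 + 0.5 * 23 - 0.5 * (1:23), rep(5, 8))[1:n]
  w <- segment_grasp(ap, t_ms)
  expect_true(w$ok)
  expect_equal(w$onset_idx, 8L) # first frame above 5.3
  g <- extract_grasp_params(ap, t_ms, w)
  expect_equal(g$max_aperture_mm, max(ap))
  expect_lt(abs(g$pct_t_max_aperture - 50), 100 / (w$offset_idx - w$onset_idx) + 1e-9)
})

test_that("reach parameter extraction satisfies its defining identities", {
  sp <- speed_profile(0.5, 700, 330, 200)
  t_ms <- seq(0, 700, length.out = length(sp))
  w <- segment_reach_velocity(sp, t_ms)
  r <- extract_reach_params(sp, t_ms, w)
  expect_equal(r$reach_time_ms, w$offset_ms - w$onset_ms)
  expect_equal(r$pct_t_vpeak, 100 * r$t_vpeak_ms / r$reach_time_ms)
  expect_gt(r$t_vpeak_ms, 0)
  expect_lt(r$t_vpeak_ms, r$reach_time_ms)
  expect_lt(abs(r$pct_t_vpeak - 50), 100 * 5 / 700 + 1e-9) # symmetry within one frame
})

test_that("segmentation matches the brute-force frame-scan oracles on random fixtures", {
  n_fix <- 250
  cfg1 <- segmentation_config("displacement_exp1")
  cfg2 <- segmentation_config("velocity_exp2")
  for (i in seq_len(n_fix)) {
    fx <- random_motion_fixture(1000 + i)
    tr <- trajectory(fx$t_ms, fx$xyz[, 1], fx$xyz[, 2], fx$xyz[, 3])
    sp <- marker_speed(tr)
    grasp_end <- fx$t_ms[round(length(fx$t_ms) * 0.8)]

    w <- segment_reach_displacement(tr, grasp_end, cfg1)
    o <- oracle_reach_displacement(fx$xyz, fx$t_ms, sp, grasp_end)
    if (is.null(o)) {
      expect_false(w$ok)
    } else if (w$ok) {
      expect_equal(w$onset_idx, o$onset)
      expect_equal(w$offset_idx, o$offset)
    }

    w2 <- segment_reach_velocity(sp, fx$t_ms, cfg2)
    o2 <- oracle_reach_velocity(sp)
    if (is.null(o2)) {
      expect_false(w2$ok)
    } else if (w2$ok) {
      expect_equal(w2$onset_idx, o2$onset)
      expect_equal(w2$offset_idx, o2$offset)
    }

    set.seed(2000 + i)
    ap <- reachgrasp:::aperture_bump(seq(0, 1, length.out = 60), 5,
                        runif(1, 40, 100), runif(1, 0.3, 0.8)) +
      rnorm(60, sd = 0.05)
    t_ap <- (0:59) * 1000 / 60
    w3 <- segment_grasp(ap, t_ap)
    o3 <- oracle_grasp(ap)
    if (is.null(o3)) {
      expect_false(w3$ok)
    } else if (w3$ok) {
      expect_equal(w3$onset_idx, o3$onset)
      expect_equal(w3$offset_idx, o3$offset)
    }
  }
})

test_that("trial processing recovers generator ground truth on a noiseless trial", {
  cfg <- noiseless(generator_preset("exp1_italian"))
  tr <- simulate_trial(condition("YOU", "AV"), NULL, cfg, seed = 7)
  row <- process_trial(tr, segmentation_config("displacement_exp1"))
  expect_false(row$segmentation_failure)
  expect_lt(abs(row$reach_time_ms - 685.6), 1000 / 60 + 1e-9)
  expect_lt(abs(row$grasp_time_ms - 685.6), 2 * 1000 / 60 + 1e-9)
  expect_lt(abs(row$max_aperture_mm - 85), 0.5)
})

test_that("velocity-variant processing yields reach but no grasp parameters", {
  cfg <- noiseless(generator_preset("exp2_german"))
  tr <- simulate_trial(condition("HE", "IV"), NULL, cfg, seed = 2)
  row <- process_trial(tr, segmentation_config("velocity_exp2"))
  expect_false(row$segmentation_failure)
  expect_lt(abs(row$reach_time_ms - 894.5), 5 + 1e-9)
  expect_true(is.na(row$grasp_time_ms))
  expect_false(is.na(row$pct_t_vpeak))
})

test_that("a motionless trial is flagged, not fatal", {
  n <- 60
  t_ms <- (0:(n - 1)) * 1000 / 60
  still <- trajectory(t_ms, rep(0, n), rep(0, n), rep(0, n))
  tr <- trial_record("S01", "T001", condition("I", "AV"),
                     markers = list(wrist = still, index = still, thumb = still))
  row <- process_trial(tr, segmentation_config("displacement_exp1"))
  expect_true(row$segmentation_failure)
  expect_true(is.na(row$reach_time_ms))
})

test_that("normalized peak latency is invariant under spatial scaling and rate refinement", {
  base <- noiseless(generator_preset("exp1_italian"))
  tr60 <- simulate_trial(condition("I", "IV"), NULL, base, seed = 3)
  r60 <- process_trial(tr60, segmentation_config("displacement_exp1"))
  # uniform spatial scaling of the trajectory leaves pct_t_vpeak unchanged
  scaled <- tr60
  for (m in names(scaled$markers)) {
    for (ax in c("x_mm", "y_mm", "z_mm")) {
      scaled$markers[[m]][[ax]] <- scaled$markers[[m]][[ax]] * 2
    }
  }
  # scaling doubles all displacements, so double the threshold to match
  cfg2 <- segmentation_config("displacement_exp1", displacement_threshold_mm = 0.6)
  r2 <- process_trial(scaled, cfg2)
  expect_equal(r2$pct_t_vpeak, r60$pct_t_vpeak, tolerance = 1e-9)
  expect_equal(r2$reach_time_ms, r60$reach_time_ms, tolerance = 1e-9)
})

test_that("increasing the generator peak fraction strictly increases extracted latency", {
  cfg <- noiseless(generator_preset("exp1_italian"))
  pcts <- c(40, 47, 54, 61)
  got <- vapply(pcts, function(p) {
    cm <- cfg$condition_means
    cm$pct_t_vpeak <- p
    c2 <- cfg
    c2$condition_means <- cm
    tr <- simulate_trial(condition("I", "AV"), NULL, c2, seed = 11)
    process_trial(tr, segmentation_config("displacement_exp1"))$pct_t_vpeak
  }, 0)
  expect_true(all(diff(got) > 0))
})
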