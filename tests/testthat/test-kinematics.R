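# Gait events and per-step kinematics.

test_that("track alignment recovers imposed rotations and guards drift", {
  trial <- flat_trial()
  ms <- trial$markers
  aligned <- align_track_frame(ms)
  expect_lt(abs(attr(aligned, "rotation")), 1e-6)

  # rotate everything by +2 degrees and expect recovery of -2 +/- 0.01
  ang <- 2 * pi / 180
  rot <- function(m) {
    cbind(cos(ang) * m[, 1L] - sin(ang) * m[, 2L],
          sin(ang) * m[, 1L] + cos(ang) * m[, 2L],
          m[, 3L])
  }
  ms_rot <- ms
  ms_rot$markers <- lapply(ms$markers, function(m) {
    out <- rot(m); colnames(out) <- c("x", "y", "z"); out
  })
  back <- align_track_frame(ms_rot)
  expect_equal(attr(back, "rotation"), -ang, tolerance = 0.01 / 2)
  com_orig <- ms$markers$hip_lf[, 2L]
  expect_equal(back$markers$hip_lf[, 2L], com_orig, tolerance = 1e-3)

  # pure lateral drift: correction clamped at the declared bound
  t <- seq(0, 5, by = 1 / 100)
  com <- cbind(0.2 * t, 3 * t, 1)  # ~3.8 degree drift
  heel <- cbind(0.2 * t, 3 * t, 0.03)
  drift <- synthetic_marker_set(t, heel, com, 100)
  expect_lt(abs(attr(align_track_frame(drift), "rotation")), 5 * pi / 180 + 1e-9)
  expect_warning(align_track_frame(drift, max_angle = 0.02), "clamped")
})

test_that("stance detection matches ground truth on noise-free trials and honours its gates", {
  trial <- flat_trial()
  ev <- detect_stance_events(trial$markers)
  tr <- trial$truth
  expect_equal(nrow(ev), nrow(tr))
  err <- vapply(tr$t_td, function(tt) min(abs(ev$t_td - tt)), 0)
  expect_lt(max(err), 1 / 300)              # within one frame
  # one touchdown per stance, strictly increasing
  expect_true(all(diff(ev$t_td) > 0))
  expect_true(all(ev$t_lo > ev$t_td))

  # heel hovering 50 mm above standing height: no stances
  t <- seq(0, 3, by = 1 / 300)
  heel <- cbind(0, 3.2 * t, 0.08)
  com <- cbind(0, 3.2 * t, 1.05)
  hover <- synthetic_marker_set(t, heel, com, 300)
  expect_warning(ev0 <- detect_stance_events(hover), "no stance")
  expect_equal(nrow(ev0), 0L)

  # stance on a 12 mm terrain peak is still detected (15 mm tolerance)
  heel2 <- cbind(0, ifelse(t < 1, 3.2 * (t - 1), 0), 0.03 + 0.012)
  heel2[t < 1, 3L] <- 0.2
  peak <- synthetic_marker_set(t, heel2, com, 300)
  ev12 <- detect_stance_events(peak)
  expect_gte(nrow(ev12), 1L)
})

test_that("landing velocity reproduces polynomial trajectories exactly", {
  t <- seq(0, 1, by = 1 / 300)
  td <- 0.9
  # exact cubic per axis
  xyz <- cbind(0.2 - 0.5 * (t - td) + 2 * (t - td)^3,
               1 + 2 * (t - td) - (t - td)^2,
               0.5 - 0.3 * (t - td) + 0.1 * (t - td)^2)
  v <- landing_velocity(t, xyz, td)
  expect_equal(unname(v), c(-0.5, 2, -0.3), tolerance = 1e-9)

  const <- cbind(rep(1, length(t)), 2, 3)
  expect_equal(unname(landing_velocity(t, const, td)), c(0, 0, 0))

  lin <- cbind(1 * t, -2 * t, 0.5 * t)
  expect_equal(unname(landing_velocity(t, lin, td)), c(1, -2, 0.5),
               tolerance = 1e-9)
  expect_error(landing_velocity(t, lin, td, window = 0.005), "4 samples")
})

test_that("per-step measures recover ground truth and are frame invariant", {
  trial <- flat_trial()
  sub <- subject_params()
  ms <- trial$markers
  ev <- detect_stance_events(ms)
  ser <- per_step_metrics(ms, ev, sub)
  ok <- !ser$is_turn
  tr <- trial$truth[!trial$truth$is_turn, ]

  expect_lt(median(abs(ser$step_length[ok] - median(tr$step_length))), 0.002)
  expect_lt(max(abs(ser$step_width[ok] - tr$step_width[1L])), 0.002)
  expect_equal(median(ser$com_speed[ok]), 3.2, tolerance = 1e-3)
  expect_equal(mean(ser$fwd_foot_speed_froude[ok]), 0.37, tolerance = 0.01)
  expect_equal(mean(ser$leg_angle[ok]), 0.20, tolerance = 0.01)
  expect_equal(mean(ser$virtual_leg_length[ok]) / sub$leg_length, 1.20,
               tolerance = 0.005)
  # CoM landing velocity carries the configured descent speed
  expect_equal(mean(-ser$v_com_z[ok]), 0.7, tolerance = 0.05)
  expect_true(all(ser$step_width >= 0))

  # straight CoM path: meander is zero
  meander <- attr(ser, "meander")
  expect_true(all(abs(meander$meander) < 1e-10))
  expect_true(all(meander$meander >= -1e-12))

  # rigid translation changes nothing
  ms_shift <- ms
  ms_shift$markers <- lapply(ms$markers, function(m) {
    out <- sweep(m, 2L, c(-3, 11, 0))   # x - (-3) etc. keeps z for heights
    colnames(out) <- c("x", "y", "z"); out
  })
  ser2 <- per_step_metrics(ms_shift, detect_stance_events(ms_shift), sub)
  for (col in c("step_length", "step_width", "com_speed", "leg_angle",
                "virtual_leg_length", "retraction_rate",
                "fwd_foot_speed_froude")) {
    expect_equal(ser2[[col]], ser[[col]], tolerance = 1e-8)
  }
})

test_that("step width doubles the heel-to-CoM-line distance and Froude speeds normalize", {
  # CoM straight along y at x = 0, stance heel at x = +0.02: width 0.04
  t <- seq(0, 2, by = 1 / 300)
  n <- length(t)
  heel <- cbind(rep(0.02, n), rep(1.0, n), rep(0.03, n))
  heel[t < 0.5, 2L] <- 3 * (t[t < 0.5] - 0.5) + 1
  heel[t < 0.5, 3L] <- 0.2
  heel[t > 1.0, 2L] <- 1.0 + 3 * (t[t > 1.0] - 1.0)
  heel[t > 1.0, 3L] <- 0.2
  # second stance so one full step exists
  heel[t > 1.4, 2L] <- 2.2
  heel[t > 1.4, 3L] <- 0.03
  com <- cbind(0, 1.5 * t, 1.05)
  ms <- synthetic_marker_set(t, heel, com, 300)
  ev <- detect_stance_events(ms)
  expect_gte(nrow(ev), 2L)
  # two stances only: too short for a meander estimate, which warns
  expect_warning(
    ser <- per_step_metrics(ms, ev, subject_params(leg_length = 0.89)),
    "meander"
  )
  expect_equal(ser$step_width[1L], 0.04, tolerance = 1e-6)
})

test_that("a CoM speed of sqrt(g l) is Froude speed one in the summary", {
  sqrtgl <- sqrt(9.81 * 0.89)
  ser <- data.frame(
    step = 1:3, t_td = (0:2) * 0.36, t_lo = (0:2) * 0.36 + 0.2,
    direction = 1, step_length = sqrtgl * 0.36, step_duration = 0.36,
    com_speed = sqrtgl, step_width = 0.04,
    virtual_leg_length = 1.07, leg_angle = 0.2,
    heel_x = 0, heel_y = 1, heel_z = 0.03,
    v_heel_x = 0, v_heel_y = 1, v_heel_z = -0.4,
    v_com_x = 0, v_com_y = sqrtgl, v_com_z = -0.7,
    retraction_rate = 1.8, fwd_foot_speed = 1,
    fwd_foot_speed_froude = 0.34, is_turn = FALSE
  )
  class(ser) <- c("step_series", "data.frame")
  out <- trial_summary(ser, subject_params(leg_length = 0.89, g = 9.81))
  expect_equal(out$mean[out$measure == "com_speed" & out$unit == "froude"], 1)
})

test_that("trial summaries match a hand-computed five-step fixture", {
  lens <- c(1.10, 1.14, 1.18, 1.12, 1.16)
  ser <- data.frame(
    step = 1:5, t_td = (0:4) * 0.36, t_lo = (0:4) * 0.36 + 0.2,
    direction = 1, step_length = lens, step_duration = 0.36,
    com_speed = lens / 0.36, step_width = 0.04,
    virtual_leg_length = 1.07, leg_angle = 0.2,
    heel_x = 0, heel_y = 1, heel_z = 0.03,
    v_heel_x = 0, v_heel_y = 1, v_heel_z = -0.4,
    v_com_x = 0, v_com_y = 3.2, v_com_z = -0.7,
    retraction_rate = 1.8, fwd_foot_speed = 1,
    fwd_foot_speed_froude = 0.34, is_turn = FALSE
  )
  class(ser) <- c("step_series", "data.frame")
  out <- trial_summary(ser, subject_params(leg_length = 0.89))
  row <- out[out$measure == "step_length" & out$unit == "m", ]
  expect_equal(row$mean, mean(lens))
  expect_equal(row$sd, sd(lens))
  expect_equal(row$median, 1.14)
  expect_equal(row$iqr, unname(diff(quantile(lens, c(0.25, 0.75)))))
  pct <- out[out$measure == "step_length" & out$unit == "%LL", ]
  expect_equal(pct$mean, mean(lens) / 0.89 * 100)

  # identical steps: zero spread everywhere
  ser0 <- ser; ser0$step_length <- 1.14; ser0$com_speed <- 1.14 / 0.36
  out0 <- trial_summary(ser0, subject_params())
  expect_true(all(out0$sd[out0$measure == "step_length"] == 0))
  # step lengths of 1.14 m at l = 0.89 m: 128 %LL as reported
  expect_equal(out0$mean[out0$measure == "step_length" &
                           out0$unit == "%LL"], 128.1, tolerance = 1e-3)
})
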