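test_that("parameter validation names the offending field", {
  expect_error(gait_sim_params(cadence = -5), "cadence", class = "trunkgait_param_error")
  expect_error(gait_sim_params(n_strides = 2), "n_strides", class = "trunkgait_param_error")
  expect_error(
    gait_sim_params(stance_fraction_left = 0.4),
    "stance_fraction_left",
    class = "trunkgait_param_error"
  )
  expect_error(gait_sim_params(noise_sd = -1), "noise_sd", class = "trunkgait_param_error")
  expect_error(gait_sim_params(sampling_rate = 20), "sampling_rate", class = "trunkgait_param_error")
  # double support must be resolvable: high cadence + stance barely above 0.5
  expect_error(
    gait_sim_params(cadence = 120, stance_fraction_left = 0.51),
    "double-support",
    class = "trunkgait_param_error"
  )
})

test_that("identical (params, seed) reproduce the identical trial", {
  p <- gait_sim_params(n_strides = 5, noise_sd = 0.1, timing_jitter_sd = 0.01)
  t1 <- simulate_trunk_signal(p, seed = 11)
  t2 <- simulate_trunk_signal(p, seed = 11)
  expect_identical(t1$signal, t2$signal)
  expect_identical(t1$truth$events, t2$truth$events)
  t3 <- simulate_trunk_signal(p, seed = 12)
  expect_false(identical(t1$signal$ap, t3$signal$ap))
})

test_that("ground truth passes the injected stance fraction through exactly", {
  tr <- quick_trial(stance_fraction_left = 0.6, stance_fraction_right = 0.6)
  expect_equal(unname(tr$truth$stance_fraction), c(0.6, 0.6))
  expect_true(all(tr$truth$cycles$stance_fraction == 0.6))
})

test_that("event span matches cadence (duration = steps / cadence-per-second)", {
  # 2 * 10 strides = 20 steps at 90 steps/min -> 13.33 s between first and
  # last initial contact
  tr <- simulate_trunk_signal(gait_sim_params(cadence = 90, n_strides = 10), seed = 1)
  ics <- truth_ics(tr)
  expect_equal(max(ics$time) - min(ics$time), 20 / (90 / 60), tolerance = 1e-9)
  # duration scales with jitter only
  trj <- simulate_trunk_signal(
    gait_sim_params(cadence = 90, n_strides = 10, timing_jitter_sd = 0.01),
    seed = 1
  )
  icsj <- truth_ics(trj)
  expect_equal(max(icsj$time) - min(icsj$time), 13.333, tolerance = 0.05)
})

test_that("symmetric parameters give identical left and right cycle templates", {
  p <- gait_sim_params(
    noise_sd = 0, amplitude_asym = 1,
    stance_fraction_left = 0.62, stance_fraction_right = 0.62
  )
  left <- trunk_cycle_template(p, "left")
  right <- trunk_cycle_template(p, "right")
  expect_equal(left, right, tolerance = 1e-12)
})

test_that("ground-truth events lie inside the signal span and alternate limbs", {
  for (seed in 1:5) {
    tr <- simulate_trunk_signal(
      gait_sim_params(n_strides = 5, timing_jitter_sd = 0.01, noise_sd = 0.1),
      seed = seed
    )
    ics <- truth_ics(tr)
    expect_true(all(ics$time >= min(tr$signal$time)))
    expect_true(all(ics$time <= max(tr$signal$time)))
    expect_true(all(ics$limb[-1] != ics$limb[-nrow(ics)]))
    # toe-offs and single-support bounds are ordered within each cycle
    cy <- tr$truth$cycles
    expect_true(all(cy$ic_time < cy$sss_time))
    expect_true(all(cy$sss_time < cy$sse_time))
    expect_true(all(cy$sse_time < cy$next_ic_time))
    expect_true(all(cy$toe_off_time > cy$sse_time))
  }
})

test_that("the contact transient is a sharp positive AP peak at each contact", {
  tr <- quick_trial()
  ics <- truth_ics(tr)
  fs <- sampling_rate(tr$signal)
  for (t0 in ics$time[2:4]) {
    win <- which(tr$signal$time >= t0 & tr$signal$time <= t0 + 0.1)
    expect_gt(max(tr$signal$ap[win]), 1.5)
  }
})

test_that("amplitude asymmetry scales only the left limb's waveform", {
  p1 <- gait_sim_params(amplitude_asym = 1)
  p2 <- gait_sim_params(amplitude_asym = 0.5)
  right1 <- trunk_cycle_template(p1, "right")
  right2 <- trunk_cycle_template(p2, "right")
  left1 <- trunk_cycle_template(p1, "left")
  left2 <- trunk_cycle_template(p2, "left")
  # compare the limb's own contact transient (first 10% of its cycle): the
  # right limb keeps its amplitude, the left transient is halved
  own <- 1:11
  expect_equal(max(right2[own]), max(right1[own]), tolerance = 1e-9)
  expect_equal(max(left2[own]), max(left1[own]) / 2, tolerance = 0.05)
})
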