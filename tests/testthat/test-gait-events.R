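test_that("noise-free contacts are recovered within one sample across the grid", {
  for (cad in c(60, 100, 120)) {
    for (f in c(0.55, 0.70)) {
      tr <- simulate_trunk_signal(
        gait_sim_params(
          cadence = cad, n_strides = 6,
          stance_fraction_left = f, stance_fraction_right = f
        ),
        seed = 42
      )
      expect_lte(max_ic_error_samples(tr), 1 + 1e-9)
      ev <- detect_initial_contacts(tr$signal)
      expect_identical(ev$limb, truth_ics(tr)$limb)
    }
  }
})

test_that("degenerate signals raise a no-gait error", {
  t <- seq(0, 10, by = 0.01)
  flat <- trunk_signal(t, rep(0, length(t)))
  expect_error(detect_initial_contacts(flat), "no gait", class = "trunkgait_no_gait_error")
  # pure noise, no gait structure
  noise <- trunk_signal(t, rnorm(length(t), 0, 0.01))
  expect_error(
    suppressWarnings(detect_initial_contacts(noise)),
    class = "trunkgait_error"
  )
})

test_that("noisy detection keeps 95% of contacts within three samples", {
  hits <- 0L
  total <- 0L
  for (seed in 1:3) {
    # noise at 10% of the transient peak amplitude
    tr <- simulate_trunk_signal(
      gait_sim_params(cadence = 100, n_strides = 20, noise_sd = 0.2),
      seed = seed
    )
    ev <- suppressWarnings(detect_initial_contacts(tr$signal))
    tru <- truth_ics(tr)
    errs <- vapply(tru$time, function(t) min(abs(ev$time - t)), numeric(1)) *
      sampling_rate(tr$signal)
    hits <- hits + sum(errs <= 3)
    total <- total + length(errs)
  }
  expect_gte(hits / total, 0.95)
})

test_that("detection is invariant to time translation and AP offset", {
  tr <- quick_trial()
  ev1 <- detect_initial_contacts(tr$signal)
  shifted <- trunk_signal(
    tr$signal$time + 5, tr$signal$ap,
    tr$signal$vertical, tr$signal$mediolateral
  )
  ev2 <- detect_initial_contacts(shifted)
  expect_equal(ev2$index, ev1$index)
  expect_equal(ev2$time, ev1$time + 5)
  offset <- trunk_signal(
    tr$signal$time, tr$signal$ap + 3.7,
    tr$signal$vertical, tr$signal$mediolateral
  )
  ev3 <- detect_initial_contacts(offset)
  expect_identical(ev3$index, ev1$index)
})

test_that("cycle segmentation counts and splits are right", {
  tr <- quick_trial(stance_fraction_left = 0.6, stance_fraction_right = 0.6)
  ev <- detect_initial_contacts(tr$signal)
  cy <- segment_cycles(ev, tr$signal)
  # stance recovered near the injected 60%, exact complement
  expect_true(all(abs(cy$stance_pct - 60) <= 2))
  expect_true(all(cy$stance_pct + cy$swing_pct == 100))
  # exactly periodic events -> all cycles the same length
  expect_equal(length(unique(cy$next_ic_idx - cy$ic_idx)), 1L)
  # three events (L, R, L) -> exactly one left cycle
  cy3 <- segment_cycles(ev[1:3, ], tr$signal)
  expect_identical(nrow(cy3), 1L)
  expect_identical(cy3$limb, ev$limb[1])
  # non-alternating labels are an event-ordering error
  bad <- ev[c(1, 3, 5), ]
  expect_error(segment_cycles(bad, tr$signal), class = "trunkgait_event_error")
  expect_error(
    segment_cycles(ev[1:2, ], tr$signal),
    class = "trunkgait_insufficient_cycles_error"
  )
})

test_that("single support is located against ground truth on clean trials", {
  tr <- quick_trial(stance_fraction_left = 0.62, stance_fraction_right = 0.62)
  ev <- detect_initial_contacts(tr$signal)
  cy <- segment_cycles(ev, tr$signal)
  fs <- sampling_rate(tr$signal)
  tru <- tr$truth$cycles
  for (k in seq_len(min(4, nrow(cy)))) {
    ss <- locate_single_support(cy[k, ], tr$signal)
    # match to the ground-truth cycle starting at the same contact
    j <- which.min(abs(tru$ic_time - tr$signal$time[cy$ic_idx[k]]))
    expect_lte(abs(tr$signal$time[ss[1]] - tru$sss_time[j]) * fs, 1.5)
    expect_lte(abs(tr$signal$time[ss[2]] - tru$sse_time[j]) * fs, 1.5)
    expect_true(ss[1] > cy$ic_idx[k] && ss[1] < ss[2] && ss[2] < cy$next_ic_idx[k])
  }
  # symmetric gait: equal single-support durations, within a sample
  dur <- tapply(cy$sse_idx - cy$sss_idx, cy$limb, function(x) mean(x))
  expect_lte(abs(diff(dur)), 1)
  # missing opposite-limb events are an error
  expect_error(
    locate_single_support(list(ic_idx = 5, opp_ic_idx = NA, next_ic_idx = 50), tr$signal),
    class = "trunkgait_event_error"
  )
})

test_that("normalization averages cycles and matches the analytic template", {
  # 200 Hz keeps the linear-interpolation error of the sharp contact
  # transient below the 2%-of-peak band being checked
  p <- gait_sim_params(
    n_strides = 6, stance_fraction_left = 0.62,
    stance_fraction_right = 0.62, sampling_rate = 200
  )
  tr <- simulate_trunk_signal(p, seed = 42)
  ev <- detect_initial_contacts(tr$signal)
  cy <- segment_cycles(ev, tr$signal)
  mcs <- normalize_and_average(cy, tr$signal)
  expect_length(mcs$left$ap_norm, 101)
  expect_equal(mcs$left$ap_mean, mean(mcs$left$ap_norm), tolerance = 1e-12)
  # mean of one cycle equals that cycle resampled
  one <- normalize_and_average(cy[1, ], tr$signal)[[1]]
  seg <- cy$ic_idx[1]:cy$next_ic_idx[1]
  direct <- approx(tr$signal$time[seg], tr$signal$ap[seg],
    xout = seq(tr$signal$time[cy$ic_idx[1]], tr$signal$time[cy$next_ic_idx[1]],
      length.out = 101
    )
  )$y
  expect_equal(one$ap_norm, direct, tolerance = 1e-12)
  # two identical cycles average to either one
  two <- normalize_and_average(cy[c(1, 1), ], tr$signal)[[1]]
  expect_equal(two$ap_norm, one$ap_norm, tolerance = 1e-12)
  # noise-free mean cycle matches the closed-form template to < 2% of peak
  # (edge cycles adjoin the lead-in/lead-out padding and are skipped)
  interior <- cy[-c(1, 2), ]
  mci <- normalize_and_average(interior, tr$signal)
  templ <- trunk_cycle_template(p, "left")
  err <- max(abs(mci$left$ap_norm - templ))
  expect_lt(err, 0.02 * max(abs(templ)))
})

test_that("spatiotemporal parameters follow their definitions", {
  tr <- simulate_trunk_signal(gait_sim_params(cadence = 90, n_strides = 8), seed = 1)
  ev <- detect_initial_contacts(tr$signal)
  st <- spatiotemporal(ev, c(left = 1.32, right = 1.32))
  expect_equal(st$cadence, 90, tolerance = 0.02)
  # v = stride * cadence / 120; 1.32 m at 90 steps/min -> 0.99 m/s
  expect_equal(st$velocity, 1.32 * st$cadence / 120, tolerance = 1e-12)
  expect_equal(st$velocity, 0.99, tolerance = 0.02)
  expect_equal(st$walk_distance_2min, st$velocity * 120, tolerance = 1e-12)
  expect_error(spatiotemporal(ev, NULL), class = "trunkgait_stride_error")
  expect_error(spatiotemporal(ev[1:4, ], c(left = 1, right = 1)),
    class = "trunkgait_insufficient_cycles_error"
  )
})

test_that("stance recovery holds over a seeded noise-free parameter batch", {
  # 50 trials spanning cadence 60-120 and stance 0.55-0.70
  set.seed(7)
  cads <- runif(50, 60, 120)
  fs <- runif(50, 0.55, 0.70)
  ok <- 0L
  for (i in 1:50) {
    tr <- simulate_trunk_signal(
      gait_sim_params(
        cadence = cads[i], n_strides = 5,
        stance_fraction_left = fs[i], stance_fraction_right = fs[i]
      ),
      seed = i
    )
    ev <- detect_initial_contacts(tr$signal)
    cy <- segment_cycles(ev, tr$signal)
    mcs <- normalize_and_average(cy, tr$signal)
    st <- c(mcs$left$stance_pct, mcs$right$stance_pct)
    if (all(abs(st - fs[i] * 100) <= 2)) ok <- ok + 1L
  }
  expect_identical(ok, 50L)
})
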