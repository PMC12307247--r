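test_that("symmetry index maps correlation extremes and midpoint exactly", {
  x <- sin(seq(0, 2 * pi, length.out = 101))
  expect_identical(symmetry_index(x, x), 100)
  expect_identical(symmetry_index(x, -x), 0)
  # orthogonal de-meaned signals -> r = 0 -> 50
  a <- rep(c(1, -1), 50)
  b <- rep(c(1, 1, -1, -1), 25)
  stopifnot(abs(sum(a * b)) < 1e-12)
  expect_equal(symmetry_index(a[1:100], b[1:100]), 50)
  expect_error(symmetry_index(rep(1, 10), rnorm(10)), class = "trunkgait_degenerate_error")
  expect_error(symmetry_index(1:5, 1:6), class = "trunkgait_param_error")
})

test_that("symmetry index equals the brute-force Pearson sum formula", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(symmetry_index(x, y), (pearson_sums(x, y) + 1) * 50,
      tolerance = 1e-10
    )
  }
})

test_that("symmetry index is invariant under positive affine maps, flips sign scale", {
  set.seed(5)
  x <- rnorm(101)
  y <- rnorm(101)
  si <- symmetry_index(x, y)
  expect_equal(symmetry_index(2.5 * x + 3, y), si, tolerance = 1e-10)
  expect_equal(symmetry_index(x, 0.1 * y - 7), si, tolerance = 1e-10)
  expect_equal(symmetry_index(-x, y), 100 - si, tolerance = 1e-10)
})

test_that("increasing timing asymmetry monotonically degrades symmetry", {
  # ladder spans the monotone regime; at much larger shifts waveform features
  # start re-aligning and the correlation recovers slightly
  offsets <- seq(0, 0.05, length.out = 10)
  si_templ <- vapply(offsets, function(off) {
    p <- gait_sim_params(n_strides = 6, timing_offset = off)
    symmetry_index(trunk_cycle_template(p, "left"), trunk_cycle_template(p, "right"))
  }, numeric(1))
  expect_true(all(diff(si_templ) <= 1e-9))
  si <- vapply(offsets, function(off) {
    # 200 Hz keeps event quantization well below the ladder step
    tr <- simulate_trunk_signal(
      gait_sim_params(n_strides = 6, timing_offset = off, sampling_rate = 200),
      seed = 99
    )
    ev <- detect_initial_contacts(tr$signal)
    cy <- segment_cycles(ev, tr$signal)
    mcs <- normalize_and_average(cy, tr$signal)
    symmetry_index(mcs$left, mcs$right)
  }, numeric(1))
  expect_true(all(diff(si) <= 0))
  expect_lt(si[10], si[1] - 5)
})

test_that("propulsion index evaluates the arctangent gradient", {
  expect_equal(propulsion_index(single_support_phase(0.2, 0.2, 0, 0.4)), 0)
  expect_equal(propulsion_index(single_support_phase(0, 0.4, 0, 0.4)), 45)
  # 0.04 m/s^2 over 0.40 s: atan(0.1) = 5.71 deg, above the 5.5 deg optimum
  expect_equal(propulsion_index(single_support_phase(0, 0.04, 0, 0.4)),
    atan(0.1) * 180 / pi,
    tolerance = 1e-12
  )
  expect_gt(propulsion_index(single_support_phase(0, 0.04, 0, 0.4)), 5.5)
  # sign preserved; g units divide the acceleration difference
  expect_lt(propulsion_index(single_support_phase(0.1, 0.05, 0, 0.5)), 0)
  expect_equal(
    propulsion_index(single_support_phase(0, 9.80665, 0, 1), units = "g"),
    45
  )
  expect_error(single_support_phase(0, 1, 0.5, 0.5), class = "trunkgait_phase_error")
})

test_that("propulsion slope is recovered within half a degree on clean trials", {
  for (slope in c(0.06, 0.10, 0.16)) {
    tr <- simulate_trunk_signal(
      gait_sim_params(
        n_strides = 6,
        single_support_slope_left = slope,
        single_support_slope_right = slope
      ),
      seed = 21
    )
    ev <- detect_initial_contacts(tr$signal)
    cy <- segment_cycles(ev, tr$signal)
    mcs <- normalize_and_average(cy, tr$signal)
    for (l in c("left", "right")) {
      got <- propulsion_index(single_support_phase_from_mean_cycle(mcs[[l]]))
      expect_lt(abs(got - atan(slope) * 180 / pi), 0.5)
    }
  }
})

test_that("quality index follows the absolute-value formula", {
  expect_identical(quality_index(60, 40), 100)
  expect_identical(quality_index(70, 30), 80)
  expect_identical(quality_index(50, 50), 80)
  expect_error(quality_index(60, 35), class = "trunkgait_consistency_error")
  # closed form: q(s, 100 - s) = 100 - |2 s - 120| over a grid
  for (s in seq(10, 110, by = 2.5)) {
    expect_equal(quality_index(s, 100 - s), 100 - abs(2 * s - 120))
  }
})

test_that("body-weight distribution is the absolute percentage difference", {
  expect_identical(bwd(50, 50), 0)
  expect_identical(bwd(60, 40), 20)
  expect_identical(bwd(100, 0), 100)
  expect_error(bwd(60, 35), class = "trunkgait_consistency_error")
})
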