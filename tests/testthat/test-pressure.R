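test_that("pressure simulation conserves load and respects the split", {
  s <- simulate_pressure_sequence(
    stance_sim_params(weight_split_left = 0.5, duration = 1, body_weight = 700),
    seed = 1
  )
  n <- dim(s$frames)[1]
  expect_identical(n, 40L)
  totals <- vapply(seq_len(n), function(i) sum(s$frames[i, , ]), numeric(1))
  expect_equal(totals, rep(700, n), tolerance = 1e-9)
  m <- attr(s, "masks")
  lsum <- vapply(seq_len(n), function(i) sum(s$frames[i, , ][m$left]), numeric(1))
  rsum <- vapply(seq_len(n), function(i) sum(s$frames[i, , ][m$right]), numeric(1))
  # balanced noise-free split: per-frame equality
  expect_equal(lsum, rsum, tolerance = 1e-9)
  expect_true(all(s$frames >= 0))
  # all load on the left: right region exactly empty
  s1 <- simulate_pressure_sequence(
    stance_sim_params(weight_split_left = 1, duration = 0.5),
    seed = 1
  )
  m1 <- attr(s1, "masks")
  expect_equal(sum(vapply(
    seq_len(dim(s1$frames)[1]),
    function(i) sum(s1$frames[i, , ][m1$right]), numeric(1)
  )), 0)
})

test_that("noisy split is recovered within 0.01 by frame averaging", {
  s <- simulate_pressure_sequence(
    stance_sim_params(weight_split_left = 0.6, pressure_noise_sd = 0.02),
    seed = 3
  )
  expect_identical(dim(s$frames)[1], 2400L)
  wd <- weight_distribution(s, segment_feet(s))
  expect_lt(abs(wd[["left_pct"]] / 100 - 0.6), 0.01)
})

test_that("segmentation recovers the generator's foot masks", {
  s <- simulate_pressure_sequence(
    stance_sim_params(weight_split_left = 0.55, duration = 1),
    seed = 2
  )
  r <- segment_feet(s)
  m <- attr(s, "masks")
  expect_identical(r$left, m$left)
  expect_identical(r$right, m$right)
  expect_false(any(r$left & r$right))
})

test_that("a single blob cannot be segmented", {
  arr <- array(0, dim = c(5, 20, 20))
  arr[, 8:12, 8:12] <- 1
  expect_error(segment_feet(pressure_sequence(arr)), class = "trunkgait_segmentation_error")
  empty <- array(0, dim = c(5, 20, 20))
  expect_error(segment_feet(pressure_sequence(empty)), class = "trunkgait_no_load_error")
})

test_that("mirroring swaps sides but leaves the loads unchanged", {
  s <- simulate_pressure_sequence(
    stance_sim_params(weight_split_left = 0.7, duration = 1),
    seed = 4
  )
  wd <- weight_distribution(s, segment_feet(s))
  mirrored <- pressure_sequence(
    s$frames[, , rev(seq_len(dim(s$frames)[3]))],
    frame_rate = s$frame_rate
  )
  wdm <- weight_distribution(mirrored, segment_feet(mirrored))
  expect_equal(wdm[["left_pct"]], wd[["right_pct"]], tolerance = 1e-9)
  expect_equal(wdm[["right_pct"]], wd[["left_pct"]], tolerance = 1e-9)
})

test_that("weight percentages sum to 100 and are scale invariant", {
  s <- simulate_pressure_sequence(
    stance_sim_params(weight_split_left = 0.63, pressure_noise_sd = 0.05, duration = 5),
    seed = 5
  )
  r <- segment_feet(s)
  wd <- weight_distribution(s, r)
  expect_identical(unname(wd[1] + wd[2]), 100)
  scaled <- pressure_sequence(s$frames * 37.5, frame_rate = s$frame_rate)
  expect_equal(weight_distribution(scaled, r), wd, tolerance = 1e-12)
  # recovery within 1 percentage point at 5% sway noise over 60 s x 40 fps
  s60 <- simulate_pressure_sequence(
    stance_sim_params(weight_split_left = 0.63, pressure_noise_sd = 0.05),
    seed = 6
  )
  wd60 <- weight_distribution(s60, segment_feet(s60))
  expect_lt(abs(wd60[["left_pct"]] - 63), 1)
})

test_that("pressure sequences round-trip through per-frame CSV", {
  s <- simulate_pressure_sequence(
    stance_sim_params(weight_split_left = 0.58, duration = 0.25),
    seed = 7
  )
  dir <- tempfile("pressure")
  write_pressure_csv(s, dir)
  s2 <- read_pressure_csv(dir)
  expect_equal(s2$frames, s$frames, tolerance = 1e-12)
  expect_equal(s2$frame_rate, s$frame_rate)
  unlink(dir, recursive = TRUE)
})
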