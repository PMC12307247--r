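test_that("group summaries report mean and sample SD per variable", {
  df <- data.frame(
    group = c("AK", "AK", "BK", "BK", "BK"),
    symmetry_index = c(60, 80, 70, 70, 70),
    cadence = c(80, 90, 85, 95, 90)
  )
  s <- summarize_groups(df)
  expect_equal(s$mean_AK[s$variable == "symmetry_index"], 70)
  expect_equal(s$sd_AK[s$variable == "symmetry_index"], sd(c(60, 80)))
  expect_equal(s$sd_AK[s$variable == "symmetry_index"], 14.14, tolerance = 1e-3)
  expect_equal(s$sd_BK[s$variable == "symmetry_index"], 0)
  expect_identical(unname(c(attr(s, "n"))), c(2L, 3L))
  expect_error(
    summarize_groups(data.frame(group = c("AK", "BK"), x = 1:2)),
    class = "trunkgait_insufficient_sample_error"
  )
})

test_that("the normality gate deterministically selects the test", {
  set.seed(42)
  x <- rnorm(14)
  y <- rnorm(15)
  r <- compare_groups(x, y)
  expect_identical(
    r$test_used,
    if (all(r$normality_p >= 0.05)) "student_t" else "wilcoxon"
  )
  # heavily skewed group -> Shapiro-Wilk rejects -> rank-sum test
  skew <- exp(rnorm(15, 0, 1.5))
  r2 <- compare_groups(x, skew)
  expect_identical(r2$test_used, "wilcoxon")
  expect_true(r2$normality_p[2] < 0.05)
  # identical groups under the t test: p = 1
  z <- c(1.2, 3.4, 2.2, 4.8, 2.9, 3.3, 1.9)
  r3 <- compare_groups(z, z)
  expect_identical(r3$test_used, "student_t")
  expect_equal(r3$p_value, 1)
  expect_error(compare_groups(1:2, 1:10), class = "trunkgait_insufficient_sample_error")
})

test_that("two well-behaved normal samples usually take the t branch with sane p", {
  set.seed(8)
  picks <- replicate(20, {
    r <- compare_groups(rnorm(100), rnorm(100))
    c(t_branch = r$test_used == "student_t", sane = r$p_value > 0.001)
  })
  # the Shapiro-Wilk gate itself has a ~5% false-rejection rate per group
  expect_gte(mean(picks["t_branch", ]), 0.8)
  expect_true(all(picks["sane", ] | !picks["t_branch", ]))
})

test_that("null rejection rate is calibrated near the nominal alpha", {
  set.seed(11)
  rej <- 0L
  n_sim <- 500L
  for (i in seq_len(n_sim)) {
    r <- compare_groups(rnorm(14), rnorm(15))
    if (r$p_value < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("a symmetry-index difference of the reported size is usually detected", {
  # group means/SDs 63.5 (14.7) vs 81.7 (15.1) at n = 14/15
  set.seed(13)
  sig <- vapply(1:200, function(i) {
    compare_groups(rnorm(14, 63.5, 14.7), rnorm(15, 81.7, 15.1))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(sig), 0.5)
})

test_that("comparison tables cover the report variables for two groups", {
  set.seed(3)
  df <- data.frame(
    group = rep(c("AK", "BK"), c(8, 9)),
    symmetry_index = c(rnorm(8, 64, 10), rnorm(9, 82, 10)),
    bwd_pct = c(rnorm(8, 35, 10), rnorm(9, 23, 10))
  )
  tab <- compare_all_variables(df)
  expect_setequal(tab$variable, c("symmetry_index", "bwd_pct"))
  expect_true(all(tab$test_used %in% c("student_t", "wilcoxon")))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})
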