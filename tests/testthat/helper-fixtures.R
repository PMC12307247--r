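# Shared fixtures, built in code at test time.

quick_trial <- function(seed = 42, ...) {
  simulate_trunk_signal(gait_sim_params(n_strides = 6, ...), seed = seed)
}

truth_ics <- function(trial) {
  trial$truth$events[trial$truth$events$type == "initial_contact", ]
}

max_ic_error_samples <- function(trial) {
  ev <- detect_initial_contacts(trial$signal)
  tr <- truth_ics(trial)
  expect_equal(nrow(ev), nrow(tr))
  max(vapply(tr$time, function(t) min(abs(ev$time - t)), numeric(1))) *
    sampling_rate(trial$signal)
}

# brute-force Pearson correlation via the explicit sum formula (independent
# oracle for the symmetry index)
pearson_sums <- function(x, y) {
  n <- length(x)
  sx <- sum(x)
  sy <- sum(y)
  sxy <- sum(x * y)
  sxx <- sum(x^2)
  syy <- sum(y^2)
  (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}
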