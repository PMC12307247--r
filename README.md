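# trunkgait

Gait and standing-balance analysis for lower-limb amputees from two simple
instruments: a single trunk-mounted (S1) triaxial accelerometer recorded
during walking, and a baropodometric platform (48 × 48 pressure cells,
40 frames/s) recorded during 60 s of quiet standing. The package turns those
raw signals into the quantities clinicians use to characterize amputee gait —
per-limb gait cycles, symmetry, propulsion and quality indices, body-weight
distribution, and spatiotemporal parameters — and compares them between
above-knee (AK) and below-knee (BK) amputation groups with a normality-gated
two-sample test.

## What it computes

From the anteroposterior (AP) trunk acceleration of a walking trial, the
pipeline detects initial contacts, labels limbs from the mediolateral
channel, segments per-limb gait cycles, and time-normalizes each cycle to
0–100% before averaging. On the per-limb mean cycles
`APs` (sound) and `APa` (amputated) it evaluates:

- **Symmetry index (%)** — the Pearson correlation r between the two limbs'
  mean normalized AP cycles, mapped to 0–100 as `(r + 1) × 100 / 2`.
  Identical waveforms score 100; 75–100 is read as high symmetry.
- **Propulsion index (°)** — per limb, `atan(Δa / Δt)` in degrees, where `Δa`
  is the AP acceleration change between the start and end of the limb's
  single-support phase and `Δt` its duration in seconds; values above 5.5°
  are considered optimal.
- **Quality index (%)** — per limb, `||(D̄stance − D̄swing) − 20| − 100|` with
  the mean stance/swing durations in % of the gait cycle; exactly 100 at the
  ideal 60/40 split.
- **BWD (%)** — from the standing pressure frames: per-foot summed load,
  averaged over frames and expressed as percentages; BWD is the absolute
  difference between the sound- and amputated-limb percentages (0% is ideal).
- **Spatiotemporal parameters** — cadence (steps/min) from the event series;
  velocity as `stride × cadence / 120` with stride length supplied as
  metadata (a single trunk accelerometer cannot measure it); projected
  two-minute walk distance as `velocity × 120`.

Because no recordings ship with the package, a first-class synthetic module
generates walking trials and standing-pressure sequences with exact ground
truth (`simulate_trunk_signal()`, `simulate_pressure_sequence()`,
`simulate_cohort()`), so every stage is testable by parameter recovery.

## Worked example

Simulate an asymmetric below-knee subject (left side amputated) and run the
full pipeline:

```r
library(trunkgait)

params <- gait_sim_params(
  cadence = 90, n_strides = 20,
  stance_fraction_left = 0.64, stance_fraction_right = 0.68,
  single_support_slope_left = 0.11, single_support_slope_right = 0.07,
  amplitude_asym = 0.85, noise_sd = 0.05, timing_offset = 0.03,
  stride_length_left = 1.35, stride_length_right = 1.35
)
trial <- simulate_trunk_signal(params, seed = 42)
trial$signal
#> <trunk_signal> 2817 samples @ 100 Hz (28.17 s)
#>   AP range [-0.17, 2.07] m/s^2

pressure <- simulate_pressure_sequence(
  stance_sim_params(weight_split_left = 0.41, pressure_noise_sd = 0.03),
  seed = 43
)
result <- run_subject(
  trial, pressure,
  metadata = list(
    subject_id = "demo", group = "BK", amputated_side = "left",
    stride_length = c(left = 1.35, right = 1.35)
  )
)
round(t(result[, c("symmetry_index", "propulsion_amputated", "propulsion_sound",
  "quality_amputated", "quality_sound", "bwd_pct", "cadence", "velocity",
  "walk_distance_2min")]), 2)
#> symmetry_index        70.11
#> propulsion_amputated   6.31
#> propulsion_sound       5.33
#> quality_amputated     91.51
#> quality_sound         80.63
#> bwd_pct               17.99
#> cadence               90.02
#> velocity               1.01
#> walk_distance_2min   121.53
```

Reading the numbers: the symmetry index of 70 sits below the 75% high-symmetry
band, reflecting the injected timing and amplitude asymmetry between the
limbs. The amputated limb's propulsion (6.31°) recovers the injected
single-support slope (`atan(0.11) = 6.28°`) and clears the 5.5° optimum. The
quality indices translate the injected stance fractions (64% amputated, 68%
sound) into deviations from the ideal 60/40 split, and the BWD of 18%
recovers the simulated standing split (41% of body weight on the amputated
side). Cadence is recovered from the signal; velocity follows from the
supplied 1.35 m stride.

Cohort-level analysis mirrors a two-group study:

```r
cohort <- simulate_cohort(cohort_spec(n_ak = 14, n_bk = 15, seed = 11))
report <- run_cohort(cohort, out_dir = "reports")
report$comparisons[, c("variable", "test_used", "p_value")]
```

which runs Shapiro–Wilk normality checks per group and variable, then a
Welch t test (both groups normal) or a Wilcoxon rank-sum test otherwise, at
α = 0.05.

A thin command-line wrapper with `simulate`, `analyze` and `cohort`
subcommands is installed at `inst/scripts/trunkgait-cli.R`.

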