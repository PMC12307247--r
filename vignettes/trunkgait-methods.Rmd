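---
title: "Methods: trunk-accelerometry gait indices and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trunk-accelerometry gait indices and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunkgait)
```

## The measurement model

A single inertial sensor at the S1 vertebra observes the trunk's
anteroposterior (AP), vertical and mediolateral acceleration while the
subject walks. The AP channel carries the gait structure this package
exploits:

- a sharp positive transient at each **initial contact** (the impact of the
  landing foot propagates to the trunk);
- a deceleration after weight acceptance, reaching its minimum when the
  opposite limb leaves the ground (**toe-off**, which by definition starts
  the stance limb's **single support**);
- an approximately linear AP acceleration rise during single support, as the
  body pivots over the stance foot and the subject pushes the centre of mass
  forward — the slope of this ramp is what the propulsion index measures;
- an oscillation during swing as the contralateral limb advances.

All indices are evaluated on per-limb **mean normalized cycles**: every
complete cycle (initial contact to next ipsilateral initial contact) is
resampled by linear interpolation to `P = 101` points over 0–100% of its own
duration — the conventional grid in gait analysis, with 1% resolution and a
point at every integer percentage — and averaged pointwise.

The four headline quantities are

* symmetry index `(r + 1) * 100 / 2` with `r` the Pearson correlation of the
  two limbs' mean cycles;
* propulsion index `atan(delta_a / delta_t)` in degrees per limb over the
  single-support phase;
* quality index `||(Dstance - Dswing) - 20| - 100|` per limb (100 at the
  ideal 60/40 stance/swing split);
* body-weight distribution (BWD), the absolute difference of the per-foot
  standing weight percentages.

Two formula-level choices deserve a note. First, the printed form of the
symmetry-index normalization can be read without square roots in the
denominator; this package implements the quantity as the **Pearson
correlation coefficient** (with the square roots), because that is the
statistic named in words wherever the index is described, and it is the form
that guarantees the documented 0–100 range. Second, `atan(delta_a/delta_t)`
mixes units (m/s² over s); the ratio is taken numerically on canonical units
before the arctangent, which reproduces the convention implied by the
published 5.5° optimum, and a `units = "g"` switch expresses `delta_a` in g
for sensors calibrated that way.

## Event detection and phase estimation

No event-detection algorithm is prescribed for this instrument, so the
package uses a standard trunk-accelerometry heuristic with every constant
exposed in `detection_config()`:

1. de-mean the AP channel and band-pass it (default **0.5–20 Hz**). The
   upper edge is chosen above the contact transient's energy band: a 40–80 ms
   transient has content up to ~25 Hz, and cutting at 10 Hz attenuates it
   below the adaptive threshold at cadences above ~90 steps/min.
2. find positive peaks above `k × MAD` of the filtered signal (default
   `k = 3`) with a minimum spacing from a cadence prior
   (`60 / (2 × cadence_max)` s, `cadence_max = 160`);
3. refine each peak to the raw local maximum, discard candidates whose local
   curvature is below 20% of the median peak's (contact transients are orders
   of magnitude sharper than any other positive AP feature, e.g. the
   mid-swing lobe), and enforce step regularity (an event closer than 60% of
   the median step interval to its neighbour is spurious; the sharper of the
   pair is kept);
4. estimate each contact as the **onset** of its transient: the start of the
   contiguous half-maximum run of the second difference behind the peak.
   This rule lands on the sample at (or immediately after) the true onset
   for any sub-sample grid alignment; a plain curvature argmax can drift one
   sample late on wide transients. Onsets whose peak-to-onset offset is an
   outlier (more than 3 samples from the event-wise median) are snapped to
   the median offset — the offset is a property of the transient shape and
   is constant across events;
5. label limbs by the sign of the mediolateral channel just after each
   contact (positive lobe = left, the embedded sign convention); if labels
   fail to alternate, the majority-vote parity is enforced with a warning.

Noise handling is adaptive: the noise level is estimated from the second
difference of the signal (`MAD/sqrt(6)`; smooth gait content has negligible
curvature at the sample scale and the sparse transients are rejected by the
MAD). Clean signals are processed unsmoothed, which keeps every feature
sample-exact; noisy signals are Savitzky–Golay smoothed for curvature
estimation and moving-average smoothed for minimum location — a positive
kernel cannot undershoot after the tall transient, so it never creates a
spurious minimum below a shallow true trough.

With one trunk sensor, toe-off is not directly observable; it is
operationalized through the single-support bracketing itself: toe-off of a
limb *is* the start of the opposite limb's single support, located as the AP
minimum between the two surrounding contacts. Phase percentages used by the
indices are located on the **averaged** cycle rather than averaged over
per-cycle estimates: the minimum of a noisy signal is a biased location
estimator, whereas cycle averaging suppresses uncorrelated noise before the
search. The searches carry physiological priors (double support within
2–30% of the cycle; stance below 88%), with parabolic sub-grid refinement;
ties at a non-convex kink resolve to the earlier grid point.

The propulsion endpoints are read by linear interpolation at the
single-support boundaries pulled inward by a 2%-of-cycle margin
(`phase_margin_pct`), so that the contact transient starting exactly at
single-support end cannot contaminate the endpoint value; both reads remain
on the traced line, leaving the slope unchanged.

Stride length cannot be derived from a single trunk accelerometer without an
inverted-pendulum model that is out of scope here; it enters as metadata (or
simulator ground truth) and velocity follows as `stride × cadence / 120`.
The projected two-minute walk distance is `velocity × 120` — a derived
quantity, not a measured walk test.

One known ambiguity is whether the symmetry correlation should be taken over
the full cycle or restricted to stance or swing. The default is the full
normalized cycle; `pipeline_config(si_window = "stance"/"swing")` restricts
both limbs to a common window ending at the smaller mean stance percentage.
Amplitude is deliberately left unscaled by the normalization: the Pearson
correlation is scale-invariant, so the symmetry index is unaffected either
way, but the propulsion index is not, and rescaling would silently change it.

## The synthetic generator

`simulate_trunk_signal()` builds trials from a piecewise cycle grammar
rather than replaying recorded data, so every downstream quantity has an
exact known value. Per inter-contact interval: a one-sided raised-cosine
contact transient (peak 2 m/s², width adapted to the double-support time,
capped at 80 ms); a half-cosine descent reaching its minimum exactly at the
swinging limb's toe-off; a linear single-support ramp with the injected
slope, centred so it crosses zero mid-phase and ending exactly at the next
contact; and a sin² mid-swing lobe (0.5 m/s²) windowed to the middle 80% of
swing so that it vanishes, with zero slope, at both single-support
endpoints — the construction keeps troughs at toe-offs and ramp endpoint
values exact. The mediolateral channel carries a signed transient per
contact (positive = left); the vertical channel a bump per contact plus a
step-frequency oscillation. Gaussian timing jitter perturbs each step;
white Gaussian noise is added to all channels; `timing_offset` shifts every
right-limb contact to inject pure timing asymmetry, and `amplitude_asym`
scales the left limb's transient and lobe.

Two generator-level constraints follow from the physics of walking: stance
fractions must exceed 0.5 (single support bracketed by opposite-limb
toe-off and contact only exists with nonnegative double support), and the
implied double-support time must be at least 40 ms so the transient is
resolvable at the sampling rate (default 100 Hz — a configurable default,
since the recording rate of the reference instrument is not published).
Single-support slopes must be positive (propulsive gait); the trough-based
toe-off estimate assumes the AP minimum sits at single-support start, which
holds in that regime.

What the generator does **not** emulate: soft-tissue and sensor-mounting
artifacts, turning strides, slopes or stairs, double-support force-sharing
dynamics, and any pelvic orientation signal. Passing the recovery tests
therefore demonstrates that the pipeline inverts this signal family
correctly — not that it is robust to every artifact of field recordings.

`simulate_pressure_sequence()` emulates quiet standing: two disjoint
elliptical foot regions with a dome-shaped pressure profile (floored at 15%
of the dome peak so the whole anatomical footprint stays above the 1%
activation threshold used in segmentation), per-frame left/right load split
conserving body weight exactly, frame-level sway noise on the split, and
within-foot texture noise renormalized so foot sums are exact. The 48 × 48
grid matches a 2304-cell square platform at 40 frames/s for 60 s.

`simulate_cohort()` draws per-subject parameters from clamped Gaussian
group distributions. The defaults encode the two amputation-level groups of
the motivating study design: cadence 82.9 ± 10.0 (AK) vs 90.5 ± 10.2 (BK)
steps/min, stride 1.60 vs 1.32 m, propulsion angles 6.1°/3.4° (AK
amputated/sound) vs 6.9°/5.8° (BK), standing weight-shift targets of 35.5%
vs 22.7% BWD, and larger timing/amplitude asymmetries in the AK group so its
symmetry index degrades more. Stance-fraction means map the group quality
indices through the long-stance branch of `s = (120 + (100 - QI)) / 2`
(both limbs of slow pathological gait can spend ~70% of their cycle in
stance; the short-stance branch at ~50% would leave no single support to
measure). Trial length is 20 strides per limb with instrument-level noise
(0.05 m/s²); a full two-minute walk has several times more strides, so
per-subject index precision here is conservative.

## Numerical choices and degenerate inputs

- Normalization grid `P = 101`; linear interpolation throughout; resampling
  ties resolve toward the earlier sample.
- Symmetry on constant (zero-variance) input raises a degenerate-signal
  error rather than returning `NaN`; flat or structureless signals raise
  "no gait detected"; fewer than two complete cycles per limb aborts the
  subject pipeline with an insufficient-cycles error (three events still
  segment into the single cycle they define).
- Weight percentages always sum to exactly 100 by construction and are
  invariant to global rescaling of the frames (platform calibration
  cancels); an all-zero sequence raises a no-load error.
- BWD checks that the two percentages sum to 100 within 0.5 before taking
  the difference; the quality index checks stance + swing = 100 within 1e-9.
- The statistical gate requires **both** groups to pass Shapiro–Wilk at
  α = 0.05 by default (`gate = "pooled"` tests pooled centred residuals
  instead); "Wilcoxon" is the rank-sum (Mann–Whitney) form, as the groups
  are independent; the t test applies Welch's correction by default with a
  pooled-variance switch. A constant sample is treated as maximally
  non-normal (Shapiro–Wilk is undefined there).
- All simulation randomness flows through a single integer seed via
  deterministic child seeds, so cohorts are bit-reproducible and the
  caller's RNG state is never disturbed.

## Validation strategy and problem sizes

The test suite validates by parameter recovery against generator ground
truth: noise-free recovery of contacts (within one sample), stance fractions
(±2 percentage points over 50 trials spanning cadence 60–120 and stance
0.55–0.70), propulsion angles (±0.5°), and the mean-cycle waveform against
the closed-form template (within 2% of peak at 200 Hz, where linear
interpolation error of the sharp transient is below that band). Under noise
at 10% of the transient peak, at least 95% of contacts are required within
three samples, and a bilaterally symmetric trial must keep its symmetry
index in the high-symmetry band (≥ 75). The symmetry index is checked
against an independent brute-force Pearson sum-formula implementation to
1e-10 on a thousand random pairs, and the normality-gated comparison is
calibrated on 500 null simulations at n = 14/15 (rejection rate within
[0.03, 0.08]). These sizes keep the default suite under a minute while
leaving each property's sampling error well inside its tolerance.

## Known limitations

- Propulsion and stance estimates degrade with noise much faster than the
  symmetry index: the single-support troughs are shallow features (depth
  `slope × duration / 2`, often ~0.02 m/s²), so at noise well above the
  instrument level their location — and with it the propulsion endpoint
  reads — becomes noise-limited. The symmetry index, computed on whole
  averaged cycles, is far more forgiving.
- Pelvic tilt/obliquity/rotation curves require orientation estimation
  (sensor fusion) that a raw accelerometer pipeline cannot provide and are
  out of scope.
- Stride length (and hence velocity and projected walk distance) is only as
  good as the supplied metadata.
- The two-minute walk distance is a projection from steady-state velocity;
  it ignores turns, accelerations and rests, and will exceed field-measured
  distances.
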