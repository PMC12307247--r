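#' Parameters for the trunk-acceleration gait simulator
#'
#' Every quantity the analysis pipeline is asked to recover is injected here as
#' exact ground truth: cadence and stride length (spatiotemporal parameters),
#' per-limb stance fraction (quality index), the linear AP acceleration ramp
#' slope during single support (propulsion index), and inter-limb
#' amplitude/timing asymmetry (symmetry index).
#'
#' @param cadence Steps per minute.
#' @param n_strides Strides generated for the leading (left) limb; the other
#'   limb gets `n_strides - 1` complete cycles.
#' @param stance_fraction_left,stance_fraction_right Stance phase as a fraction
#'   of the limb's own gait cycle. Must lie in (0.5, 0.8]: walking gait has a
#'   nonnegative double-support time, and the single-support bracketing used by
#'   the pipeline (opposite-limb toe-off to opposite-limb initial contact) only
#'   exists above 0.5.
#' @param single_support_slope_left,single_support_slope_right Slope (m/s^3) of
#'   the linear AP acceleration ramp spanning each limb's single-support phase.
#'   Must be positive (propulsive gait); the injected propulsion index is
#'   `atan(slope)` in degrees.
#' @param amplitude_asym Multiplicative factor (>= 0) applied to the left
#'   limb's transient and swing-lobe amplitudes; 1 means symmetric amplitudes.
#' @param timing_jitter_sd SD (s) of Gaussian jitter added to each step time.
#' @param noise_sd SD (m/s^2) of additive white Gaussian noise on all channels.
#' @param sampling_rate Sampling rate in Hz (>= 50).
#' @param stride_length_left,stride_length_right Stride length (m) per limb,
#'   carried as metadata ground truth (a single trunk accelerometer does not
#'   measure it).
#' @param timing_offset Constant shift (s) applied to every right-limb initial
#'   contact; nonzero values inject pure timing asymmetry between the limbs.
#' @param peak_amplitude Amplitude (m/s^2) of the initial-contact AP transient.
#' @param swing_amplitude Amplitude (m/s^2) of the mid-swing AP lobe.
#'
#' @return An object of class `gait_sim_params` (a validated list).
#' @seealso [simulate_trunk_signal()]
#' @export
gait_sim_params <- function(cadence = 100,
                            n_strides = 12,
                            stance_fraction_left = 0.60,
                            stance_fraction_right = 0.60,
                            single_support_slope_left = 0.10,
                            single_support_slope_right = 0.10,
                            amplitude_asym = 1,
                            timing_jitter_sd = 0,
                            noise_sd = 0,
                            sampling_rate = 100,
                            stride_length_left = 1.4,
                            stride_length_right = 1.4,
                            timing_offset = 0,
                            peak_amplitude = 2.0,
                            swing_amplitude = 0.5) {
  check_number(cadence, "cadence", lower = 20, upper = 200)
  if (!is.numeric(n_strides) || length(n_strides) != 1L || n_strides < 3 ||
      n_strides != round(n_strides)) {
    tg_param_error("n_strides", "must be an integer >= 3")
  }
  check_number(stance_fraction_left, "stance_fraction_left",
    lower = 0.5, upper = 0.8, closed_lower = FALSE
  )
  check_number(stance_fraction_right, "stance_fraction_right",
    lower = 0.5, upper = 0.8, closed_lower = FALSE
  )
  check_number(single_support_slope_left, "single_support_slope_left",
    lower = 0, closed_lower = FALSE
  )
  check_number(single_support_slope_right, "single_support_slope_right",
    lower = 0, closed_lower = FALSE
  )
  check_number(amplitude_asym, "amplitude_asym", lower = 0)
  check_number(timing_jitter_sd, "timing_jitter_sd", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sampling_rate, "sampling_rate", lower = 50)
  check_number(stride_length_left, "stride_length_left", lower = 0, closed_lower = FALSE)
  check_number(stride_length_right, "stride_length_right", lower = 0, closed_lower = FALSE)
  check_number(timing_offset, "timing_offset", lower = -0.2, upper = 0.2)
  check_number(peak_amplitude, "peak_amplitude", lower = 0, closed_lower = FALSE)
  check_number(swing_amplitude, "swing_amplitude", lower = 0)

  p <- list(
    cadence = cadence, n_strides = as.integer(n_strides),
    stance_fraction_left = stance_fraction_left,
    stance_fraction_right = stance_fraction_right,
    single_support_slope_left = single_support_slope_left,
    single_support_slope_right = single_support_slope_right,
    amplitude_asym = amplitude_asym,
    timing_jitter_sd = timing_jitter_sd,
    noise_sd = noise_sd,
    sampling_rate = sampling_rate,
    stride_length_left = stride_length_left,
    stride_length_right = stride_length_right,
    timing_offset = timing_offset,
    peak_amplitude = peak_amplitude,
    swing_amplitude = swing_amplitude
  )
  class(p) <- "gait_sim_params"

  # The double-support window must be long enough to host the contact
  # transient at this sampling rate, otherwise the waveform is unresolvable.
  stride_t <- 120 / cadence
  ds <- (min(stance_fraction_left, stance_fraction_right) - 0.5) * stride_t
  if (ds < 0.04) {
    tg_param_error(
      "stance_fraction_left/right",
      sprintf(
        "implied double-support time %.0f ms < 40 ms at cadence %g; increase stance fraction or lower cadence",
        ds * 1000, cadence
      )
    )
  }
  if (bump_width(p) < 2 / sampling_rate) {
    tg_param_error(
      "sampling_rate",
      "contact transient narrower than 2 samples; raise sampling_rate"
    )
  }
  p
}

#' @export
print.gait_sim_params <- function(x, ...) {
  cat(sprintf(
    "<gait_sim_params> cadence %g steps/min, %d strides, stance L/R %.2f/%.2f, slope L/R %.3g/%.3g m/s^3\n",
    x$cadence, x$n_strides, x$stance_fraction_left, x$stance_fraction_right,
    x$single_support_slope_left, x$single_support_slope_right
  ))
  cat(sprintf(
    "  amplitude_asym %.2f, jitter %.3g s, noise %.3g m/s^2, fs %g Hz\n",
    x$amplitude_asym, x$timing_jitter_sd, x$noise_sd, x$sampling_rate
  ))
  invisible(x)
}

#' Parameters for the standing plantar-pressure simulator
#'
#' Emulates quiet standing on a square pressure platform: two disjoint
#' elliptical foot regions whose summed load splits the body weight in a
#' controllable left/right ratio, sampled as a stack of frames.
#'
#' @param weight_split_left Fraction of body weight on the left foot, in
#'   \[0, 1\].
#' @param body_weight Body weight in newtons.
#' @param duration Recording duration in seconds (default 60 s of standing).
#' @param frame_rate Frames per second (default 40).
#' @param grid_shape Integer vector `c(rows, cols)` of the sensor matrix
#'   (default 48 x 48, i.e. 2304 cells).
#' @param foot_length_cells,foot_width_cells Axes (in cells) of the elliptical
#'   foot regions.
#' @param pressure_noise_sd SD of the per-frame relative fluctuation of the
#'   left/right load split (postural sway); per-cell multiplicative texture
#'   noise uses the same relative SD.
#'
#' @return An object of class `stance_sim_params`.
#' @seealso [simulate_pressure_sequence()]
#' @export
stance_sim_params <- function(weight_split_left = 0.5,
                              body_weight = 700,
                              duration = 60,
                              frame_rate = 40,
                              grid_shape = c(48L, 48L),
                              foot_length_cells = 22,
                              foot_width_cells = 9,
                              pressure_noise_sd = 0) {
  check_number(weight_split_left, "weight_split_left", lower = 0, upper = 1)
  check_number(body_weight, "body_weight", lower = 0, closed_lower = FALSE)
  check_number(duration, "duration", lower = 0, closed_lower = FALSE)
  check_number(frame_rate, "frame_rate", lower = 0, closed_lower = FALSE)
  if (length(grid_shape) != 2L || any(grid_shape < 8) ||
      any(grid_shape != round(grid_shape))) {
    tg_param_error("grid_shape", "must be two integers >= 8")
  }
  check_number(foot_length_cells, "foot_length_cells", lower = 4, upper = grid_shape[1])
  check_number(foot_width_cells, "foot_width_cells", lower = 2, upper = floor(grid_shape[2] / 2) - 2)
  check_number(pressure_noise_sd, "pressure_noise_sd", lower = 0, upper = 0.5)
  if (2 * (foot_width_cells + 2) > grid_shape[2]) {
    tg_stop(
      "foot regions do not fit disjointly in the grid",
      "trunkgait_config_error"
    )
  }
  structure(
    list(
      weight_split_left = weight_split_left, body_weight = body_weight,
      duration = duration, frame_rate = frame_rate,
      grid_shape = as.integer(grid_shape),
      foot_length_cells = foot_length_cells,
      foot_width_cells = foot_width_cells,
      pressure_noise_sd = pressure_noise_sd
    ),
    class = "stance_sim_params"
  )
}
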