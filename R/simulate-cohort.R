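# Cohort-level simulation: subject parameters drawn from per-group
# distributions shaped like the study conditions (above-knee vs below-knee
# amputees), each subject yielding one walking trial plus one standing
# pressure sequence with full ground truth.

#' Per-group parameter distributions for cohort simulation
#'
#' Each entry is `c(mean, sd)` of a clamped Gaussian draw. The defaults encode
#' the two amputation-level groups: cadence and stride length at the group
#' means; per-limb propulsion angles (converted to ramp slopes via `tan`);
#' stance fractions on the long-stance branch consistent with the group
#' quality indices; a standing weight-bearing shift toward the sound limb
#' sized to the group body-weight distribution; and timing/amplitude
#' asymmetries that degrade the above-knee group's gait symmetry more.
#'
#' @param cadence,stride_length,propulsion_deg_amputated,propulsion_deg_sound,
#'   stance_amputated,stance_sound,bwd_target,timing_offset,amplitude_asym_amputated
#'   Numeric `c(mean, sd)` pairs.
#' @param noise_sd,timing_jitter_sd,n_strides,sampling_rate Scalars shared by
#'   all subjects in the group.
#' @param pressure_duration,pressure_noise_sd Standing-recording length (s)
#'   and relative sway/texture noise for the pressure sequences.
#' @return A list of class `group_params`.
#' @export
group_params <- function(cadence = c(90, 10),
                         stride_length = c(1.4, 0.2),
                         propulsion_deg_amputated = c(6.5, 2.2),
                         propulsion_deg_sound = c(4.5, 2.0),
                         stance_amputated = c(0.67, 0.03),
                         stance_sound = c(0.67, 0.03),
                         bwd_target = c(25, 15),
                         timing_offset = c(0.02, 0.015),
                         amplitude_asym_amputated = c(0.9, 0.05),
                         noise_sd = 0.05,
                         timing_jitter_sd = 0.008,
                         n_strides = 20,
                         sampling_rate = 100,
                         pressure_duration = 60,
                         pressure_noise_sd = 0.03) {
  pars <- list(
    cadence = cadence, stride_length = stride_length,
    propulsion_deg_amputated = propulsion_deg_amputated,
    propulsion_deg_sound = propulsion_deg_sound,
    stance_amputated = stance_amputated, stance_sound = stance_sound,
    bwd_target = bwd_target, timing_offset = timing_offset,
    amplitude_asym_amputated = amplitude_asym_amputated
  )
  for (nm in names(pars)) {
    v <- pars[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || v[2] < 0) {
      tg_param_error(nm, "must be c(mean, sd) with sd >= 0")
    }
  }
  structure(
    c(pars, list(
      noise_sd = noise_sd, timing_jitter_sd = timing_jitter_sd,
      n_strides = n_strides, sampling_rate = sampling_rate,
      pressure_duration = pressure_duration,
      pressure_noise_sd = pressure_noise_sd
    )),
    class = "group_params"
  )
}

#' Above-knee and below-knee default group conditions
#'
#' Group distributions centred on the two amputation levels: the above-knee
#' (AK) group walks with lower cadence, longer strides, weaker sound-limb
#' propulsion, larger standing weight-bearing asymmetry and larger timing and
#' amplitude asymmetry than the below-knee (BK) group.
#' @return A `group_params` list.
#' @export
ak_group_params <- function() {
  group_params(
    cadence = c(82.9, 10.0), stride_length = c(1.60, 0.25),
    propulsion_deg_amputated = c(6.1, 2.5), propulsion_deg_sound = c(3.4, 1.5),
    stance_amputated = c(0.695, 0.04), stance_sound = c(0.70, 0.035),
    bwd_target = c(35.5, 20), timing_offset = c(0.045, 0.02),
    amplitude_asym_amputated = c(0.82, 0.07)
  )
}

#' @rdname ak_group_params
#' @export
bk_group_params <- function() {
  group_params(
    cadence = c(90.5, 10.2), stride_length = c(1.32, 0.17),
    propulsion_deg_amputated = c(6.9, 2.0), propulsion_deg_sound = c(5.8, 2.4),
    stance_amputated = c(0.656, 0.03), stance_sound = c(0.642, 0.03),
    bwd_target = c(22.7, 14), timing_offset = c(0.015, 0.01),
    amplitude_asym_amputated = c(0.93, 0.04)
  )
}

#' Cohort specification
#'
#' @param n_ak,n_bk Subjects per amputation-level group (>= 2 each).
#' @param ak,bk [group_params()] for each group.
#' @param side_rule How amputated sides are assigned: `"alternate"` or
#'   `"random"` (balanced laterality by default).
#' @param body_weight `c(mean, sd)` body weight in newtons.
#' @param seed Master seed; every subject derives a child seed from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ak = 14, n_bk = 15,
                        ak = ak_group_params(), bk = bk_group_params(),
                        side_rule = c("alternate", "random"),
                        body_weight = c(750, 110),
                        seed = 1L) {
  side_rule <- match.arg(side_rule)
  if (!is.numeric(n_ak) || n_ak < 2 || !is.numeric(n_bk) || n_bk < 2) {
    tg_param_error("n_ak/n_bk", "need at least 2 subjects per group")
  }
  stopifnot(inherits(ak, "group_params"), inherits(bk, "group_params"))
  structure(
    list(
      n_ak = as.integer(n_ak), n_bk = as.integer(n_bk), ak = ak, bk = bk,
      side_rule = side_rule, body_weight = body_weight,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

draw_clamped <- function(ms, lo = -Inf, hi = Inf) {
  pmin(hi, pmax(lo, rnorm(1, ms[1], ms[2])))
}

simulate_subject_dataset <- function(gp, group, side, subject_id, body_weight_ms, seed) {
  pars <- with_sim_seed(child_seed(seed, 1L), {
    cad <- draw_clamped(gp$cadence, 50, 140)
    stride <- draw_clamped(gp$stride_length, 0.6, 2.2)
    # stance fractions clamped so double support stays resolvable
    min_f <- 0.5 + 0.05 * cad / 120 + 0.01
    f_amp <- draw_clamped(gp$stance_amputated, min_f, 0.78)
    f_snd <- draw_clamped(gp$stance_sound, min_f, 0.78)
    ang_amp <- draw_clamped(gp$propulsion_deg_amputated, 0.5, 20)
    ang_snd <- draw_clamped(gp$propulsion_deg_sound, 0.5, 20)
    asym <- draw_clamped(gp$amplitude_asym_amputated, 0.4, 1.2)
    toff <- draw_clamped(gp$timing_offset, -0.08, 0.08)
    bwd_t <- draw_clamped(gp$bwd_target, 0, 80)
    bw <- draw_clamped(body_weight_ms, 450, 1200)
    list(
      cad = cad, stride = stride, f_amp = f_amp, f_snd = f_snd,
      ang_amp = ang_amp, ang_snd = ang_snd, asym = asym, toff = toff,
      bwd_t = bwd_t, bw = bw
    )
  })

  left_is_amp <- side == "left"
  gait <- gait_sim_params(
    cadence = pars$cad,
    n_strides = gp$n_strides,
    stance_fraction_left = if (left_is_amp) pars$f_amp else pars$f_snd,
    stance_fraction_right = if (left_is_amp) pars$f_snd else pars$f_amp,
    single_support_slope_left = tan((if (left_is_amp) pars$ang_amp else pars$ang_snd) * pi / 180),
    single_support_slope_right = tan((if (left_is_amp) pars$ang_snd else pars$ang_amp) * pi / 180),
    # the generator scales the left limb; express the amputated-limb
    # attenuation relative to the sound limb either way round
    amplitude_asym = if (left_is_amp) pars$asym else 1 / pars$asym,
    timing_jitter_sd = gp$timing_jitter_sd,
    noise_sd = gp$noise_sd,
    sampling_rate = gp$sampling_rate,
    stride_length_left = pars$stride,
    stride_length_right = pars$stride,
    timing_offset = pars$toff
  )
  trial <- simulate_trunk_signal(gait, seed = child_seed(seed, 2L))

  split_sound <- (100 + pars$bwd_t) / 200
  split_left <- if (left_is_amp) 1 - split_sound else split_sound
  stance <- stance_sim_params(
    weight_split_left = split_left,
    body_weight = pars$bw,
    duration = gp$pressure_duration,
    pressure_noise_sd = gp$pressure_noise_sd
  )
  pressure <- simulate_pressure_sequence(stance, seed = child_seed(seed, 3L))

  structure(
    list(
      subject_id = subject_id, group = group, amputated_side = side,
      trial = trial, pressure = pressure,
      metadata = list(
        stride_length = c(left = pars$stride, right = pars$stride),
        body_weight = pars$bw,
        bwd_target = pars$bwd_t
      )
    ),
    class = "subject_dataset"
  )
}

#' Simulate a two-group amputee cohort
#'
#' Draws per-subject gait and standing parameters from the group
#' distributions, assigns amputated sides by the spec's rule, and generates
#' one walking trial and one standing pressure sequence per subject, fully
#' reproducible from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` of `subject_dataset` objects, each with
#'   `subject_id`, `group`, `amputated_side`, `trial` (signal + ground truth),
#'   `pressure` and `metadata`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_ak + spec$n_bk
  groups <- c(rep("AK", spec$n_ak), rep("BK", spec$n_bk))
  sides <- with_sim_seed(child_seed(spec$seed, 0L), {
    if (spec$side_rule == "alternate") {
      unlist(lapply(c(spec$n_ak, spec$n_bk), function(k) {
        rep(c("left", "right"), length.out = k)
      }))
    } else {
      sample(c("left", "right"), n, replace = TRUE)
    }
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    gp <- if (groups[i] == "AK") spec$ak else spec$bk
    out[[i]] <- simulate_subject_dataset(
      gp, groups[i], sides[i],
      subject_id = sprintf("S%02d", i),
      body_weight_ms = spec$body_weight,
      seed = child_seed(spec$seed, 10L + i)
    )
  }
  structure(out, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  gr <- vapply(x, function(s) s$group, character(1))
  cat(sprintf(
    "<cohort> %d subjects (%d AK, %d BK)\n",
    length(x), sum(gr == "AK"), sum(gr == "BK")
  ))
  invisible(x)
}
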