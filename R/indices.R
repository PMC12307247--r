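# The four headline metrics of the pipeline. All are pure functions of the
# mean normalized cycles / phase summaries / weight percentages.

ap_vector <- function(x, arg) {
  if (inherits(x, "mean_cycle")) {
    return(x$ap_norm)
  }
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  tg_param_error(arg, "must be a mean_cycle or a numeric vector")
}

#' Gait symmetry index
#'
#' Pearson correlation between the two limbs' mean normalized anteroposterior
#' acceleration cycles, mapped affinely from \[-1, 1\] to \[0, 100\]:
#' `(r + 1) * 100 / 2`. Identical waveforms score 100, exactly opposite ones 0;
#' 75-100 is conventionally read as high symmetry.
#'
#' @param sound,amputated `mean_cycle` objects (or plain numeric vectors) of
#'   equal length.
#' @return Symmetry index in percent.
#' @export
#' @examples
#' x <- sin(seq(0, 2 * pi, length.out = 101))
#' symmetry_index(x, x) # 100
#' symmetry_index(x, -x) # 0
symmetry_index <- function(sound, amputated) {
  s <- ap_vector(sound, "sound")
  a <- ap_vector(amputated, "amputated")
  if (length(s) != length(a)) {
    tg_param_error("sound/amputated", "mean cycles must have equal length")
  }
  if (var(s) == 0 || var(a) == 0) {
    tg_stop("degenerate signal: zero variance, correlation undefined", "trunkgait_degenerate_error")
  }
  r <- cor(s, a)
  (r + 1) * 100 / 2
}

#' Single-support phase endpoints
#'
#' Holds the anteroposterior acceleration at the start and end of a limb's
#' single-support phase and the phase duration, the ingredients of the
#' propulsion index.
#'
#' @param a_start,a_end AP acceleration (m/s^2) at single-support start/end.
#' @param t_start,t_end Times (s) of the phase endpoints; `t_end > t_start`.
#' @param limb Optional limb label.
#' @return A list of class `single_support_phase`.
#' @export
single_support_phase <- function(a_start, a_end, t_start, t_end, limb = NA_character_) {
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_end <= t_start) {
    tg_stop("invalid phase: single-support duration must be positive", "trunkgait_phase_error")
  }
  structure(
    list(
      limb = limb, a_start = a_start, a_end = a_end,
      t_start = t_start, t_end = t_end
    ),
    class = "single_support_phase"
  )
}

#' Extract the single-support phase from a mean cycle
#'
#' Maps the averaged single-support start/end percentages back to mean-cycle
#' time and traces the acceleration line across the phase. A small inset
#' margin (default 2% of the cycle) pulls the window just inside the phase so
#' contact transients at its boundaries do not contaminate the endpoint
#' values; the slope is unaffected because both points lie on the traced
#' line. Endpoints are read by linear interpolation on the normalized grid.
#'
#' @param mc A `mean_cycle`.
#' @param margin_pct Inset margin in percent of the cycle.
#' @return A [single_support_phase()].
#' @export
single_support_phase_from_mean_cycle <- function(mc, margin_pct = 2) {
  stopifnot(inherits(mc, "mean_cycle"))
  p <- length(mc$ap_norm)
  pct <- seq(0, 100, length.out = p)
  p1 <- mc$sss_pct + margin_pct
  p2 <- mc$sse_pct - margin_pct
  if (p2 <= p1) {
    tg_stop("invalid phase: single-support window collapsed by the margin", "trunkgait_phase_error")
  }
  t1 <- p1 / 100 * mc$duration_s
  t2 <- p2 / 100 * mc$duration_s
  a1 <- approx(pct, mc$ap_norm, xout = p1)$y
  a2 <- approx(pct, mc$ap_norm, xout = p2)$y
  single_support_phase(
    a_start = a1, a_end = a2,
    t_start = t1, t_end = t2,
    limb = mc$limb
  )
}

#' Propulsion index
#'
#' Arctangent, in degrees, of the anteroposterior acceleration change over the
#' single-support phase: `atan(delta_a / delta_t)` with `delta_a` in m/s^2 and
#' `delta_t` in s (set `units = "g"` to express `delta_a` in g before the
#' ratio). The sign of the slope is preserved; values above 5.5 degrees are
#' conventionally read as optimal propulsion.
#'
#' @param phase A [single_support_phase()].
#' @param units Units for the acceleration difference: `"ms2"` (default) or
#'   `"g"`.
#' @return Propulsion index in degrees.
#' @export
#' @examples
#' propulsion_index(single_support_phase(0, 0.04, 0, 0.4)) # atan(0.1) = 5.71
propulsion_index <- function(phase, units = c("ms2", "g")) {
  units <- match.arg(units)
  stopifnot(inherits(phase, "single_support_phase"))
  dt <- phase$t_end - phase$t_start
  if (dt <= 0) {
    tg_stop("invalid phase: single-support duration must be positive", "trunkgait_phase_error")
  }
  da <- phase$a_end - phase$a_start
  if (units == "g") da <- da / 9.80665
  atan(da / dt) * 180 / pi
}

#' Gait quality index
#'
#' Deviation of a limb's stance/swing split from the ideal 60/40 division of
#' the gait cycle: `||(Dstance - Dswing) - 20| - 100|` with the mean phase
#' durations in percent of the cycle. Exactly 100 at the ideal split.
#'
#' @param stance Mean stance duration in percent of the gait cycle, a
#'   `phase_summary` (giving one value per limb), or a single-limb element of
#'   one.
#' @param swing Mean swing duration in percent; defaults to `100 - stance`
#'   when `stance` is numeric.
#' @return Quality index in percent (named per limb for a `phase_summary`).
#' @export
#' @examples
#' quality_index(60) # 100
#' quality_index(70) # 80
quality_index <- function(stance, swing = NULL) {
  if (inherits(stance, "phase_summary")) {
    return(vapply(
      stance,
      function(el) quality_index(el$d_stance_mean, el$d_swing_mean),
      numeric(1)
    ))
  }
  if (is.list(stance) && !is.null(stance$d_stance_mean)) {
    return(quality_index(stance$d_stance_mean, stance$d_swing_mean))
  }
  swing <- swing %||% (100 - stance)
  if (abs(stance + swing - 100) > 1e-9) {
    tg_stop("consistency error: stance + swing must equal 100", "trunkgait_consistency_error")
  }
  abs(abs((stance - swing) - 20) - 100)
}

#' Body-weight distribution (BWD)
#'
#' Absolute difference between the percentages of body weight borne by the
#' sound and amputated limbs during quiet standing; 0% is the ideal, balanced
#' loading.
#'
#' @param sound_pct,amputated_pct Per-limb weight percentages; they must sum
#'   to 100 within `tol`.
#' @param tol Tolerance on the percentage sum (default 0.5).
#' @return BWD in percent.
#' @export
#' @examples
#' bwd(60, 40) # 20
bwd <- function(sound_pct, amputated_pct, tol = 0.5) {
  if (abs(sound_pct + amputated_pct - 100) > tol) {
    tg_stop("consistency error: weight percentages must sum to 100", "trunkgait_consistency_error")
  }
  abs(sound_pct - amputated_pct)
}
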