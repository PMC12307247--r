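# Synthetic trunk-acceleration gait trials with exact ground truth.
#
# Waveform grammar, per interval between consecutive initial contacts
# [IC_j, IC_{j+1}] (limb A contacts at IC_j, limb B swings):
#   1. contact transient: one-sided raised cosine on [IC_j, IC_j + w], blending
#      down from the previous ramp's end value; its onset marks the contact.
#   2. descent: half-cosine from 0 down to the trough value, reaching the
#      minimum exactly at limb B's toe-off (zero slope there).
#   3. single-support ramp of limb A: linear with the injected slope from the
#      trough up to IC_{j+1}; the trough is centred so the ramp crosses zero
#      mid single support.
#   4. swing lobe of limb B: a sin^2 lobe over the middle 80% of the swing,
#      zero (with zero slope) near both ramp endpoints.
# The construction keeps every analysis target exact: troughs sit at toe-offs,
# ramp endpoint values encode the propulsion slope, and contact onsets are the
# event times.

bump_width <- function(params) {
  stride_t <- 120 / params$cadence
  ds_min <- (min(params$stance_fraction_left, params$stance_fraction_right) - 0.5) * stride_t
  min(0.08, 0.75 * ds_min)
}

limb_amp <- function(params, limb, base) {
  base * ifelse(limb == "left", params$amplitude_asym, 1)
}

limb_field <- function(params, limb, prefix) {
  unname(unlist(params[paste0(prefix, "_", limb)]))
}

# Piecewise AP evaluator shared by the simulator and the analytic cycle
# template. `ev` are extended initial-contact times (>= 2 virtual events on
# each side), `limbs` their alternating labels.
ap_piecewise <- function(tgrid, ev, limbs, params) {
  w <- bump_width(params)
  v <- numeric(length(tgrid))
  m <- length(ev)
  for (j in 3:(m - 1)) {
    a <- ev[j]
    b <- ev[j + 1]
    idx <- which(tgrid >= a & tgrid < b)
    if (!length(idx)) next
    t <- tgrid[idx]
    A_limb <- limbs[j]
    sw_limb <- limbs[j + 1] # the limb that contacts next is currently swinging
    f_sw <- limb_field(params, sw_limb, "stance_fraction")
    f_A <- limb_field(params, A_limb, "stance_fraction")
    s_A <- limb_field(params, A_limb, "single_support_slope")
    s_sw <- limb_field(params, sw_limb, "single_support_slope")
    tt <- ev[j - 1] + f_sw * (b - ev[j - 1]) # toe-off of swinging limb
    tt <- max(tt, a + w + 1e-9)
    dss <- b - tt
    m_val <- -s_A * dss / 2
    # end value of the previous interval's ramp (limb sw in single support,
    # limb A toeing off during interval j-1)
    tt_prev <- ev[j - 2] + f_A * (a - ev[j - 2])
    e_prev <- s_sw * (a - tt_prev) / 2
    amp_a <- limb_amp(params, A_limb, params$peak_amplitude)
    amp_sw <- limb_amp(params, sw_limb, params$swing_amplitude)

    vi <- numeric(length(t))
    seg1 <- t < a + w
    if (any(seg1)) {
      u <- (t[seg1] - a) / w
      vi[seg1] <- e_prev * (1 - u) + amp_a * 0.5 * (1 - cos(2 * pi * u))
    }
    seg2 <- !seg1 & t < tt
    if (any(seg2)) {
      len <- tt - (a + w)
      u <- (t[seg2] - (a + w)) / len
      vi[seg2] <- m_val * 0.5 * (1 - cos(pi * u))
    }
    seg3 <- t >= tt
    if (any(seg3)) {
      tr <- t[seg3]
      ramp <- m_val + s_A * (tr - tt)
      us <- (tr - tt) / dss
      lobe <- ifelse(us >= 0.1 & us <= 0.9,
        amp_sw * sin(pi * (us - 0.1) / 0.8)^2, 0
      )
      vi[seg3] <- ramp + lobe
    }
    v[idx] <- vi
  }
  v
}

extended_events <- function(params) {
  step <- 60 / params$cadence
  n_ev <- 2L * params$n_strides + 1L
  pad <- 1.0
  nominal <- pad + (seq_len(n_ev) - 1L) * step
  limbs <- rep(c("left", "right"), length.out = n_ev)
  nominal[limbs == "right"] <- nominal[limbs == "right"] + params$timing_offset
  jit <- rnorm(n_ev, 0, params$timing_jitter_sd)
  times <- nominal + jit
  if (any(diff(times) < 0.35 * step)) {
    tg_stop(
      "timing jitter too large: step intervals collapsed below 35% of the nominal step",
      "trunkgait_param_error"
    )
  }
  # two virtual events on each side so the waveform is defined across edges;
  # the right-limb timing offset applies to virtual events too
  pre <- c(times[1] - 2 * step, times[1] - step + params$timing_offset)
  post <- c(
    times[n_ev] + step + params$timing_offset,
    times[n_ev] + 2 * step
  )
  list(
    times = times, limbs = limbs,
    ev = c(pre, times, post),
    ev_limbs = c("left", "right", limbs, "right", "left"),
    step = step, pad = pad
  )
}

#' Simulate a trunk-acceleration walking trial with ground truth
#'
#' Generates a triaxial trunk acceleration trial built from alternating
#' left/right gait cycles. Each cycle carries a sharp positive AP transient at
#' initial contact, a linear AP ramp with the injected slope spanning the
#' single-support phase, and a mid-swing oscillation lobe; the mediolateral
#' channel carries a signed transient at each contact (positive for left) so
#' limb labelling is recoverable from the signal. Identical `(params, seed)`
#' reproduce the identical trial.
#'
#' @param params A [gait_sim_params()] object.
#' @param seed Integer seed controlling jitter and noise.
#'
#' @return A list of class `simulated_trial` with elements
#'   \describe{
#'     \item{signal}{a [trunk_signal()]}
#'     \item{truth}{a `gait_ground_truth` list: `events` (initial contacts and
#'       toe-offs with limb labels), `cycles` (per complete cycle: initial
#'       contact, next initial contact, own toe-off, single-support start/end
#'       times, stance fraction, slope and the implied propulsion angle), the
#'       per-limb stance fractions, slopes, stride lengths, the nominal
#'       cadence, and the generating parameters.}
#'   }
#' @export
#' @examples
#' trial <- simulate_trunk_signal(gait_sim_params(n_strides = 5), seed = 1)
#' trial$signal
#' head(trial$truth$events)
simulate_trunk_signal <- function(params, seed = 1L) {
  if (!inherits(params, "gait_sim_params")) {
    params <- do.call(gait_sim_params, as.list(params))
  }
  fs <- params$sampling_rate
  with_sim_seed(seed, {
    ex <- extended_events(params)
    dur <- ex$times[length(ex$times)] + 0.5
    tgrid <- seq(0, dur, by = 1 / fs)
    ap <- ap_piecewise(tgrid, ex$ev, ex$ev_limbs, params)

    # mediolateral: signed contact transient (left positive); vertical: bump
    # per contact plus a step-frequency oscillation
    w <- bump_width(params)
    ml <- numeric(length(tgrid))
    vert <- 0.25 * sin(2 * pi * tgrid / ex$step)
    for (j in seq_along(ex$ev)) {
      tj <- ex$ev[j]
      idx <- which(tgrid >= tj & tgrid < tj + w)
      if (!length(idx)) next
      u <- (tgrid[idx] - tj) / w
      shape <- 0.5 * (1 - cos(2 * pi * u))
      sgn <- if (ex$ev_limbs[j] == "left") 1 else -1
      ml[idx] <- ml[idx] + sgn * limb_amp(params, ex$ev_limbs[j], 1.0) * shape
      vert[idx] <- vert[idx] + 1.2 * shape
    }
    if (params$noise_sd > 0) {
      ap <- ap + rnorm(length(ap), 0, params$noise_sd)
      ml <- ml + rnorm(length(ml), 0, params$noise_sd)
      vert <- vert + rnorm(length(vert), 0, params$noise_sd)
    }
    signal <- trunk_signal(tgrid, ap, vert, ml, sampling_rate = fs)
    truth <- ground_truth_from_events(ex, params)
    structure(list(signal = signal, truth = truth), class = "simulated_trial")
  })
}

ground_truth_from_events <- function(ex, params) {
  ev <- ex$ev
  limbs <- ex$ev_limbs
  n_real <- length(ex$times)
  real_idx <- seq(3L, 2L + n_real) # position of real events inside `ev`

  toe_time <- function(j) {
    # toe-off of the limb contacting at extended position j
    f <- limb_field(params, limbs[j], "stance_fraction")
    ev[j] + f * (ev[j + 2] - ev[j])
  }

  cycles <- list()
  for (k in seq_len(n_real - 2L)) {
    j <- real_idx[k]
    if (j + 2 > max(real_idx)) break
    limb <- limbs[j]
    cycles[[length(cycles) + 1L]] <- data.frame(
      limb = limb,
      ic_time = ev[j],
      opp_ic_time = ev[j + 1],
      next_ic_time = ev[j + 2],
      toe_off_time = toe_time(j),
      sss_time = toe_time(j - 1),
      sse_time = ev[j + 1],
      stance_fraction = limb_field(params, limb, "stance_fraction"),
      slope = limb_field(params, limb, "single_support_slope")
    )
  }
  cycles <- do.call(rbind, cycles)
  cycles$propulsion_deg <- atan(cycles$slope) * 180 / pi

  toe_events <- data.frame(
    time = vapply(real_idx[seq_len(n_real - 2L)], toe_time, numeric(1)),
    limb = limbs[real_idx[seq_len(n_real - 2L)]],
    type = "toe_off"
  )
  events <- rbind(
    data.frame(time = ex$times, limb = ex$limbs, type = "initial_contact"),
    toe_events
  )
  events <- events[order(events$time), ]
  rownames(events) <- NULL

  structure(
    list(
      events = events,
      cycles = cycles,
      stance_fraction = c(
        left = params$stance_fraction_left,
        right = params$stance_fraction_right
      ),
      slope = c(
        left = params$single_support_slope_left,
        right = params$single_support_slope_right
      ),
      propulsion_deg = c(
        left = atan(params$single_support_slope_left) * 180 / pi,
        right = atan(params$single_support_slope_right) * 180 / pi
      ),
      stride_length = c(
        left = params$stride_length_left,
        right = params$stride_length_right
      ),
      cadence = params$cadence,
      params = params
    ),
    class = "gait_ground_truth"
  )
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<gait_ground_truth> %d initial contacts, %d complete cycles; cadence %g steps/min\n",
    sum(x$events$type == "initial_contact"), nrow(x$cycles), x$cadence
  ))
  invisible(x)
}

#' @export
print.simulated_trial <- function(x, ...) {
  print(x$signal)
  print(x$truth)
  invisible(x)
}

#' Analytic mean-cycle template of the simulator
#'
#' Evaluates the noise- and jitter-free AP waveform of one limb's gait cycle on
#' the normalized 0-100% grid, directly from the generating parameters. This is
#' the closed form that the event-detection / normalization pipeline should
#' reproduce from a simulated trial.
#'
#' @param params A [gait_sim_params()] object.
#' @param limb `"left"` or `"right"`.
#' @param p Number of grid points over 0-100% of the cycle (default 101).
#' @return Numeric vector of length `p`.
#' @export
trunk_cycle_template <- function(params, limb = c("left", "right"), p = 101) {
  limb <- match.arg(limb)
  stride_t <- 120 / params$cadence
  step <- stride_t / 2
  off <- params$timing_offset
  # extended nominal contacts around one cycle of `limb` starting at 0;
  # the right-limb timing offset is expressed relative to the anchored limb
  ev <- seq(-4, 4) * step
  if (limb == "left") {
    limbs <- rep(c("left", "right"), length.out = 9)
    ev[limbs == "right"] <- ev[limbs == "right"] + off
  } else {
    limbs <- rep(c("right", "left"), length.out = 9)
    ev[limbs == "left"] <- ev[limbs == "left"] - off
  }
  tgrid <- seq(0, stride_t, length.out = p)
  # shift the final grid point just inside the last interval so it is covered
  tgrid[p] <- tgrid[p] - 1e-9
  ap_piecewise(tgrid, ev, limbs, params)
}
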