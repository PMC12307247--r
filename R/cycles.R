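#' Segment detected events into per-limb gait cycles
#'
#' Pairs consecutive same-limb initial contacts into complete gait cycles and
#' derives each cycle's stance/swing split. With a single trunk sensor, toe-off
#' of a limb is taken as the start of the opposite limb's single support: the
#' anteroposterior minimum (trough) between the opposite limb's initial contact
#' and the cycle-closing contact. Partial first/last cycles are discarded by
#' construction.
#'
#' @param events A `gait_events` data frame from [detect_initial_contacts()].
#' @param signal The [trunk_signal()] the events were detected in.
#' @param config A [detection_config()]; defaults to the one the events were
#'   detected with.
#' @param min_cycles_per_limb Minimum complete cycles required per limb before
#'   an "insufficient cycles" error is raised. The default 0 only requires at
#'   least one complete cycle overall (three events yield a single cycle of
#'   the leading limb); the subject pipeline raises it to 2.
#' @return A data frame of class `gait_cycles`: one row per complete cycle with
#'   sample indices `ic_idx`, `opp_ic_idx`, `next_ic_idx`, `toe_off_idx`,
#'   `sss_idx`, `sse_idx` and the exact split `stance_pct` + `swing_pct` = 100.
#' @export
segment_cycles <- function(events, signal, config = NULL,
                           min_cycles_per_limb = 0L) {
  stopifnot(inherits(signal, "trunk_signal"))
  config <- config %||% attr(events, "config") %||% detection_config()
  if (nrow(events) < 3L) {
    tg_stop("insufficient cycles: need at least 3 events", "trunkgait_insufficient_cycles_error")
  }
  if (any(events$limb[-1] == events$limb[-nrow(events)])) {
    tg_stop("event ordering: consecutive events must alternate limbs", "trunkgait_event_error")
  }
  ap <- signal$ap - mean(signal$ap)
  aps <- adaptive_smooth_min(ap, config)

  rows <- list()
  for (i in seq_len(nrow(events) - 2L)) {
    ic <- events$index[i]
    opp <- events$index[i + 1L]
    nxt <- events$index[i + 2L]
    toe <- trough_between(aps, opp, nxt) # own toe-off, during opposite cycle
    sss <- trough_between(aps, ic, opp) # opposite toe-off = own SS start
    stance <- 100 * (signal$time[toe] - signal$time[ic]) /
      (signal$time[nxt] - signal$time[ic])
    rows[[i]] <- data.frame(
      limb = events$limb[i],
      ic_idx = ic, opp_ic_idx = opp, next_ic_idx = nxt,
      toe_off_idx = toe, sss_idx = sss, sse_idx = opp,
      stance_pct = stance, swing_pct = 100 - stance
    )
  }
  out <- do.call(rbind, rows)
  counts <- table(factor(out$limb, levels = unique(events$limb)))
  if (any(counts < min_cycles_per_limb)) {
    tg_stop(
      sprintf(
        "insufficient cycles: need >= %d complete cycles per limb (got %s)",
        min_cycles_per_limb,
        paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")
      ),
      "trunkgait_insufficient_cycles_error"
    )
  }
  rownames(out) <- NULL
  structure(out, class = c("gait_cycles", "data.frame"), config = config)
}

#' Locate the single-support phase of one gait cycle
#'
#' Single support of a limb spans from the opposite limb's toe-off (the AP
#' trough following this cycle's initial contact) to the opposite limb's
#' initial contact.
#'
#' @param cycle One row of a `gait_cycles` data frame (or a list with
#'   `ic_idx`, `opp_ic_idx`, `next_ic_idx`).
#' @param signal The [trunk_signal()].
#' @param config A [detection_config()].
#' @return Named integer vector `c(single_support_start_idx,
#'   single_support_end_idx)`.
#' @export
locate_single_support <- function(cycle, signal, config = detection_config()) {
  ic <- cycle$ic_idx
  opp <- cycle$opp_ic_idx
  nxt <- cycle$next_ic_idx
  if (is.null(ic) || is.null(opp) || is.null(nxt) ||
      any(is.na(c(ic, opp, nxt)))) {
    tg_stop("event ordering: cycle is missing opposite-limb events", "trunkgait_event_error")
  }
  if (!(ic < opp && opp < nxt)) {
    tg_stop("event ordering: expected ic < opposite ic < next ic", "trunkgait_event_error")
  }
  ap <- signal$ap - mean(signal$ap)
  aps <- adaptive_smooth_min(ap, config)
  sss <- trough_between(aps, ic, opp)
  c(single_support_start_idx = sss, single_support_end_idx = as.integer(opp))
}

# Sub-grid minimum refinement: fit a parabola through the three points around
# a discrete argmin; fall back to the grid point at a non-convex kink.
refine_min <- function(y, i) {
  if (i <= 1L || i >= length(y)) {
    return(i)
  }
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (den <= 0) {
    return(i)
  }
  i + max(-0.5, min(0.5, 0.5 * (y[i - 1] - y[i + 1]) / den))
}

#' Time-normalize cycles and average per limb
#'
#' Resamples each cycle's AP segment to `p` points over 0-100% of its own
#' duration by linear interpolation and averages pointwise across cycles of
#' the same limb. The single-support end percentage is the (averaged) position
#' of the opposite limb's initial contact; the single-support start and the
#' limb's own toe-off (stance percentage) are then located as AP minima on the
#' averaged cycle, where uncorrelated noise has been suppressed by the
#' cycle averaging, with parabolic sub-grid refinement.
#'
#' @param cycles A `gait_cycles` data frame.
#' @param signal The [trunk_signal()].
#' @param p Number of normalized grid points (default 101: 0-100% inclusive).
#' @return A named list of `mean_cycle` objects, one per limb, each with
#'   `ap_norm` (length `p`), `ap_mean`, `sss_pct`, `sse_pct`, `stance_pct`,
#'   `n_cycles_averaged` and the mean cycle `duration_s`.
#' @export
normalize_and_average <- function(cycles, signal, p = 101) {
  stopifnot(inherits(signal, "trunk_signal"))
  check_number(p, "p", lower = 11)
  limbs <- unique(cycles$limb)
  pct <- seq(0, 100, length.out = p)
  out <- list()
  for (lb in limbs) {
    cy <- cycles[cycles$limb == lb, , drop = FALSE]
    if (nrow(cy) == 0L) {
      tg_stop(sprintf("insufficient cycles: none for limb %s", lb), "trunkgait_insufficient_cycles_error")
    }
    grids <- matrix(NA_real_, nrow = nrow(cy), ncol = p)
    sse_pct <- dur <- numeric(nrow(cy))
    for (k in seq_len(nrow(cy))) {
      t0 <- signal$time[cy$ic_idx[k]]
      t1 <- signal$time[cy$next_ic_idx[k]]
      tt <- seq(t0, t1, length.out = p)
      seg <- cy$ic_idx[k]:cy$next_ic_idx[k]
      grids[k, ] <- approx(signal$time[seg], signal$ap[seg], xout = tt)$y
      sse_pct[k] <- 100 * (signal$time[cy$sse_idx[k]] - t0) / (t1 - t0)
      dur[k] <- t1 - t0
    }
    ap_norm <- colMeans(grids)
    sse <- mean(sse_pct)
    # minima are searched on a lightly smoothed copy when the trial is noisy
    # (the shallow single-support troughs are the noise-limited features);
    # clean trials keep the sample-exact curve
    ap_search <- ap_norm
    if (is_noisy(signal$ap, detection_config())) {
      k <- rep(1 / 5, 5)
      sm <- stats::filter(ap_norm, k, sides = 2)
      ap_search <- ifelse(is.na(sm), ap_norm, as.numeric(sm))
    }
    # single-support start: AP minimum on the averaged cycle before the
    # opposite contact (sub-grid refined). The search carries a physiological
    # prior: double support occupies roughly 2-30% of the cycle, so the
    # minimum is sought there, which keeps the phase identifiable when the
    # ramp is shallow relative to residual noise.
    w1 <- which(pct > 1 & pct < min(sse - 5, 32))
    i1 <- w1[which.min(ap_search[w1])]
    sss <- approx(seq_len(p), pct, xout = refine_min(ap_search, i1))$y
    # own toe-off: AP minimum on the averaged cycle after the opposite
    # contact (stance fractions above ~88% are outside walking gait)
    w2 <- which(pct > sse + 1 & pct < 88)
    i2 <- w2[which.min(ap_search[w2])]
    stance <- approx(seq_len(p), pct, xout = refine_min(ap_search, i2))$y
    out[[lb]] <- structure(
      list(
        limb = lb,
        ap_norm = ap_norm,
        ap_mean = mean(ap_norm),
        sss_pct = sss,
        sse_pct = sse,
        stance_pct = stance,
        n_cycles_averaged = nrow(cy),
        duration_s = mean(dur)
      ),
      class = "mean_cycle"
    )
  }
  out
}

#' @export
print.mean_cycle <- function(x, ...) {
  cat(sprintf(
    "<mean_cycle> limb %s: %d points, %d cycles averaged, SS %.1f-%.1f%%, mean AP %.4g m/s^2\n",
    x$limb, length(x$ap_norm), x$n_cycles_averaged, x$sss_pct, x$sse_pct, x$ap_mean
  ))
  invisible(x)
}

#' Per-limb stance/swing phase summary
#'
#' With only the cycles, the mean stance is the average of the per-cycle
#' estimates; when the corresponding mean cycles are supplied, the
#' noise-suppressed stance percentage located on the averaged cycle is used
#' instead (the per-cycle list is kept either way).
#'
#' @param cycles A `gait_cycles` data frame.
#' @param mean_cycles Optional list of `mean_cycle` objects from
#'   [normalize_and_average()] (same limb labels).
#' @return A list of class `phase_summary`, one element per limb, each with
#'   `d_stance_mean`, `d_swing_mean` (exactly summing to 100) and the
#'   per-cycle stance percentages.
#' @export
phase_summary <- function(cycles, mean_cycles = NULL) {
  out <- lapply(split(cycles$stance_pct, cycles$limb), function(s) {
    list(
      d_stance_mean = mean(s),
      d_swing_mean = 100 - mean(s),
      stance_pct = s
    )
  })
  if (!is.null(mean_cycles)) {
    for (lb in names(out)) {
      st <- mean_cycles[[lb]]$stance_pct
      if (!is.null(st)) {
        out[[lb]]$d_stance_mean <- st
        out[[lb]]$d_swing_mean <- 100 - st
      }
    }
  }
  structure(out, class = "phase_summary")
}

#' Map left/right limbs to sound/amputated roles
#'
#' @param x A `gait_cycles` data frame, a list of `mean_cycle` objects, or a
#'   `phase_summary`.
#' @param amputated_side `"left"` or `"right"`.
#' @return The same object with limb labels `"amputated"`/`"sound"`.
#' @export
assign_limb_roles <- function(x, amputated_side = c("left", "right")) {
  amputated_side <- match.arg(amputated_side)
  relab <- function(l) ifelse(l == amputated_side, "amputated", "sound")
  if (inherits(x, "gait_cycles")) {
    x$limb <- relab(x$limb)
    return(x)
  }
  if (inherits(x, "phase_summary") || (is.list(x) && all(vapply(x, inherits, logical(1), "mean_cycle")))) {
    names(x) <- relab(names(x))
    x <- lapply(x, function(el) {
      if (!is.null(el$limb)) el$limb <- relab(el$limb)
      el
    })
    class(x) <- if (all(vapply(x, is.list, logical(1))) &&
      !is.null(x[[1]]$d_stance_mean)) "phase_summary" else class(x)
    return(x)
  }
  tg_param_error("x", "cannot assign limb roles to this object")
}

#' Spatiotemporal gait parameters
#'
#' Cadence is the number of steps (inter-contact intervals) per minute over the
#' detected event span. Stride length is not observable from a single trunk
#' accelerometer and is taken from metadata (or simulator ground truth);
#' velocity follows as `mean stride length * cadence / 120` and the projected
#' two-minute walk distance as `velocity * 120`.
#'
#' @param events A `gait_events` data frame (>= 5 events, i.e. two complete
#'   cycles per limb).
#' @param stride_length Named numeric vector of per-limb stride lengths in
#'   metres, e.g. `c(left = 1.4, right = 1.35)` (or sound/amputated names).
#' @return A list with `cadence` (steps/min), `velocity` (m/s),
#'   `stride_length` (the per-limb input), `stride_length_mean` (m) and
#'   `walk_distance_2min` (m).
#' @export
spatiotemporal <- function(events, stride_length = NULL) {
  if (nrow(events) < 5L) {
    tg_stop("insufficient cycles: need at least 2 complete cycles per limb", "trunkgait_insufficient_cycles_error")
  }
  if (is.null(stride_length) || !is.numeric(stride_length) ||
      any(is.na(stride_length))) {
    tg_stop(
      "stride length unavailable: supply per-limb stride lengths (metadata or ground truth)",
      "trunkgait_stride_error"
    )
  }
  elapsed <- events$time[nrow(events)] - events$time[1]
  steps <- nrow(events) - 1L
  cadence <- 60 * steps / elapsed
  velocity <- mean(stride_length) * cadence / 120
  list(
    cadence = cadence,
    velocity = velocity,
    stride_length = stride_length,
    stride_length_mean = mean(stride_length),
    walk_distance_2min = velocity * 120
  )
}
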