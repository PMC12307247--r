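#' Detection configuration
#'
#' Tunable constants of the initial-contact detector and the downstream cycle
#' machinery. Defaults follow common trunk-accelerometry practice; every value
#' is overridable.
#'
#' @param band Band-pass edges (Hz) applied before peak finding.
#' @param k_mad Adaptive peak threshold as a multiple of the MAD of the
#'   band-passed AP signal.
#' @param cadence_max Cadence prior (steps/min) setting the minimum inter-peak
#'   spacing `60 / (2 * cadence_max)` seconds.
#' @param refine_window Half-width (s) of the raw-signal window used to refine
#'   each band-passed peak to the raw local maximum.
#' @param onset_window Look-back (s) from each refined peak when searching for
#'   the contact onset (maximum-curvature point).
#' @param label_window Window (s) after each contact over which the
#'   mediolateral channel is averaged to infer the limb (positive = left).
#' @param smooth_threshold Relative noise level (high-frequency residual SD
#'   over peak amplitude) above which Savitzky-Golay smoothing is applied
#'   before onset/trough estimation.
#' @param sg_n Savitzky-Golay window length (odd, samples).
#' @param p Normalization grid size for mean cycles (points over 0-100%).
#' @param phase_margin_pct Inset (% of cycle) applied when reading the
#'   single-support endpoint accelerations for the propulsion index, guarding
#'   the reads against contact transients.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(band = c(0.5, 20),
                             k_mad = 3,
                             cadence_max = 160,
                             refine_window = 0.06,
                             onset_window = 0.15,
                             label_window = 0.08,
                             smooth_threshold = 0.01,
                             sg_n = 9,
                             p = 101,
                             phase_margin_pct = 2) {
  check_number(k_mad, "k_mad", lower = 0, closed_lower = FALSE)
  check_number(cadence_max, "cadence_max", lower = 30, upper = 300)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    tg_param_error("band", "must be increasing positive band edges in Hz")
  }
  check_number(p, "p", lower = 11)
  check_number(phase_margin_pct, "phase_margin_pct", lower = 0, upper = 10)
  structure(
    list(
      band = band, k_mad = k_mad, cadence_max = cadence_max,
      refine_window = refine_window, onset_window = onset_window,
      label_window = label_window, smooth_threshold = smooth_threshold,
      sg_n = sg_n, p = as.integer(p), phase_margin_pct = phase_margin_pct
    ),
    class = "detection_config"
  )
}

# Estimate broadband noise SD from the second difference: smooth gait content
# has negligible curvature at the sample scale and the sparse contact
# transients are rejected by the MAD.
estimate_noise_sd <- function(x) {
  mad(diff(diff(x))) / sqrt(6)
}

is_noisy <- function(x, config) {
  amp <- max(abs(x - median(x)))
  amp > 0 && estimate_noise_sd(x) / amp > config$smooth_threshold
}

# Adaptive pre-smoothing for onset (curvature) estimation: identity on clean
# signals so they keep sample-exact features, Savitzky-Golay on noisy ones.
adaptive_smooth <- function(x, config) {
  if (!is_noisy(x, config)) {
    return(x)
  }
  n <- config$sg_n
  if (n %% 2 == 0) n <- n + 1
  as.numeric(signal::sgolayfilt(x, p = 3, n = n))
}

# Adaptive pre-smoothing for trough (minimum) location: a positive moving-
# average kernel cannot undershoot after the tall contact transient, so it
# never creates a spurious minimum below a shallow true trough.
adaptive_smooth_min <- function(x, config) {
  if (!is_noisy(x, config)) {
    return(x)
  }
  n <- config$sg_n
  if (n %% 2 == 0) n <- n + 1
  k <- rep(1 / n, n)
  sm <- stats::filter(x, k, sides = 2)
  sm[is.na(sm)] <- x[is.na(sm)]
  as.numeric(sm)
}

#' Detect initial contacts in a trunk acceleration trial
#'
#' Finds the sharp positive anteroposterior transients that mark initial
#' contact. The de-meaned AP channel is band-pass filtered; positive peaks
#' above an adaptive `k_mad * MAD` threshold with a cadence-prior minimum
#' spacing are refined to the raw-signal local maximum, then traced back to the
#' transient onset (the maximum-curvature point preceding the peak), which is
#' reported as the contact sample. Limbs are labelled
#' from the sign of the mediolateral channel just after each contact (positive
#' lobe = left, configurable convention); non-alternating labels trigger a
#' warning and strict alternation is restored by majority vote.
#'
#' @param signal A [trunk_signal()] of at least 3 s, sampled at >= 50 Hz.
#' @param config A [detection_config()].
#' @return A data frame of class `gait_events` with columns `index`, `time`,
#'   `limb`, ordered in time with alternating limbs.
#' @export
detect_initial_contacts <- function(signal, config = detection_config()) {
  stopifnot(inherits(signal, "trunk_signal"))
  fs <- sampling_rate(signal)
  if (fs < 50) tg_param_error("sampling_rate", "detector requires >= 50 Hz")
  if (nrow(signal) < 3 * fs) {
    tg_param_error("signal", "detector requires at least 3 s of data")
  }
  ap <- signal$ap - mean(signal$ap)

  ny <- fs / 2
  bf <- signal::butter(2, pmin(config$band / ny, 0.99), type = "pass")
  apf <- as.numeric(signal::filtfilt(bf, ap))

  thr <- config$k_mad * mad(apf)
  if (thr <= 0 || max(apf) <= thr) {
    tg_stop("no gait detected: no AP peaks above the adaptive threshold", "trunkgait_no_gait_error")
  }
  min_dist <- max(1L, round(60 / (2 * config$cadence_max) * fs))
  pk <- pracma::findpeaks(apf,
    minpeakheight = thr,
    minpeakdistance = min_dist
  )
  if (is.null(pk) || nrow(pk) < 2L) {
    tg_stop("no gait detected: fewer than two contact transients found", "trunkgait_no_gait_error")
  }
  peaks <- sort(pk[, 2])

  # refine each peak to the raw local maximum nearby
  half <- as.integer(max(1, round(config$refine_window * fs)))
  n <- length(ap)
  peaks <- vapply(peaks, function(p0) {
    lo <- max(1L, as.integer(p0) - half)
    hi <- min(n, as.integer(p0) + half)
    lo + which.max(ap[lo:hi]) - 1L
  }, integer(1))
  peaks <- unique(peaks)

  # onset: maximum curvature (second difference) looking back from each peak
  aps <- adaptive_smooth(ap, config)
  d2 <- c(0, diff(diff(aps)), 0)
  wback <- as.integer(max(2, round(config$onset_window * fs)))

  # contact transients are far sharper than any other positive AP feature
  # (e.g. the mid-swing lobe); drop candidate peaks whose local curvature is
  # a small fraction of the typical peak's
  wsh <- as.integer(max(2, round(0.06 * fs)))
  sharp <- vapply(peaks, function(p0) {
    lo <- max(2L, p0 - wsh)
    hi <- min(n - 1L, p0 + wsh)
    max(abs(d2[lo:hi]))
  }, numeric(1))
  keep <- sharp >= 0.2 * median(sharp)
  peaks <- peaks[keep]
  sharp <- sharp[keep]
  if (length(peaks) < 2L) {
    tg_stop("no gait detected: fewer than two contact transients found", "trunkgait_no_gait_error")
  }

  # step-regularity filter: a contact closer than 60% of the median step
  # interval to its neighbour is spurious; keep the sharper of the pair
  repeat {
    if (length(peaks) < 3L) break
    iv <- diff(peaks)
    short <- which(iv < 0.6 * median(iv))
    if (!length(short)) break
    pair <- c(short[1], short[1] + 1L)
    drop <- pair[which.min(sharp[pair])]
    peaks <- peaks[-drop]
    sharp <- sharp[-drop]
  }
  onsets <- vapply(peaks, function(p0) {
    lo <- max(2L, p0 - wback)
    hi <- max(lo, p0 - 1L)
    win <- d2[lo:hi]
    # onset = start of the contiguous half-maximum curvature run containing
    # the curvature peak: lands on the sample at (or right after) the
    # transient onset for any sub-sample grid alignment (a plain argmax can
    # drift a sample late on wide transients), while noise dips elsewhere in
    # the window cannot drag the estimate early
    j <- which.max(win)
    thr_run <- 0.5 * win[j]
    while (j > 1L && win[j - 1L] >= thr_run) j <- j - 1L
    lo + j - 1L
  }, integer(1))
  # the peak-to-onset offset is a property of the transient shape, constant
  # across events: snap outlier onsets to the robust median offset
  offs <- peaks - onsets
  med_off <- round(median(offs))
  bad <- abs(offs - med_off) > 3L
  onsets[bad] <- peaks[bad] - med_off
  ics <- sort(unique(pmax(1L, as.integer(onsets))))

  limb <- label_limbs(signal, ics, config)
  out <- data.frame(index = ics, time = signal$time[ics], limb = limb)
  out <- out[order(out$index), ]
  rownames(out) <- NULL
  structure(out, class = c("gait_events", "data.frame"), config = config)
}

label_limbs <- function(signal, ics, config) {
  fs <- sampling_rate(signal)
  wl <- max(1L, round(config$label_window * fs))
  n <- nrow(signal)
  ml <- signal$mediolateral - median(signal$mediolateral)
  sc <- vapply(ics, function(i) {
    mean(ml[i:min(n, i + wl)])
  }, numeric(1))
  limb <- ifelse(sc > 0, "left", "right")
  # enforce strict alternation; repair by majority vote over parity if needed
  if (length(limb) > 1 && any(limb[-1] == limb[-length(limb)])) {
    odd_left <- mean(limb[seq(1, length(limb), by = 2)] == "left")
    even_left <- if (length(limb) > 1) {
      mean(limb[seq(2, length(limb), by = 2)] == "left")
    } else {
      0
    }
    start_left <- odd_left >= even_left
    repaired <- rep(
      if (start_left) c("left", "right") else c("right", "left"),
      length.out = length(limb)
    )
    warning("non-alternating limb labels; falling back to strict alternation",
      call. = FALSE
    )
    limb <- repaired
  }
  limb
}

# Locate the AP minimum (toe-off of the swinging limb) between two successive
# initial-contact indices. On clean signals the raw argmin is sample-exact; on
# noisy signals the adaptively smoothed channel is used.
trough_between <- function(ap_smooth, i_from, i_to) {
  if (i_to - i_from < 3L) {
    tg_stop("interval too short to locate a trough", "trunkgait_event_error")
  }
  seg <- (i_from + 1L):(i_to - 1L)
  seg[which.min(ap_smooth[seg])]
}
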