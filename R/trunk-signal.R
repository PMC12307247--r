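#' Trunk acceleration trial
#'
#' Container for a triaxial trunk (S1-mounted sensor) acceleration recording on
#' a uniform time grid. All downstream gait analysis works on the
#' anteroposterior (AP) channel; the mediolateral channel carries the left/right
#' labelling convention and the vertical channel is retained for completeness.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced.
#' @param ap,vertical,mediolateral Numeric acceleration channels in m/s^2, all
#'   the same length as `time`.
#' @param sampling_rate Sampling rate in Hz. If missing it is inferred from
#'   `time`.
#'
#' @return An object of class `trunk_signal`: a data frame with columns
#'   `time`, `ap`, `vertical`, `mediolateral` and a `sampling_rate` attribute.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' sig <- trunk_signal(t, sin(2 * pi * t), cos(2 * pi * t), 0 * t)
#' sampling_rate(sig)
trunk_signal <- function(time, ap, vertical = NULL, mediolateral = NULL,
                         sampling_rate = NULL) {
  n <- length(time)
  vertical <- vertical %||% rep(0, n)
  mediolateral <- mediolateral %||% rep(0, n)
  if (length(ap) != n || length(vertical) != n || length(mediolateral) != n) {
    tg_param_error("ap/vertical/mediolateral", "all channels must match length(time)")
  }
  if (n < 2L) tg_param_error("time", "need at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) tg_param_error("time", "must be strictly increasing")
  if (diff(range(dt)) > 1e-9) {
    tg_param_error("time", "must be uniformly spaced (within 1e-9 s)")
  }
  fs <- sampling_rate %||% (1 / mean(dt))
  check_number(fs, "sampling_rate", lower = 0, closed_lower = FALSE)
  out <- data.frame(
    time = as.numeric(time), ap = as.numeric(ap),
    vertical = as.numeric(vertical), mediolateral = as.numeric(mediolateral)
  )
  structure(out, sampling_rate = fs, class = c("trunk_signal", "data.frame"))
}

#' @rdname trunk_signal
#' @param x A `trunk_signal`.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' @export
print.trunk_signal <- function(x, ...) {
  cat(sprintf(
    "<trunk_signal> %d samples @ %.6g Hz (%.2f s)\n",
    nrow(x), sampling_rate(x), nrow(x) / sampling_rate(x)
  ))
  cat(sprintf(
    "  AP range [%.3g, %.3g] m/s^2\n",
    min(x$ap), max(x$ap)
  ))
  invisible(x)
}

#' Read or write a trunk acceleration trial as CSV
#'
#' The on-disk dialect is a comma-separated UTF-8 file with a header row
#' `time_s, ap_ms2, vert_ms2, ml_ms2` and `.` as the decimal mark.
#'
#' @param path File path.
#' @return `read_trial_csv()` returns a [trunk_signal()];
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) tg_stop(paste0("file not found: ", path), "trunkgait_io_error")
  df <- read.csv(path)
  need <- c("time_s", "ap_ms2", "vert_ms2", "ml_ms2")
  if (!all(need %in% names(df))) {
    tg_stop(
      sprintf("trial CSV must have columns %s", paste(need, collapse = ", ")),
      "trunkgait_io_error"
    )
  }
  trunk_signal(df$time_s, df$ap_ms2, df$vert_ms2, df$ml_ms2)
}

#' @rdname read_trial_csv
#' @param signal A [trunk_signal()].
#' @export
write_trial_csv <- function(signal, path) {
  stopifnot(inherits(signal, "trunk_signal"))
  df <- data.frame(
    time_s = signal$time, ap_ms2 = signal$ap,
    vert_ms2 = signal$vertical, ml_ms2 = signal$mediolateral
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
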