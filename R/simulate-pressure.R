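# Synthetic standing plantar-pressure sequences.
#
# Two elliptical foot regions with a smooth dome-shaped pressure profile; the
# body weight is split left/right by the requested ratio. Per-frame postural
# sway moves load between the feet (total load per frame is conserved
# exactly), and per-cell texture noise redistributes pressure within a foot
# without changing its sum.

foot_masks <- function(params) {
  rows <- params$grid_shape[1]
  cols <- params$grid_shape[2]
  len <- params$foot_length_cells
  wid <- params$foot_width_cells
  r0 <- rows / 2
  c_left <- cols / 2 - (wid / 2 + 3)
  c_right <- cols / 2 + (wid / 2 + 3)
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ell <- function(cx) ((rr - r0) / (len / 2))^2 + ((cc - cx) / (wid / 2))^2
  left <- ell(c_left) <= 1
  right <- ell(c_right) <= 1
  if (any(left & right)) {
    tg_stop("foot regions overlap: widen the grid or narrow the feet", "trunkgait_config_error")
  }
  # dome profile: pressure highest at the foot centre, fading towards the
  # edge but with a floor well above the activation threshold, so every cell
  # of the true foot region is recoverable by segmentation
  dome <- function(mask, cx) {
    d <- 0.15 + 0.85 * pmax(0, 1 - ell(cx))
    d[!mask] <- 0
    d / sum(d)
  }
  list(
    left = left, right = right,
    left_profile = dome(left, c_left), right_profile = dome(right, c_right)
  )
}

#' Simulate a standing plantar-pressure sequence
#'
#' Generates a stack of pressure frames in which two disjoint elliptical foot
#' regions carry the body weight in a controllable left/right split. The
#' per-frame total load equals the body weight exactly; sway noise shifts load
#' between the feet frame by frame, so the time-averaged split converges to
#' `weight_split_left` as frames accumulate.
#'
#' @param params A [stance_sim_params()] object.
#' @param seed Integer seed.
#' @return A [pressure_sequence()] with attributes `truth` (the generating
#'   parameters) and `masks` (the ground-truth foot masks).
#' @export
#' @examples
#' seq50 <- simulate_pressure_sequence(stance_sim_params(duration = 1), seed = 1)
#' wd <- weight_distribution(seq50, segment_feet(seq50))
simulate_pressure_sequence <- function(params, seed = 1L) {
  if (!inherits(params, "stance_sim_params")) {
    params <- do.call(stance_sim_params, as.list(params))
  }
  with_sim_seed(seed, {
    n_frames <- max(1L, round(params$duration * params$frame_rate))
    masks <- foot_masks(params)
    split <- params$weight_split_left
    sway <- if (params$pressure_noise_sd > 0) {
      rnorm(n_frames, 0, params$pressure_noise_sd)
    } else {
      numeric(n_frames)
    }
    split_t <- pmin(1, pmax(0, split + sway))

    rows <- params$grid_shape[1]
    cols <- params$grid_shape[2]
    frames <- array(0, dim = c(n_frames, rows, cols))
    for (i in seq_len(n_frames)) {
      lp <- masks$left_profile
      rp <- masks$right_profile
      if (params$pressure_noise_sd > 0) {
        # within-foot texture noise, renormalized so foot sums are exact
        tex <- function(prof, mask) {
          p <- prof
          p[mask] <- p[mask] * pmax(0, 1 + rnorm(sum(mask), 0, params$pressure_noise_sd))
          s <- sum(p)
          if (s > 0) p / s else prof
        }
        lp <- tex(lp, masks$left)
        rp <- tex(rp, masks$right)
      }
      frames[i, , ] <- params$body_weight *
        (split_t[i] * lp + (1 - split_t[i]) * rp)
    }
    out <- pressure_sequence(frames, frame_rate = params$frame_rate)
    attr(out, "truth") <- params
    attr(out, "masks") <- masks[c("left", "right")]
    out
  })
}
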