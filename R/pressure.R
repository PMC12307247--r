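#' Plantar pressure frame sequence
#'
#' Stack of standing plantar-pressure frames from a square sensor matrix
#' (the emulated platform is a 480 x 480 mm, 48 x 48 = 2304 cell device
#' sampled at 40 frames/s).
#'
#' @param frames Numeric array `n_frames x rows x cols`, all values >= 0.
#' @param frame_rate Frames per second.
#' @param cell_size Cell edge length in mm (default 10).
#' @return An object of class `pressure_sequence`.
#' @export
pressure_sequence <- function(frames, frame_rate = 40, cell_size = 10) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    tg_param_error("frames", "must be a 3-D array (frames x rows x cols)")
  }
  if (any(frames < 0)) tg_param_error("frames", "pressure values must be >= 0")
  check_number(frame_rate, "frame_rate", lower = 0, closed_lower = FALSE)
  structure(
    list(frames = frames, frame_rate = frame_rate, cell_size = cell_size),
    class = "pressure_sequence"
  )
}

#' @export
print.pressure_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<pressure_sequence> %d frames of %dx%d cells @ %g fps (%.1f s)\n",
    d[1], d[2], d[3], x$frame_rate, d[1] / x$frame_rate
  ))
  invisible(x)
}

#' Segment the two feet in a pressure sequence
#'
#' Thresholds the time-averaged frame (a cell is active if its mean pressure
#' exceeds a fraction of the global maximum), labels connected components, and
#' groups them into exactly two feet by horizontal centroid; the foot with the
#' smaller column centroid is labelled left.
#'
#' @param sequence A [pressure_sequence()].
#' @param active_threshold Activation threshold as a fraction of the maximum
#'   time-averaged cell pressure (default 0.01).
#' @return A list of class `foot_regions` with logical masks `left` and
#'   `right` (disjoint) over the sensor grid.
#' @export
segment_feet <- function(sequence, active_threshold = 0.01) {
  stopifnot(inherits(sequence, "pressure_sequence"))
  mean_map <- apply(sequence$frames, c(2, 3), mean)
  mx <- max(mean_map)
  if (mx <= 0) tg_stop("no load: all pressure frames are empty", "trunkgait_no_load_error")
  active <- mean_map > active_threshold * mx
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(active * 1)))
  ncomp <- max(labels)
  if (ncomp < 2L) {
    tg_stop("cannot segment feet: fewer than two pressure regions found", "trunkgait_segmentation_error")
  }
  cols <- col(mean_map)
  centroid <- vapply(seq_len(ncomp), function(k) {
    mean(cols[labels == k])
  }, numeric(1))
  side <- if (ncomp == 2L) {
    ifelse(centroid == min(centroid), 1L, 2L)
  } else {
    km <- kmeans(centroid, centers = sort(range(centroid)))
    cl <- km$cluster
    # cluster with smaller centroid mean is left
    if (km$centers[1] <= km$centers[2]) cl else 3L - cl
  }
  left <- matrix(FALSE, nrow(mean_map), ncol(mean_map))
  right <- left
  for (k in seq_len(ncomp)) {
    if (side[k] == 1L) left[labels == k] <- TRUE else right[labels == k] <- TRUE
  }
  structure(list(left = left, right = right), class = "foot_regions")
}

#' @export
print.foot_regions <- function(x, ...) {
  cat(sprintf(
    "<foot_regions> left: %d cells, right: %d cells\n",
    sum(x$left), sum(x$right)
  ))
  invisible(x)
}

#' Per-foot body-weight distribution percentages
#'
#' Sums the load over each foot region per frame, averages over all frames,
#' and expresses the result as percentages that sum exactly to 100. The
#' percentages are calibration-invariant: rescaling all frames leaves them
#' unchanged.
#'
#' @param sequence A [pressure_sequence()].
#' @param regions A `foot_regions` object from [segment_feet()].
#' @return Named numeric vector `c(left_pct, right_pct)`.
#' @export
weight_distribution <- function(sequence, regions) {
  stopifnot(inherits(sequence, "pressure_sequence"), inherits(regions, "foot_regions"))
  if (any(regions$left & regions$right)) {
    tg_stop("foot regions overlap", "trunkgait_segmentation_error")
  }
  n <- dim(sequence$frames)[1]
  lsum <- vapply(seq_len(n), function(i) {
    sum(sequence$frames[i, , ][regions$left])
  }, numeric(1))
  rsum <- vapply(seq_len(n), function(i) {
    sum(sequence$frames[i, , ][regions$right])
  }, numeric(1))
  ml <- mean(lsum)
  mr <- mean(rsum)
  if (ml + mr <= 0) tg_stop("no load: zero total pressure in the foot regions", "trunkgait_no_load_error")
  c(left_pct = 100 * ml / (ml + mr), right_pct = 100 * mr / (ml + mr))
}

#' Read or write a pressure sequence as per-frame CSV files
#'
#' Frames are stored as plain CSV matrices `frame_000001.csv, ...` in a
#' directory together with a `sequence.json` sidecar holding the frame rate
#' and grid shape.
#'
#' @param dir Directory path.
#' @return `read_pressure_csv()` returns a [pressure_sequence()];
#'   `write_pressure_csv()` returns `dir` invisibly.
#' @export
read_pressure_csv <- function(dir) {
  meta_path <- file.path(dir, "sequence.json")
  if (!file.exists(meta_path)) {
    tg_stop(paste0("missing sidecar: ", meta_path), "trunkgait_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$", full.names = TRUE))
  if (!length(files)) tg_stop("no frame CSVs found", "trunkgait_io_error")
  mats <- lapply(files, function(f) as.matrix(read.csv(f, header = FALSE)))
  arr <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  pressure_sequence(arr,
    frame_rate = meta$frame_rate,
    cell_size = meta$cell_size %||% 10
  )
}

#' @rdname read_pressure_csv
#' @param sequence A [pressure_sequence()].
#' @export
write_pressure_csv <- function(sequence, dir) {
  stopifnot(inherits(sequence, "pressure_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(sequence$frames)[1]
  for (i in seq_len(n)) {
    write.table(sequence$frames[i, , ],
      file.path(dir, sprintf("frame_%06d.csv", i)),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  jsonlite::write_json(
    list(
      frame_rate = sequence$frame_rate, cell_size = sequence$cell_size,
      n_frames = n, grid_shape = dim(sequence$frames)[2:3]
    ),
    file.path(dir, "sequence.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}
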