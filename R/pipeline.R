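#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline with documented defaults.
#' The configuration round-trips losslessly through YAML
#' ([write_config()] / [read_config()]) and its hash is embedded in every
#' report for provenance.
#'
#' @param detection A [detection_config()].
#' @param p Normalization grid size (points over 0-100% of the cycle).
#' @param si_window Cycle window for the symmetry index: `"full"` (default),
#'   `"stance"` or `"swing"`.
#' @param propulsion_units `"ms2"` or `"g"` for the propulsion ratio.
#' @param phase_margin_pct Endpoint inset (% of cycle) for the propulsion
#'   reads.
#' @param alpha Significance level for the statistical gate and tests.
#' @param gate `"both"` or `"pooled"` normality gate.
#' @param var_equal Pooled-variance t test instead of Welch.
#' @param min_cycles_per_limb Complete cycles required per limb.
#' @param verbose Emit one structured log line per stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            p = 101,
                            si_window = c("full", "stance", "swing"),
                            propulsion_units = c("ms2", "g"),
                            phase_margin_pct = 2,
                            alpha = 0.05,
                            gate = c("both", "pooled"),
                            var_equal = FALSE,
                            min_cycles_per_limb = 2L,
                            verbose = FALSE) {
  structure(
    list(
      detection = detection, p = as.integer(p),
      si_window = match.arg(si_window),
      propulsion_units = match.arg(propulsion_units),
      phase_margin_pct = phase_margin_pct,
      alpha = alpha, gate = match.arg(gate), var_equal = var_equal,
      min_cycles_per_limb = as.integer(min_cycles_per_limb),
      verbose = verbose
    ),
    class = "pipeline_config"
  )
}

#' Serialize or restore a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns a [pipeline_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$detection <- unclass(lst$detection)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  det <- do.call(detection_config, lst$detection)
  lst$detection <- NULL
  do.call(pipeline_config, c(list(detection = det), lst))
}

#' @rdname write_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

log_stage <- function(config, stage, subject_id, ...) {
  if (isTRUE(config$verbose)) {
    kv <- list(...)
    msg <- paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " ")
    message(sprintf("[%s] subject=%s %s", stage, subject_id, msg))
  }
}

with_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, trunkgait_error = function(e) {
    e$message <- sprintf("[stage %s, subject %s] %s", stage, subject_id, e$message)
    stop(e)
  })
}

# Restrict the two mean cycles to a common stance or swing window (grid index
# up to the smaller of the two limbs' mean stance percentages) before the
# correlation; the default correlates the full normalized cycle.
si_window_vectors <- function(mc_sound, mc_amp, phases, window) {
  if (window == "full") {
    return(list(s = mc_sound$ap_norm, a = mc_amp$ap_norm))
  }
  p <- length(mc_sound$ap_norm)
  k <- round(min(
    phases$sound$d_stance_mean,
    phases$amputated$d_stance_mean
  ) / 100 * (p - 1))
  k <- max(3L, min(p - 3L, k))
  if (window == "stance") {
    list(s = mc_sound$ap_norm[1:k], a = mc_amp$ap_norm[1:k])
  } else {
    list(s = mc_sound$ap_norm[(k + 1):p], a = mc_amp$ap_norm[(k + 1):p])
  }
}

#' Analyze one subject end to end
#'
#' Runs the full pipeline for one subject: event detection, cycle
#' segmentation, normalization/averaging, the four indices, standing
#' weight-distribution, and the spatiotemporal parameters. Inputs may be file
#' paths (trial CSV, pressure frame directory) or in-memory objects. A missing
#' pressure input leaves the body-weight distribution `NA` while the gait
#' indices are still computed.
#'
#' @param trial A [trunk_signal()], a `simulated_trial`, or a trial CSV path.
#' @param pressure A [pressure_sequence()], a pressure CSV directory, or
#'   `NULL`.
#' @param metadata A list with `subject_id`, `group` (`"AK"`/`"BK"` or other
#'   labels), `amputated_side` (`"left"`/`"right"`), and `stride_length`
#'   (named per-limb vector in metres).
#' @param config A [pipeline_config()].
#' @param intermediates Return the intermediate objects (events, cycles, mean
#'   cycles) alongside the result row.
#' @return A one-row data frame of class `subject_result` (or, with
#'   `intermediates = TRUE`, a list with `result` and the intermediates).
#' @export
run_subject <- function(trial, pressure = NULL, metadata = list(),
                        config = pipeline_config(), intermediates = FALSE) {
  sid <- metadata$subject_id %||% "unknown"
  side <- metadata$amputated_side %||% "left"
  if (!side %in% c("left", "right")) {
    tg_param_error("amputated_side", "must be 'left' or 'right'")
  }

  if (inherits(trial, "simulated_trial")) trial <- trial$signal
  if (is.character(trial)) {
    trial <- with_stage("read_trial", sid, read_trial_csv(trial))
  }

  events <- with_stage("detect", sid, detect_initial_contacts(trial, config$detection))
  log_stage(config, "detect", sid, events = nrow(events))

  cycles <- with_stage(
    "segment", sid,
    segment_cycles(events, trial,
      config = config$detection,
      min_cycles_per_limb = config$min_cycles_per_limb
    )
  )
  log_stage(config, "segment", sid,
    cycles = nrow(cycles),
    discarded = nrow(events) - nrow(cycles) - 2L
  )

  mcs <- with_stage("normalize", sid, normalize_and_average(cycles, trial, p = config$p))
  mcs_role <- assign_limb_roles(mcs, side)
  cycles_role <- assign_limb_roles(cycles, side)
  phases <- phase_summary(cycles_role, mcs_role)

  si <- with_stage("indices", sid, {
    v <- si_window_vectors(mcs_role$sound, mcs_role$amputated, phases, config$si_window)
    symmetry_index(v$s, v$a)
  })
  prop <- vapply(c("sound", "amputated"), function(role) {
    ph <- single_support_phase_from_mean_cycle(mcs_role[[role]],
      margin_pct = config$phase_margin_pct
    )
    propulsion_index(ph, units = config$propulsion_units)
  }, numeric(1))
  qi <- quality_index(phases)

  # standing pressure -> body-weight distribution
  bwd_pct <- NA_real_
  w_sound <- w_amp <- NA_real_
  if (!is.null(pressure)) {
    if (is.character(pressure)) {
      pressure <- with_stage("read_pressure", sid, read_pressure_csv(pressure))
    }
    wd <- with_stage("pressure", sid, {
      regions <- segment_feet(pressure)
      weight_distribution(pressure, regions)
    })
    log_stage(config, "pressure", sid, frames = dim(pressure$frames)[1])
    w_sound <- if (side == "left") wd[["right_pct"]] else wd[["left_pct"]]
    w_amp <- 100 - w_sound
    bwd_pct <- bwd(w_sound, w_amp)
  }

  stride <- metadata$stride_length
  if (!is.null(stride) && all(c("left", "right") %in% names(stride))) {
    stride_role <- c(
      sound = unname(stride[[if (side == "left") "right" else "left"]]),
      amputated = unname(stride[[side]])
    )
  } else {
    stride_role <- stride
  }
  st <- with_stage("spatiotemporal", sid, spatiotemporal(events, stride_role))

  result <- data.frame(
    subject_id = sid,
    group = metadata$group %||% NA_character_,
    amputated_side = side,
    symmetry_index = si,
    propulsion_amputated = unname(prop["amputated"]),
    propulsion_sound = unname(prop["sound"]),
    quality_amputated = unname(qi[["amputated"]]),
    quality_sound = unname(qi[["sound"]]),
    bwd_pct = unname(bwd_pct),
    weight_sound_pct = unname(w_sound),
    weight_amputated_pct = unname(w_amp),
    cadence = st$cadence,
    velocity = st$velocity,
    stride_amputated = unname(stride_role[["amputated"]]),
    stride_sound = unname(stride_role[["sound"]]),
    walk_distance_2min = st$walk_distance_2min,
    n_cycles = nrow(cycles)
  )
  class(result) <- c("subject_result", "data.frame")
  if (intermediates) {
    list(
      result = result, events = events, cycles = cycles,
      mean_cycles = mcs_role, phases = phases
    )
  } else {
    result
  }
}

subject_from_dataset <- function(ds, config) {
  run_subject(
    trial = ds$trial,
    pressure = ds$pressure,
    metadata = list(
      subject_id = ds$subject_id, group = ds$group,
      amputated_side = ds$amputated_side,
      stride_length = ds$metadata$stride_length
    ),
    config = config
  )
}

#' Analyze a cohort and produce group reports
#'
#' Accepts either a simulated [simulate_cohort()] object or a manifest CSV
#' listing one subject per row (columns `subject_id`, `group`,
#' `amputated_side`, `trial_csv`, `pressure_dir` (may be empty),
#' `stride_length_left`, `stride_length_right`). Produces the per-subject
#' result table, the per-group mean (SD) summary, and the normality-gated
#' comparisons; optionally writes them (JSON + CSV, stamped with the config
#' hash) to `out_dir`.
#'
#' @param cohort A `cohort` object or a manifest CSV path.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for report files.
#' @return A list of class `cohort_report`: `results` (subject rows),
#'   `summary` ([summarize_groups()]), `comparisons`
#'   ([compare_all_variables()]), and `config_hash`.
#' @export
run_cohort <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  if (is.character(cohort)) {
    subjects <- read_manifest(cohort)
    rows <- lapply(subjects, function(m) {
      run_subject(
        trial = m$trial_csv,
        pressure = m$pressure_dir,
        metadata = m, config = config
      )
    })
  } else if (inherits(cohort, "cohort")) {
    rows <- lapply(cohort, subject_from_dataset, config = config)
  } else {
    tg_param_error("cohort", "must be a cohort object or a manifest CSV path")
  }
  if (!length(rows)) tg_stop("empty manifest: no subjects to analyze", "trunkgait_io_error")
  results <- do.call(rbind, rows)
  summary <- summarize_groups(results)
  comparisons <- if (length(unique(results$group)) == 2L &&
    all(table(results$group) >= 3L)) {
    compare_all_variables(results,
      alpha = config$alpha, gate = config$gate,
      var_equal = config$var_equal
    )
  } else {
    NULL
  }
  report <- structure(
    list(
      results = results, summary = summary, comparisons = comparisons,
      config_hash = config_hash(config)
    ),
    class = "cohort_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %d subjects; config %s\n",
    nrow(x$results), x$config_hash
  ))
  if (!is.null(x$comparisons)) {
    print(as.data.frame(x$comparisons)[, c("variable", "test_used", "p_value")])
  }
  invisible(x)
}

read_manifest <- function(path) {
  if (!file.exists(path)) tg_stop(paste0("manifest not found: ", path), "trunkgait_io_error")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE), error = function(e) {
    tg_stop(paste0("malformed manifest: ", conditionMessage(e)), "trunkgait_io_error")
  })
  if (nrow(df) == 0L) tg_stop("empty manifest: no subjects listed", "trunkgait_io_error")
  need <- c(
    "subject_id", "group", "amputated_side", "trial_csv",
    "stride_length_left", "stride_length_right"
  )
  for (nm in need) {
    if (!nm %in% names(df)) {
      tg_stop(sprintf("malformed manifest: missing column `%s`", nm), "trunkgait_io_error")
    }
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    if (!row$amputated_side %in% c("left", "right") ||
        !is.finite(row$stride_length_left)) {
      tg_stop(sprintf("malformed manifest: line %d invalid", i + 1L), "trunkgait_io_error")
    }
    list(
      subject_id = row$subject_id, group = row$group,
      amputated_side = row$amputated_side,
      trial_csv = row$trial_csv,
      pressure_dir = if (!is.null(row$pressure_dir) && nzchar(row$pressure_dir) &&
        !is.na(row$pressure_dir)) row$pressure_dir else NULL,
      stride_length = c(
        left = row$stride_length_left,
        right = row$stride_length_right
      )
    )
  })
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  jsonlite::write_json(
    c(list(config_hash = report$config_hash), split(res, res$subject_id)),
    file.path(out_dir, "subjects.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  write.csv(as.data.frame(report$summary),
    file.path(out_dir, "group_summary.csv"),
    row.names = FALSE
  )
  if (!is.null(report$comparisons)) {
    write.csv(as.data.frame(report$comparisons),
      file.path(out_dir, "comparisons.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(
      list(
        config_hash = report$config_hash,
        comparisons = as.data.frame(report$comparisons)
      ),
      file.path(out_dir, "comparisons.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(out_dir)
}

#' Materialize a simulated cohort to disk
#'
#' Writes each subject's trial CSV (and optionally the pressure frames) plus a
#' manifest CSV that [run_cohort()] can consume.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @param write_pressure Also write per-frame pressure CSVs (bulky; off by
#'   default).
#' @return The manifest path, invisibly.
#' @export
write_cohort_files <- function(cohort, dir, write_pressure = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(ds) {
    trial_csv <- file.path(dir, paste0(ds$subject_id, "_trial.csv"))
    write_trial_csv(ds$trial$signal, trial_csv)
    pdir <- ""
    if (write_pressure) {
      pdir <- file.path(dir, paste0(ds$subject_id, "_pressure"))
      write_pressure_csv(ds$pressure, pdir)
    }
    data.frame(
      subject_id = ds$subject_id, group = ds$group,
      amputated_side = ds$amputated_side,
      trial_csv = trial_csv, pressure_dir = pdir,
      stride_length_left = ds$metadata$stride_length[["left"]],
      stride_length_right = ds$metadata$stride_length[["right"]]
    )
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
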