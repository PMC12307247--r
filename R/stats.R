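# Cohort-level statistics: per-group summaries in the report schema and the
# normality-gated two-sample comparison.

# Report variable order (the study's table schema).
tg_variables <- function() {
  c(
    "bwd_pct", "walk_distance_2min", "velocity", "cadence",
    "symmetry_index", "propulsion_amputated", "propulsion_sound",
    "quality_amputated", "quality_sound",
    "stride_amputated", "stride_sound"
  )
}

#' Per-group mean (SD) summary of subject results
#'
#' @param results A data frame of subject results (one row per subject) with a
#'   `group` column, e.g. from [run_cohort()] or `rbind`-ed [run_subject()]
#'   rows.
#' @param variables Variables to summarize, in report order.
#' @return A data frame of class `group_summary`: one row per variable with
#'   per-group `mean` and `sd` columns and per-group `n` in the attributes.
#' @export
summarize_groups <- function(results, variables = tg_variables()) {
  if (!is.data.frame(results) || !"group" %in% names(results)) {
    tg_param_error("results", "must be a data frame with a `group` column")
  }
  groups <- unique(results$group)
  if (any(table(results$group) < 2)) {
    tg_stop("each group needs at least 2 subjects", "trunkgait_insufficient_sample_error")
  }
  variables <- intersect(variables, names(results))
  rows <- lapply(variables, function(v) {
    row <- data.frame(variable = v)
    for (g in groups) {
      x <- results[[v]][results$group == g]
      row[[paste0("mean_", g)]] <- mean(x, na.rm = TRUE)
      row[[paste0("sd_", g)]] <- sd(x, na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  structure(out,
    class = c("group_summary", "data.frame"),
    n = table(results$group)
  )
}

#' Normality-gated two-group comparison
#'
#' Runs a Shapiro-Wilk normality test in each group; if both groups pass at
#' `alpha` (the default gate; set `gate = "pooled"` to test the pooled
#' residuals instead), the groups are compared with an unpaired two-sided
#' Student t test (Welch by default), otherwise with the Wilcoxon rank-sum
#' (Mann-Whitney) test.
#'
#' @param x,y Numeric samples for the two groups (>= 3 values each).
#' @param alpha Significance level for both the gate and the comparison
#'   (default 0.05).
#' @param gate `"both"` (default): both groups must pass normality;
#'   `"pooled"`: Shapiro-Wilk on the pooled mean-centred groups.
#' @param var_equal Use the pooled-variance t statistic instead of Welch.
#' @param variable Optional variable name carried into the result.
#' @return A list of class `comparison_result` with `variable`,
#'   `normality_p` (per group), `test_used` (`"student_t"` or `"wilcoxon"`),
#'   `p_value`, `significant`, and per-group `mean` and `sd`.
#' @export
#' @examples
#' compare_groups(rnorm(14), rnorm(15))
compare_groups <- function(x, y, alpha = 0.05,
                           gate = c("both", "pooled"),
                           var_equal = FALSE,
                           variable = NA_character_) {
  gate <- match.arg(gate)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    tg_stop("insufficient sample: Shapiro-Wilk needs at least 3 values per group", "trunkgait_insufficient_sample_error")
  }
  sw <- function(v) {
    if (sd(v) == 0) {
      return(0) # a constant sample is maximally non-normal
    }
    shapiro.test(v)$p.value
  }
  norm_p <- c(sw(x), sw(y))
  normal <- if (gate == "both") {
    all(norm_p >= alpha)
  } else {
    pooled <- c(x - mean(x), y - mean(y))
    sw(pooled) >= alpha
  }
  if (normal) {
    test_used <- "student_t"
    p <- t.test(x, y, var.equal = var_equal)$p.value
  } else {
    test_used <- "wilcoxon"
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  }
  structure(
    list(
      variable = variable,
      normality_p = norm_p,
      test_used = test_used,
      p_value = p,
      significant = p < alpha,
      mean = c(mean(x), mean(y)),
      sd = c(sd(x), sd(y)),
      n = c(length(x), length(y)),
      alpha = alpha
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result>%s %s: p = %.4g (%ssignificant at alpha = %g)\n",
    if (is.na(x$variable)) "" else paste0(" ", x$variable),
    x$test_used, x$p_value, if (x$significant) "" else "not ", x$alpha
  ))
  cat(sprintf(
    "  group means %.3g (SD %.3g) vs %.3g (SD %.3g); normality p = %.3g, %.3g\n",
    x$mean[1], x$sd[1], x$mean[2], x$sd[2], x$normality_p[1], x$normality_p[2]
  ))
  invisible(x)
}

#' Compare every report variable between two groups
#'
#' @inheritParams summarize_groups
#' @inheritParams compare_groups
#' @return A data frame of class `comparison_table`: one row per variable with
#'   group means/SDs, normality p-values, the gated test used and its p-value.
#' @export
compare_all_variables <- function(results, variables = tg_variables(),
                                  alpha = 0.05, gate = "both",
                                  var_equal = FALSE) {
  groups <- unique(results$group)
  if (length(groups) != 2L) {
    tg_param_error("results", "need exactly two groups")
  }
  variables <- intersect(variables, names(results))
  rows <- lapply(variables, function(v) {
    x <- results[[v]][results$group == groups[1]]
    y <- results[[v]][results$group == groups[2]]
    cr <- compare_groups(x, y,
      alpha = alpha, gate = gate,
      var_equal = var_equal, variable = v
    )
    data.frame(
      variable = v,
      mean_1 = cr$mean[1], sd_1 = cr$sd[1],
      mean_2 = cr$mean[2], sd_2 = cr$sd[2],
      normality_p_1 = cr$normality_p[1], normality_p_2 = cr$normality_p[2],
      test_used = cr$test_used, p_value = cr$p_value,
      significant = cr$significant
    )
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_1$", paste0("_", groups[1]), names(out))
  names(out) <- sub("_2$", paste0("_", groups[2]), names(out))
  structure(out, class = c("comparison_table", "data.frame"), groups = groups)
}
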