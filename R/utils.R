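#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx kmeans mad median p.adjust quantile rnorm sd
#'   shapiro.test t.test wilcox.test var cor
#' @importFrom utils read.csv write.csv head tail
NULL

# Classed conditions: every user-facing failure carries a subclass so callers
# (and tests) can distinguish parameter errors from data problems.
tg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "trunkgait_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

tg_param_error <- function(field, msg) {
  tg_stop(sprintf("invalid parameter `%s`: %s", field, msg), "trunkgait_param_error")
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    tg_param_error(field, "must be a single finite number")
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    tg_param_error(field, sprintf(
      "must be in %s%g, %g%s (got %g)",
      if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

# All simulation randomness goes through withr::with_seed so that generation
# is reproducible and never disturbs the caller's RNG state.
with_sim_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    tg_param_error("seed", "must be a single finite integer")
  }
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31;
# arithmetic in doubles, exact well below 2^53).
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483562)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
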