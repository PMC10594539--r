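#' Score a rudimentary visual-acuity ladder
#'
#' Applies the pass rules of the low-vision acuity battery: for the single
#' tumbling E ladder (0.8-2.6 LogMAR) a level is passed when at least half
#' the trials are correct (4 of 8); for the grating ladder (2.3-2.9 LogMAR)
#' when at least seven eighths are correct (7 of 8). The assigned visual
#' acuity is the best (numerically smallest) level passed; if no level is
#' passed anywhere the conventional ceiling of 3.0 LogMAR is assigned.
#'
#' @param trials data.frame with columns `level` (LogMAR), `n_correct`,
#'   `n_total` and optionally `test` ("E" or "grating"; inferred from the
#'   ladder membership when absent: 0.8, 1.0, ..., 2.6 are tumbling-E
#'   levels, 2.3, 2.5, 2.7, 2.9 grating levels).
#' @return An object of class `ladder_result`: list with `va_logmar` and the
#'   annotated `trials` (logical `passed` column).
#' @export
brvt_score <- function(trials) {
  trials <- as.data.frame(trials)
  req <- c("level", "n_correct", "n_total")
  if (!all(req %in% names(trials)))
    stopf("trials must have columns %s", paste(req, collapse = ", "))
  if (any(trials$n_total <= 0) || any(trials$n_correct < 0) ||
      any(trials$n_correct > trials$n_total) ||
      any(trials$n_correct != round(trials$n_correct)))
    stopf("malformed trial counts")
  e_levels <- seq(0.8, 2.6, by = 0.2)
  g_levels <- c(2.3, 2.5, 2.7, 2.9)
  near <- function(x, set) vapply(x, function(v) any(abs(v - set) < 1e-9), logical(1))
  if (!"test" %in% names(trials)) {
    trials$test <- ifelse(near(trials$level, e_levels), "E",
                          ifelse(near(trials$level, g_levels), "grating", NA))
    if (anyNA(trials$test))
      stopf("cannot infer test type for level(s): %s",
            paste(trials$level[is.na(trials$test)], collapse = ", "))
  }
  frac_needed <- ifelse(trials$test == "E", 4 / 8, 7 / 8)
  trials$passed <- trials$n_correct >= frac_needed * trials$n_total
  va <- if (any(trials$passed)) min(trials$level[trials$passed]) else 3.0
  structure(list(va_logmar = va, trials = trials), class = "ladder_result")
}

#' @export
print.ladder_result <- function(x, ...) {
  cat(sprintf("Visual acuity: %.1f LogMAR (%d level(s) passed of %d tested)\n",
              x$va_logmar, sum(x$trials$passed), nrow(x$trials)))
  invisible(x)
}

#' Validation block around a measured acuity
#'
#' After the adaptive ladder, the measured VA is validated by retesting at
#' three levels (VA - 0.2, VA, VA + 0.2 LogMAR) with 12 trials each.
#'
#' @param va measured visual acuity, LogMAR.
#' @return data.frame with columns `level` and `n_trials`; attribute
#'   `below_floor` flags levels under the 0.8 LogMAR ladder floor.
#' @export
validation_block <- function(va) {
  stopifnot(is.finite(va))
  levels <- c(va - 0.2, va, va + 0.2)
  structure(data.frame(level = levels, n_trials = 12L),
            below_floor = levels < 0.8 - 1e-9)
}
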