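# Venous-occlusion plethysmography: slope of limb-volume increase during
# brief venous occlusion, in %/min, equals blood inflow in ml/min per
# 100 ml of limb -- a unit relabelling, not a computation.

#' Convert an occlusion slope to leg blood flow
#'
#' @param slope Limb-volume slope during venous occlusion, % per minute.
#' @return Blood flow, ml/min per 100 ml leg (numerically equal).
#' @export
slope_to_flow <- function(slope) {
  if (any(!is.finite(slope)) || any(slope < 0)) {
    lt_stop("occlusion slope must be finite and non-negative",
            "lt_invalid_reading_error")
  }
  slope
}

#' Leg blood flow and plasma flow for one study occasion
#'
#' The pre- and post-sampling occlusion series bracket the arteriovenous
#' sampling period; their phase means are averaged (not pooled), and
#' plasma flow is blood flow times (1 - hematocrit).
#'
#' @param pre,post Numeric vectors of occlusion slopes (%/min), nominally
#'   10 readings per phase.
#' @param hematocrit Fraction in (0, 1).
#' @param min_readings Minimum readings required per phase (default 5).
#' @param trim If `TRUE`, drop readings further than 3 median absolute
#'   deviations from the phase median before averaging (off by default:
#'   no automatic outlier rejection).
#' @return An object of class `flow_result`: `blood_flow`, `plasma_flow`
#'   (ml/min/100 ml leg), `n_readings_used`, `phase_means`.
#' @export
occasion_flow <- function(pre, post, hematocrit, min_readings = 5,
                          trim = FALSE) {
  if (length(hematocrit) != 1 || !is.finite(hematocrit) ||
      hematocrit < 0 || hematocrit >= 1) {
    lt_stop("hematocrit must be a single value in [0, 1)",
            "lt_validation_error")
  }
  phases <- list(pre = slope_to_flow(pre), post = slope_to_flow(post))
  if (trim) {
    phases <- lapply(phases, function(v) {
      med <- median(v)
      madv <- 1.4826 * median(abs(v - med))
      # zero MAD (a majority of identical readings): keep the majority
      if (madv == 0) v[v == med] else v[abs(v - med) <= 3 * madv]
    })
  }
  n <- vapply(phases, length, integer(1))
  if (any(n < min_readings)) {
    lt_stop(sprintf("phase has %d reading(s); at least %d required",
                    min(n), min_readings), "lt_insufficient_data_error")
  }
  phase_means <- vapply(phases, mean, numeric(1))
  blood_flow <- mean(phase_means)
  structure(list(blood_flow = blood_flow,
                 plasma_flow = blood_flow * (1 - hematocrit),
                 n_readings_used = sum(n),
                 phase_means = phase_means),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> blood %.3f, plasma %.3f ml/min/100 ml (n = %d readings)\n",
              x$blood_flow, x$plasma_flow, x$n_readings_used))
  invisible(x)
}

#' Fit an occlusion slope from a raw volume-vs-time trace
#'
#' Optional pre-processing for digitized plethysmography traces: ordinary
#' least squares on the initial post-occlusion window, where venous
#' outflow is still negligible and volume rises linearly.
#'
#' @param time_s Time since occlusion onset, seconds.
#' @param volume_pct Limb volume change, % of limb volume.
#' @param window_s Length of the initial fitting window, seconds
#'   (default 15).
#' @return Slope in %/min.
#' @export
trace_to_slope <- function(time_s, volume_pct, window_s = 15) {
  keep <- time_s <= window_s
  if (sum(keep) < 3) {
    lt_stop("fewer than 3 trace points inside the fitting window",
            "lt_insufficient_data_error")
  }
  fit <- lm(volume_pct[keep] ~ time_s[keep])
  unname(coef(fit)[2]) * 60
}
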