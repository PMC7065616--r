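#' Fit the pressure-sensor to force calibration
#'
#' Ordinary least-squares affine fit of gauge force (newtons) against the
#' internal pressure-sensor readout (kPa), reproducing the two-step chain of
#' a strain gauge precalibrated with known weights and then read against the
#' sensor. The fit's R-squared is reported so departures from linearity are
#' visible rather than hidden.
#'
#' @param pressure_readouts Sensor readouts in kPa (>= 2 distinct values).
#' @param gauge_forces Matching gauge forces in newtons.
#' @return An object of class `calibration_model` with fields `slope`
#'   (N/kPa), `intercept` (N), `fit_r2` and `n_points`.
#' @examples
#' p <- c(2, 6, 10, 14, 18.18)
#' cal <- fit_calibration(p, 0.006645 * p)
#' cal$slope      # 0.006645 N/kPa
#' @export
fit_calibration <- function(pressure_readouts, gauge_forces) {
  if (length(pressure_readouts) != length(gauge_forces))
    cp_stop("corneapuff_invalid_spec", "inputs must have equal length")
  if (length(pressure_readouts) < 2L)
    cp_stop("corneapuff_invalid_spec", "need at least 2 calibration points")
  if (length(unique(pressure_readouts)) < 2L)
    cp_stop("corneapuff_degenerate_design",
            "all pressure readouts identical; slope is unidentifiable")
  fit <- stats::lm(gauge_forces ~ pressure_readouts)
  # R^2 computed directly: summary.lm warns on (common) exact calibrations
  tss <- sum((gauge_forces - mean(gauge_forces))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  r2 <- min(max(r2, 0), 1)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit_r2 = r2, n_points = length(pressure_readouts)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> force = %.6g N/kPa x pressure + %.3g N (R2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$fit_r2, x$n_points))
  invisible(x)
}

#' Convert a pressure trace to a force trace
#'
#' Applies a fitted [fit_calibration()] model elementwise:
#' `force = slope * pressure + intercept`. Timestamps pass through unchanged.
#'
#' @param pressure A data.frame with columns `time_s` and `value` (kPa), as
#'   returned by [read_trace_csv()].
#' @param model A `calibration_model`.
#' @return A [force_trace()].
#' @export
pressure_to_force <- function(pressure, model) {
  if (!inherits(model, "calibration_model"))
    cp_stop("corneapuff_invalid_spec", "model must be a calibration_model")
  if (!is.data.frame(pressure) || !all(c("time_s", "value") %in% names(pressure)))
    cp_stop("corneapuff_invalid_trace",
            "pressure must be a data.frame with columns time_s,value")
  force_trace(pressure$time_s, model$slope * pressure$value + model$intercept)
}

#' Gauge weights to force
#'
#' Converts calibration weights in grams to force in newtons with
#' g = 9.81 m/s^2 (1 g maps to 9.81 mN).
#'
#' @param grams Weights in grams.
#' @return Forces in newtons.
#' @export
weights_to_force <- function(grams) grams * 1e-3 * 9.81

#' The default synthetic sensor calibration
#'
#' A noiseless five-point calibration whose slope maps a peak sensor readout
#' of 18.18 kPa to 120.8 mN — the operating point of the stimulus used
#' throughout the synthetic cohorts.
#'
#' @return A `calibration_model` with slope 0.0066447 N/kPa, intercept 0.
#' @export
default_calibration <- function() {
  p <- c(3, 7, 11, 15, 18.18)
  fit_calibration(p, (0.1208 / 18.18) * p)
}
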