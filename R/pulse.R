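#' Air-puff pulse specification
#'
#' Parameterizes the temporal profile of the force exerted by the air-puff
#' chamber on the corneal apex. The default matches the record geometry of a
#' noncontact-tonometer stimulus sampled at the OCT A-scan rate: 1600 samples
#' at 50 kHz (32 ms) peaking at 120.8 mN.
#'
#' Two shapes are available. `raised_cosine` rises and falls as half-cosines,
#' peaking `rise_time` after onset; it starts and ends exactly at zero and its
#' time integral is `peak_force * (total_duration - delay) / 2` regardless of
#' asymmetry. `gamma` is a right-skewed gamma-like profile
#' `(t/tr)^2 exp(2 (1 - t/tr))` peaking at `rise_time`, with a cosine taper
#' over the final 10% of the record so the trace ends at zero.
#'
#' @param peak_force Peak force in newtons (> 0).
#' @param total_duration Record duration in seconds.
#' @param rise_time Time from stimulus onset to the force peak, in seconds;
#'   must lie in (0, active duration).
#' @param shape `"raised_cosine"` (default) or `"gamma"`.
#' @param sample_rate Sampling rate in Hz (the OCT A-scan rate).
#' @param delay Quiet time before stimulus onset, in seconds (default 0).
#'   A nonzero delay leaves a pre-stimulus baseline in every derived trace.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(peak_force = 0.1208, total_duration = 0.032,
                       rise_time = (total_duration - delay) / 2,
                       shape = c("raised_cosine", "gamma"),
                       sample_rate = 50000, delay = 0) {
  shape <- match.arg(shape)
  check_scalar(peak_force, "peak_force", positive = TRUE)
  check_scalar(total_duration, "total_duration", positive = TRUE)
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  check_scalar(delay, "delay", nonneg = TRUE)
  check_scalar(rise_time, "rise_time", positive = TRUE)
  if (delay >= total_duration)
    cp_stop("corneapuff_invalid_spec", "delay must be < total_duration")
  if (rise_time >= total_duration - delay)
    cp_stop("corneapuff_invalid_spec",
            "rise_time must be < total_duration - delay")
  structure(list(peak_force = peak_force, total_duration = total_duration,
                 rise_time = rise_time, shape = shape,
                 sample_rate = sample_rate, delay = delay),
            class = "pulse_spec")
}

#' Generate an air-puff force pulse
#'
#' Renders a [pulse_spec()] as a sampled [force_trace()]. The trace has
#' `round(total_duration * sample_rate)` samples with endpoints pinned to the
#' record boundaries, is nonnegative, starts and ends at zero force, and
#' attains `peak_force` at the nominal peak time (within one sample).
#'
#' @param spec A [pulse_spec()].
#' @return A [force_trace()].
#' @examples
#' p <- generate_force_pulse(pulse_spec())
#' length(p$time)   # 1600
#' max(p$force)     # 0.1208 N
#' @export
generate_force_pulse <- function(spec) {
  if (!inherits(spec, "pulse_spec"))
    cp_stop("corneapuff_invalid_spec", "spec must be a pulse_spec")
  n <- round(spec$total_duration * spec$sample_rate)
  if (n < 4L)
    cp_stop("corneapuff_invalid_spec", "pulse too short: %d samples", n)
  t <- seq(0, spec$total_duration, length.out = n)
  tau <- t - spec$delay                     # time since stimulus onset
  active <- spec$total_duration - spec$delay
  tr <- spec$rise_time
  f <- numeric(n)
  if (spec$shape == "raised_cosine") {
    up <- tau >= 0 & tau <= tr
    dn <- tau > tr & tau <= active
    f[up] <- 0.5 * (1 - cos(pi * tau[up] / tr))
    f[dn] <- 0.5 * (1 + cos(pi * (tau[dn] - tr) / (active - tr)))
  } else {
    on <- tau > 0
    u <- tau[on] / tr
    f[on] <- u^2 * exp(2 * (1 - u))
    taper_from <- 0.9 * spec$total_duration
    tp <- t > taper_from
    f[tp] <- f[tp] * 0.5 *
      (1 + cos(pi * (t[tp] - taper_from) / (spec$total_duration - taper_from)))
    f[n] <- 0
  }
  force_trace(t, spec$peak_force * f)
}
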