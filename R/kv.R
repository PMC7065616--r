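#' Kelvin-Voigt parameters
#'
#' A massless Kelvin-Voigt element — spring of stiffness `k` in parallel with
#' a dashpot of damping `c` — is the minimal linear viscoelastic model of the
#' corneal apex response to the air puff. An inertial (mass) term is out of
#' scope.
#'
#' @param k Coefficient of elasticity in N/m (> 0).
#' @param c Damping coefficient in N s/m (>= 0).
#' @return An object of class `kv_params`.
#' @export
kv_params <- function(k, c = 0) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    cp_stop("corneapuff_invalid_parameter", "k must be a finite scalar > 0")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0)
    cp_stop("corneapuff_invalid_parameter", "c must be a finite scalar >= 0")
  structure(list(k = k, c = c), class = "kv_params")
}

#' Kelvin-Voigt displacement response
#'
#' Solves `c x'(t) + k x(t) = F(t)` with `x(0) = 0` by an exact per-step
#' exponential integrator: within each sampling interval the force is taken
#' as linear between its endpoint samples, for which the ODE has a closed-form
#' update. The scheme is unconditionally stable and introduces no tolerance
#' parameters; for `c = 0` the algebraic elastic solution `x = F / k` is
#' returned. Time sampling may be non-uniform.
#'
#' @param force A [force_trace()] in newtons.
#' @param params A [kv_params()].
#' @return A [displacement_trace()] in micrometers, inward positive.
#' @examples
#' f <- generate_force_pulse(pulse_spec())
#' x <- kv_response(f, kv_params(k = 150, c = 0.12))
#' max(x$x)  # peak apex displacement, um
#' @export
kv_response <- function(force, params) {
  if (!inherits(force, "force_trace"))
    cp_stop("corneapuff_invalid_trace", "force must be a force_trace")
  if (!inherits(params, "kv_params"))
    cp_stop("corneapuff_invalid_parameter", "params must be kv_params")
  t <- force$time
  fv <- force$force
  k <- params$k
  cc <- params$c
  if (cc == 0) {
    x_m <- fv / k
  } else {
    n <- length(t)
    x_m <- numeric(n)
    a <- k / cc
    dt <- diff(t)
    slope <- diff(fv) / dt
    # particular solution for F = F_i + s*tau:  x_p(tau) = (F_i + s tau)/k - s c/k^2
    for (i in seq_len(n - 1L)) {
      s <- slope[i]
      xp0 <- fv[i] / k - s * cc / k^2
      xp1 <- fv[i + 1L] / k - s * cc / k^2
      x_m[i + 1L] <- xp1 + (x_m[i] - xp0) * exp(-a * dt[i])
    }
  }
  displacement_trace(t, 1e6 * x_m)
}

#' Sweep a Kelvin-Voigt parameter
#'
#' Simulates the apex response to one fixed force pulse for a family of `k`
#' or `c` values and tabulates the hysteresis descriptors of each response,
#' mirroring the numerical exploration of how stiffness (an intraocular
#' pressure proxy) and damping shape the loop.
#'
#' @param force A [force_trace()].
#' @param base A [kv_params()] providing the parameter that is held fixed.
#' @param which `"k"` or `"c"` — the parameter swept.
#' @param values Numeric vector of parameter values (positive for `k`,
#'   nonnegative for `c`).
#' @return A list with `traces` (list of [displacement_trace()]) and
#'   `metrics` (data.frame: one row per value with mad_um, ha_j, hr_pct,
#'   s_sec_n_per_m, s_low_n_per_m, s_high_n_per_m; slope columns are NA where
#'   a window is undefined for that loop).
#' @export
sweep_parameter <- function(force, base, which = c("k", "c"), values) {
  which <- match.arg(which)
  if (length(values) == 0L)
    cp_stop("corneapuff_invalid_spec", "values must be non-empty")
  if (which == "k" && any(values <= 0))
    cp_stop("corneapuff_invalid_spec", "k values must be > 0")
  if (which == "c" && any(values < 0))
    cp_stop("corneapuff_invalid_spec", "c values must be >= 0")
  traces <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- if (which == "k") kv_params(values[i], base$c)
         else kv_params(base$k, values[i])
    x <- kv_response(force, p)
    traces[[i]] <- x
    m <- compute_all_metrics(x, force)
    rows[[i]] <- data.frame(
      value = values[i], mad_um = m$mad, ha_j = m$ha, hr_pct = m$hr,
      s_sec_n_per_m = m$s_sec, s_low_n_per_m = m$s_low,
      s_high_n_per_m = m$s_high
    )
  }
  metrics <- do.call(rbind, rows)
  names(metrics)[1] <- which
  list(traces = traces, metrics = metrics)
}
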