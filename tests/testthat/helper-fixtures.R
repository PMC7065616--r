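# Shared fixtures: analytic loops with closed-form descriptors, random
# monotone loops for the area-oracle property, and a small default phantom.

# Loop with linear loading F = 0.12 * x[mm] and quadratic unloading
# F = 0.12 * x[mm]^2, MAD = 1 mm. Closed forms: loading energy 6e-5 J,
# unloading energy 4e-5 J, HA = 2e-5 J, HR = 100/3 %.
analytic_loop <- function(n = 10000) {
  n2 <- n %/% 2
  x_load <- seq(0, 1000, length.out = n2)
  x_unl <- seq(1000, 0, length.out = n2)[-1]
  xx <- c(x_load, x_unl)
  ff <- c(0.12 * x_load / 1000, 0.12 * (x_unl / 1000)^2)
  t <- seq_along(xx) * 1e-3
  build_hysteresis(displacement_trace(t, xx), force_trace(t, ff))
}

# Piecewise-bilinear loading (slopes s1 then s2 N/m, break at x_break um),
# straight-line unloading back to the origin.
bilinear_loop <- function(s1 = 44, s2 = 82, mad = 1000, x_break = 500,
                          n = 4000) {
  n2 <- n %/% 2
  x_load <- seq(0, mad, length.out = n2)
  f_load <- ifelse(x_load <= x_break, s1 * x_load * 1e-6,
                   s1 * x_break * 1e-6 + s2 * (x_load - x_break) * 1e-6)
  x_unl <- seq(mad, 0, length.out = n2)[-1]
  f_unl <- f_load[n2] * x_unl / mad * 0.5
  xx <- c(x_load, x_unl)
  ff <- c(f_load, f_unl)
  t <- seq_along(xx) * 1e-3
  build_hysteresis(displacement_trace(t, xx), force_trace(t, ff))
}

# Random closed loop whose loading and unloading phases are each strictly
# monotone in x; forces are random nonnegative, endpoints pinned so the loop
# closes at the origin.
random_monotone_loop <- function() {
  n_l <- sample(10:60, 1)
  n_u <- sample(10:60, 1)
  mad <- stats::runif(1, 100, 1500)
  x_load <- mad * sort(stats::runif(n_l, 0.01, 1))
  x_load <- c(0, x_load[-n_l], mad)
  f_load <- c(0, stats::runif(n_l, 0, 0.15))
  x_unl <- c(sort(stats::runif(n_u - 1, 0.001, 0.999), decreasing = TRUE) * mad, 0)
  f_unl <- c(stats::runif(n_u - 1, 0, 0.15), 0)
  xx <- c(x_load, x_unl)
  ff <- c(f_load, f_unl)
  t <- seq_along(xx) * 1e-3
  build_hysteresis(displacement_trace(t, xx), force_trace(t, ff))
}

# Independent area oracle: loading area minus unloading area, both taken
# ascending in x via the trapezoid rule (x in meters).
eq1_area <- function(h) {
  li <- seq_len(h$split_index)
  ui <- h$split_index:length(h$x)
  trapz2 <- function(x, y) {
    n <- length(x)
    sum((y[-1] + y[-n]) * diff(x)) / 2
  }
  a_load <- trapz2(h$x[li] * 1e-6, h$F[li])
  a_unl <- trapz2(rev(h$x[ui]) * 1e-6, rev(h$F[ui]))
  a_load - a_unl
}

default_pulse <- function() pulse_spec(delay = 0.004)

# Phantom + rendered scan + truth for recovery tests.
make_phantom_record <- function(k = 150, c = 0.12, speckle = 0.5, seed = 1,
                                compression = 0.03, axial_pitch = 8,
                                depth_px = 448) {
  f <- generate_force_pulse(default_pulse())
  ph <- phantom_spec(kv = kv_params(k, c), compression_fraction = compression,
                     speckle_contrast = speckle, seed = seed)
  x <- simulate_eye_response(f, ph)
  m <- render_mscan(x, ph, axial_pitch = axial_pitch, depth_px = depth_px)
  list(force = f, phantom = ph, x = x, mscan = m, baseline = 1:190)
}

# Noiseless two-band image with flat surfaces at fixed rows (0-based).
flat_band_mscan <- function(ant_row = 50, post_row = 150, n = 64,
                            depth_px = 256, pitch = 10, sigma_px = 2) {
  rows <- seq_len(depth_px) - 1
  col <- exp(-(rows - ant_row)^2 / (2 * sigma_px^2)) +
    exp(-(rows - post_row)^2 / (2 * sigma_px^2))
  mscan(matrix(rep(col, n), ncol = n), axial_pitch = pitch,
        ascan_rate = 50000, t0 = 0)
}
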